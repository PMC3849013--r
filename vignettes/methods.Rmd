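---
title: "Weighted logical rules for supervised regulatory-network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted logical rules for supervised regulatory-network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Given a partially known directed network of transcriptional regulations over
a set of genes, together with heterogeneous descriptors of those genes —
expression levels under perturbation of a regulator, Gene Ontology (GO)
biological-process annotations, subcellular localization of the protein
products, physical protein–protein interactions, and chromosomal locations —
`regmln` learns a binary classifier that assigns *Regulation* / *No
regulation* to an ordered gene pair `(regulator, regulee)`. The classifier
can then complete the network: score unlabeled pairs among the known genes,
or pairs connecting the known genes to a new candidate set.

The package's model is a **non-recursive Markov Logic Network (MLN)**: a set
of Horn rules concluding on a single target predicate `Regulates(g1,g2)`,
each carrying a real weight. The rules are symbolic and readable — e.g.

```
Processbio(g2,Cell_proliferation) ^ Processbio(g1,Negative_regulation_of_cell_proliferation) => Regulates(g1,g2)
```

— which is the point of the approach compared with black-box pairwise
classifiers: the biologist can inspect what evidence drives each prediction.

## First-order representation

All knowledge is expressed as ground atoms over a typed vocabulary
(`logic_core` and `fol_encoding` in package terms):

* `Expwt(G,L)`, `Expsiid2(G,L)`, `Expprcid2(G,L)` — the discretized
  expression level `L` of gene `G` in the wild-type, knock-down and
  over-expression conditions. Levels come from **equal-width discretization
  into 5 bins**, fitted per condition over the observed value range, with
  half-open bins and the maximum assigned to the last bin. Per-condition
  fitting was chosen because the three conditions come from different
  arrays, so their absolute ranges are not comparable; the assignment is
  invariant under affine rescaling of a condition.
* `Expmore/Expless/Expsame(G,Exp)` — direction of expression change of `G`
  between the wild type and condition `Exp`. The numeric criterion is a
  fold change at threshold 1.5 (the conventional differential-expression
  cutoff): ratio above 1.5 is *more*, below 1/1.5 is *less*, otherwise
  *same*. Exactly one of the three holds per `(gene, condition)`.
* `Processbio(G,Proc)`, `ProtLoccell(G,Loc)` — GO process and subcellular
  localization, as opaque constants (no ontology propagation).
* `Inteprot(G1,G2)` — physical interaction of the protein products, emitted
  in both orders since the relation is unordered.
* `Samechro(G1,G2)`, `Sameband(G1,G2)` — chromosomal proximity derived from
  chromosome and band locations: same chromosome, and overlapping band
  intervals (arms compared lexically `p < q`, bands numerically).

Constants start with an upper-case character and variables with a
lower-case one; identifiers from input tables are case-normalized at
ingest with a warning rather than rejected. Evidence databases are
**closed-world**: a ground atom not asserted is false. This matches the
practice of the ILP and MLN systems this design follows, whose input is a
set of true ground facts. `Regulates` atoms are routed to the label set and
never into the evidence, so the learners cannot leak labels through the
background knowledge.

Grounding is typed (a level constant never instantiates a gene variable)
and deterministic (lexicographic enumeration), and self-pairs `(g, g)` are
part of the candidate space — autoregulation is real, and the candidate
arithmetic of the study protocols (a universe of `n` genes has `n^2`
ordered pairs) only works with self-pairs included.

## Rule induction

Structure learning is a classic ILP covering loop (`rule_induction`):

1. take the first positive example not yet covered;
2. **saturate** it into its bottom clause: the most specific clause covering
   it, with gene constants variabilized consistently and all evidence atoms
   within `depth` hops of the seed pair's genes (default depth 1);
3. search **top-down, best-first** in the subsumption lattice bounded by the
   bottom clause, adding one connected bottom-clause atom at a time;
4. keep the best admissible clause, remove the positives it covers, prune
   theory clauses theta-subsumed by the new clause;
5. repeat until all positives are covered or no admissible clause exists.

The clause score is coverage `P - N` (covered positives minus covered
negatives), evaluated against the positives *not yet covered* by the
theory, which is what makes the sequential covering converge on distinct
rules rather than rediscovering the dominant one. Ties break towards
shorter bodies, then a deterministic serialization order. Non-gene
arguments (levels, processes, locations) stay as ground constants in rule
bodies; that is the shape of every credible regulatory rule here, and it
keeps the search space finite.

Admissibility of a kept clause is governed by a **minimum training
precision** `min_acc = 0.8` rather than by an absolute cap on covered
negatives. The negatives in this problem are *unlabeled* pairs: some of
them are true regulations that have not been curated yet (the network
update study is built on exactly this fact). An absolute noise budget makes
a strong rule inadmissible the moment a handful of its matches happen to be
sampled not-yet-known regulations, with a cliff-edge collapse of the
theory; a precision threshold scales with the clause's coverage and
degrades gracefully. The absolute budget (`noise`) is still available for
users who want classic consistency, and a degenerate bias
(`noise = |negatives|`, `min_acc = 0`) reproduces the textbook behaviour of
returning the single most-general rule.

The search is budgeted: at most `node_budget = 200` node expansions per
seed, stopping early after `patience = 50` expansions without improvement,
and at most `max_failures = 10` hopeless seeds per covering run. These are
desk-scale determinizations of an anytime search; on the synthetic
benchmarks below the best clause is typically found within the first few
dozen expansions. Clause bodies are capped at `l_max = 5` atoms and
`v_max = 6` distinct variables; learned rules of up to five predicates are
the regime this method is designed for.

## Weight learning and inference

Because rules are non-recursive (the target predicate never appears in a
body), the query atoms are conditionally independent given the evidence,
and inference is closed-form. For query `Y_j` and clause `i`, let `n1_ij`
and `n0_ij` be the numbers of true groundings whose head is exactly `Y_j`
with `Y_j` clamped true and false. The conditional probability is the
two-exponential ratio

$$
P(Y_j = 1 \mid x, w)
  = \frac{e^{\sum_i w_i\, n1_{ij}}}
         {e^{\sum_i w_i\, n0_{ij}} + e^{\sum_i w_i\, n1_{ij}}}
  = \sigma\!\Big(\sum_i w_i\,(n1_{ij} - n0_{ij})\Big),
$$

the logistic function of the weighted body-true count gap; the package
evaluates the logistic form on the log scale for stability and keeps the
two-term ratio as the reference formula in its tests, where it is verified
against exhaustive world enumeration on small knowledge bases.

Weights maximize the l2-penalized conditional log-likelihood

$$
f(w) = \sum_j \log P(Y_j = y_j \mid x, w) - \lambda \lVert w \rVert_2^2,
$$

with `lambda` multiplying the squared norm exactly as written (not
`lambda/2`). The objective is concave; optimization uses limited-memory
BFGS from `w = 0`, so weight learning is deterministic and all ensemble
variability comes from negative sampling. Grounding counts do not depend on
`w` and are cached, so a whole `lambda` grid costs one counting pass. The
default grid is `{20, 50, 100, 500, 750, 1000}`; no automatic selection
rule is imposed — `lambda` is exposed as configuration, and the study
runners report results per grid value. Useful values are large (tens to
thousands): the count gaps are small integers, so weak regularization
overfits the sampled negatives.

## Class imbalance: asymmetric bagging

Known regulations are rare relative to the `n^2` candidate space, so the
package trains **B balanced base models** (default 30), each on all
positives plus an equal-size uniform subsample (without replacement) of the
negative pool, and averages their predicted probabilities. SVM decision
values are calibrated through a logistic link before averaging so that
heterogeneous base learners emit scores on a common `[0, 1]` scale. When a
hard decision is needed, the threshold is chosen to maximize the F1 measure
averaged over per-bag stratified 2/3–1/3 train/validation splits, on a grid
from 0 to 1 in steps of 0.01 (ties to the smallest threshold).

Negative pools are explicit about exclusions: in the network-update
protocol, negatives are drawn from the complement of the *earlier*
positives minus all *later* positives, so future positives never pollute
training negatives.

## The pairwise-kernel SVM baseline

The baseline scores ordered pairs with a soft-margin SVM on the
**asymmetric tensor-product pairwise kernel**
`K((G1,G2),(G3,G4)) = k(G1,G3) · k(G2,G4)`: pairs are similar when their
regulator candidates are similar *and* their regulee candidates are
similar, which preserves edge orientation. Six Gaussian base kernels are
built, one per descriptor source; each bandwidth maximizes the Shannon
entropy of the off-diagonal kernel values (20 equal-width bins on `[0, 1]`,
15 log-spaced candidates around the median pairwise distance) — a
saturated kernel near all-0 or all-1 carries no information, and the
entropy criterion lands between the extremes. Two combinations are
provided: averaging the six pairwise kernels (`pairwise_sum`) and the
tensor product of the averaged base kernel (`sum`); the two coincide
exactly when all bases are equal and differ in general (mean of products
versus product of means). The per-source feature vectorizations (raw
condition values, log fold changes, binary indicator vectors, chromosome
indicator plus band midpoint) are this package's documented stand-ins; the
sources themselves are fixed, their vectorization was open.

## Evaluation

`roc_auc()` integrates the ROC curve by trapezoid over all distinct score
cuts with ties grouped; this equals the tie-corrected Mann–Whitney
statistic, which the tests assert to 1e-10. `pr_auc()` standardizes the
precision–recall curve by nonlinear interpolation: between consecutive
achievable confusion points the true-positive count advances one unit at a
time with false positives interpolated linearly in it, so precision follows
the attainable hyperbolic path rather than an optimistic straight line; the
curve is anchored by extending the first achievable precision to recall 0,
and a constant scorer's area is exactly the class prevalence. Comparisons
of AUCs between methods are delegated to the established
Mann–Whitney-based test in `pROC` (`compare_auc()`), not re-derived.

Three study protocols wrap these metrics:

1. **Balanced cross-validation** (`run_study1`): 30 balanced negative
   subsamples, stratified 10-fold cross-validation each, AUCs on
   predictions pooled within a sample (per-fold precision–recall on a
   handful of positives is too unstable to average), reported mean ± sd.
2. **Network update** (`run_study2`): train on the earlier snapshot with
   asymmetric bagging, select the F1 threshold, report the true positive
   rate on the newly discovered regulations (a positives-only test set by
   construction).
3. **New-gene completion** (`run_study3`): train within the known universe,
   score every ordered pair crossing to a disjoint new gene set in both
   directions, and report AUCs on that full, unbalanced candidate space.

## The synthetic benchmark

Real curated regulatory datasets of this shape are proprietary, so the
package ships a generator (`generate_dataset()`) whose output *is* the
test bed. It draws a gene universe with the full attribute vocabulary and
plants a ground-truth network defined by known Horn rules: every ordered
pair whose attributes satisfy a planted rule's body becomes a true edge
with probability `p_rule`, any other pair with probability
`background_edge_rate`. The two default planted rules exercise both
information pathways — a symbolic GO-process rule and a
discretized-expression rule — mirroring the shapes of credible regulatory
rules (process-to-process implication; specific level combinations under
knock-down and over-expression). Defaults: 50 training genes, 15 new-universe
genes, 12 processes (the two rule processes carried with probability 0.15
each), 6 compartments, 10 chromosomes, PPI rate 0.03, `p_rule = 1`, no
background edges, no attribute noise. A third of the within-universe edges
is withheld from the earlier network snapshot to emulate a curation update
— over a couple of years a curated network of this size typically grows by
a few tens of percent. Two genes pin the expression range ends per condition so that the
equal-width bin edges fall exactly on the planted level boundaries;
without such anchors the recovered levels would drift with the sampled
range and the expression rule would be blurred at the bin edges.

Attribute noise re-randomizes a gene's levels, process set or localization
with the given probability *after* edges are planted, decoupling evidence
from labels the way measurement noise and annotation staleness do. What
the generator does **not** emulate: realistic expression dynamics,
ontology structure among processes, degree heterogeneity of real
regulatory networks, and correlated annotation errors. Passing the
synthetic benchmarks therefore shows the pipeline recovers planted logical
structure under its own noise model — not that it would reach any
particular accuracy on a real curated network.

Problem sizes used by the shipped end-to-end checks: 50 training genes and
15 new genes; rule recovery and held-out ranking on the noise-free
configuration; the balanced cross-validation protocol with 5 negative
subsamples and the new-gene protocol with 5 generator seeds and 5 bags at
`p_rule = 0.9`, attribute noise 0.1. These sizes keep a full run on one
core in the minutes range while leaving the planted structure clearly
learnable.

## Numerical choices and degenerate inputs

* Bin assignment clips values outside the fitted range into the extreme
  bins; a constant expression column is an error (zero-width bins).
* A zero wild-type value with a positive perturbed value counts as *more*;
  two zeros as *same*.
* `select_threshold` falls back to 0.5 with a warning when F1 is zero
  everywhere; `select_bandwidth` warns and returns the median candidate for
  a degenerate (all-identical) feature view.
* Kernel matrices are accepted as PSD when the smallest eigenvalue is no
  lower than `-1e-8` times the largest magnitude.
* An empty induced theory is legal: the MLN then scores every pair 0.5.
* Weight optimization warns and returns best-so-far weights if the
  iteration cap is hit.

## Known limitations

* Negation in rule bodies is not supported; no printed rule in the method's
  regime uses it, and the closed-world evidence would make negated
  descriptors ambiguous between "false" and "unmeasured".
* Gene products are identified with their genes (one name per gene); a
  `CodesFor` indirection would be needed for multi-product genes.
* The ILP search is a budgeted, deterministic approximation of a complete
  bounded search; with adversarial data the kept clause can be suboptimal
  within its bottom clause's lattice.
* Exact inference relies on non-recursivity; rules with `Regulates` in the
  body are rejected rather than approximated.
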