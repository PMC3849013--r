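#' Language bias for rule induction
#'
#' Declarative restrictions on learnable rules: the head predicate is fixed
#' to `Regulates`; the body draws from the evidence predicates. `l_max`
#' bounds the number of body atoms (rules of up to five predicates), `v_max`
#' the number of distinct variables, `depth` the saturation depth (how many
#' hops of shared constants the bottom clause may follow from the seed
#' pair), `noise` the number of negative examples a kept clause may cover,
#' and `min_pos` the minimum positive coverage of a kept clause.
#'
#' @param l_max Maximum body atoms per clause (default 5).
#' @param v_max Maximum distinct variables per clause (default 6).
#' @param depth Saturation depth (default 1).
#' @param noise Maximum covered negatives for an admissible clause. The
#'   default is effectively unlimited (1e7): negatives here are unlabeled
#'   pairs, some of which are true but not-yet-known regulations, so
#'   admissibility is governed by the precision criterion `min_acc` rather
#'   than by exact consistency; set a finite value to recover the classic
#'   absolute budget.
#' @param min_acc Minimum training precision `P / (P + N)` of an admissible
#'   clause (default 0.8). Unlike an absolute noise budget this criterion
#'   scales with the clause's coverage, so a strong rule is not discarded
#'   because a handful of its matches are not-yet-known regulations.
#' @param min_pos Minimum covered positives for an admissible clause (default 2).
#' @param node_budget Maximum node expansions of the top-down search per seed
#'   (default 200).
#' @param patience Stop a seed's search after this many consecutive
#'   expansions without improvement of the best admissible clause (default
#'   50); keeps the budgeted search from wandering plateaus once the best
#'   clause has stabilized.
#' @param max_failures Stop the covering loop after this many seeds fail to
#'   yield an admissible clause (default 10); the remaining uncovered
#'   positives are logged as uncoverable. Bounds the total search effort on
#'   noisy samples where many seeds are individually hopeless.
#' @param scoring Clause score: `"coverage"` (P - N, the default),
#'   `"accuracy"` (P / (P + N)) or `"laplace"` ((P + 1) / (P + N + 2)).
#' @param max_bottom Cap on the number of body atoms retained in a bottom
#'   clause (default 150; atoms are kept in deterministic serialization order).
#' @return A list of class `language_bias`.
#' @export
language_bias <- function(l_max = 5L, v_max = 6L, depth = 1L, noise = 10000000L,
                          min_acc = 0.8, min_pos = 2L, node_budget = 200L,
                          patience = 50L, max_failures = 10L,
                          scoring = c("coverage", "accuracy", "laplace"),
                          max_bottom = 150L) {
  scoring <- match.arg(scoring)
  stopifnot(l_max >= 1L, v_max >= 2L, depth >= 1L, noise >= 0L, min_pos >= 1L,
            min_acc >= 0, min_acc <= 1)
  structure(list(l_max = as.integer(l_max), v_max = as.integer(v_max),
                 depth = as.integer(depth), noise = as.integer(noise),
                 min_acc = min_acc, min_pos = as.integer(min_pos),
                 node_budget = as.integer(node_budget),
                 patience = as.integer(patience),
                 max_failures = as.integer(max_failures), scoring = scoring,
                 max_bottom = as.integer(max_bottom)),
            class = "language_bias")
}

regulates_atom <- function(regulator, regulee) {
  atom("Regulates", c(regulator, regulee))
}

# head substitution for an example pair
head_subst <- function(cl, example) {
  stats::setNames(example$args, cl$head$args)
}

#' Does a clause cover a labeled example?
#'
#' A clause covers the ground example `Regulates(A,B)` when some
#' sort-respecting substitution maps its head onto the example and every
#' body atom, under that substitution (extended over any remaining body
#' variables), is true in the evidence database.
#'
#' @param cl An `mln_clause` with head predicate `Regulates`.
#' @param example A ground `Regulates` atom (or its serialization).
#' @param db An `evidence_db`.
#' @return Logical scalar.
#' @export
covers <- function(cl, example, db) {
  if (is.character(example)) example <- parse_atom(example, db$sigs)
  if (example$pred != cl$head$pred) {
    stop("example predicate (", example$pred, ") does not match clause head (",
         cl$head$pred, ")")
  }
  hv <- cl$head$args
  subst <- character(0)
  for (i in seq_along(hv)) {
    if (is_variable_term(hv[i])) {
      if (hv[i] %in% names(subst) && subst[[hv[i]]] != example$args[i]) {
        return(FALSE)
      }
      subst[hv[i]] <- example$args[i]
    } else if (hv[i] != example$args[i]) {
      return(FALSE)
    }
  }
  satisfy_exists(cl$body, subst, db)
}

#' Saturate a seed example into its bottom clause
#'
#' Builds the most specific clause covering the seed under the bias: the
#' head is the seed with its gene constants variabilized (`g1`, `g2`), and
#' the body collects every evidence atom reachable from the seed's constants
#' within `bias$depth` hops, with gene constants variabilized consistently
#' (same constant, same variable) and non-gene constants kept ground.
#'
#' @param seed A ground positive `Regulates` atom (or serialization).
#' @param db An `evidence_db`.
#' @param bias A [language_bias()].
#' @return A list with elements `clause` (the bottom clause), `seed`, and
#'   `var_map` (constant -> variable), of class `bottom_clause`.
#' @export
saturate <- function(seed, db, bias = language_bias()) {
  if (is.character(seed)) seed <- parse_atom(seed, db$sigs)
  stopifnot(seed$pred == "Regulates", is_ground(seed))
  genes <- db_constants(db, "gene")
  if (!all(seed$args %in% genes)) {
    stop("seed gene(s) absent from evidence database: ",
         paste(setdiff(seed$args, genes), collapse = ", "))
  }
  var_map <- stats::setNames(c("g1", "g2"), seed$args)
  if (seed$args[1] == seed$args[2]) var_map <- var_map[1]

  frontier <- unique(seed$args)
  seen_atoms <- character(0)
  body <- list()
  for (d in seq_len(bias$depth)) {
    new_consts <- character(0)
    for (p in setdiff(names(db$index), "Regulates")) {
      mat <- db$index[[p]]
      sorts <- db$sigs[[p]]
      gene_cols <- which(sorts == "gene")
      if (length(gene_cols) == 0L) next
      hit <- rep(FALSE, nrow(mat))
      for (j in gene_cols) hit <- hit | mat[, j] %in% frontier
      for (r in which(hit)) {
        key <- paste0(p, "(", paste(mat[r, ], collapse = ","), ")")
        if (key %in% seen_atoms) next
        seen_atoms <- c(seen_atoms, key)
        args <- mat[r, ]
        for (j in gene_cols) {
          const <- args[j]
          if (!const %in% names(var_map)) {
            var_map[const] <- paste0("g", length(var_map) + 1L)
            new_consts <- c(new_consts, const)
          }
          args[j] <- var_map[[const]]
        }
        body[[length(body) + 1L]] <- atom(p, args)
      }
    }
    frontier <- unique(new_consts)
    if (length(frontier) == 0L) break
  }
  ord <- order(vapply(body, format, character(1)), method = "radix")
  body <- body[ord]
  if (length(body) > bias$max_bottom) body <- body[seq_len(bias$max_bottom)]
  head <- atom("Regulates", unname(var_map[seed$args]))
  structure(list(clause = horn_clause(head, body), seed = seed,
                 var_map = var_map),
            class = "bottom_clause")
}

#' @export
print.bottom_clause <- function(x, ...) {
  cat("<bottom_clause> seed ", format(x$seed), ", ",
      length(x$clause$body), " body atoms\n", sep = "")
  invisible(x)
}

#' Refine a clause within the bottom clause's search space
#'
#' Each child extends the clause by exactly one body atom drawn from the
#' bottom clause's body, provided the atom shares a variable with the clause
#' (head variables count), the body length stays within `l_max` and the
#' number of distinct variables within `v_max`. Children are deduplicated up
#' to variable renaming.
#'
#' @param cl An `mln_clause` generalizing `bottom`.
#' @param bottom A `bottom_clause` from [saturate()].
#' @param bias A [language_bias()].
#' @return List of `mln_clause` children (possibly empty).
#' @export
refine <- function(cl, bottom, bias = language_bias()) {
  if (length(cl$body) >= bias$l_max) return(list())
  have <- vapply(cl$body, format, character(1))
  vars <- clause_vars(cl)
  out <- list()
  seen <- character(0)
  for (a in bottom$clause$body) {
    key <- format(a)
    if (key %in% have) next
    avars <- a$args[is_variable_term(a$args)]
    if (!any(avars %in% vars)) next
    if (length(union(vars, avars)) > bias$v_max) next
    child <- horn_clause(cl$head, c(cl$body, list(a)))
    ckey <- canonical_clause_string(child)
    if (ckey %in% seen) next
    seen <- c(seen, ckey)
    out[[length(out) + 1L]] <- child
  }
  out
}

#' Score a clause by its coverage
#'
#' The default score is coverage `P - N`, where `P` and `N` are the numbers
#' of covered positive and negative examples; `"accuracy"` and `"laplace"`
#' variants are available through the bias.
#'
#' @param cl An `mln_clause`.
#' @param positives,negatives Data frames with columns `regulator`,
#'   `regulee`.
#' @param db An `evidence_db`.
#' @param scoring One of `"coverage"`, `"accuracy"`, `"laplace"`.
#' @return Numeric score (higher is better).
#' @export
score_clause <- function(cl, positives, negatives, db,
                         scoring = "coverage") {
  P <- sum(vapply(seq_len(nrow(positives)), function(i) {
    covers(cl, regulates_atom(positives$regulator[i], positives$regulee[i]), db)
  }, logical(1)))
  N <- sum(vapply(seq_len(nrow(negatives)), function(i) {
    covers(cl, regulates_atom(negatives$regulator[i], negatives$regulee[i]), db)
  }, logical(1)))
  clause_score(P, N, scoring)
}

clause_score <- function(P, N, scoring) {
  switch(scoring,
         coverage = P - N,
         accuracy = if (P + N == 0) 0 else P / (P + N),
         laplace = (P + 1) / (P + N + 2),
         stop("unknown scoring: ", scoring))
}

#' Test theta-subsumption between two function-free Horn clauses
#'
#' Clause `c1` theta-subsumes `c2` when a substitution of `c1`'s variables
#' exists mapping its head onto `c2`'s head and its body into a subset of
#' `c2`'s body. A subsuming clause is at least as general, so subsumed
#' clauses are redundant in a theory.
#'
#' @param c1,c2 `mln_clause` objects.
#' @return Logical scalar.
#' @export
theta_subsumes <- function(c1, c2) {
  # unify terms t1 (from c1, may be var) with t2 (term of c2, kept fixed)
  unify_args <- function(args1, args2, theta) {
    for (i in seq_along(args1)) {
      t1 <- args1[i]; t2 <- args2[i]
      if (is_variable_term(t1)) {
        if (t1 %in% names(theta)) {
          if (theta[[t1]] != t2) return(NULL)
        } else {
          theta[t1] <- t2
        }
      } else if (t1 != t2) {
        return(NULL)
      }
    }
    theta
  }
  theta0 <- unify_args(c1$head$args, c2$head$args, character(0))
  if (is.null(theta0)) return(FALSE)
  body2 <- c2$body
  rec <- function(atoms, theta) {
    if (length(atoms) == 0L) return(TRUE)
    a <- atoms[[1]]
    for (b in body2) {
      if (b$pred != a$pred) next
      th <- unify_args(a$args, b$args, theta)
      if (!is.null(th) && rec(atoms[-1], th)) return(TRUE)
    }
    FALSE
  }
  rec(c1$body, theta0)
}

#' Two clauses are equivalent up to variable renaming?
#'
#' @param c1,c2 `mln_clause` objects.
#' @return `TRUE` iff each theta-subsumes the other.
#' @export
clause_equivalent <- function(c1, c2) {
  theta_subsumes(c1, c2) && theta_subsumes(c2, c1)
}

# --- coverage bit-vectors over an example table ------------------------------

# head substitutions per example (NULL when the head cannot bind, e.g. a
# Regulates(g1,g1) head against a non-self pair)
example_head_substs <- function(head, examples) {
  lapply(seq_len(nrow(examples)), function(i) {
    bind_head(head, examples$regulator[i], examples$regulee[i])
  })
}

# examples: data.frame(regulator, regulee). For a body atom of the bottom
# clause whose variables are all head variables, substitution by the example
# pair grounds it completely, so coverage is a membership test; otherwise the
# marginal coverage requires an existential match.
atom_coverage <- function(a, head_substs, db, head_vars) {
  n <- length(head_substs)
  out <- logical(n)
  simple <- all(a$args[is_variable_term(a$args)] %in% head_vars)
  for (i in seq_len(n)) {
    subst <- head_substs[[i]]
    if (is.null(subst)) next
    if (simple) {
      out[i] <- db_contains(db, substitute_atom(a, subst))
    } else {
      out[i] <- satisfy_exists(list(a), subst, db)
    }
  }
  out
}

# exact coverage of a clause on the examples flagged TRUE in `mask`
clause_coverage_exact <- function(cl, examples, db, mask = NULL) {
  n <- nrow(examples)
  if (is.null(mask)) mask <- rep(TRUE, n)
  out <- logical(n)
  for (i in which(mask)) {
    out[i] <- covers(cl, regulates_atom(examples$regulator[i],
                                        examples$regulee[i]), db)
  }
  out
}

# best-first top-down search below one bottom clause; returns the best
# admissible clause or NULL
search_best_clause <- function(bottom, pos, neg, db, bias) {
  batoms <- bottom$clause$body
  nb <- length(batoms)
  head <- bottom$clause$head
  head_vars <- unique(head$args[is_variable_term(head$args)])
  hs_pos <- example_head_substs(head, pos)
  hs_neg <- example_head_substs(head, neg)
  cov_pos_atoms <- lapply(batoms, atom_coverage, head_substs = hs_pos,
                          db = db, head_vars = head_vars)
  cov_neg_atoms <- lapply(batoms, atom_coverage, head_substs = hs_neg,
                          db = db, head_vars = head_vars)
  simple <- vapply(batoms, function(a) {
    all(a$args[is_variable_term(a$args)] %in% head_vars)
  }, logical(1))
  atom_extra_vars <- lapply(batoms, function(a) {
    setdiff(a$args[is_variable_term(a$args)], head_vars)
  })

  atom_vars <- lapply(batoms, function(a) a$args[is_variable_term(a$args)])
  # within one bottom clause a body is determined by its atom index set, so
  # the sorted index set serves as the search key; ties in the best-first
  # queue break towards shorter bodies then smaller index sets, which is the
  # lexicographic order of the (deterministically sorted) bottom atoms
  node <- function(idx, cp, cn, exact, extra_vars = character(0)) {
    list(idx = idx, cp = cp, cn = cn, exact = exact,
         extra_vars = extra_vars,
         vars = unique(c(head_vars, unlist(atom_vars[idx]))),
         key = paste0("k", paste(sort(idx), collapse = ".")),
         score = clause_score(sum(cp), sum(cn), bias$scoring))
  }
  as_clause <- function(nd) horn_clause(head, batoms[sort(nd$idx)])
  connected <- function(nd) {
    length(nd$idx) > 0L &&
      all(head_vars %in% unlist(atom_vars[nd$idx]))
  }
  root <- node(integer(0),
               !vapply(hs_pos, is.null, logical(1)),
               !vapply(hs_neg, is.null, logical(1)), TRUE)
  open <- list(root)
  open_score <- root$score
  open_len <- 0L
  open_key <- root$key
  open_live <- TRUE
  closed <- new.env(parent = emptyenv(), hash = TRUE)
  best <- NULL
  # a clause with body atoms but a free head variable is rejected as
  # non-connected; the bare empty-body hypothesis is allowed so a degenerate
  # bias (noise >= |negatives|) can return the most general rule
  admissible <- function(nd) {
    P <- sum(nd$cp)
    N <- sum(nd$cn)
    P >= bias$min_pos && N <= bias$noise &&
      (P + N == 0L || P / (P + N) >= bias$min_acc) &&
      (length(nd$idx) == 0L || connected(nd))
  }
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$score != b$score) return(a$score > b$score)
    if (length(a$idx) != length(b$idx)) return(length(a$idx) < length(b$idx))
    a$key < b$key
  }
  # optimistic bound on any refinement of a node: coverage can only shrink,
  # so the best descendant score is bounded by the node's positive count
  bound <- function(nd) clause_score(sum(nd$cp), 0L, bias$scoring)
  expansions <- 0L
  since_improve <- 0L
  while (any(open_live) && expansions < bias$node_budget &&
         since_improve <= bias$patience) {
    live <- which(open_live)
    pick <- live[order(-open_score[live], open_len[live], open_key[live],
                       method = "radix")[1]]
    nd <- open[[pick]]
    open_live[pick] <- FALSE
    if (exists(nd$key, envir = closed, inherits = FALSE)) next
    if (!nd$exact) {
      # lazy correction: the AND of marginal coverages over-counts when
      # non-head variables are shared between atoms; recompute exactly when
      # the node surfaces and push it back with its corrected score
      cl <- as_clause(nd)
      nd$cp <- clause_coverage_exact(cl, pos, db, mask = nd$cp)
      nd$cn <- clause_coverage_exact(cl, neg, db, mask = nd$cn)
      nd$exact <- TRUE
      nd$score <- clause_score(sum(nd$cp), sum(nd$cn), bias$scoring)
      if (sum(nd$cp) < bias$min_pos) next
      k <- length(open) + 1L
      open[[k]] <- nd
      open_score[k] <- nd$score
      open_len[k] <- length(nd$idx)
      open_key[k] <- nd$key
      open_live[k] <- TRUE
      next
    }
    assign(nd$key, TRUE, envir = closed)
    expansions <- expansions + 1L
    since_improve <- since_improve + 1L
    if (admissible(nd) && better(nd, best)) {
      best <- nd
      since_improve <- 0L
    }
    if (!is.null(best) && bound(nd) < best$score) next
    if (length(nd$idx) >= bias$l_max) next
    for (j in setdiff(seq_len(nb), nd$idx)) {
      avars <- atom_vars[[j]]
      if (!any(avars %in% nd$vars)) next
      if (length(union(nd$vars, avars)) > bias$v_max) next
      cp <- nd$cp & cov_pos_atoms[[j]]
      cn <- nd$cn & cov_neg_atoms[[j]]
      if (sum(cp) < bias$min_pos) next  # monotone: cannot recover
      # existentials over disjoint non-head variables factorize, so the AND
      # of marginal coverages stays exact; only shared non-head variables
      # force a joint recomputation on the candidate set
      shares <- length(intersect(atom_extra_vars[[j]], nd$extra_vars)) > 0L
      child <- node(c(nd$idx, j), cp, cn, !shares,
                    union(nd$extra_vars, atom_extra_vars[[j]]))
      if (exists(child$key, envir = closed, inherits = FALSE)) next
      k <- length(open) + 1L
      open[[k]] <- child
      open_score[k] <- child$score
      open_len[k] <- length(child$idx)
      open_key[k] <- child$key
      open_live[k] <- TRUE
    }
  }
  if (is.null(best)) NULL else list(clause = as_clause(best),
                                    cov_pos = best$cp,
                                    cov_neg = best$cn, score = best$score)
}

#' Induce a theory of Horn rules concluding on Regulates
#'
#' Sequential covering in the style of classic ILP learners: pick the first
#' positive example not yet covered, saturate it into a bottom clause,
#' search top-down (best-first on the clause score, ties broken towards
#' shorter bodies then lexicographically smaller serializations) in the
#' space the bottom clause bounds, keep the best clause whose positive
#' coverage reaches `min_pos` and whose negative coverage stays within
#' `noise`, remove the positives it covers, prune theory clauses
#' theta-subsumed by the new clause, and repeat until every positive is
#' covered or no admissible clause exists for any remaining seed.
#'
#' @param positives,negatives Data frames with columns `regulator`,
#'   `regulee` (one labeled ordered pair per row).
#' @param db An `evidence_db`.
#' @param bias A [language_bias()].
#' @param seed_order Optional integer permutation of the positive rows; by
#'   default positives are visited in input order.
#' @return A list of class `mln_theory` with elements `clauses` (list of
#'   `mln_clause`), `coverage` (tibble of per-clause positive/negative
#'   coverage counts) and `uncovered` (tibble of positives left uncovered).
#' @export
induce <- function(positives, negatives, db, bias = language_bias(),
                   seed_order = seq_len(nrow(positives))) {
  stopifnot(nrow(positives) >= 1L)
  positives <- positives[seed_order, , drop = FALSE]
  covered <- rep(FALSE, nrow(positives))
  uncoverable <- rep(FALSE, nrow(positives))
  clauses <- list()
  stats <- list()
  failures <- 0L
  while (any(!covered & !uncoverable)) {
    if (failures >= bias$max_failures) {
      uncoverable[!covered] <- TRUE
      break
    }
    seed_i <- which(!covered & !uncoverable)[1]
    # sequential covering: clauses are scored against the positives not yet
    # covered by the theory (covered ones are removed from the example set)
    rem_idx <- which(!covered)
    pos_rem <- positives[rem_idx, , drop = FALSE]
    seed <- regulates_atom(positives$regulator[seed_i],
                           positives$regulee[seed_i])
    bottom <- saturate(seed, db, bias)
    found <- search_best_clause(bottom, pos_rem, negatives, db, bias)
    seed_rem <- match(seed_i, rem_idx)
    if (is.null(found) || !found$cov_pos[seed_rem]) {
      uncoverable[seed_i] <- TRUE
      failures <- failures + 1L
      next
    }
    keep <- vapply(clauses, function(c0) {
      !theta_subsumes(found$clause, c0)
    }, logical(1))
    clauses <- clauses[keep]
    stats <- stats[keep]
    clauses[[length(clauses) + 1L]] <- found$clause
    stats[[length(stats) + 1L]] <- c(P = sum(found$cov_pos),
                                     N = sum(found$cov_neg))
    covered[rem_idx[found$cov_pos]] <- TRUE
  }
  coverage <- tibble::tibble(
    rule = vapply(clauses, format, character(1)),
    n_pos = vapply(stats, `[[`, numeric(1), "P"),
    n_neg = vapply(stats, `[[`, numeric(1), "N")
  )
  uncovered <- positives[uncoverable, , drop = FALSE]
  structure(list(clauses = clauses, coverage = coverage,
                 uncovered = tibble::as_tibble(uncovered)),
            class = "mln_theory")
}

#' @export
print.mln_theory <- function(x, ...) {
  cat("<mln_theory> ", length(x$clauses), " rules, ",
      nrow(x$uncovered), " uncoverable positives\n", sep = "")
  for (cl in x$clauses) cat("  ", format(cl), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.mln_theory <- function(x, ...) {
  x$coverage
}

#' Write a theory to a file (one clause per line)
#'
#' @param theory An `mln_theory` or list of `mln_clause`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_theory <- function(theory, path) {
  clauses <- if (inherits(theory, "mln_theory")) theory$clauses else theory
  writeLines(vapply(clauses, format, character(1)), path)
  invisible(path)
}

#' Read a theory from a file
#'
#' @param path Input file path.
#' @param sigs An `mln_signatures` object.
#' @return List of `mln_clause`.
#' @export
read_theory <- function(path, sigs = default_signatures()) {
  lines <- trimws(sub("#.*$", "", readLines(path)))
  lines <- lines[nzchar(lines)]
  lapply(lines, parse_clause, sigs = sigs)
}
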