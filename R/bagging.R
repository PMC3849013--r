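#' Enumerate the candidate ordered pair space
#'
#' Within a single gene set `A` (with `universe_b = NULL`), all ordered
#' pairs `(g1, g2)` with `g1, g2` in `A`, self-pairs included by default:
#' `|A|^2` pairs. Across two disjoint sets `A` and `B`, all pairs in both
#' orientations: `2 |A| |B|` pairs.
#'
#' @param universe_a Character vector of gene constants.
#' @param universe_b Optional second gene set (cross-universe enumeration).
#' @param include_self Include self-pairs `(g, g)` in the within-set case
#'   (default `TRUE`).
#' @return A tibble `regulator`, `regulee` in deterministic lexicographic
#'   order.
#' @export
enumerate_candidate_pairs <- function(universe_a, universe_b = NULL,
                                      include_self = TRUE) {
  stopifnot(length(universe_a) >= 1L)
  a <- sort(unique(universe_a))
  if (is.null(universe_b)) {
    grid <- expand.grid(regulee = a, regulator = a,
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    out <- tibble::tibble(regulator = grid$regulator, regulee = grid$regulee)
    if (!include_self) out <- out[out$regulator != out$regulee, , drop = FALSE]
  } else {
    b <- sort(unique(universe_b))
    if (length(intersect(a, b))) {
      stop("cross-universe enumeration requires disjoint gene sets; shared: ",
           paste(utils::head(intersect(a, b), 5), collapse = ", "))
    }
    g1 <- expand.grid(regulee = b, regulator = a, stringsAsFactors = FALSE)
    g2 <- expand.grid(regulee = a, regulator = b, stringsAsFactors = FALSE)
    out <- tibble::tibble(
      regulator = c(g1$regulator, g2$regulator),
      regulee = c(g1$regulee, g2$regulee)
    )
    out <- out[order(out$regulator, out$regulee, method = "radix"), ,
               drop = FALSE]
  }
  tibble::as_tibble(out)
}

pair_keys <- function(df) paste(df$regulator, df$regulee, sep = "\r")

#' Set-difference of pair tables
#'
#' @param pairs,remove Data frames with columns `regulator`, `regulee`.
#' @return Rows of `pairs` whose ordered pair does not occur in `remove`.
#' @export
pairs_setdiff <- function(pairs, remove) {
  keep <- !(pair_keys(pairs) %in% pair_keys(remove))
  tibble::as_tibble(pairs[keep, , drop = FALSE])
}

#' Sample negatives uniformly from the pool
#'
#' Uniform sampling without replacement (a subsample, not a bootstrap),
#' reproducible given the seed. The asymmetric-bagging contract is `n =
#' |positives|`, so each base learner sees a balanced task.
#'
#' @param pool Tibble `regulator`, `regulee`: the negative candidate pool.
#' @param n Number of pairs to draw.
#' @param seed Integer seed.
#' @param exclusions Optional pair tibble removed from the pool before
#'   sampling (e.g. future positives that must not pollute the negatives).
#' @return A tibble of `n` pairs.
#' @export
sample_negatives <- function(pool, n, seed, exclusions = NULL) {
  if (!is.null(exclusions)) pool <- pairs_setdiff(pool, exclusions)
  if (nrow(pool) < n) {
    stop("negative pool too small: ", nrow(pool), " < ", n)
  }
  idx <- withr::with_seed(seed, sample.int(nrow(pool), n))
  tibble::as_tibble(pool[idx, , drop = FALSE])
}

#' Harmonic mean of precision and recall
#'
#' `F1 = 2 * precision * recall / (precision + recall)`, with the limit
#' convention that F1 is 0 when either argument is 0.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

f1_at_threshold <- function(scores, labels, theta) {
  pred <- scores >= theta
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  p <- sum(labels == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (p == 0) 0 else tp / p
  f1_score(precision, recall)
}

#' Select a decision threshold by maximizing the averaged F1
#'
#' Over a grid of thresholds, computes per validation sample the F1 of the
#' thresholded scores and returns the grid point maximizing the mean F1
#' across samples; ties go to the smallest threshold. If every threshold
#' yields zero F1, 0.5 is returned with a warning.
#'
#' @param scores_by_sample List of numeric score vectors (one per
#'   validation sample).
#' @param labels_by_sample List of matching 0/1 label vectors.
#' @param grid Threshold grid (default `seq(0, 1, by = 0.01)`).
#' @return The selected threshold.
#' @export
select_threshold <- function(scores_by_sample, labels_by_sample,
                             grid = seq(0, 1, by = 0.01)) {
  stopifnot(length(scores_by_sample) == length(labels_by_sample),
            length(grid) >= 1L)
  mean_f1 <- vapply(grid, function(theta) {
    mean(mapply(f1_at_threshold, scores_by_sample, labels_by_sample,
                MoreArgs = list(theta = theta)))
  }, numeric(1))
  if (all(mean_f1 == 0)) {
    warning("F1 is zero over the whole threshold grid; falling back to 0.5")
    return(0.5)
  }
  grid[which.max(mean_f1)]
}

#' Asymmetric bagging over negative subsamples
#'
#' Trains `B` base models, each on the full positive set plus an
#' independent balanced negative subsample; predictions are later averaged.
#' All base models see identical positives, so ensemble variability comes
#' only from the negative sampling.
#'
#' @param positives Tibble `regulator`, `regulee` (the minority class).
#' @param pool Tibble of candidate negatives.
#' @param db The `evidence_db` handed to the base learner.
#' @param learner A base learner from [mln_learner()] or [svm_learner()].
#' @param B Number of bags (default 30).
#' @param seed Master seed; per-bag seeds are derived deterministically.
#' @param exclusions Pairs excluded from the negative pool (see
#'   [sample_negatives()]).
#' @return An object of class `bagged_model`.
#' @export
fit_bagged <- function(positives, pool, db, learner, B = 30L, seed = 1L,
                       exclusions = NULL) {
  B <- as.integer(B)
  stopifnot(B >= 1L, inherits(learner, "base_learner"))
  bag_seeds <- derive_seeds(seed, B)
  models <- vector("list", B)
  neg_samples <- vector("list", B)
  for (b in seq_len(B)) {
    neg <- sample_negatives(pool, nrow(positives), bag_seeds[b],
                            exclusions = exclusions)
    train <- dplyr::bind_rows(
      dplyr::mutate(positives, label = 1),
      dplyr::mutate(neg, label = 0)
    )
    models[[b]] <- learner$fit(train, db)
    neg_samples[[b]] <- neg
  }
  structure(list(models = models, learner = learner, B = B,
                 seeds = bag_seeds, neg_samples = neg_samples,
                 threshold = NA_real_),
            class = "bagged_model")
}

#' @export
print.bagged_model <- function(x, ...) {
  cat("<bagged_model> B = ", x$B,
      if (!is.na(x$threshold)) paste0(", threshold = ", x$threshold), "\n",
      sep = "")
  invisible(x)
}

#' Average the base model predictions
#'
#' @param object A `bagged_model`.
#' @param pairs Tibble `regulator`, `regulee`.
#' @param db An `evidence_db`.
#' @param ... Unused.
#' @return Tibble `regulator`, `regulee`, `score`: the arithmetic mean of
#'   the base scores, each already in `[0, 1]`.
#' @export
predict.bagged_model <- function(object, pairs, db, ...) {
  scores <- vapply(object$models, function(m) {
    object$learner$predict(m, pairs, db)
  }, numeric(nrow(pairs)))
  if (nrow(pairs) == 1L) scores <- matrix(scores, nrow = 1L)
  tibble::tibble(regulator = pairs$regulator, regulee = pairs$regulee,
                 score = rowMeans(scores))
}

# deterministic stream of 31-bit seeds from one master seed
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Save / load a bagged MLN ensemble as a model bundle directory
#'
#' The bundle holds one weighted-MLN file per bag member
#' (`member_<b>.mln`) plus `manifest.json` recording the per-bag seeds and
#' the selected decision threshold, enough to replay or audit the
#' ensemble. Only MLN base models are serializable this way.
#'
#' @param model A `bagged_model` whose members are `mln` objects.
#' @param dir Bundle directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bagged_model <- function(model, dir) {
  stopifnot(inherits(model, "bagged_model"))
  if (!all(vapply(model$models, inherits, logical(1), "mln"))) {
    stop("only ensembles of MLN base models can be written as a bundle")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in seq_len(model$B)) {
    write_mln(model$models[[b]], file.path(dir, sprintf("member_%03d.mln", b)))
  }
  jsonlite::write_json(
    list(B = model$B, seeds = model$seeds, threshold = model$threshold),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_bagged_model
#' @param sigs An `mln_signatures` object for parsing the member files.
#' @export
read_bagged_model <- function(dir, sigs = default_signatures()) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  models <- lapply(seq_len(manifest$B), function(b) {
    read_mln(file.path(dir, sprintf("member_%03d.mln", b)), sigs)
  })
  structure(list(models = models, learner = mln_learner(),
                 B = as.integer(manifest$B), seeds = manifest$seeds,
                 neg_samples = NULL,
                 threshold = if (is.null(manifest$threshold)) NA_real_
                             else manifest$threshold),
            class = "bagged_model")
}
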