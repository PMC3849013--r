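#' Balanced cross-validation study (study 1)
#'
#' Measures average performance on a balanced edge-prediction task: for
#' each of `n_samples` negative subsamples of positive-set size, a
#' stratified k-fold cross-validation is run, held-out predictions are
#' pooled within the sample, and AUC-ROC / AUC-PR are computed per sample.
#'
#' @param positives Tibble `regulator`, `regulee` of known regulations.
#' @param pool Tibble of candidate negative pairs (unknown regulations).
#' @param db An `evidence_db`.
#' @param learner A base learner ([mln_learner()] or [svm_learner()]).
#' @param n_samples Number of negative subsamples (default 30).
#' @param folds Cross-validation folds (default 10).
#' @param seed Master seed.
#' @return A `study_report` with per-sample metrics and their mean/sd.
#' @export
run_study1 <- function(positives, pool, db, learner, n_samples = 30L,
                       folds = 10L, seed = 1L) {
  sample_seeds <- derive_seeds(seed, 2L * n_samples)
  res <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    neg <- sample_negatives(pool, nrow(positives), sample_seeds[i])
    labeled <- dplyr::bind_rows(dplyr::mutate(positives, label = 1),
                                dplyr::mutate(neg, label = 0))
    fold_id <- stratified_folds(labeled$label, folds,
                                sample_seeds[n_samples + i])
    scores <- numeric(nrow(labeled))
    for (f in seq_len(folds)) {
      train <- labeled[fold_id != f, , drop = FALSE]
      test <- labeled[fold_id == f, , drop = FALSE]
      model <- learner$fit(train, db)
      scores[fold_id == f] <- learner$predict(model, test, db)
    }
    sp <- tibble::tibble(score = scores, label = labeled$label)
    res[[i]] <- tibble::tibble(sample = i,
                               auc_roc = roc_auc(sp)$auc,
                               auc_pr = pr_auc(sp)$auc)
  }
  new_study_report(study = 1L, samples = dplyr::bind_rows(res), seed = seed,
                   learner = learner$label)
}

#' Network-update study (study 2)
#'
#' Emulates completing a known network after new regulations are
#' discovered: asymmetric bagging is trained on the earlier snapshot's
#' positives (negatives drawn from the complement excluding all later
#' positives), a decision threshold is selected by maximizing the averaged
#' F1 on per-bag 2/3-1/3 stratified validation splits, and the true
#' positive rate of the averaged predictions on the newly discovered
#' regulations is reported (the test examples are all positive).
#'
#' @param positives_t0 Earlier-snapshot positive pairs (training labels).
#' @param positives_t1 Later-snapshot positives; must contain
#'   `positives_t0`.
#' @param pool Candidate negative pool (pairs not positive at t0).
#' @param db An `evidence_db`.
#' @param learner A base learner.
#' @param B Number of bags (default 30).
#' @param seed Master seed.
#' @param grid Threshold grid for [select_threshold()].
#' @return A `study_report` carrying the selected threshold and the TPR on
#'   the new positives.
#' @export
run_study2 <- function(positives_t0, positives_t1, pool, db, learner,
                       B = 30L, seed = 1L, grid = seq(0, 1, by = 0.01)) {
  if (nrow(pairs_setdiff(positives_t0, positives_t1)) > 0L) {
    stop("positives_t0 must be a subset of positives_t1")
  }
  new_pos <- pairs_setdiff(positives_t1, positives_t0)
  if (nrow(new_pos) == 0L) {
    warning("no new positives between the two snapshots")
  }
  bag_seeds <- derive_seeds(seed, 2L * B)
  models <- vector("list", B)
  val_scores <- vector("list", B)
  val_labels <- vector("list", B)
  for (b in seq_len(B)) {
    neg <- sample_negatives(pool, nrow(positives_t0), bag_seeds[b],
                            exclusions = positives_t1)
    labeled <- dplyr::bind_rows(dplyr::mutate(positives_t0, label = 1),
                                dplyr::mutate(neg, label = 0))
    split <- stratified_split(labeled$label, 2 / 3, bag_seeds[B + b])
    train <- labeled[split, , drop = FALSE]
    valid <- labeled[!split, , drop = FALSE]
    models[[b]] <- learner$fit(train, db)
    val_scores[[b]] <- learner$predict(models[[b]], valid, db)
    val_labels[[b]] <- valid$label
  }
  theta <- select_threshold(val_scores, val_labels, grid)
  test_scores <- if (nrow(new_pos)) {
    rowMeans(vapply(models, function(m) learner$predict(m, new_pos, db),
                    numeric(nrow(new_pos))))
  } else numeric(0)
  sp <- tibble::tibble(score = test_scores, label = rep(1, nrow(new_pos)))
  tpr <- if (nrow(new_pos)) tpr_at_threshold(sp, theta) else NA_real_
  new_study_report(study = 2L,
                   samples = tibble::tibble(sample = 1L, tpr = tpr),
                   seed = seed, learner = learner$label,
                   extra = list(threshold = theta, n_new_positives = nrow(new_pos),
                                scored = sp))
}

#' New-gene network-completion study (study 3)
#'
#' Tests generalization to genes never seen in training: asymmetric
#' bagging is trained on regulations within the training universe, every
#' ordered pair crossing from the training to the new universe (both
#' directions) is scored with the averaged ensemble, and AUC-ROC / AUC-PR
#' are computed on the full, unbalanced cross-universe candidate set.
#'
#' @param train_positives Positive pairs within the training universe.
#' @param train_pool Negative candidate pool within the training universe.
#' @param db An `evidence_db` with descriptors for both universes.
#' @param learner A base learner.
#' @param universe_a Training gene set.
#' @param universe_b New gene set (disjoint from `universe_a`).
#' @param test_positives Known positive pairs crossing the universes.
#' @param B Number of bags (default 30).
#' @param seed Master seed.
#' @return A `study_report` with the cross-universe AUCs.
#' @export
run_study3 <- function(train_positives, train_pool, db, learner,
                       universe_a, universe_b, test_positives,
                       B = 30L, seed = 1L) {
  if (length(intersect(universe_a, universe_b))) {
    stop("training and new gene universes must be disjoint")
  }
  candidates <- enumerate_candidate_pairs(universe_a, universe_b)
  labels <- as.integer(pair_keys(candidates) %in% pair_keys(test_positives))
  if (nrow(test_positives) && sum(labels) != nrow(dplyr::distinct(test_positives))) {
    stop("test positives must all lie in the cross-universe candidate space")
  }
  bagged <- fit_bagged(train_positives, train_pool, db, learner, B = B,
                       seed = seed)
  pred <- predict(bagged, candidates, db)
  sp <- tibble::tibble(score = pred$score, label = labels)
  new_study_report(study = 3L,
                   samples = tibble::tibble(sample = 1L,
                                            auc_roc = roc_auc(sp)$auc,
                                            auc_pr = pr_auc(sp)$auc),
                   seed = seed, learner = learner$label,
                   extra = list(scored = sp, n_candidates = nrow(candidates)))
}

new_study_report <- function(study, samples, seed, learner, extra = list()) {
  structure(c(list(study = study, samples = samples, seed = seed,
                   learner = learner), extra),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> study ", x$study, ", learner ", x$learner,
      ", seed ", x$seed, "\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.study_report <- function(x, ...) {
  x$samples
}

#' @importFrom generics glance
#' @export
glance.study_report <- function(x, ...) {
  metrics <- setdiff(names(x$samples), "sample")
  out <- tibble::tibble(study = x$study, learner = x$learner,
                        n_samples = nrow(x$samples))
  for (m in metrics) {
    out[[paste0("mean_", m)]] <- mean(x$samples[[m]])
    out[[paste0("sd_", m)]] <- stats::sd(x$samples[[m]])
  }
  if (!is.null(x$threshold)) out$threshold <- x$threshold
  out
}

#' Write a study report to JSON
#'
#' @param report A `study_report` (or list of them).
#' @param path Output file path; written atomically (temp file + rename).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "study_report")) report <- list(report)
  payload <- lapply(report, function(r) {
    out <- list(study = r$study, learner = r$learner, seed = r$seed,
                samples = r$samples, summary = glance(r))
    if (!is.null(r$threshold)) out$threshold <- r$threshold
    out
  })
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  file.rename(tmp, path)
  invisible(path)
}

# stratified fold assignment, seeded and deterministic
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

# stratified TRUE/FALSE split with given training fraction
stratified_split <- function(labels, frac, seed) {
  keep <- logical(length(labels))
  withr::with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      n_train <- max(1L, round(frac * length(idx)))
      keep[sample(idx, n_train)] <- TRUE
    }
  })
  keep
}

#' Plot per-sample AUCs of a balanced cross-validation report
#'
#' @param object A `study_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_report <- function(object, ...) {
  metrics <- setdiff(names(object$samples), "sample")
  long <- tidyr::pivot_longer(object$samples, dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "value",
                  title = paste0("Study ", object$study, " (", object$learner,
                                 "), ", nrow(object$samples), " samples"))
}
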