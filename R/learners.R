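#' Base learners for asymmetric bagging
#'
#' A base learner is a pair of closures, `fit(train, db)` and
#' `predict(model, pairs, db)`, trained on a balanced labeled pair table
#' and returning scores in `[0, 1]`. Two learners are provided: the MLN
#' learner (rule induction followed by weight learning; its scores are
#' posterior probabilities) and the pairwise-kernel SVM learner (decision
#' values calibrated to `[0, 1]` by a logistic link so that heterogeneous
#' base scores can be averaged).
#'
#' @param bias A [language_bias()] for rule induction.
#' @param config A [training_config()] for weight learning.
#' @return An object of class `base_learner`.
#' @name base_learners
NULL

#' @rdname base_learners
#' @export
mln_learner <- function(bias = language_bias(), config = training_config()) {
  structure(list(
    fit = function(train, db) {
      pos <- train[train$label == 1, c("regulator", "regulee")]
      neg <- train[train$label == 0, c("regulator", "regulee")]
      theory <- induce(pos, neg, db, bias)
      learn_weights(theory, db, train, labels = train$label, config = config)
    },
    predict = function(model, pairs, db) {
      predict(model, db, pairs)$score
    },
    label = "mln"
  ), class = "base_learner")
}

#' @rdname base_learners
#' @param base_kernels Named list of gene-level kernel matrices (see
#'   [feature_views()] and [gaussian_kernel()]).
#' @param combination `"sum"` (tensor product of the averaged base kernel)
#'   or `"pairwise_sum"` (average of the per-source pair kernels).
#' @param C Soft-margin cost.
#' @export
svm_learner <- function(base_kernels, combination = c("sum", "pairwise_sum"),
                        C = 1) {
  combination <- match.arg(combination)
  pair_kernel <- function(pairs_a, pairs_b) {
    if (combination == "sum") {
      combine_sum(base_kernels, pairs_a, pairs_b)
    } else {
      combine_pairwise_sum(base_kernels, pairs_a, pairs_b)
    }
  }
  structure(list(
    fit = function(train, db) {
      tp <- train[, c("regulator", "regulee")]
      K <- pair_kernel(tp, tp)
      svm <- train_pairwise_svm(K, train$label, C = C)
      list(svm = svm, train_pairs = tp)
    },
    predict = function(model, pairs, db) {
      K <- pair_kernel(pairs, model$train_pairs)
      stats::plogis(model$svm$decision(K))
    },
    label = paste0("svm_", combination)
  ), class = "base_learner")
}

#' Build entropy-bandwidth Gaussian kernels for all six views
#'
#' Convenience wrapper: vectorize the descriptor tables into the six
#' feature views, select each view's bandwidth by the entropy criterion,
#' and return the six Gaussian kernel matrices.
#'
#' @param expr Expression data frame.
#' @param annotations An [annotation_tables()].
#' @return Named list of six kernel matrices.
#' @export
build_base_kernels <- function(expr, annotations = annotation_tables()) {
  views <- feature_views(expr, annotations)
  lapply(views, function(v) {
    sigma <- tryCatch(select_bandwidth(v),
                      warning = function(w) 1)
    gaussian_kernel(v, sigma)
  })
}
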