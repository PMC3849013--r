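#' @keywords internal
#' cumulative confusion counts at every distinct score cut (scores sorted
#' descending, ties grouped)
confusion_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  cuts <- !duplicated(s)
  grp <- cumsum(cuts)
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tibble::tibble(threshold = s[last], tp = tp[last], fp = fp[last])
}

check_scored <- function(sp) {
  stopifnot(all(c("score", "label") %in% names(sp)))
  stopifnot(all(sp$label %in% c(0, 1)))
  sp
}

#' ROC curve and area
#'
#' Sweeps the decision threshold over the scores, computing the true
#' positive rate `TPR = tp/p` against the false positive rate `FPR = fp/n`,
#' and integrates by the trapezoid rule. With ties grouped, the trapezoid
#' area equals the tie-corrected Mann-Whitney probability that a random
#' positive outscores a random negative (ties credited 1/2).
#'
#' @param sp Data frame of scored pairs with columns `score` and `label`
#'   (0/1); both classes must be present.
#' @return A list of class `curve_summary` with `points` (tibble
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(sp) {
  check_scored(sp)
  p <- sum(sp$label == 1)
  n <- sum(sp$label == 0)
  if (p == 0 || n == 0) stop("ROC requires both classes present")
  cp <- confusion_points(sp$score, sp$label)
  tpr <- c(0, cp$tp / p)
  fpr <- c(0, cp$fp / n)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = tibble::tibble(threshold = c(Inf, cp$threshold),
                                         fpr = fpr, tpr = tpr),
                 auc = auc, type = "roc"),
            class = "curve_summary")
}

#' Standardized precision-recall curve and area
#'
#' Builds the precision-recall curve over all distinct score cuts and
#' interpolates nonlinearly between achievable points: between two
#' consecutive cuts the true-positive count is stepped one unit at a time
#' with the false positives interpolated linearly in the true positives, so
#' precision follows the attainable hyperbolic path rather than a straight
#' line. The curve is anchored at its smallest achievable recall (precision
#' extended constantly to recall 0) and the area is taken over recall in
#' `[0, 1]`.
#'
#' @param sp Data frame with columns `score`, `label`; at least one
#'   positive required.
#' @return A `curve_summary` with `points` (tibble `recall`, `precision`)
#'   and `auc`.
#' @export
pr_auc <- function(sp) {
  check_scored(sp)
  p <- sum(sp$label == 1)
  if (p == 0) stop("PR curve requires at least one positive")
  cp <- confusion_points(sp$score, sp$label)
  tp <- c(0, cp$tp)
  fp <- c(0, cp$fp)
  rec <- numeric(0)
  prec <- numeric(0)
  for (k in seq_len(length(tp) - 1L)) {
    dtp <- tp[k + 1L] - tp[k]
    dfp <- fp[k + 1L] - fp[k]
    if (dtp == 0) {
      # vertical drop in precision at constant recall: no area contribution,
      # but keep the end point for plotting
      if (tp[k + 1L] > 0) {
        rec <- c(rec, tp[k + 1L] / p)
        prec <- c(prec, tp[k + 1L] / (tp[k + 1L] + fp[k + 1L]))
      }
      next
    }
    x <- seq_len(dtp)
    rec <- c(rec, (tp[k] + x) / p)
    prec <- c(prec, (tp[k] + x) / (tp[k] + x + fp[k] + dfp * x / dtp))
  }
  # anchor: extend the first achievable precision to recall 0
  rec <- c(0, rec)
  prec <- c(prec[1], prec)
  auc <- sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
  structure(list(points = tibble::tibble(recall = rec, precision = prec),
                 auc = auc, type = "pr"),
            class = "curve_summary")
}

#' @export
print.curve_summary <- function(x, ...) {
  cat("<curve_summary> ", toupper(x$type), " AUC = ",
      format(x$auc, digits = 4), " (", nrow(x$points), " points)\n", sep = "")
  invisible(x)
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.curve_summary <- function(object, ...) {
  if (object$type == "roc") {
    ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_step() +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    title = sprintf("ROC curve (AUC = %.3f)", object$auc))
  } else {
    ggplot2::ggplot(object$points,
                    ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_line() +
      ggplot2::ylim(0, 1) +
      ggplot2::labs(x = "Recall", y = "Precision",
                    title = sprintf("PR curve (AUC = %.3f)", object$auc))
  }
}

#' Export a curve's points as CSV
#'
#' @param curve A `curve_summary` from [roc_auc()] or [pr_auc()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "curve_summary"))
  utils::write.csv(curve$points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' True positive rate at a fixed threshold
#'
#' Fraction of positives scored at or above the threshold. Positives-only
#' inputs are legal (network-update evaluation scores a set of newly
#' discovered regulations, all positive).
#'
#' @param sp Data frame with columns `score`, `label`.
#' @param theta Threshold in `[0, 1]`.
#' @return TPR in `[0, 1]`.
#' @export
tpr_at_threshold <- function(sp, theta) {
  check_scored(sp)
  stopifnot(theta >= 0, theta <= 1)
  pos <- sp$score[sp$label == 1]
  if (length(pos) == 0) stop("no positives in the scored set")
  mean(pos >= theta)
}

#' Compare two AUC-ROC values by the Mann-Whitney-statistic test
#'
#' Delegates to the established nonparametric AUC-comparison routine of the
#' pROC package (DeLong's test on paired scores by default).
#'
#' @param sp1,sp2 Scored data frames (`score`, `label`) over the same test
#'   pairs.
#' @param ... Passed to `pROC::roc.test`.
#' @return The htest-like object returned by `pROC::roc.test`.
#' @export
compare_auc <- function(sp1, sp2, ...) {
  if (!requireNamespace("pROC", quietly = TRUE)) {
    stop("the pROC package is required for compare_auc()")
  }
  r1 <- pROC::roc(sp1$label, sp1$score, quiet = TRUE, direction = "<")
  r2 <- pROC::roc(sp2$label, sp2$score, quiet = TRUE, direction = "<")
  pROC::roc.test(r1, r2, ...)
}
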