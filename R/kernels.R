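#' Build the six per-source feature views
#'
#' Vectorizes each descriptor source into one numeric vector per gene:
#' `expression` (the three raw condition values), `expression_change` (two
#' log2 fold changes versus wild type), `ppi` (binary interaction indicator
#' over the gene universe), `localization` and `process` (binary indicator
#' vectors over the observed vocabularies) and `chrom_location` (chromosome
#' indicator plus the numeric band-interval midpoint, with the arm coded
#' 0/1).
#'
#' @param expr Expression data frame (`gene`, `wt`, `siid2`, `prcid2`).
#' @param annotations An [annotation_tables()].
#' @return Named list of numeric matrices (genes x features), rows named by
#'   gene constants.
#' @export
feature_views <- function(expr, annotations = annotation_tables()) {
  check_expression(expr)
  genes <- const_name(expr$gene)
  n <- length(genes)

  expr_m <- as.matrix(expr[, expr_conditions])
  rownames(expr_m) <- genes

  eps <- 1e-9
  change <- cbind(
    siid2 = log2((expr$siid2 + eps) / (expr$wt + eps)),
    prcid2 = log2((expr$prcid2 + eps) / (expr$wt + eps))
  )
  rownames(change) <- genes

  indicator <- function(df, gene_col, value_col) {
    vals <- sort(unique(const_name(df[[value_col]])))
    m <- matrix(0, n, max(length(vals), 1L),
                dimnames = list(genes, if (length(vals)) vals else "none"))
    if (nrow(df)) {
      g <- const_name(df[[gene_col]])
      v <- const_name(df[[value_col]])
      for (i in seq_len(nrow(df))) m[g[i], v[i]] <- 1
    }
    m
  }

  ppi_m <- matrix(0, n, n, dimnames = list(genes, genes))
  if (nrow(annotations$ppi)) {
    ga <- const_name(annotations$ppi$gene_a)
    gb <- const_name(annotations$ppi$gene_b)
    for (i in seq_along(ga)) {
      ppi_m[ga[i], gb[i]] <- 1
      ppi_m[gb[i], ga[i]] <- 1
    }
  }

  ch <- annotations$chromosome
  if (nrow(ch)) {
    chrom_ind <- indicator(ch, "gene", "chrom")
    midpoint <- (ch$band_begin + ch$band_end) / 2
    arm <- as.numeric(ch$arm_begin == "q")
    pos <- matrix(0, n, 2, dimnames = list(genes, c("arm", "band_mid")))
    g <- const_name(ch$gene)
    pos[g, "arm"] <- arm
    pos[g, "band_mid"] <- midpoint
    chrom_m <- cbind(chrom_ind, pos)
  } else {
    chrom_m <- matrix(0, n, 1, dimnames = list(genes, "none"))
  }

  list(expression = expr_m,
       expression_change = change,
       ppi = ppi_m,
       localization = indicator(annotations$localization, "gene", "compartment"),
       process = indicator(annotations$go, "gene", "process"),
       chrom_location = chrom_m)
}

#' Gaussian kernel over a feature view
#'
#' `k(u, v) = exp(-||u - v||^2 / (2 sigma^2))`: symmetric, positive
#' semidefinite, unit diagonal.
#'
#' @param view Numeric matrix (genes x features) with row names.
#' @param sigma Positive bandwidth.
#' @return Symmetric kernel matrix with the view's row names.
#' @export
gaussian_kernel <- function(view, sigma) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  d2 <- as.matrix(stats::dist(view))^2
  exp(-d2 / (2 * sigma^2))
}

#' Select a Gaussian bandwidth by maximizing kernel-value entropy
#'
#' For each candidate bandwidth, the Shannon entropy of the histogram (20
#' equal-width bins over `[0, 1]`) of the off-diagonal kernel values is
#' computed; the candidate with maximal entropy is returned, ties going to
#' the smaller bandwidth. A kernel saturated at 0 or 1 carries no
#' information (entropy near zero), so the criterion avoids both extremes.
#'
#' @param view Numeric matrix (genes x features).
#' @param candidates Optional bandwidth grid; by default 15 log-spaced
#'   values spanning two decades around the median pairwise distance.
#' @return The selected bandwidth.
#' @export
select_bandwidth <- function(view, candidates = NULL) {
  if (nrow(view) < 2L) stop("need at least two genes")
  d <- stats::dist(view)
  if (all(d == 0)) {
    warning("degenerate view: all feature vectors identical; using median candidate")
    if (is.null(candidates)) candidates <- 1
    return(stats::median(candidates))
  }
  if (is.null(candidates)) {
    med <- stats::median(d[d > 0])
    candidates <- exp(seq(log(med / 10), log(med * 10), length.out = 15))
  }
  entropy <- vapply(candidates, function(s) {
    k <- exp(-as.numeric(d)^2 / (2 * s^2))
    h <- tabulate(pmin(floor(k * 20) + 1L, 20L), nbins = 20L)
    p <- h / sum(h)
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
  candidates[which.max(entropy)]  # which.max takes the first (smaller) tie
}

#' Tensor-product pairwise kernel over ordered gene pairs
#'
#' `K((G1,G2),(G3,G4)) = k(G1,G3) k(G2,G4)`: similarity of ordered pairs as
#' regulator-to-regulator times regulee-to-regulee similarity. The kernel
#' is positive semidefinite (tensor product of PSD kernels) and asymmetric
#' in pair orientation: swapping one pair's orientation generally changes
#' the value, so edge direction matters.
#'
#' @param base Gene-level kernel matrix with gene names as dimnames.
#' @param pairs_a Tibble `regulator`, `regulee` indexing the rows.
#' @param pairs_b Tibble indexing the columns (default `pairs_a`).
#' @return Matrix of dimension `nrow(pairs_a)` x `nrow(pairs_b)`.
#' @export
pairwise_kernel <- function(base, pairs_a, pairs_b = pairs_a) {
  genes <- rownames(base)
  used <- unique(c(pairs_a$regulator, pairs_a$regulee,
                   pairs_b$regulator, pairs_b$regulee))
  missing_g <- setdiff(used, genes)
  if (length(missing_g)) {
    stop("genes absent from the base kernel: ",
         paste(utils::head(missing_g, 5), collapse = ", "))
  }
  base[pairs_a$regulator, pairs_b$regulator, drop = FALSE] *
    base[pairs_a$regulee, pairs_b$regulee, drop = FALSE]
}

#' Average of the per-source pairwise kernels
#'
#' Derives one tensor-product pairwise kernel per base kernel and averages
#' them: `K_pairwisesum = (1/m) sum_i K_i`.
#'
#' @param base_kernels List of gene-level kernel matrices.
#' @param pairs_a,pairs_b Pair tables as in [pairwise_kernel()].
#' @return Pair kernel matrix.
#' @export
combine_pairwise_sum <- function(base_kernels, pairs_a, pairs_b = pairs_a) {
  parts <- lapply(base_kernels, pairwise_kernel, pairs_a = pairs_a,
                  pairs_b = pairs_b)
  Reduce(`+`, parts) / length(parts)
}

#' Tensor product of the averaged base kernel
#'
#' First averages the gene-level kernels, `kbar = (1/m) sum_i k_i`, then
#' forms the tensor-product pair kernel of `kbar`. In general this differs
#' from [combine_pairwise_sum()] (product of means versus mean of
#' products); the two coincide when all base kernels are equal.
#'
#' @inheritParams combine_pairwise_sum
#' @return Pair kernel matrix.
#' @export
combine_sum <- function(base_kernels, pairs_a, pairs_b = pairs_a) {
  kbar <- Reduce(`+`, base_kernels) / length(base_kernels)
  pairwise_kernel(kbar, pairs_a, pairs_b)
}

#' Check a kernel matrix for positive semidefiniteness
#'
#' @param K Symmetric matrix.
#' @param tol Relative tolerance on the most negative eigenvalue.
#' @return `TRUE` iff `min(eigenvalues) >= -tol * max(abs(eigenvalues))`.
#' @export
is_psd <- function(K, tol = 1e-8) {
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(abs(ev), 1e-300)
  min(ev) >= -tol * mx
}

#' Write a kernel matrix as TSV with pair-id headers
#'
#' For inspection and interchange: row/column identifiers are either gene
#' names (base kernels) or `regulator->regulee` pair ids (pair kernels).
#'
#' @param K Kernel matrix with dimnames, or a pair kernel plus `pairs`.
#' @param path Output TSV path.
#' @param pairs Optional tibble (`regulator`, `regulee`) labelling the
#'   rows/columns of a pair kernel.
#' @return `path`, invisibly.
#' @export
write_kernel_tsv <- function(K, path, pairs = NULL) {
  if (!is.null(pairs)) {
    ids <- paste0(pairs$regulator, "->", pairs$regulee)
    dimnames(K) <- list(ids, ids)
  }
  df <- data.frame(id = rownames(K), K, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Train a soft-margin SVM on a precomputed pair kernel
#'
#' Wraps a C-SVM on the precomputed Gram matrix of training pairs and
#' exposes a real-valued decision score for test pairs through their
#' kernel rows against the training pairs.
#'
#' @param K_train Gram matrix over the training pairs (PSD within
#'   tolerance).
#' @param labels 0/1 vector, one per training pair.
#' @param C Soft-margin cost (default 1).
#' @return An object of class `pairwise_svm` with a `decision` closure.
#' @export
train_pairwise_svm <- function(K_train, labels, C = 1) {
  stopifnot(C > 0, nrow(K_train) == length(labels))
  if (!is_psd(K_train, tol = 1e-6)) {
    stop("training kernel matrix is not positive semidefinite within tolerance")
  }
  y <- factor(labels, levels = c(0, 1))
  model <- kernlab::ksvm(kernlab::as.kernelMatrix(K_train), y,
                         type = "C-svc", C = C, scaled = FALSE)
  dec_train <- kernlab::predict(
    model, kernlab::as.kernelMatrix(K_train[, kernlab::SVindex(model),
                                            drop = FALSE]),
    type = "decision")[, 1]
  # fix the sign so positives score high regardless of kernlab's internal
  # label ordering
  flip <- mean(dec_train[labels == 1]) < mean(dec_train[labels == 0])
  sign_mult <- if (isTRUE(flip)) -1 else 1
  structure(list(model = model, sign = sign_mult,
                 decision = function(K_test_train) {
                   d <- kernlab::predict(
                     model,
                     kernlab::as.kernelMatrix(
                       K_test_train[, kernlab::SVindex(model), drop = FALSE]),
                     type = "decision")[, 1]
                   sign_mult * d
                 }),
            class = "pairwise_svm")
}
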