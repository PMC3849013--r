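#' Normalize names into logical constants
#'
#' Constants must start with an upper-case character; identifiers from input
#' tables (gene symbols, GO terms, compartments) are sanitized by replacing
#' non-alphanumeric characters with `_` and upper-casing the first letter
#' (so the gene symbol `CTH` becomes the constant `Cth`). A warning is
#' emitted when case normalization changes a leading lower-case letter.
#'
#' @param x Character vector of raw identifiers.
#' @return Character vector of valid constant names.
#' @export
const_name <- function(x) {
  x <- gsub("[^A-Za-z0-9_]", "_", as.character(x))
  lower <- grepl("^[a-z]", x)
  if (any(lower)) {
    warning("case-normalizing ", sum(lower),
            " identifier(s) starting with a lower-case letter (e.g. '",
            x[lower][1], "')")
  }
  # all-caps gene symbols are title-cased so constants read as in
  # Samechro(Cth,Id3); mixed-case identifiers only get their first letter fixed
  allcaps <- !grepl("[a-z]", x)
  ifelse(allcaps,
         paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x)))),
         paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x))))
}

expr_conditions <- c("wt", "siid2", "prcid2")
expr_predicates <- c(wt = "Expwt", siid2 = "Expsiid2", prcid2 = "Expprcid2")

check_expression <- function(expr) {
  need <- c("gene", expr_conditions)
  missing_cols <- setdiff(need, names(expr))
  if (length(missing_cols)) {
    stop("expression table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(expr$gene)) stop("duplicated gene in expression table")
  if (anyNA(expr[expr_conditions])) {
    stop("missing expression values; remove genes with incomplete information first")
  }
  invisible(expr)
}

#' Fit an equal-width discretization of expression values
#'
#' Per condition, the observed value range `[min, max]` is divided into
#' `n_bins` intervals of equal width. Bins are half-open `[e_k, e_{k+1})`
#' with the maximum assigned to the last bin. Fitting is per condition: the
#' three conditions come from different arrays, so their ranges are not
#' comparable.
#'
#' @param expr Data frame with columns `gene`, `wt`, `siid2`, `prcid2`.
#' @param n_bins Number of intervals (default 5).
#' @return A list of class `discretization_scheme` with per-condition edge
#'   vectors of length `n_bins + 1`.
#' @export
fit_discretization <- function(expr, n_bins = 5L) {
  check_expression(expr)
  stopifnot(n_bins >= 2L)
  edges <- lapply(expr_conditions, function(cond) {
    v <- expr[[cond]]
    if (length(unique(v)) < 2L) {
      stop("condition '", cond, "' is constant; equal-width bins would have zero width")
    }
    seq(min(v), max(v), length.out = n_bins + 1L)
  })
  names(edges) <- expr_conditions
  structure(list(n_bins = as.integer(n_bins), edges = edges),
            class = "discretization_scheme")
}

#' Map values to discretization levels
#'
#' @param values Numeric vector.
#' @param edges Edge vector of length `n_bins + 1` (from
#'   [fit_discretization()]).
#' @return Integer levels in `1..n_bins`; values outside the fitted range
#'   are clipped to the extreme bins.
#' @export
assign_levels <- function(values, edges) {
  n_bins <- length(edges) - 1L
  width <- (edges[n_bins + 1L] - edges[1L]) / n_bins
  lvl <- floor((values - edges[1L]) / width) + 1L
  as.integer(pmin(pmax(lvl, 1L), n_bins))
}

#' Encode expression levels as ground atoms
#'
#' Emits `Expwt(G,LevelK)`, `Expsiid2(G,LevelK)` and `Expprcid2(G,LevelK)`
#' for every gene: exactly three atoms per gene.
#'
#' @param expr Data frame with columns `gene`, `wt`, `siid2`, `prcid2`.
#' @param scheme A `discretization_scheme` fitted on `expr`.
#' @return List of ground `mln_atom`.
#' @export
encode_expression <- function(expr, scheme) {
  check_expression(expr)
  genes <- const_name(expr$gene)
  out <- list()
  for (cond in expr_conditions) {
    lvl <- assign_levels(expr[[cond]], scheme$edges[[cond]])
    for (i in seq_along(genes)) {
      out[[length(out) + 1L]] <-
        atom(expr_predicates[[cond]], c(genes[i], paste0("Level", lvl[i])))
    }
  }
  out
}

#' Derive expression-change predicates
#'
#' For each gene and each perturbed condition `Exp` in `{Prcid2, Siid2}`,
#' exactly one of `Expmore(G,Exp)`, `Expless(G,Exp)`, `Expsame(G,Exp)` is
#' emitted, comparing that condition's value to the wild type by fold
#' change: ratio above `fold_threshold` means more, below
#' `1/fold_threshold` means less, otherwise same. A zero wild-type value
#' with a positive perturbed value counts as more; two zeros as same.
#'
#' @param expr Data frame with columns `gene`, `wt`, `siid2`, `prcid2`
#'   (non-negative expression units).
#' @param fold_threshold Fold-change cutoff (default 1.5, the conventional
#'   differential-expression cutoff).
#' @return List of ground `mln_atom`, `2 * n_genes` atoms in total.
#' @export
derive_change_predicates <- function(expr, fold_threshold = 1.5) {
  check_expression(expr)
  stopifnot(fold_threshold > 1)
  genes <- const_name(expr$gene)
  out <- list()
  for (cond in c("prcid2", "siid2")) {
    cname <- if (cond == "prcid2") "Prcid2" else "Siid2"
    for (i in seq_along(genes)) {
      v <- expr[[cond]][i]
      w <- expr$wt[i]
      pred <- if (w == 0 && v == 0) {
        "Expsame"
      } else if (w == 0) {
        "Expmore"
      } else {
        r <- v / w
        if (r > fold_threshold) "Expmore"
        else if (r < 1 / fold_threshold) "Expless"
        else "Expsame"
      }
      out[[length(out) + 1L]] <- atom(pred, c(genes[i], cname))
    }
  }
  out
}

#' Bundle gene annotation tables
#'
#' @param go Data frame `gene`, `process` (GO biological process).
#' @param localization Data frame `gene`, `compartment`.
#' @param ppi Data frame `gene_a`, `gene_b` (unordered physical
#'   interactions).
#' @param chromosome Data frame `gene`, `chrom`, `arm_begin`, `band_begin`,
#'   `arm_end`, `band_end`.
#' @return A list of class `annotation_tables`.
#' @export
annotation_tables <- function(go = NULL, localization = NULL, ppi = NULL,
                              chromosome = NULL) {
  empty <- function(...) tibble::tibble(...)
  structure(list(
    go = if (is.null(go)) empty(gene = character(), process = character())
         else tibble::as_tibble(go),
    localization = if (is.null(localization))
      empty(gene = character(), compartment = character())
      else tibble::as_tibble(localization),
    ppi = if (is.null(ppi)) empty(gene_a = character(), gene_b = character())
          else tibble::as_tibble(ppi),
    chromosome = if (is.null(chromosome))
      empty(gene = character(), chrom = character(),
            arm_begin = character(), band_begin = numeric(),
            arm_end = character(), band_end = numeric())
      else tibble::as_tibble(chromosome)
  ), class = "annotation_tables")
}

# composite (arm, band) position comparison; arms compared lexically
# (p < q), bands numerically within an arm
pos_leq <- function(arm1, band1, arm2, band2) {
  ifelse(arm1 != arm2, arm1 < arm2, band1 <= band2)
}

#' Derive chromosomal-proximity predicates
#'
#' `Samechro(G1,G2)` is emitted (in both orders) for distinct genes on the
#' same chromosome; `Sameband(G1,G2)` additionally requires the genes'
#' chromosomal band intervals to overlap, comparing `(arm, band)` positions
#' with the arm ordered lexically (`p < q`) and the band numerically.
#'
#' @param annotations An [annotation_tables()] (only `$chromosome` is used).
#' @return List of ground `mln_atom`.
#' @export
derive_location_predicates <- function(annotations) {
  ch <- annotations$chromosome
  out <- list()
  if (nrow(ch) < 2L) return(out)
  genes <- const_name(ch$gene)
  for (i in seq_len(nrow(ch) - 1L)) {
    for (j in seq(i + 1L, nrow(ch))) {
      if (ch$chrom[i] != ch$chrom[j]) next
      out[[length(out) + 1L]] <- atom("Samechro", c(genes[i], genes[j]))
      out[[length(out) + 1L]] <- atom("Samechro", c(genes[j], genes[i]))
      overlap <-
        pos_leq(ch$arm_begin[i], ch$band_begin[i], ch$arm_end[j], ch$band_end[j]) &&
        pos_leq(ch$arm_begin[j], ch$band_begin[j], ch$arm_end[i], ch$band_end[i])
      if (isTRUE(overlap)) {
        out[[length(out) + 1L]] <- atom("Sameband", c(genes[i], genes[j]))
        out[[length(out) + 1L]] <- atom("Sameband", c(genes[j], genes[i]))
      }
    }
  }
  out
}

#' Encode a full dataset into an evidence database and labeled pairs
#'
#' Assembles the complete predicate vocabulary: discretized expression
#' (`Expwt`/`Expsiid2`/`Expprcid2`), expression change
#' (`Expmore`/`Expless`/`Expsame`), physical interaction (`Inteprot`,
#' emitted in both orders), localization (`ProtLoccell`), GO process
#' (`Processbio`) and chromosomal proximity (`Samechro`/`Sameband`).
#' Known regulations are routed to the label set, never to the evidence.
#'
#' @param expr Expression data frame (`gene`, `wt`, `siid2`, `prcid2`);
#'   genes with incomplete expression must be removed beforehand.
#' @param annotations An [annotation_tables()].
#' @param regulations Data frame `regulator`, `regulee` of known positive
#'   regulations (may be `NULL`).
#' @param n_bins Discretization bins (default 5).
#' @param fold_threshold Fold-change cutoff for the change predicates.
#' @return A list with `db` (an `evidence_db`), `positives` (tibble
#'   `regulator`, `regulee` in constant form), `genes` (character vector of
#'   gene constants) and `scheme` (the fitted discretization).
#' @export
encode_all <- function(expr, annotations = annotation_tables(),
                       regulations = NULL, n_bins = 5L,
                       fold_threshold = 1.5) {
  check_expression(expr)
  genes <- const_name(expr$gene)
  universe <- stats::setNames(genes, expr$gene)

  check_genes <- function(raw, what) {
    bad <- setdiff(const_name(raw), genes)
    if (length(bad)) {
      stop(what, " references gene(s) outside the expression universe: ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }

  scheme <- fit_discretization(expr, n_bins)
  atoms <- c(encode_expression(expr, scheme),
             derive_change_predicates(expr, fold_threshold))

  if (nrow(annotations$go)) {
    check_genes(annotations$go$gene, "GO annotation")
    g <- const_name(annotations$go$gene)
    p <- const_name(annotations$go$process)
    atoms <- c(atoms, lapply(seq_along(g), function(i) {
      atom("Processbio", c(g[i], p[i]))
    }))
  }
  if (nrow(annotations$localization)) {
    check_genes(annotations$localization$gene, "localization annotation")
    g <- const_name(annotations$localization$gene)
    l <- const_name(annotations$localization$compartment)
    atoms <- c(atoms, lapply(seq_along(g), function(i) {
      atom("ProtLoccell", c(g[i], l[i]))
    }))
  }
  if (nrow(annotations$ppi)) {
    check_genes(annotations$ppi$gene_a, "PPI table")
    check_genes(annotations$ppi$gene_b, "PPI table")
    ga <- const_name(annotations$ppi$gene_a)
    gb <- const_name(annotations$ppi$gene_b)
    keep <- ga != gb
    atoms <- c(atoms,
               lapply(which(keep), function(i) atom("Inteprot", c(ga[i], gb[i]))),
               lapply(which(keep), function(i) atom("Inteprot", c(gb[i], ga[i]))))
  }
  if (nrow(annotations$chromosome)) {
    check_genes(annotations$chromosome$gene, "chromosome table")
    atoms <- c(atoms, derive_location_predicates(annotations))
  }

  db <- evidence_db(atoms, sigs = default_signatures(),
                    extra_constants = list(
                      gene = genes,
                      level = paste0("Level", seq_len(n_bins)),
                      condition = c("Prcid2", "Siid2")
                    ))

  positives <- tibble::tibble(regulator = character(), regulee = character())
  if (!is.null(regulations) && nrow(regulations)) {
    check_genes(regulations$regulator, "regulation list")
    check_genes(regulations$regulee, "regulation list")
    positives <- tibble::tibble(regulator = const_name(regulations$regulator),
                                regulee = const_name(regulations$regulee))
    positives <- dplyr::distinct(positives)
  }
  list(db = db, positives = positives, genes = genes, scheme = scheme)
}

#' Read the descriptor TSV suite from a directory
#'
#' Expects `expression.tsv` (gene, wt, siid2, prcid2) and optionally
#' `go.tsv` (gene, process), `localization.tsv` (gene, compartment),
#' `ppi.tsv` (gene_a, gene_b), `chromosome.tsv` (gene, chrom, arm_begin,
#' band_begin, arm_end, band_end) and `regulations.tsv` (regulator,
#' regulee). All files are tab-separated with a header row.
#'
#' @param dir Directory path.
#' @return A list with `expression`, `annotations` (an
#'   [annotation_tables()]) and `regulations` (tibble or `NULL`).
#' @export
read_descriptor_tables <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
  }
  expr <- rd("expression.tsv")
  if (is.null(expr)) stop("expression.tsv not found in ", dir)
  list(expression = expr,
       annotations = annotation_tables(go = rd("go.tsv"),
                                       localization = rd("localization.tsv"),
                                       ppi = rd("ppi.tsv"),
                                       chromosome = rd("chromosome.tsv")),
       regulations = rd("regulations.tsv"))
}
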