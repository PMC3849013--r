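#' Configuration of the synthetic regulatory-network generator
#'
#' The generator emulates the statistical structure the learners consume: a
#' gene universe with heterogeneous attributes (discretizable expression
#' levels in three conditions, GO-like process annotations, subcellular
#' localizations, physical interactions, chromosomal locations) and a
#' directed regulation network *planted* to satisfy known Horn rules, so
#' that rule induction, weight learning, bagging and the three study
#' protocols can all be tested against a known ground truth.
#'
#' The two default planted rules mirror the two kinds of printed rule
#' shapes the method is meant to recover: a symbolic GO-process rule
#' (`Processbio(g2,Proc01) ^ Processbio(g1,Proc02) => Regulates(g1,g2)`)
#' and a discretized-expression rule
#' (`Expsiid2(g1,Level3) ^ Expprcid2(g2,Level5) => Regulates(g1,g2)`).
#'
#' @param n_genes_train Genes in the training universe (default 50).
#' @param n_genes_new Genes in the held-out universe for the new-gene study
#'   (default 15).
#' @param n_processes,n_locations,n_chromosomes Vocabulary sizes.
#' @param planted_rules List of `mln_clause` concluding on `Regulates`;
#'   `NULL` for the two defaults above.
#' @param p_rule Probability that a pair matching a planted rule's body is
#'   a true edge (default 1).
#' @param background_edge_rate Probability that a non-matching pair is a
#'   true edge (default 0).
#' @param attribute_noise Per-gene, per-attribute-group probability of
#'   re-randomizing the attribute after edges are planted (default 0).
#' @param rule_process_prob Probability a gene carries each of the two
#'   rule processes (default 0.15; calibrates planted-rule match frequency).
#' @param ppi_rate Per unordered pair probability of a physical interaction.
#' @param holdout_fraction Fraction of within-train edges withheld from the
#'   earlier network snapshot t0 (default 1/3, mirroring a two-year
#'   curation update in which roughly a third of the final regulations were
#'   not yet known).
#' @param seed Master seed; the dataset is a deterministic function of the
#'   configuration.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_genes_train = 50L, n_genes_new = 15L,
                             n_processes = 12L, n_locations = 6L,
                             n_chromosomes = 10L, planted_rules = NULL,
                             p_rule = 1, background_edge_rate = 0,
                             attribute_noise = 0, rule_process_prob = 0.15,
                             ppi_rate = 0.03, holdout_fraction = 1 / 3,
                             seed = 1L) {
  stopifnot(n_genes_train >= 5L, p_rule > 0, p_rule <= 1,
            background_edge_rate >= 0, background_edge_rate <= 1,
            attribute_noise >= 0, attribute_noise <= 1)
  if (is.null(planted_rules)) {
    planted_rules <- list(
      parse_clause(paste0("Processbio(g2,Proc01) ^ Processbio(g1,Proc02)",
                          " => Regulates(g1,g2)")),
      parse_clause(paste0("Expsiid2(g1,Level3) ^ Expprcid2(g2,Level5)",
                          " => Regulates(g1,g2)"))
    )
  }
  for (cl in planted_rules) {
    if (cl$head$pred != "Regulates") {
      stop("planted rules must conclude on Regulates")
    }
  }
  structure(list(n_genes_train = as.integer(n_genes_train),
                 n_genes_new = as.integer(n_genes_new),
                 n_processes = as.integer(n_processes),
                 n_locations = as.integer(n_locations),
                 n_chromosomes = as.integer(n_chromosomes),
                 planted_rules = planted_rules, p_rule = p_rule,
                 background_edge_rate = background_edge_rate,
                 attribute_noise = attribute_noise,
                 rule_process_prob = rule_process_prob,
                 ppi_rate = ppi_rate, holdout_fraction = holdout_fraction,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# attribute tables for a set of gene names; returns list(expression, go,
# localization, ppi, chromosome) with discrete level bookkeeping
draw_attributes <- function(genes, cfg) {
  n <- length(genes)
  procs <- sprintf("Proc%02d", seq_len(cfg$n_processes))
  locs <- sprintf("Loc%02d", seq_len(cfg$n_locations))
  chroms <- sprintf("Chr%02d", seq_len(cfg$n_chromosomes))

  levels <- matrix(sample(1:5, n * 3, replace = TRUE), n, 3,
                   dimnames = list(genes, expr_conditions))
  # anchor genes pin the value range so equal-width bin edges fall exactly
  # on the integers and planted levels survive discretization
  levels[1, ] <- 1L
  levels[2, ] <- 5L
  values <- (levels - 1) + matrix(stats::runif(n * 3), n, 3)
  values[1, ] <- 0
  values[2, ] <- 5

  go <- list()
  for (i in seq_len(n)) {
    ps <- character(0)
    if (stats::runif(1) < cfg$rule_process_prob) ps <- c(ps, procs[1])
    if (stats::runif(1) < cfg$rule_process_prob) ps <- c(ps, procs[2])
    extra <- sample(procs[-(1:2)], sample(1:2, 1))
    ps <- unique(c(ps, extra))
    go[[i]] <- tibble::tibble(gene = genes[i], process = ps)
  }

  ppi <- tibble::tibble(gene_a = character(), gene_b = character())
  if (n >= 2L) {
    idx <- utils::combn(n, 2)
    hit <- stats::runif(ncol(idx)) < cfg$ppi_rate
    ppi <- tibble::tibble(gene_a = genes[idx[1, hit]],
                          gene_b = genes[idx[2, hit]])
  }

  arm <- sample(c("p", "q"), n, replace = TRUE)
  band_begin <- sample(10:30, n, replace = TRUE)
  list(
    expression = tibble::tibble(gene = genes, wt = values[, "wt"],
                                siid2 = values[, "siid2"],
                                prcid2 = values[, "prcid2"]),
    levels = levels,
    go = dplyr::bind_rows(go),
    localization = tibble::tibble(gene = genes,
                                  compartment = sample(locs, n, replace = TRUE)),
    ppi = ppi,
    chromosome = tibble::tibble(gene = genes,
                                chrom = sample(chroms, n, replace = TRUE),
                                arm_begin = arm, band_begin = band_begin,
                                arm_end = arm,
                                band_end = band_begin + sample(0:4, n, replace = TRUE))
  )
}

# re-randomize attribute groups per gene with probability `rate`
corrupt_attributes <- function(att, cfg, rate) {
  if (rate == 0) return(att)
  genes <- att$expression$gene
  n <- length(genes)
  procs <- sprintf("Proc%02d", seq_len(cfg$n_processes))
  locs <- sprintf("Loc%02d", seq_len(cfg$n_locations))
  for (i in seq_len(n)) {
    if (stats::runif(1) < rate) {
      lv <- sample(1:5, 3, replace = TRUE)
      att$expression[i, expr_conditions] <- as.list((lv - 1) + stats::runif(3))
      att$levels[i, ] <- lv
    }
    if (stats::runif(1) < rate) {
      ps <- unique(sample(procs, sample(1:3, 1)))
      att$go <- dplyr::bind_rows(att$go[att$go$gene != genes[i], ],
                                 tibble::tibble(gene = genes[i], process = ps))
    }
    if (stats::runif(1) < rate) {
      att$localization$compartment[i] <- sample(locs, 1)
    }
  }
  # keep the range anchors intact so bin edges stay exact
  att$expression[1, expr_conditions] <- list(0, 0, 0)
  att$expression[2, expr_conditions] <- list(5, 5, 5)
  att$levels[1, ] <- 1L
  att$levels[2, ] <- 5L
  att
}

#' Generate a synthetic dataset with a planted regulation network
#'
#' Draws gene attributes, encodes them, plants a true edge (with
#' probability `p_rule`) on every ordered pair whose attributes satisfy a
#' planted rule's body and (with probability `background_edge_rate`) on any
#' other pair, withholds a fraction of the within-train edges from the
#' earlier network snapshot t0, and finally applies attribute noise. The
#' per-edge provenance (which rule produced it) is kept as bookkeeping.
#'
#' @param config A [generator_config()].
#' @return A list of class `grn_dataset` with elements `expression`,
#'   `annotations`, `regulations` (tibble `regulator`, `regulee`, `rule`,
#'   `in_t0`), `universe_train`, `universe_new`, `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  cfg <- config
  for (cl in cfg$planted_rules) {
    preds <- vapply(cl$body, `[[`, character(1), "pred")
    known <- names(default_signatures())
    if (!all(preds %in% known)) {
      stop("planted rule uses predicates outside the vocabulary: ",
           paste(setdiff(preds, known), collapse = ", "))
    }
  }
  withr::with_seed(cfg$seed, {
    genes_train <- sprintf("Ga%02d", seq_len(cfg$n_genes_train))
    genes_new <- if (cfg$n_genes_new > 0L) {
      sprintf("Gb%02d", seq_len(cfg$n_genes_new))
    } else character(0)
    att <- draw_attributes(c(genes_train, genes_new), cfg)
    annotations <- annotation_tables(go = att$go,
                                     localization = att$localization,
                                     ppi = att$ppi,
                                     chromosome = att$chromosome)
    clean <- encode_all(att$expression, annotations)
    genes <- clean$genes

    # plant edges by matching rule bodies against the clean evidence
    pairs <- enumerate_candidate_pairs(genes, include_self = TRUE)
    rule_hit <- rep(NA_character_, nrow(pairs))
    for (r in seq_along(cfg$planted_rules)) {
      cl <- cfg$planted_rules[[r]]
      hit <- vapply(seq_len(nrow(pairs)), function(i) {
        covers(cl, regulates_atom(pairs$regulator[i], pairs$regulee[i]),
               clean$db)
      }, logical(1))
      rule_hit[is.na(rule_hit) & hit] <- paste0("rule", r)
    }
    u <- stats::runif(nrow(pairs))
    is_edge <- ifelse(!is.na(rule_hit), u < cfg$p_rule,
                      u < cfg$background_edge_rate)
    regulations <- tibble::tibble(
      regulator = pairs$regulator[is_edge],
      regulee = pairs$regulee[is_edge],
      rule = dplyr::coalesce(rule_hit[is_edge], "background")
    )
    # earlier snapshot: withhold a fraction of the within-train edges
    within <- regulations$regulator %in% genes_train &
      regulations$regulee %in% genes_train
    regulations$in_t0 <- within
    w_idx <- which(within)
    n_hold <- round(cfg$holdout_fraction * length(w_idx))
    if (n_hold > 0L && length(w_idx) > n_hold) {
      regulations$in_t0[sample(w_idx, n_hold)] <- FALSE
    }

    att <- corrupt_attributes(att, cfg, cfg$attribute_noise)
  })
  structure(list(
    expression = att$expression,
    annotations = annotation_tables(go = att$go,
                                    localization = att$localization,
                                    ppi = att$ppi,
                                    chromosome = att$chromosome),
    regulations = regulations,
    universe_train = genes_train,
    universe_new = genes_new,
    config = cfg
  ), class = "grn_dataset")
}

#' @export
print.grn_dataset <- function(x, ...) {
  cat("<grn_dataset> ", length(x$universe_train), " train + ",
      length(x$universe_new), " new genes, ", nrow(x$regulations),
      " true regulations (", sum(x$regulations$in_t0), " in t0)\n", sep = "")
  invisible(x)
}

#' Encode a synthetic dataset into an evidence database
#'
#' @param ds A `grn_dataset`.
#' @param universe `"all"` (default) or `"train"` to restrict the evidence
#'   to the training universe.
#' @return As [encode_all()].
#' @export
encode_dataset <- function(ds, universe = c("all", "train")) {
  universe <- match.arg(universe)
  expr <- ds$expression
  ann <- ds$annotations
  if (universe == "train") {
    keep <- expr$gene %in% ds$universe_train
    expr <- expr[keep, , drop = FALSE]
    g <- ds$universe_train
    ann <- annotation_tables(
      go = ann$go[ann$go$gene %in% g, ],
      localization = ann$localization[ann$localization$gene %in% g, ],
      ppi = ann$ppi[ann$ppi$gene_a %in% g & ann$ppi$gene_b %in% g, ],
      chromosome = ann$chromosome[ann$chromosome$gene %in% g, ]
    )
  }
  encode_all(expr, ann,
             regulations = ds$regulations[, c("regulator", "regulee")])
}

#' Build the labeled pair sets for a study protocol
#'
#' Study 1: within-train t0 positives against the complement of the t0
#' positives over the train universe (self-pairs included). Study 2: t0
#' positives for training, the t1-minus-t0 positives (all positive) for
#' testing, with the negative pool excluding every t1 positive. Study 3:
#' all within-train t1 positives for training and the full cross-universe
#' candidate space (both directions) for testing.
#'
#' @param ds A `grn_dataset`.
#' @param study 1, 2 or 3.
#' @return A list whose components depend on the study (positives, pool,
#'   and for studies 2-3 the test sets).
#' @export
make_study_splits <- function(ds, study) {
  stopifnot(study %in% 1:3)
  ga <- ds$universe_train
  reg <- ds$regulations
  within <- reg[reg$regulator %in% ga & reg$regulee %in% ga, ]
  pos_t0 <- tibble::as_tibble(within[within$in_t0, c("regulator", "regulee")])
  pos_t1 <- tibble::as_tibble(within[, c("regulator", "regulee")])
  all_pairs <- enumerate_candidate_pairs(ga, include_self = TRUE)
  if (study == 1) {
    list(positives = pos_t0, pool = pairs_setdiff(all_pairs, pos_t0))
  } else if (study == 2) {
    list(positives_t0 = pos_t0, positives_t1 = pos_t1,
         pool = pairs_setdiff(all_pairs, pos_t0),
         test_positives = pairs_setdiff(pos_t1, pos_t0))
  } else {
    if (length(ds$universe_new) == 0L) {
      stop("study 3 requires a non-empty new gene universe")
    }
    gb <- ds$universe_new
    cross <- reg[(reg$regulator %in% ga & reg$regulee %in% gb) |
                   (reg$regulator %in% gb & reg$regulee %in% ga), ]
    list(positives = pos_t1, pool = pairs_setdiff(all_pairs, pos_t1),
         universe_a = ga, universe_b = gb,
         test_positives = tibble::as_tibble(cross[, c("regulator", "regulee")]))
  }
}

#' Write a synthetic dataset as a TSV suite plus manifest
#'
#' Emits `expression.tsv`, `go.tsv`, `localization.tsv`, `ppi.tsv`,
#' `chromosome.tsv`, `regulations.tsv` (t0 positives), and
#' `manifest.json` with the full edge provenance and generator settings.
#'
#' @param ds A `grn_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) readr::write_tsv(df, file.path(dir, f), progress = FALSE)
  wr(ds$expression, "expression.tsv")
  wr(ds$annotations$go, "go.tsv")
  wr(ds$annotations$localization, "localization.tsv")
  wr(ds$annotations$ppi, "ppi.tsv")
  wr(ds$annotations$chromosome, "chromosome.tsv")
  wr(ds$regulations[ds$regulations$in_t0, c("regulator", "regulee")],
     "regulations.tsv")
  manifest <- list(
    config = ds$config[setdiff(names(ds$config), "planted_rules")],
    planted_rules = vapply(ds$config$planted_rules, format, character(1)),
    universe_train = ds$universe_train,
    universe_new = ds$universe_new,
    edges = ds$regulations
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
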