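# Shared fixture builders. Everything is constructed in code; no files.

# tiny two-gene world of the grounding worked example
example_clause1 <- function() {
  parse_clause(paste0(
    "Processbio(g2,Cell_proliferation) ^ ",
    "Processbio(g1,Negative_regulation_of_cell_proliferation)",
    " => Regulates(g1,g2)"))
}

example_world_db <- function() {
  evidence_db(c(
    "Processbio(B,Cell_proliferation)",
    "Processbio(A,Negative_regulation_of_cell_proliferation)"
  ))
}

# a small random evidence database over n_genes genes with the expression /
# process / localization predicate families populated at random
random_db <- function(n_genes = 4, seed = 1, n_process = 3) {
  withr::with_seed(seed, {
    genes <- paste0("G", seq_len(n_genes))
    atoms <- character(0)
    for (g in genes) {
      atoms <- c(atoms,
                 sprintf("Expwt(%s,Level%d)", g, sample(1:5, 1)),
                 sprintf("Expsiid2(%s,Level%d)", g, sample(1:5, 1)),
                 sprintf("Expprcid2(%s,Level%d)", g, sample(1:5, 1)))
      for (p in sample(paste0("P", seq_len(n_process)), sample(1:2, 1))) {
        atoms <- c(atoms, sprintf("Processbio(%s,%s)", g, p))
      }
    }
    pairs <- expand.grid(a = genes, b = genes, stringsAsFactors = FALSE)
    hit <- runif(nrow(pairs)) < 0.2
    atoms <- c(atoms, sprintf("Inteprot(%s,%s)", pairs$a[hit], pairs$b[hit]))
    evidence_db(unique(atoms), extra_constants = list(gene = genes))
  })
}

# random non-recursive clause over the default vocabulary with head
# Regulates(g1,g2) and n_body atoms using variables from g1,g2,g3
random_clause <- function(seed = 1, n_body = 2) {
  withr::with_seed(seed, {
    body <- character(n_body)
    for (i in seq_len(n_body)) {
      kind <- sample(c("exp", "proc", "inte"), 1)
      v <- sample(c("g1", "g2", "g3"), 1)
      body[i] <- switch(kind,
        exp = sprintf("Exp%s(%s,Level%d)",
                      sample(c("wt", "siid2", "prcid2"), 1), v, sample(1:5, 1)),
        proc = sprintf("Processbio(%s,P%d)", v, sample(1:3, 1)),
        inte = sprintf("Inteprot(%s,%s)", v, sample(c("g1", "g2", "g3"), 1)))
    }
    parse_clause(paste(paste(body, collapse = " ^ "), "=> Regulates(g1,g2)"))
  })
}

# independent brute-force oracle: enumerate all sort-respecting
# substitutions with expand.grid and evaluate the implication directly
oracle_count_true_groundings <- function(cl, db) {
  vsorts <- clause_var_sorts(cl, db$sigs)
  if (length(vsorts) == 0L) {
    body_true <- all(vapply(cl$body, function(a) db_contains(db, a), logical(1)))
    return(as.integer(!body_true || db_contains(db, cl$head)))
  }
  vars <- names(vsorts)
  pools <- lapply(vars, function(v) db_constants(db, vsorts[[v]]))
  grid <- expand.grid(pools, stringsAsFactors = FALSE)
  names(grid) <- vars
  n <- 0L
  for (i in seq_len(nrow(grid))) {
    subst <- stats::setNames(as.character(grid[i, ]), vars)
    gc <- substitute_clause(cl, subst)
    body_true <- all(vapply(gc$body, function(a) db_contains(db, a), logical(1)))
    if (!body_true || db_contains(db, gc$head)) n <- n + 1L
  }
  n
}

# brute-force coverage oracle: try every assignment of the clause's
# variables and test head match plus body truth
oracle_covers <- function(cl, example, db) {
  if (is.character(example)) example <- parse_atom(example, db$sigs)
  vsorts <- clause_var_sorts(cl, db$sigs)
  vars <- names(vsorts)
  if (length(vars) == 0L) {
    return(format(cl$head) == format(example) &&
             all(vapply(cl$body, function(a) db_contains(db, a), logical(1))))
  }
  pools <- lapply(vars, function(v) db_constants(db, vsorts[[v]]))
  grid <- expand.grid(pools, stringsAsFactors = FALSE)
  names(grid) <- vars
  for (i in seq_len(nrow(grid))) {
    subst <- stats::setNames(as.character(grid[i, ]), vars)
    gc <- substitute_clause(cl, subst)
    if (format(gc$head) != format(example)) next
    if (all(vapply(gc$body, function(a) db_contains(db, a), logical(1)))) {
      return(TRUE)
    }
  }
  FALSE
}

# exhaustive world-enumeration oracle for the conditional probability of a
# query atom: P(Y_j = 1 | evidence) over all truth assignments of the query
# atoms, with weights w on the clauses (Markov-network conditional)
oracle_posterior <- function(clauses, weights, db, queries, j) {
  q <- nrow(queries)
  qatoms <- sprintf("Regulates(%s,%s)", queries$regulator, queries$regulee)
  num <- 0
  den <- 0
  for (mask in 0:(2^q - 1)) {
    on <- as.logical(bitwAnd(mask, 2^(seq_len(q) - 1L)))
    world <- if (any(on)) db_add(db, qatoms[on]) else db
    logw <- sum(weights * vapply(clauses, count_true_groundings, numeric(1),
                                 db = world))
    den <- den + exp(logw)
    if (on[j]) num <- num + exp(logw)
  }
  num / den
}

# a small deterministic scored-pairs tibble
scored_fixture <- function(seed = 1, n = 20) {
  withr::with_seed(seed, {
    label <- rbinom(n, 1, 0.4)
    score <- round(runif(n), 2)  # rounding forces ties
    tibble::tibble(score = score, label = label)
  })
}

# Mann-Whitney pair-counting AUC oracle with half credit for ties
oracle_auc_mw <- function(sp) {
  pos <- sp$score[sp$label == 1]
  neg <- sp$score[sp$label == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}
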