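two_gene_queries <- function(genes = c("A", "B")) {
  grid <- expand.grid(regulee = genes, regulator = genes,
                      stringsAsFactors = FALSE)
  tibble::tibble(regulator = grid$regulator, regulee = grid$regulee)
}

test_that("MLN construction rejects recursive or off-target clauses", {
  expect_error(new_mln(list(parse_clause("Processbio(g1,P1) => Expwt(g1,Level1)"))),
               "conclude on Regulates")
  expect_error(new_mln(list(parse_clause("Regulates(g1,g2) => Regulates(g2,g1)"))),
               "recursive")
})

test_that("clamped grounding counts behave at the boundary cases", {
  db <- example_world_db()
  cl <- example_clause1()
  m <- new_mln(list(cl))
  qs <- two_gene_queries()
  cnt <- compute_counts(m, db, qs)
  # body true only for the (A,B) grounding: n0 = 0, n1 = 1 there
  i_ab <- which(qs$regulator == "A" & qs$regulee == "B")
  expect_equal(cnt$n0[i_ab, 1], 0)
  expect_equal(cnt$n1[i_ab, 1], 1)
  # every other head's body is false: implication vacuously true either way
  expect_equal(cnt$n0[-i_ab, 1], rep(1, 3))
  expect_equal(cnt$n1[-i_ab, 1], rep(1, 3))
  # n1 >= n0 always
  expect_true(all(cnt$n1 >= cnt$n0))
})

test_that("counts match the logic-core brute force on random KBs", {
  for (s in 1:8) {
    db <- random_db(2, seed = s)
    cl <- random_clause(seed = s + 200, n_body = sample(1:2, 1))
    qs <- two_gene_queries(db_constants(db, "gene"))
    cnt <- compute_counts(new_mln(list(cl)), db, qs)
    for (j in seq_len(nrow(qs))) {
      y <- sprintf("Regulates(%s,%s)", qs$regulator[j], qs$regulee[j])
      # oracle: count groundings with this head via full instantiation
      insts <- instantiate_clause(cl, db)
      with_head <- Filter(function(g) format(g$head) == y, insts)
      db1 <- db_add(db, y)
      n1 <- sum(vapply(with_head, eval_ground_clause, logical(1), db = db1))
      n0 <- sum(vapply(with_head, eval_ground_clause, logical(1), db = db))
      expect_equal(cnt$n1[j, 1], n1, info = paste(s, y))
      expect_equal(cnt$n0[j, 1], n0, info = paste(s, y))
    }
  }
})

test_that("query posteriors reduce to the logistic of the weighted count gap", {
  db <- example_world_db()
  cl <- example_clause1()
  qs <- two_gene_queries()
  m0 <- new_mln(list(cl), 0)
  cnt <- compute_counts(m0, db, qs)
  expect_equal(query_posterior(m0, cnt, 1), 0.5)
  m2 <- new_mln(list(cl), 2)
  i_ab <- which(qs$regulator == "A" & qs$regulee == "B")
  expect_equal(query_posterior(m2, cnt, i_ab), 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  # normalization: P(Y=0) + P(Y=1) = 1 by construction of the two-term ratio
  p1 <- query_posterior(m2, cnt, i_ab)
  expect_equal(p1 + (1 - p1), 1)
})

test_that("posteriors equal exhaustive world enumeration on tiny KBs", {
  for (s in 1:10) {
    db <- random_db(2, seed = s, n_process = 2)
    clauses <- list(random_clause(seed = s + 300, n_body = 1),
                    random_clause(seed = s + 400, n_body = 2))
    weights <- withr::with_seed(s, stats::runif(2, -1.5, 1.5))
    m <- new_mln(clauses, weights)
    qs <- two_gene_queries(db_constants(db, "gene"))
    cnt <- compute_counts(m, db, qs)
    for (j in seq_len(nrow(qs))) {
      expect_equal(query_posterior(m, cnt, j),
                   oracle_posterior(clauses, weights, db, qs, j),
                   tolerance = 1e-10, info = paste("seed", s, "query", j))
    }
  }
})

test_that("the penalized conditional log-likelihood and gradient are correct", {
  db <- example_world_db()
  m <- new_mln(list(example_clause1()))
  qs <- two_gene_queries()
  cnt <- compute_counts(m, db, qs)
  labels <- as.integer(qs$regulator == "A" & qs$regulee == "B")

  # w = 0: every query contributes log(1/2)
  expect_equal(penalized_cll(0, cnt, labels, 0), nrow(qs) * log(0.5))

  # single-query scalar check against log sigma(+-w * dn)
  one <- list(n0 = cnt$n0[2, , drop = FALSE], n1 = cnt$n1[2, , drop = FALSE],
              delta = cnt$delta[2, , drop = FALSE])
  w <- 0.7
  dn <- one$delta[1, 1]
  expect_equal(penalized_cll(w, one, 1, 0), log(stats::plogis(w * dn)))
  expect_equal(penalized_cll(w, one, 0, 0), log(stats::plogis(-w * dn)))

  # analytic gradient vs central finite differences on random instances
  for (s in 1:6) {
    withr::with_seed(s, {
      p <- 3
      delta <- matrix(sample(0:2, 12, replace = TRUE), 4, p)
      cnt2 <- list(n0 = delta * 0, n1 = delta, delta = delta)
      lab <- rbinom(4, 1, 0.5)
      w0 <- rnorm(p)
      lam <- runif(1, 0, 2)
    })
    g <- penalized_cll_gradient(w0, cnt2, lab, lam)
    h <- 1e-6
    for (k in 1:3) {
      e <- numeric(3); e[k] <- h
      fd <- (penalized_cll(w0 + e, cnt2, lab, lam) -
               penalized_cll(w0 - e, cnt2, lab, lam)) / (2 * h)
      expect_equal(g[k], fd, tolerance = 1e-5)
    }
  }
})

test_that("weight learning maximizes the objective deterministically", {
  db <- example_world_db()
  clauses <- list(example_clause1())
  qs <- two_gene_queries()
  labels <- as.integer(qs$regulator == "A" & qs$regulee == "B")
  qs$label <- labels

  m <- learn_weights(clauses, db, qs, config = training_config(lambda = 0.1))
  expect_gte(attr(m, "objective"),
             penalized_cll(0, compute_counts(new_mln(clauses), db, qs),
                           labels, 0.1))
  m2 <- learn_weights(clauses, db, qs, config = training_config(lambda = 0.1))
  expect_identical(m$weights, m2$weights)

  # an overwhelming penalty shrinks the weights to zero and posteriors to 1/2
  m3 <- learn_weights(clauses, db, qs, config = training_config(lambda = 1e9))
  expect_lt(max(abs(m3$weights)), 1e-4)
  expect_equal(predict(m3, db, qs[, 1:2])$score, rep(0.5, 4), tolerance = 1e-3)
})

test_that("a separating clause achieves perfect training ranking", {
  db <- evidence_db(c("Processbio(A,P1)", "Processbio(C,P1)",
                      "Expwt(A,Level1)", "Expwt(B,Level1)", "Expwt(C,Level1)"),
                    extra_constants = list(gene = c("A", "B", "C")))
  cl <- parse_clause("Processbio(g1,P1) => Regulates(g1,g2)")
  qs <- tibble::tibble(regulator = c("A", "C", "B", "B"),
                       regulee = c("B", "B", "A", "C"),
                       label = c(1, 1, 0, 0))
  m <- learn_weights(list(cl), db, qs, config = training_config(lambda = 0.01))
  sc <- predict(m, db, qs[, 1:2])$score
  expect_true(all(sc[qs$label == 1] > 0.5))
  expect_equal(sc[qs$label == 0], rep(0.5, 2))  # n1 = n0 keeps them at 1/2
  expect_equal(roc_auc(tibble::tibble(score = sc, label = qs$label))$auc, 1)
})

test_that("the optimal weight norm is non-increasing along the lambda grid", {
  ds <- generate_dataset(generator_config(n_genes_train = 12, n_genes_new = 0,
                                          seed = 5))
  enc <- encode_dataset(ds)
  sp <- make_study_splits(ds, 1)
  neg <- sample_negatives(sp$pool, nrow(sp$positives), 2)
  train <- dplyr::bind_rows(dplyr::mutate(sp$positives, label = 1),
                            dplyr::mutate(neg, label = 0))
  th <- induce(train[train$label == 1, 1:2], train[train$label == 0, 1:2], enc$db)
  expect_gt(length(th$clauses), 0)
  cnt <- compute_counts(new_mln(th$clauses), enc$db, train)
  norms <- vapply(lambda_grid(), function(lam) {
    m <- learn_weights(th$clauses, enc$db, train, config = training_config(lambda = lam),
                       counts = cnt)
    sqrt(sum(m$weights^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("prediction contracts hold", {
  db <- example_world_db()
  qs <- two_gene_queries()
  # empty clause list: all scores 1/2
  m0 <- new_mln(list())
  expect_equal(predict(m0, db, qs)$score, rep(0.5, 4))
  # duplicated clause at half weight scores identically (linear exponent)
  cl <- example_clause1()
  m1 <- new_mln(list(cl), 1.4)
  m2 <- new_mln(list(cl, cl), c(0.7, 0.7))
  expect_equal(predict(m1, db, qs)$score, predict(m2, db, qs)$score)
  # unknown genes are reported
  expect_error(predict(m1, db, tibble::tibble(regulator = "Z", regulee = "A")),
               "unknown")
})

test_that("MLN files round-trip weights and clauses", {
  m <- new_mln(list(example_clause1(),
                    parse_clause("Expwt(g1,Level2) => Regulates(g1,g2)")),
               c(0.25, -1.75))
  path <- withr::local_tempfile(fileext = ".mln")
  write_mln(m, path)
  back <- read_mln(path)
  expect_equal(back$weights, m$weights)
  expect_identical(vapply(back$clauses, format, character(1)),
                   vapply(m$clauses, format, character(1)))
})
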