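test_that("candidate pair spaces have the published cardinalities", {
  ga <- sprintf("G%02d", 1:63)
  within <- enumerate_candidate_pairs(ga)
  expect_identical(nrow(within), 63L * 63L)
  # 106 known regulations leave 3863 unlabeled candidate pairs
  some_pos <- within[round(seq(1, nrow(within), length.out = 106)), ]
  expect_identical(nrow(pairs_setdiff(within, some_pos)), 3969L - 106L)

  gb <- sprintf("H%02d", 1:24)
  cross <- enumerate_candidate_pairs(ga, gb)
  expect_identical(nrow(cross), 2L * 63L * 24L)
  some_cross <- cross[round(seq(2, nrow(cross), length.out = 55)), ]
  expect_identical(nrow(pairs_setdiff(cross, some_cross)), 3024L - 55L)

  expect_identical(nrow(enumerate_candidate_pairs("G1", include_self = FALSE)), 0L)
  expect_error(enumerate_candidate_pairs(ga, ga), "disjoint")
})

test_that("negative sampling is balanced, seeded and respects exclusions", {
  pool <- enumerate_candidate_pairs(paste0("G", 1:10))
  s1 <- sample_negatives(pool, 15, seed = 3)
  s2 <- sample_negatives(pool, 15, seed = 3)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 15L)
  s3 <- sample_negatives(pool, 15, seed = 4)
  expect_false(identical(s1, s3))

  excl <- pool[1:95, ]
  s4 <- sample_negatives(pool, 5, seed = 1, exclusions = excl)
  expect_identical(nrow(s4), 5L)
  expect_false(any(regmln:::pair_keys(s4) %in% regmln:::pair_keys(excl)))
  expect_error(sample_negatives(pool, 6, seed = 1, exclusions = excl),
               "too small")

  # repeated draws with distinct seeds are not all identical
  draws <- lapply(1:30, function(s) sample_negatives(pool, 10, s))
  keys <- vapply(draws, function(d) paste(regmln:::pair_keys(d), collapse = ";"),
                 character(1))
  expect_gt(length(unique(keys)), 1)
})

test_that("the F1 measure follows the harmonic-mean formula with limits", {
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(1, 0), 0)
  expect_equal(f1_score(0.5, 0.5), 0.5)
  expect_equal(f1_score(0.25, 0.75), 2 * 0.25 * 0.75 / (0.25 + 0.75))
})

test_that("threshold selection maximizes the averaged F1 on a grid", {
  # perfectly separated scores: any threshold in (0.1, 0.9] is maximal,
  # ties resolve to the smallest grid point above the top negative
  scores <- c(0.95, 0.92, 0.91, 0.08, 0.05)
  labels <- c(1, 1, 1, 0, 0)
  th <- select_threshold(list(scores), list(labels))
  expect_equal(th, 0.09)

  # single sample agrees with exhaustive grid evaluation
  sc <- c(0.9, 0.6, 0.55, 0.4, 0.2)
  lb <- c(1, 0, 1, 1, 0)
  grid <- seq(0, 1, by = 0.01)
  f1s <- vapply(grid, function(t) {
    tp <- sum(sc >= t & lb == 1); fp <- sum(sc >= t & lb == 0)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- tp / sum(lb == 1)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  expect_equal(select_threshold(list(sc), list(lb), grid),
               grid[which.max(f1s)])

  # degenerate: no threshold achieves a positive F1
  expect_warning(th0 <- select_threshold(list(c(0.2, 0.1)), list(c(0, 0))),
                 "zero")
  expect_equal(th0, 0.5)
})

# a trivial deterministic learner whose scores depend on the bag's negative
# sample (so ensemble averaging has something to smooth)
memorizing_learner <- function() {
  structure(list(
    fit = function(train, db) {
      list(pos_reg = unique(train$regulator[train$label == 1]),
           neg_reg = unique(train$regulator[train$label == 0]))
    },
    predict = function(model, pairs, db) {
      0.8 * (pairs$regulator %in% model$pos_reg) +
        0.2 * !(pairs$regulator %in% model$neg_reg)
    },
    label = "memorizer"
  ), class = "base_learner")
}

test_that("asymmetric bagging trains balanced base models and averages scores", {
  genes <- paste0("G", 1:12)
  pool <- enumerate_candidate_pairs(genes)
  pos <- pool[c(5, 20, 40, 60, 80), ]
  pool <- pairs_setdiff(pool, pos)
  bm <- fit_bagged(pos, pool, db = NULL, learner = memorizing_learner(),
                   B = 7, seed = 2)
  expect_identical(bm$B, 7L)
  expect_true(all(vapply(bm$neg_samples, nrow, integer(1)) == nrow(pos)))
  # every bag sees the identical positive set by construction; scores are means
  pred <- predict(bm, pool[1:20, ], db = NULL)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  # all base models give positives their pos_reg credit: mean >= 0.8
  pred_pos <- predict(bm, pos, db = NULL)
  expect_true(all(pred_pos$score >= 0.8))
  # a constant-score set averages to itself under model-order permutations
  bm_perm <- bm
  bm_perm$models <- rev(bm$models)
  expect_equal(predict(bm_perm, pool[1:10, ], NULL)$score,
               predict(bm, pool[1:10, ], NULL)$score)

  # B = 1 reduces to a single balanced fit
  b1 <- fit_bagged(pos, pool, NULL, memorizing_learner(), B = 1, seed = 9)
  expect_length(b1$models, 1)
})

test_that("bagged score variance shrinks as B grows", {
  genes <- paste0("G", 1:15)
  pool0 <- enumerate_candidate_pairs(genes)
  pos <- pool0[seq(3, 200, by = 13), ]
  pool <- pairs_setdiff(pool0, pos)
  test_pairs <- pool[1:30, ]
  var_at <- function(B) {
    reps <- vapply(1:8, function(r) {
      bm <- fit_bagged(pos, pool, NULL, memorizing_learner(), B = B,
                       seed = 100 + r)
      mean(predict(bm, test_pairs, NULL)$score)
    }, numeric(1))
    stats::var(reps)
  }
  vs <- c(var_at(1), var_at(5), var_at(30))
  expect_true(vs[3] <= vs[1] + 1e-12)
  expect_true(vs[2] <= vs[1] + 1e-12)
})

test_that("bagged MLN ensembles round-trip through the bundle directory", {
  db <- evidence_db(c("Processbio(A,P1)", "Processbio(C,P1)",
                      "Expwt(A,Level1)", "Expwt(B,Level2)", "Expwt(C,Level1)"),
                    extra_constants = list(gene = c("A", "B", "C")))
  pos <- tibble::tibble(regulator = c("A", "C"), regulee = c("B", "B"))
  pool <- pairs_setdiff(enumerate_candidate_pairs(c("A", "B", "C")), pos)
  bm <- fit_bagged(pos, pool, db, mln_learner(bias = language_bias(min_pos = 1)),
                   B = 2, seed = 5)
  bm$threshold <- 0.42
  dir <- withr::local_tempdir()
  write_bagged_model(bm, dir)
  back <- read_bagged_model(dir)
  expect_identical(back$B, 2L)
  expect_equal(back$threshold, 0.42)
  test_pairs <- pool[1:3, ]
  expect_equal(predict(back, test_pairs, db)$score,
               predict(bm, test_pairs, db)$score)
})
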