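test_that("coverage semantics follow existential body satisfaction", {
  db <- example_world_db()
  # the empty-body clause covers every example
  top <- parse_clause("=> Regulates(g1,g2)")
  expect_true(covers(top, "Regulates(A,B)", db))
  expect_true(covers(top, "Regulates(B,B)", db))

  # the process rule covers the oriented pair only
  cl <- example_clause1()
  expect_true(covers(cl, "Regulates(A,B)", db))
  expect_false(covers(cl, "Regulates(B,A)", db))

  # random clauses agree with the brute-force substitution oracle
  for (s in 1:10) {
    db2 <- random_db(3, seed = s)
    cl2 <- random_clause(seed = s + 20, n_body = sample(1:3, 1))
    genes <- db_constants(db2, "gene")
    for (ex in c(sprintf("Regulates(%s,%s)", genes[1], genes[2]),
                 sprintf("Regulates(%s,%s)", genes[2], genes[2]))) {
      expect_identical(covers(cl2, ex, db2), oracle_covers(cl2, ex, db2),
                       info = paste("seed", s, ex))
    }
  }
})

test_that("saturation variabilizes the seed's neighbourhood consistently", {
  db <- evidence_db(c("Processbio(A,P1)", "Processbio(B,P2)"),
                    extra_constants = list(gene = c("A", "B")))
  bot <- saturate("Regulates(A,B)", db)
  expect_identical(format(bot$clause$head), "Regulates(g1,g2)")
  body <- sort(vapply(bot$clause$body, format, character(1)))
  expect_identical(body, c("Processbio(g1,P1)", "Processbio(g2,P2)"))
  expect_true(covers(bot$clause, "Regulates(A,B)", db))

  # no atoms mention the seed genes: empty body
  db2 <- evidence_db(c("Processbio(C,P1)"),
                     extra_constants = list(gene = c("A", "B", "C")))
  expect_length(saturate("Regulates(A,B)", db2)$clause$body, 0)

  expect_error(saturate("Regulates(X,Y)", db), "absent")

  # bottom clauses always cover their own seed
  for (s in 1:5) {
    db3 <- random_db(4, seed = s)
    genes <- db_constants(db3, "gene")
    seed <- sprintf("Regulates(%s,%s)", genes[1], genes[3])
    expect_true(covers(saturate(seed, db3)$clause, seed, db3))
  }
})

test_that("refinement adds single connected atoms within the bias bounds", {
  db <- evidence_db(c("Processbio(A,P1)", "Processbio(B,P2)", "Expwt(A,Level3)"),
                    extra_constants = list(gene = c("A", "B")))
  bot <- saturate("Regulates(A,B)", db)
  expect_length(bot$clause$body, 3)
  top <- horn_clause(bot$clause$head, list())
  kids <- refine(top, bot, language_bias())
  expect_lte(length(kids), 3)
  expect_true(all(vapply(kids, function(k) length(k$body), integer(1)) == 1))
  # every child generalizes the bottom clause
  expect_true(all(vapply(kids, theta_subsumes, logical(1), c2 = bot$clause)))
  # at l_max the refinement is empty
  expect_length(refine(bot$clause, bot, language_bias(l_max = 3)), 0)
})

test_that("clause scoring is covered-positives minus covered-negatives", {
  db <- evidence_db(c("Processbio(A,P1)", "Processbio(B,P1)"),
                    extra_constants = list(gene = c("A", "B")))
  cl <- parse_clause("Processbio(g1,P1) => Regulates(g1,g2)")
  pos <- tibble::tibble(regulator = c("A", "B"), regulee = c("B", "A"))
  neg <- tibble::tibble(regulator = "A", regulee = "A")
  expect_equal(score_clause(cl, pos, neg, db), 2 - 1)
  none <- parse_clause("Processbio(g1,P2) => Regulates(g1,g2)")
  expect_equal(score_clause(none, pos, neg, db), 0)
})

test_that("induce learns a separating rule on a hand-built fixture", {
  # P1 on the regulator separates the positives from all negatives
  db <- evidence_db(c("Processbio(A,P1)", "Processbio(B,P1)",
                      "Processbio(C,P2)", "Processbio(D,P2)",
                      "Expwt(A,Level1)", "Expwt(B,Level1)",
                      "Expwt(C,Level1)", "Expwt(D,Level1)"),
                    extra_constants = list(gene = c("A", "B", "C", "D")))
  pos <- tibble::tibble(regulator = c("A", "B"), regulee = c("C", "D"))
  neg <- tibble::tibble(regulator = c("C", "D"), regulee = c("A", "B"))
  th <- induce(pos, neg, db, language_bias(min_pos = 2))
  expect_gte(length(th$clauses), 1)
  expect_identical(nrow(th$uncovered), 0L)
  lead <- th$clauses[[1]]
  expect_true(all(vapply(seq_len(nrow(pos)), function(i) {
    covers(lead, sprintf("Regulates(%s,%s)", pos$regulator[i], pos$regulee[i]), db)
  }, logical(1))))
  expect_false(any(vapply(seq_len(nrow(neg)), function(i) {
    covers(lead, sprintf("Regulates(%s,%s)", neg$regulator[i], neg$regulee[i]), db)
  }, logical(1))))
})

test_that("a degenerate bias yields the single empty-body rule", {
  # indistinguishable genes: no refinement can separate, so the most general
  # hypothesis wins the tie on clause length
  db <- evidence_db(c("Expwt(A,Level1)", "Expwt(B,Level1)"),
                    extra_constants = list(gene = c("A", "B")))
  pos <- tibble::tibble(regulator = "A", regulee = "B")
  neg <- tibble::tibble(regulator = "B", regulee = "A")
  th <- induce(pos, neg, db,
               language_bias(noise = nrow(neg), min_acc = 0, min_pos = 1))
  expect_length(th$clauses, 1)
  expect_length(th$clauses[[1]]$body, 0)
})

test_that("refinement chains only shrink coverage and induction is deterministic", {
  db <- random_db(4, seed = 6)
  genes <- db_constants(db, "gene")
  examples <- expand.grid(regulator = genes, regulee = genes,
                          stringsAsFactors = FALSE)
  bot <- saturate(sprintf("Regulates(%s,%s)", genes[1], genes[2]), db)
  cl <- horn_clause(bot$clause$head, list())
  cov <- function(x) {
    vapply(seq_len(nrow(examples)), function(i) {
      covers(x, sprintf("Regulates(%s,%s)", examples$regulator[i],
                        examples$regulee[i]), db)
    }, logical(1))
  }
  for (step in 1:4) {
    kids <- refine(cl, bot, language_bias())
    if (length(kids) == 0) break
    parent_cov <- cov(cl)
    child <- kids[[1]]
    expect_true(all(cov(child) <= parent_cov))
    cl <- child
  }

  ds <- generate_dataset(generator_config(n_genes_train = 12, n_genes_new = 0,
                                          seed = 3))
  enc <- encode_dataset(ds)
  sp <- make_study_splits(ds, 1)
  if (nrow(sp$positives) >= 2) {
    neg <- sample_negatives(sp$pool, nrow(sp$positives), 4)
    t1 <- induce(sp$positives, neg, enc$db)
    t2 <- induce(sp$positives, neg, enc$db)
    expect_identical(vapply(t1$clauses, format, character(1)),
                     vapply(t2$clauses, format, character(1)))
  }
})

test_that("theories round-trip through their file format", {
  clauses <- list(example_clause1(),
                  parse_clause("Expwt(g1,Level3) ^ Inteprot(g1,g2) => Regulates(g1,g2)"))
  path <- withr::local_tempfile(fileext = ".rules")
  write_theory(clauses, path)
  back <- read_theory(path)
  expect_identical(vapply(back, format, character(1)),
                   vapply(clauses, format, character(1)))
})
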