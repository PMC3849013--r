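test_that("atoms parse, serialize and validate against signatures", {
  a <- parse_atom("ProtLoccell(Akt1,Cytoplasm)")
  expect_s3_class(a, "mln_atom")
  expect_true(is_ground(a))
  expect_identical(format(a), "ProtLoccell(Akt1,Cytoplasm)")

  b <- parse_atom("Regulates(g1,g2)")
  expect_false(is_ground(b))
  expect_true(all(is_variable_term(b$args)))

  expect_error(parse_atom("Regulates(g1)"), "arity")
  expect_error(parse_atom("Frobnicates(A,B)"), "unknown predicate")
  expect_error(parse_atom("Regulates(A,"), "malformed")
  # same variable at positions of different sorts
  expect_error(parse_atom("Processbio(x,x)"), "sort mismatch")

  # round-trip is byte-identical (canonical form has no spaces)
  for (txt in c("Regulates(A,B)", "Processbio(g1,P1)", "Expwt(G1,Level3)")) {
    expect_identical(format(parse_atom(txt)), txt)
  }
})

test_that("clauses parse, serialize and expose their variables", {
  cl <- example_clause1()
  expect_length(cl$body, 2)
  expect_identical(cl$head$pred, "Regulates")
  expect_setequal(clause_vars(cl), c("g1", "g2"))
  expect_identical(format(parse_clause(format(cl))), format(cl))

  vs <- clause_var_sorts(cl, default_signatures())
  expect_identical(unname(vs[c("g1", "g2")]), c("gene", "gene"))

  expect_true(is_connected(cl))
  expect_false(is_connected(parse_clause("=> Regulates(g1,g2)")))
  expect_true(is_connected(parse_clause("Inteprot(g1,g2) => Regulates(g1,g2)")))
})

test_that("evidence databases are closed-world and round-trip through files", {
  db <- example_world_db()
  expect_true(db_contains(db, "Processbio(B,Cell_proliferation)"))
  expect_false(db_contains(db, "Processbio(A,Cell_proliferation)"))
  expect_setequal(db_constants(db, "gene"), c("A", "B"))
  expect_error(evidence_db(list(parse_atom("Regulates(g1,g2)"))), "ground")

  path <- withr::local_tempfile(fileext = ".db")
  write_evidence(db, path)
  db2 <- read_evidence(path)
  expect_identical(db_atom_strings(db2), db_atom_strings(db))
})

test_that("signature files round-trip", {
  path <- withr::local_tempfile(fileext = ".sig")
  write_signatures(default_signatures(), path)
  sigs <- read_signatures(path)
  expect_identical(unclass(sigs), unclass(default_signatures()))
})

test_that("clause instantiation enumerates the sort cross-product", {
  cl <- example_clause1()
  db <- example_world_db()
  inst <- instantiate_clause(cl, db)
  expect_length(inst, 4)
  expect_true(all(vapply(inst, is_ground, logical(1))))
  heads <- vapply(inst, function(g) format(g$head), character(1))
  expect_setequal(heads, c("Regulates(A,B)", "Regulates(B,A)",
                           "Regulates(A,A)", "Regulates(B,B)"))
  # deterministic order
  expect_identical(heads, vapply(instantiate_clause(cl, db),
                                 function(g) format(g$head), character(1)))

  # a ground clause instantiates to itself
  gc <- parse_clause("Processbio(A,P1) => Regulates(A,B)")
  dbx <- random_db(3)
  expect_length(instantiate_clause(gc, dbx), 1)
  expect_identical(format(instantiate_clause(gc, dbx)[[1]]), format(gc))

  # 2 gene variables over 3 gene constants: 3^2 groundings
  cl2 <- parse_clause("Inteprot(g1,g2) => Regulates(g1,g2)")
  expect_length(instantiate_clause(cl2, random_db(3)), 9)
})

test_that("ground-clause evaluation follows material implication", {
  db <- example_world_db()
  false_one <- parse_clause(paste0(
    "Processbio(B,Cell_proliferation) ^ ",
    "Processbio(A,Negative_regulation_of_cell_proliferation)",
    " => Regulates(A,B)"))
  expect_false(eval_ground_clause(false_one, db))  # body true, head false

  premise_false <- parse_clause(paste0(
    "Processbio(A,Cell_proliferation) ^ ",
    "Processbio(B,Negative_regulation_of_cell_proliferation)",
    " => Regulates(B,A)"))
  expect_true(eval_ground_clause(premise_false, db))

  db2 <- db_add(db, "Regulates(A,B)")
  expect_true(eval_ground_clause(parse_clause("=> Regulates(A,B)"), db2))
  expect_error(eval_ground_clause(example_clause1(), db), "not ground")
})

test_that("the worked grounding example counts 3 true groundings", {
  expect_identical(count_true_groundings(example_clause1(),
                                         example_world_db()), 3L)
})

test_that("true-grounding counts match the brute-force oracle on random worlds", {
  for (s in 1:12) {
    db <- random_db(n_genes = 3, seed = s)
    cl <- random_clause(seed = s + 100, n_body = sample(1:3, 1))
    expect_equal(count_true_groundings(cl, db),
                 oracle_count_true_groundings(cl, db),
                 info = paste("seed", s))
  }
})

test_that("grounding invariants hold", {
  for (s in 1:6) {
    db <- random_db(n_genes = 3, seed = s)
    cl <- random_clause(seed = s + 50)
    inst <- instantiate_clause(cl, db)
    n_true <- count_true_groundings(cl, db)
    n_false <- sum(!vapply(inst, eval_ground_clause, logical(1), db = db))
    expect_identical(n_true + n_false, length(inst))
    # |instantiations| = g^v for gene-only variables
    vsorts <- clause_var_sorts(cl, db$sigs)
    g <- length(db_constants(db, "gene"))
    expect_equal(length(inst), g^sum(vsorts == "gene"))
  }
  # head monotonicity: asserting the head never flips a grounding true->false
  db <- random_db(4, seed = 3)
  cl <- random_clause(seed = 9)
  for (gc in instantiate_clause(cl, db)[1:10]) {
    before <- eval_ground_clause(gc, db)
    after <- eval_ground_clause(gc, db_add(db, list(gc$head)))
    expect_true(!before || after)
  }
})

test_that("theta-subsumption orders clauses by generality", {
  general <- parse_clause("Processbio(g1,P1) => Regulates(g1,g2)")
  specific <- parse_clause("Processbio(g1,P1) ^ Processbio(g2,P2) => Regulates(g1,g2)")
  expect_true(theta_subsumes(general, specific))
  expect_false(theta_subsumes(specific, general))
  expect_true(clause_equivalent(
    parse_clause("Processbio(ga,P1) ^ Processbio(gb,P2) => Regulates(ga,gb)"),
    parse_clause("Processbio(g2,P2) ^ Processbio(g1,P1) => Regulates(g1,g2)")))
  expect_false(clause_equivalent(general, specific))
})
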