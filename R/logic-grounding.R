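#' Instantiate a clause over an evidence database's constants
#'
#' Enumerates the full cross-product of sort-respecting substitutions of the
#' clause's variables by the database's constants. The result is a list (not
#' a set): substitution tuples are enumerated in lexicographic order of the
#' variable names and constant names, so grounding is deterministic.
#'
#' @param cl An `mln_clause`.
#' @param db An `evidence_db`.
#' @return List of ground `mln_clause` objects; for a clause with `v` gene
#'   variables over `g` gene constants the list has `g^v` elements.
#' @export
instantiate_clause <- function(cl, db) {
  vsorts <- clause_var_sorts(cl, db$sigs)
  if (length(vsorts) == 0L) return(list(cl))
  vars <- sort(names(vsorts))
  pools <- lapply(vars, function(v) db_constants(db, vsorts[[v]]))
  empty <- lengths(pools) == 0L
  if (any(empty)) {
    stop("no constants of sort '", vsorts[[vars[which(empty)[1]]]],
         "' available to instantiate variable '", vars[which(empty)[1]], "'")
  }
  # expand.grid varies the first factor fastest; reverse the pools so the
  # last variable varies fastest, giving lexicographic tuple order
  grid <- rev(expand.grid(rev(pools), stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE))
  names(grid) <- vars
  lapply(seq_len(nrow(grid)), function(i) {
    substitute_clause(cl, stats::setNames(as.character(grid[i, ]), vars))
  })
}

#' Evaluate a ground Horn clause in a world
#'
#' Material-implication semantics under the closed-world assumption: the
#' clause is false iff every body atom is true in the database and the head
#' is not; it is true whenever its premise is false (and when its head is
#' true).
#'
#' @param gc A ground `mln_clause`.
#' @param db An `evidence_db`.
#' @return Logical scalar.
#' @export
eval_ground_clause <- function(gc, db) {
  if (!is_ground(gc)) stop("clause is not ground: ", format(gc))
  body_true <- all(vapply(gc$body, function(a) db_contains(db, a), logical(1)))
  if (!body_true) return(TRUE)
  db_contains(db, gc$head)
}

#' Count the true groundings of a clause in a world
#'
#' The Markov-logic sufficient statistic `n_i(x)`: the number of ground
#' instantiations of the clause whose implication evaluates true in the
#' world `x` held by the database.
#'
#' @param cl An `mln_clause`.
#' @param db An `evidence_db`.
#' @return Non-negative integer.
#' @examples
#' sigs <- default_signatures()
#' cl <- parse_clause(paste0("Processbio(g2,Cell_proliferation) ^ ",
#'   "Processbio(g1,Negative_regulation_of_cell_proliferation)",
#'   " => Regulates(g1,g2)"), sigs)
#' db <- evidence_db(c("Processbio(B,Cell_proliferation)",
#'                     "Processbio(A,Negative_regulation_of_cell_proliferation)"))
#' count_true_groundings(cl, db)  # 3 of the 4 instantiations are true
#' @export
count_true_groundings <- function(cl, db) {
  gcs <- instantiate_clause(cl, db)
  sum(vapply(gcs, eval_ground_clause, logical(1), db = db))
}

# --- pattern matching over the database index --------------------------------

# rows of db$index[[pred]] matching a possibly non-ground atom under subst;
# returns a (possibly empty) list of extended substitutions
match_atom <- function(a, subst, db) {
  a <- substitute_atom(a, subst)
  mat <- db$index[[a$pred]]
  if (is.null(mat)) return(list())
  iv <- is_variable_term(a$args)
  if (!iv[1]) {
    rows <- db$index_by_first[[a$pred]][[a$args[1]]]
    if (is.null(rows)) return(list())
    for (j in which(!iv)[-1]) rows <- rows[mat[rows, j] == a$args[j]]
  } else {
    keep <- rep(TRUE, nrow(mat))
    for (j in which(!iv)) keep <- keep & mat[, j] == a$args[j]
    rows <- which(keep)
  }
  if (length(rows) == 0L) return(list())
  if (!any(iv)) {
    if (length(rows)) return(list(subst)) else return(list())
  }
  out <- list()
  seen <- character(0)
  vj <- which(iv)
  for (r in rows) {
    vals <- mat[r, vj]
    # a variable occurring twice in the atom must bind consistently
    ext <- stats::setNames(vals, a$args[vj])
    if (anyDuplicated(names(ext))) {
      ok <- all(tapply(ext, names(ext), function(v) length(unique(v)) == 1L))
      if (!ok) next
      ext <- ext[!duplicated(names(ext))]
    }
    key <- paste(ext, collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- c(subst, ext)
  }
  out
}

# does a substitution extending `subst` exist that makes all atoms true?
satisfy_exists <- function(atoms, subst, db) {
  if (length(atoms) == 0L) return(TRUE)
  a <- atoms[[1]]
  rest <- atoms[-1]
  for (s in match_atom(a, subst, db)) {
    if (satisfy_exists(rest, s, db)) return(TRUE)
  }
  FALSE
}

# count assignments of `vars` (with sorts `vsorts`, pools from db) that make
# all atoms true under subst; enumerates the full cross-product with pruning
count_satisfying <- function(atoms, vars, vsorts, subst, db) {
  unbound <- setdiff(vars, names(subst))
  if (length(unbound) == 0L) {
    ok <- all(vapply(atoms, function(a) {
      db_contains(db, substitute_atom(a, subst))
    }, logical(1)))
    return(as.integer(ok))
  }
  v <- unbound[1]
  pool <- db_constants(db, vsorts[[v]])
  total <- 0L
  for (const in pool) {
    s <- c(subst, stats::setNames(const, v))
    # prune on atoms that are now fully ground and false
    ground_now <- vapply(atoms, function(a) {
      aa <- substitute_atom(a, s)
      !any(is_variable_term(aa$args)) && !db_contains(db, aa)
    }, logical(1))
    if (any(ground_now)) next
    still <- atoms[!vapply(atoms, function(a) {
      !any(is_variable_term(substitute_atom(a, s)$args))
    }, logical(1))]
    total <- total + count_satisfying(still, vars, vsorts, s, db)
  }
  total
}
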