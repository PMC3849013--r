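#' Closed-world evidence databases
#'
#' An evidence database holds the set of ground atoms that are *true* in the
#' world `x`: gene descriptors and background relations. Under the
#' closed-world assumption any ground atom not in the database is false.
#' The database also carries, per sort, the pool of constants over which
#' variables of that sort range during grounding.
#'
#' @param atoms A list of ground `mln_atom` objects (or a character vector of
#'   their serializations).
#' @param sigs An `mln_signatures` object.
#' @param extra_constants Optional named list `sort -> character vector` of
#'   constants to add to the pools beyond those occurring in `atoms` (e.g.
#'   genes that carry no annotation but must remain instantiable).
#' @return An object of class `evidence_db`.
#' @examples
#' db <- evidence_db(list(parse_atom("Processbio(A,Cell_proliferation)")))
#' db_contains(db, parse_atom("Processbio(A,Cell_proliferation)"))
#' @export
evidence_db <- function(atoms = list(), sigs = default_signatures(),
                        extra_constants = list()) {
  if (is.character(atoms)) atoms <- lapply(atoms, parse_atom, sigs = sigs)
  ground <- vapply(atoms, is_ground, logical(1))
  if (any(!ground)) {
    stop("evidence atoms must be ground; offending atom: ",
         format(atoms[[which(!ground)[1]]]))
  }
  keys <- vapply(atoms, format, character(1))
  dup <- duplicated(keys)
  atoms <- atoms[!dup]
  keys <- keys[!dup]

  set <- new.env(parent = emptyenv(), hash = TRUE)
  for (k in keys) assign(k, TRUE, envir = set)

  # per-predicate argument index for pattern matching, with a first-argument
  # bucketing that accelerates matches whose first argument is already bound
  index <- list()
  index_by_first <- list()
  preds <- vapply(atoms, `[[`, character(1), "pred")
  for (p in unique(preds)) {
    rows <- atoms[preds == p]
    mat <- do.call(rbind, lapply(rows, `[[`, "args"))
    index[[p]] <- mat
    index_by_first[[p]] <- split(seq_len(nrow(mat)), mat[, 1])
  }

  # constant pools per sort
  pools <- list()
  add_const <- function(sort, vals) {
    pools[[sort]] <<- union(pools[[sort]], vals)
  }
  for (a in atoms) {
    sorts <- atom_sorts(a, sigs)
    for (i in seq_along(sorts)) add_const(sorts[i], a$args[i])
  }
  for (s in names(extra_constants)) add_const(s, extra_constants[[s]])
  pools <- lapply(pools, function(v) sort(unique(v)))

  structure(list(set = set, index = index, index_by_first = index_by_first,
                 constants = pools, sigs = sigs, n_atoms = length(atoms)),
            class = "evidence_db")
}

#' @export
print.evidence_db <- function(x, ...) {
  cat("<evidence_db> ", x$n_atoms, " ground atoms, ",
      length(x$index), " predicates, sorts: ",
      paste(names(x$constants), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Membership test for a ground atom
#'
#' @param db An `evidence_db`.
#' @param a A ground `mln_atom` (or its serialization).
#' @return `TRUE` iff the atom is asserted true in the database.
#' @export
db_contains <- function(db, a) {
  key <- if (is.character(a)) a else format(a)
  exists(key, envir = db$set, inherits = FALSE)
}

#' Constants of a sort known to the database
#'
#' @param db An `evidence_db`.
#' @param sort Sort name, e.g. `"gene"`.
#' @return Sorted character vector of constants (possibly empty).
#' @export
db_constants <- function(db, sort) {
  out <- db$constants[[sort]]
  if (is.null(out)) character(0) else out
}

#' All atoms of the database, serialized
#'
#' @param db An `evidence_db`.
#' @return Sorted character vector of atom serializations.
#' @export
db_atom_strings <- function(db) {
  sort(ls(envir = db$set))
}

#' Add ground atoms to an evidence database
#'
#' Returns a new database; the input is not modified.
#'
#' @param db An `evidence_db`.
#' @param atoms List of ground `mln_atom` (or character serializations).
#' @return A new `evidence_db`.
#' @export
db_add <- function(db, atoms) {
  if (is.character(atoms)) atoms <- lapply(atoms, parse_atom, sigs = db$sigs)
  old <- lapply(db_atom_strings(db), parse_atom, sigs = db$sigs)
  evidence_db(c(old, atoms), sigs = db$sigs, extra_constants = db$constants)
}

#' Write an evidence database to a file
#'
#' Plain-text format: one ground atom per line in canonical serialization;
#' `#` starts a comment; blank lines are ignored.
#'
#' @param db An `evidence_db`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(db, path) {
  writeLines(db_atom_strings(db), path)
  invisible(path)
}

#' Read an evidence database from a file
#'
#' @param path Input file path (format as in [write_evidence()]).
#' @param sigs An `mln_signatures` object.
#' @param extra_constants Passed to [evidence_db()].
#' @return An `evidence_db`.
#' @export
read_evidence <- function(path, sigs = default_signatures(),
                          extra_constants = list()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  evidence_db(lines, sigs = sigs, extra_constants = extra_constants)
}

#' Read predicate signatures from a file
#'
#' One declaration per line, `Symbol(sort1,sort2)`; `#` comments and blank
#' lines are ignored.
#'
#' @param path Input file path.
#' @return An `mln_signatures` object.
#' @export
read_signatures <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  decls <- lapply(lines, function(l) {
    m <- regmatches(l, regexec("^([A-Za-z][A-Za-z0-9_]*)\\(([^()]*)\\)$", l))[[1]]
    if (length(m) != 3L) stop("malformed signature declaration: ", l)
    stats::setNames(list(trimws(strsplit(m[3], ",")[[1]])), m[2])
  })
  signatures(do.call(c, decls))
}

#' Write predicate signatures to a file
#'
#' @param sigs An `mln_signatures` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(sigs, path) {
  writeLines(vapply(names(sigs), function(p) {
    paste0(p, "(", paste(sigs[[p]], collapse = ","), ")")
  }, character(1)), path)
  invisible(path)
}
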