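#' First-order logic atoms
#'
#' The knowledge representation unit of the package is the *atom*
#' `Pred(t1,...,tn)`: a predicate applied to terms. A term is either a
#' constant (name starts with an upper-case character, e.g. `Akt1`,
#' `Cytoplasm`) or a variable (lower-case, e.g. `g1`). An atom is *ground*
#' when all its terms are constants. Atoms are lightweight S3 objects;
#' their canonical serialization has no whitespace: `Pred(T1,T2)`.
#'
#' @param predicate Predicate symbol (character scalar).
#' @param terms Character vector of term names.
#' @return An object of class `mln_atom`.
#' @examples
#' a <- atom("ProtLoccell", c("Akt1", "Cytoplasm"))
#' is_ground(a)
#' format(a)
#' @export
atom <- function(predicate, terms) {
  stopifnot(is.character(predicate), length(predicate) == 1L,
            is.character(terms), length(terms) >= 1L)
  structure(list(pred = predicate, args = as.character(terms)),
            class = "mln_atom")
}

#' @export
format.mln_atom <- function(x, ...) {
  paste0(x$pred, "(", paste(x$args, collapse = ","), ")")
}

#' @export
print.mln_atom <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Test whether a term name denotes a variable
#'
#' Terms beginning with a lower-case character are variables; terms beginning
#' with an upper-case character (or a digit) are constants.
#'
#' @param term Character vector of term names.
#' @return Logical vector.
#' @export
is_variable_term <- function(term) {
  grepl("^[a-z]", term)
}

#' Test whether an atom (or clause) is ground
#'
#' @param x An `mln_atom` or `mln_clause`.
#' @return `TRUE` iff every term is a constant.
#' @export
is_ground <- function(x) UseMethod("is_ground")

#' @export
is_ground.mln_atom <- function(x) !any(is_variable_term(x$args))

#' Predicate signatures
#'
#' A signature set declares, for each predicate symbol, the ordered sorts of
#' its arguments (e.g. `Processbio(gene, process)`). Sorts type the logic:
#' substitution is sort-respecting, so a level constant never binds a gene
#' variable.
#'
#' @param ... Named character vectors, one per predicate; the name is the
#'   predicate symbol and the value its argument sorts.
#' @return A named list of class `mln_signatures`.
#' @examples
#' signatures(Processbio = c("gene", "process"), Regulates = c("gene", "gene"))
#' @export
signatures <- function(...) {
  sig <- list(...)
  if (length(sig) == 1L && is.list(sig[[1]]) && is.null(names(sig))) {
    sig <- sig[[1]]
  }
  if (is.null(names(sig)) || any(names(sig) == "")) {
    stop("every signature must be named by its predicate symbol")
  }
  if (anyDuplicated(names(sig))) {
    stop("duplicated predicate symbol in signature set")
  }
  structure(lapply(sig, as.character), class = "mln_signatures")
}

#' The default gene-descriptor predicate vocabulary
#'
#' Declares the predicates used to describe genes and their products:
#' discretized expression levels in the three experimental conditions
#' (`Expwt`, `Expsiid2`, `Expprcid2`), expression-change predicates
#' (`Expmore`, `Expless`, `Expsame`), physical protein interaction
#' (`Inteprot`), subcellular protein localization (`ProtLoccell`), GO
#' biological process (`Processbio`), chromosomal proximity (`Samechro`,
#' `Sameband`) and the target relation `Regulates`.
#'
#' @return An `mln_signatures` object.
#' @export
default_signatures <- function() {
  signatures(
    Expwt       = c("gene", "level"),
    Expsiid2    = c("gene", "level"),
    Expprcid2   = c("gene", "level"),
    Expmore     = c("gene", "condition"),
    Expless     = c("gene", "condition"),
    Expsame     = c("gene", "condition"),
    Inteprot    = c("gene", "gene"),
    ProtLoccell = c("gene", "location"),
    Processbio  = c("gene", "process"),
    Samechro    = c("gene", "gene"),
    Sameband    = c("gene", "gene"),
    Regulates   = c("gene", "gene")
  )
}

#' Sorts of an atom's arguments under a signature set
#'
#' @param x An `mln_atom`.
#' @param sigs An `mln_signatures` object.
#' @return Character vector of sorts, one per argument.
#' @export
atom_sorts <- function(x, sigs) {
  s <- sigs[[x$pred]]
  if (is.null(s)) stop("unknown predicate: ", x$pred)
  if (length(s) != length(x$args)) {
    stop("arity mismatch for ", x$pred, ": expected ", length(s),
         " arguments, got ", length(x$args))
  }
  s
}

#' Parse an atom from its text form
#'
#' Accepts the canonical serialization `Symbol(t1,...,tn)` and validates it
#' against a signature set: the predicate must be declared, the arity must
#' match, and a variable reused within the atom must occupy positions of a
#' single sort.
#'
#' @param text Character scalar, e.g. `"ProtLoccell(Akt1,Cytoplasm)"`.
#' @param sigs An `mln_signatures` object (default [default_signatures()]).
#' @return An `mln_atom`.
#' @examples
#' parse_atom("Regulates(g1,g2)")
#' @export
parse_atom <- function(text, sigs = default_signatures()) {
  text <- trimws(text)
  m <- regmatches(text, regexec("^([A-Za-z][A-Za-z0-9_]*)\\(([^()]*)\\)$", text))[[1]]
  if (length(m) != 3L) stop("malformed atom: ", text)
  pred <- m[2]
  args <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
  if (length(args) == 0L || any(args == "")) stop("malformed argument list in: ", text)
  bad <- !grepl("^[A-Za-z][A-Za-z0-9_]*$", args)
  if (any(bad)) stop("malformed term '", args[bad][1], "' in: ", text)
  a <- atom(pred, args)
  sorts <- atom_sorts(a, sigs)
  vars <- args[is_variable_term(args)]
  if (length(vars)) {
    vs <- split(sorts[is_variable_term(args)], vars)
    confl <- vapply(vs, function(s) length(unique(s)) > 1L, logical(1))
    if (any(confl)) {
      stop("sort mismatch: variable '", names(vs)[confl][1],
           "' used at positions of different sorts in: ", text)
    }
  }
  a
}

# variable -> sort map of an atom (only variable terms), as a named character
# vector; errors on conflicts are caught earlier by parse/clause validation
atom_var_sorts <- function(a, sigs) {
  sorts <- atom_sorts(a, sigs)
  iv <- is_variable_term(a$args)
  stats::setNames(sorts[iv], a$args[iv])
}

#' Apply a substitution to an atom
#'
#' @param a An `mln_atom`.
#' @param subst Named character vector mapping variable names to constants.
#' @return The substituted `mln_atom`.
#' @export
substitute_atom <- function(a, subst) {
  hit <- a$args %in% names(subst)
  if (any(hit)) a$args[hit] <- subst[a$args[hit]]
  a
}
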