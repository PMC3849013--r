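#' Horn clauses
#'
#' A Horn clause is an implication `A1 ^ ... ^ An => Head` whose body is a
#' conjunction of atoms and whose head is a single atom. Learned rules always
#' conclude on `Regulates(g1,g2)`. The canonical serialization joins body
#' atoms with `" ^ "` and separates body from head with `" => "`; an empty
#' body serializes as `"=> Head"`.
#'
#' @param head An `mln_atom`.
#' @param body A list of `mln_atom` (possibly empty).
#' @return An object of class `mln_clause`.
#' @examples
#' cl <- horn_clause(parse_atom("Regulates(g1,g2)"),
#'                   list(parse_atom("Processbio(g2,Cell_proliferation)")))
#' format(cl)
#' @export
horn_clause <- function(head, body = list()) {
  stopifnot(inherits(head, "mln_atom"))
  stopifnot(all(vapply(body, inherits, logical(1), "mln_atom")))
  structure(list(head = head, body = body), class = "mln_clause")
}

#' @export
format.mln_clause <- function(x, ...) {
  if (length(x$body) == 0L) {
    paste0("=> ", format(x$head))
  } else {
    paste0(paste(vapply(x$body, format, character(1)), collapse = " ^ "),
           " => ", format(x$head))
  }
}

#' @export
print.mln_clause <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
is_ground.mln_clause <- function(x) {
  is_ground(x$head) && all(vapply(x$body, is_ground, logical(1)))
}

#' Parse a Horn clause from its text form
#'
#' @param text Character scalar, e.g.
#'   `"Processbio(g2,Cell_proliferation) => Regulates(g1,g2)"`.
#' @param sigs An `mln_signatures` object.
#' @return An `mln_clause`.
#' @export
parse_clause <- function(text, sigs = default_signatures()) {
  parts <- strsplit(text, "=>", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("malformed clause (expected one '=>'): ", text)
  head <- parse_atom(parts[2], sigs)
  body_txt <- trimws(parts[1])
  body <- list()
  if (nzchar(body_txt)) {
    body <- lapply(trimws(strsplit(body_txt, "^", fixed = TRUE)[[1]]),
                   parse_atom, sigs = sigs)
  }
  cl <- horn_clause(head, body)
  clause_var_sorts(cl, sigs)  # validates cross-atom sort consistency
  cl
}

#' Variables of a clause, in order of first appearance (head first)
#'
#' @param cl An `mln_clause`.
#' @return Character vector of variable names.
#' @export
clause_vars <- function(cl) {
  terms <- c(cl$head$args, unlist(lapply(cl$body, `[[`, "args")))
  unique(terms[is_variable_term(terms)])
}

#' Variable-to-sort map of a clause
#'
#' Errors if a variable is used at positions of different sorts.
#'
#' @param cl An `mln_clause`.
#' @param sigs An `mln_signatures` object.
#' @return Named character vector: variable name -> sort.
#' @export
clause_var_sorts <- function(cl, sigs) {
  maps <- c(list(atom_var_sorts(cl$head, sigs)),
            lapply(cl$body, atom_var_sorts, sigs = sigs))
  all_vars <- unlist(lapply(maps, names))
  all_sorts <- unlist(maps)
  if (length(all_vars) == 0L) return(stats::setNames(character(0), character(0)))
  by_var <- split(all_sorts, all_vars)
  confl <- vapply(by_var, function(s) length(unique(s)) > 1L, logical(1))
  if (any(confl)) {
    stop("sort mismatch: variable '", names(by_var)[confl][1],
         "' used at positions of different sorts")
  }
  out <- vapply(by_var, `[[`, character(1), 1L)
  out[unique(all_vars)]
}

#' Is a clause connected?
#'
#' A clause is connected when every variable of its head also appears in its
#' body. Non-connected clauses are rejected by the rule inducer (an unbound
#' head variable would make the rule fire on arbitrary genes).
#'
#' @param cl An `mln_clause`.
#' @return Logical scalar.
#' @export
is_connected <- function(cl) {
  hv <- cl$head$args[is_variable_term(cl$head$args)]
  if (length(hv) == 0L) return(TRUE)
  bt <- unlist(lapply(cl$body, `[[`, "args"))
  all(hv %in% bt[is_variable_term(bt)])
}

#' Apply a substitution to a clause
#'
#' @param cl An `mln_clause`.
#' @param subst Named character vector mapping variables to constants.
#' @return The substituted `mln_clause`.
#' @export
substitute_clause <- function(cl, subst) {
  horn_clause(substitute_atom(cl$head, subst),
              lapply(cl$body, substitute_atom, subst = subst))
}

# canonical form up to variable renaming: rename variables g1,g2,... by order
# of first appearance (head first), then sort body atom strings
canonical_clause_string <- function(cl) {
  vars <- clause_vars(cl)
  ren <- stats::setNames(paste0("v", seq_along(vars)), vars)
  rename <- function(a) {
    iv <- is_variable_term(a$args)
    a$args[iv] <- ren[a$args[iv]]
    a
  }
  head <- rename(cl$head)
  body <- vapply(lapply(cl$body, rename), format, character(1))
  paste0(paste(sort(body), collapse = " ^ "), " => ", format(head))
}
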