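#' Construct a Markov Logic Network
#'
#' An MLN is a set of weighted Horn clauses, all concluding on `Regulates`
#' and non-recursive (the target predicate never appears in a body). Because
#' the network is non-recursive, query atoms are conditionally independent
#' given the evidence and inference is closed-form.
#'
#' @param clauses List of `mln_clause` (or an `mln_theory`).
#' @param weights Numeric vector, one weight per clause (default all 0).
#' @param lambda The l2 penalty the weights were trained with, if any.
#' @return An object of class `mln`.
#' @export
new_mln <- function(clauses, weights = rep(0, length(clauses)), lambda = NA_real_) {
  if (inherits(clauses, "mln_theory")) clauses <- clauses$clauses
  stopifnot(length(weights) == length(clauses), all(is.finite(weights)))
  for (cl in clauses) {
    if (cl$head$pred != "Regulates") {
      stop("every MLN clause must conclude on Regulates; got head ",
           format(cl$head))
    }
    if (any(vapply(cl$body, function(a) a$pred == "Regulates", logical(1)))) {
      stop("recursive clause (Regulates in body) not supported: ", format(cl))
    }
  }
  structure(list(clauses = clauses, weights = as.numeric(weights),
                 lambda = lambda),
            class = "mln")
}

#' @export
print.mln <- function(x, ...) {
  cat("<mln> ", length(x$clauses), " weighted clauses",
      if (!is.na(x$lambda)) paste0(" (lambda = ", x$lambda, ")"), "\n",
      sep = "")
  for (i in seq_along(x$clauses)) {
    cat(sprintf("  %+.4f  %s\n", x$weights[i], format(x$clauses[[i]])))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.mln <- function(x, ...) {
  tibble::tibble(rule = vapply(x$clauses, format, character(1)),
                 weight = x$weights)
}

#' @importFrom generics glance
#' @export
glance.mln <- function(x, ...) {
  tibble::tibble(n_clauses = length(x$clauses), lambda = x$lambda,
                 max_abs_weight = if (length(x$weights)) max(abs(x$weights)) else 0)
}

#' Per-query true-grounding counts with the query atom clamped
#'
#' For clause `i` and query atom `Y_j = Regulates(A,B)`, only groundings
#' whose head is exactly `Y_j` contribute. `n0` and `n1` are the numbers of
#' such groundings whose implication is true when `Y_j` is clamped false and
#' true respectively; their difference equals the number of body-true
#' groundings, the quantity the conditional likelihood depends on.
#'
#' @param mln An `mln` object (weights are not used).
#' @param db An `evidence_db`.
#' @param queries Data frame with columns `regulator`, `regulee`.
#' @return A list of class `grounding_counts` with matrices `n0`, `n1`,
#'   `delta` (queries x clauses).
#' @export
compute_counts <- function(mln, db, queries) {
  if (inherits(mln, "mln_theory") || is.list(mln) && !inherits(mln, "mln")) {
    mln <- new_mln(mln)
  }
  p <- length(mln$clauses)
  q <- nrow(queries)
  n0 <- matrix(0, q, p)
  n1 <- matrix(0, q, p)
  for (i in seq_len(p)) {
    cl <- mln$clauses[[i]]
    vsorts <- clause_var_sorts(cl, db$sigs)
    extra <- setdiff(names(vsorts), cl$head$args[is_variable_term(cl$head$args)])
    t_all <- if (length(extra) == 0L) 1 else {
      prod(vapply(extra, function(v) length(db_constants(db, vsorts[[v]])),
                  numeric(1)))
    }
    for (j in seq_len(q)) {
      subst <- bind_head(cl$head, queries$regulator[j], queries$regulee[j])
      if (is.null(subst)) next  # head cannot ground to this query atom
      if (length(extra) == 0L) {
        b <- as.integer(all(vapply(cl$body, function(a) {
          db_contains(db, substitute_atom(a, subst))
        }, logical(1))))
        t_j <- 1
      } else {
        b <- count_satisfying(cl$body, extra, vsorts, subst, db)
        t_j <- t_all
      }
      n1[j, i] <- t_j
      n0[j, i] <- t_j - b
    }
  }
  structure(list(n0 = n0, n1 = n1, delta = n1 - n0),
            class = "grounding_counts")
}

# bind the head atom's terms to a query pair; NULL if impossible
bind_head <- function(head, regulator, regulee) {
  vals <- c(regulator, regulee)
  subst <- character(0)
  for (i in 1:2) {
    t <- head$args[i]
    if (is_variable_term(t)) {
      if (t %in% names(subst)) {
        if (subst[[t]] != vals[i]) return(NULL)
      } else {
        subst[t] <- vals[i]
      }
    } else if (t != vals[i]) {
      return(NULL)
    }
  }
  subst
}

#' Closed-form conditional probability of a query atom
#'
#' With the query's grounding counts precomputed, the conditional
#' probability that `Y_j` is true given the evidence is the two-exponential
#' ratio `exp(sum_i w_i n1_ij) / (exp(sum_i w_i n0_ij) + exp(sum_i w_i
#' n1_ij))`, i.e. the logistic function of `sum_i w_i (n1_ij - n0_ij)`;
#' computed on the log scale for numerical stability.
#'
#' @param mln An `mln` object.
#' @param counts A `grounding_counts` from [compute_counts()].
#' @param j Query index (row of the counts).
#' @return Probability in `[0, 1]`.
#' @export
query_posterior <- function(mln, counts, j) {
  stats::plogis(drop(counts$delta[j, , drop = FALSE] %*% mln$weights))
}

#' l2-penalized conditional log-likelihood
#'
#' `sum_j log P(Y_j = y_j | x, w) - lambda * ||w||^2`. The likelihood term
#' factorizes over queries because the MLN is non-recursive.
#'
#' @param w Numeric weight vector.
#' @param counts A `grounding_counts`.
#' @param labels 0/1 vector, one per query.
#' @param lambda Non-negative l2 penalty.
#' @return Numeric scalar.
#' @export
penalized_cll <- function(w, counts, labels, lambda) {
  stopifnot(lambda >= 0, length(labels) == nrow(counts$delta))
  s <- drop(counts$delta %*% w)
  ll <- sum(stats::plogis(ifelse(labels == 1, s, -s), log.p = TRUE))
  ll - lambda * sum(w^2)
}

#' Gradient of the penalized conditional log-likelihood
#'
#' @inheritParams penalized_cll
#' @return Numeric vector, one element per clause.
#' @export
penalized_cll_gradient <- function(w, counts, labels, lambda) {
  s <- drop(counts$delta %*% w)
  resid <- labels - stats::plogis(s)
  drop(crossprod(counts$delta, resid)) - 2 * lambda * w
}

#' Training configuration for weight learning
#'
#' @param lambda Non-negative l2 penalty (default 100, the middle of the
#'   default grid).
#' @param tol Convergence tolerance passed to the optimizer (default 1e-10,
#'   as a relative reduction criterion).
#' @param max_iter Maximum optimizer iterations (default 200).
#' @return A list of class `training_config`.
#' @export
training_config <- function(lambda = 100, tol = 1e-10, max_iter = 200L) {
  stopifnot(lambda >= 0)
  structure(list(lambda = lambda, tol = tol, max_iter = as.integer(max_iter)),
            class = "training_config")
}

#' The default l2 penalty grid
#'
#' @return Numeric vector `c(20, 50, 100, 500, 750, 1000)`.
#' @export
lambda_grid <- function() c(20, 50, 100, 500, 750, 1000)

#' Learn MLN weights by penalized conditional log-likelihood
#'
#' Maximizes [penalized_cll()] with the limited-memory BFGS algorithm,
#' starting from `w = 0`; the objective is concave, so the optimization is
#' deterministic given its inputs.
#'
#' @param clauses List of `mln_clause` or an `mln_theory`.
#' @param db An `evidence_db`.
#' @param queries Data frame with columns `regulator`, `regulee` and `label`
#'   (0/1), or separate `labels`.
#' @param labels Optional 0/1 vector if `queries` has no `label` column.
#' @param config A [training_config()].
#' @param counts Optional precomputed `grounding_counts` (they do not depend
#'   on the weights, so they can be cached across a lambda grid).
#' @return A fitted `mln` object with attributes `objective` (optimum value)
#'   and `converged`.
#' @export
learn_weights <- function(clauses, db, queries, labels = NULL,
                          config = training_config(), counts = NULL) {
  mln0 <- if (inherits(clauses, "mln")) clauses else new_mln(clauses)
  if (is.null(labels)) {
    stopifnot("label" %in% names(queries))
    labels <- queries$label
  }
  if (is.null(counts)) counts <- compute_counts(mln0, db, queries)
  p <- length(mln0$clauses)
  if (p == 0L) {
    out <- new_mln(list(), numeric(0), lambda = config$lambda)
    attr(out, "objective") <- penalized_cll(numeric(0), counts, labels,
                                            config$lambda)
    attr(out, "converged") <- TRUE
    return(out)
  }
  opt <- stats::optim(
    par = rep(0, p),
    fn = function(w) -penalized_cll(w, counts, labels, config$lambda),
    gr = function(w) -penalized_cll_gradient(w, counts, labels, config$lambda),
    method = "L-BFGS-B",
    control = list(maxit = config$max_iter, factr = config$tol / .Machine$double.eps)
  )
  if (opt$convergence != 0L) {
    warning("weight learning did not converge within ", config$max_iter,
            " iterations (code ", opt$convergence, "); returning best-so-far weights")
  }
  out <- new_mln(mln0$clauses, opt$par, lambda = config$lambda)
  attr(out, "objective") <- -opt$value
  attr(out, "converged") <- opt$convergence == 0L
  out
}

#' Score candidate gene pairs with a fitted MLN
#'
#' @param object A fitted `mln`.
#' @param db An `evidence_db`.
#' @param pairs Data frame with columns `regulator`, `regulee`.
#' @param ... Unused.
#' @return A tibble `regulator`, `regulee`, `score` where `score` is the
#'   posterior probability of regulation. Thresholding is left to the
#'   caller.
#' @export
predict.mln <- function(object, db, pairs, ...) {
  genes <- db_constants(db, "gene")
  bad <- !(pairs$regulator %in% genes) | !(pairs$regulee %in% genes)
  if (any(bad)) {
    offending <- paste0("(", pairs$regulator[bad], ",", pairs$regulee[bad], ")")
    stop("pairs involve genes unknown to the evidence database: ",
         paste(utils::head(offending, 5), collapse = " "),
         if (sum(bad) > 5) " ...")
  }
  counts <- compute_counts(object, db, pairs)
  score <- stats::plogis(drop(counts$delta %*% object$weights))
  if (length(object$clauses) == 0L) score <- rep(0.5, nrow(pairs))
  tibble::tibble(regulator = pairs$regulator, regulee = pairs$regulee,
                 score = score)
}

#' Write a weighted MLN to a file
#'
#' One line per clause: `weight<TAB>clause-serialization`.
#'
#' @param mln An `mln` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mln <- function(mln, path) {
  lines <- vapply(seq_along(mln$clauses), function(i) {
    paste0(format(mln$weights[i], digits = 17), "\t",
           format(mln$clauses[[i]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a weighted MLN from a file
#'
#' @param path Input file path (format as in [write_mln()]).
#' @param sigs An `mln_signatures` object.
#' @return An `mln` object.
#' @export
read_mln <- function(path, sigs = default_signatures()) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  weights <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
  clauses <- lapply(parts, function(p) parse_clause(p[2], sigs))
  new_mln(clauses, weights)
}
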