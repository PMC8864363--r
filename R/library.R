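#' Construct a polynomial candidate library
#'
#' Builds the ordered set of monomial candidate functions
#' \eqn{\Theta(x)} of total degree at most `degree` in the `d` state
#' variables, including the constant term. The sparse linear combination
#' \eqn{\dot x^\top = \Theta(x)\,\Xi} over this library defines the class of
#' dynamical models considered for discovery, so the ordering of terms is part
#' of the public contract: coefficient matrices and report tables are indexed
#' by it.
#'
#' Terms are listed in graded order: by total degree, and within each degree
#' the pure powers of each variable (in the declared variable order) come
#' first, followed by the mixed monomials in decreasing lexicographic order of
#' their exponent vectors. For two variables `u, v` this yields
#' `1, u, v, u2, v2, uv` at degree 2 and appends `u3, v3, u2v, uv2` at
#' degree 3.
#'
#' @param state_names character vector of `d >= 1` distinct variable names.
#' @param degree maximum total degree, a non-negative integer.
#' @return an object of class `sindy_library`: a list with elements
#'   `state_names`, `d`, `max_degree`, `exponents` (an `l x d` integer matrix
#'   of monomial exponents, one row per term), `labels` (compact names such
#'   as `"u2v"`), and `l` (the number of terms,
#'   `choose(d + degree, degree)`).
#' @examples
#' lib <- build_polynomial_library(c("u", "v"), 2)
#' lib$labels # "1" "u" "v" "u2" "v2" "uv"
#' @export
build_polynomial_library <- function(state_names, degree) {
  if (!is.character(state_names) || length(state_names) < 1L ||
      anyNA(state_names) || !all(nzchar(state_names))) {
    stop("`state_names` must be a non-empty character vector", call. = FALSE)
  }
  if (anyDuplicated(state_names)) {
    stop("duplicate state names: ",
         paste(unique(state_names[duplicated(state_names)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(degree) != 1L || !is.numeric(degree) || is.na(degree) ||
      degree < 0 || degree != round(degree)) {
    stop("`degree` must be a single non-negative integer", call. = FALSE)
  }
  degree <- as.integer(degree)
  d <- length(state_names)

  exps <- list(matrix(0L, 1L, d)) # degree 0: the constant term
  if (degree >= 1L) {
    for (g in seq_len(degree)) {
      pure <- diag(d)[rep(seq_len(d), each = 1L), , drop = FALSE] * g
      storage.mode(pure) <- "integer"
      mixed <- compositions_of(g, d)
      mixed <- mixed[rowSums(mixed > 0L) >= 2L, , drop = FALSE]
      if (nrow(mixed) > 1L) {
        ord <- do.call(order, c(lapply(seq_len(d), function(k) -mixed[, k])))
        mixed <- mixed[ord, , drop = FALSE]
      }
      exps <- c(exps, list(pure), list(mixed))
    }
  }
  E <- do.call(rbind, exps)
  colnames(E) <- state_names

  structure(
    list(state_names = state_names, d = d, max_degree = degree,
         exponents = E, labels = apply(E, 1L, term_label, names = state_names),
         l = nrow(E)),
    class = "sindy_library")
}

# all length-d non-negative integer vectors summing to g
compositions_of <- function(g, d) {
  if (d == 1L) return(matrix(as.integer(g), 1L, 1L))
  out <- list()
  for (first in g:0) {
    rest <- compositions_of(g - first, d - 1L)
    out[[length(out) + 1L]] <- cbind(as.integer(first), rest)
  }
  do.call(rbind, out)
}

term_label <- function(e, names) {
  if (all(e == 0L)) return("1")
  parts <- vapply(which(e > 0L), function(k) {
    if (e[k] == 1L) names[k] else paste0(names[k], e[k])
  }, character(1))
  paste(parts, collapse = "")
}

#' @export
print.sindy_library <- function(x, ...) {
  cat(sprintf("Polynomial candidate library: %d terms, degree <= %d in (%s)\n",
              x$l, x$max_degree, paste(x$state_names, collapse = ", ")))
  cat("  ", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate a candidate library for run reports
#'
#' @param x a `sindy_library`.
#' @param ... unused.
#' @return a data frame with one row per term: column index, label, and one
#'   exponent column per state variable (machine-readable alternative to the
#'   compact labels).
#' @export
as.data.frame.sindy_library <- function(x, ...) {
  out <- data.frame(index = seq_len(x$l), label = x$labels,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(x$exponents))
}

#' Evaluate a candidate library at one or more states
#'
#' Computes the monomials of the library at a single `d`-vector state or
#' row-wise at an `n x d` matrix of states, returning the design row
#' \eqn{\Theta(x)} (or matrix \eqn{\Theta(X)}).
#'
#' @param lib a `sindy_library`.
#' @param state a numeric `d`-vector or an `n x d` numeric matrix.
#' @return a numeric `l`-vector (for a single state) or `n x l` matrix, with
#'   columns named by the term labels.
#' @export
evaluate_library <- function(lib, state) {
  stopifnot(inherits(lib, "sindy_library"))
  single <- is.null(dim(state))
  X <- if (single) matrix(as.numeric(state), nrow = 1L) else
    as.matrix(state)
  if (ncol(X) != lib$d) {
    stop(sprintf("state has dimension %d but library expects %d",
                 ncol(X), lib$d), call. = FALSE)
  }
  if (!all(is.finite(X))) stop("non-finite state values", call. = FALSE)
  out <- cpp_eval_library(X, lib$exponents)
  colnames(out) <- lib$labels
  if (single) drop(out) else out
}

#' Degree of the stabilizing damping term
#'
#' A candidate model with an even leading total degree can diverge in finite
#' time, which stalls ODE integration during sampling. Each state equation is
#' therefore augmented with \eqn{-\varepsilon x_j^m} where `m` is the smallest
#' odd degree strictly greater than the library degree: `degree + 1` when
#' `degree` is even, `degree + 2` when odd. An odd `m` guarantees the damping
#' opposes the sign of `x` on both sides of the origin.
#'
#' @param max_degree library polynomial degree, non-negative integer.
#' @return the (odd) degree of the damping monomial.
#' @examples
#' stabilization_degree(2) # 3: a quadratic library gains a cubic damper
#' @export
stabilization_degree <- function(max_degree) {
  if (length(max_degree) != 1L || !is.numeric(max_degree) ||
      is.na(max_degree) || max_degree < 0 || max_degree != round(max_degree)) {
    stop("`max_degree` must be a single non-negative integer", call. = FALSE)
  }
  m <- as.integer(max_degree)
  if (m %% 2L == 0L) m + 1L else m + 2L
}
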