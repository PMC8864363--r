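# The original point-estimate SINDy comparator: finite-difference
# derivatives + sequential thresholded least squares (STLSQ).

# derivative weights of the quadratic through (ts[1],ts[2],ts[3]) at te
lagrange_deriv_weights <- function(ts, te) {
  w <- numeric(3)
  for (k in 1:3) {
    others <- ts[-k]
    denom <- prod(ts[k] - others)
    w[k] <- ((te - others[1]) + (te - others[2])) / denom
  }
  w
}

#' Finite-difference time derivatives
#'
#' Second-order derivatives on a possibly nonuniform grid: the derivative of
#' the local quadratic interpolant, centred in the interior and one-sided
#' (still three-point) at the boundaries.
#'
#' @param data a `uq_ts` with at least 3 snapshots.
#' @return an `n x d` matrix of estimated derivatives.
#' @export
finite_difference_derivatives <- function(data) {
  stopifnot(inherits(data, "uq_ts"))
  t <- data$times; X <- data$states
  n <- nrow(X)
  if (n < 3) stop("need at least 3 snapshots", call. = FALSE)
  D <- matrix(NA_real_, n, ncol(X))
  for (i in seq_len(n)) {
    j <- if (i == 1) 1:3 else if (i == n) (n - 2):n else (i - 1):(i + 1)
    w <- lagrange_deriv_weights(t[j], t[i])
    D[i, ] <- w %*% X[j, , drop = FALSE]
  }
  colnames(D) <- colnames(X)
  D
}

#' STLSQ settings
#'
#' @param threshold hard-thresholding magnitude; coefficients below it are
#'   zeroed each iteration.
#' @param max_iterations maximum refit/threshold sweeps.
#' @param ridge_penalty optional ridge regularization added to the normal
#'   equations.
#' @return a list of settings.
#' @export
stlsq_control <- function(threshold = 0.05, max_iterations = 10,
                          ridge_penalty = 0) {
  stopifnot(threshold >= 0, max_iterations >= 1, ridge_penalty >= 0)
  list(threshold = threshold, max_iterations = as.integer(max_iterations),
       ridge_penalty = ridge_penalty)
}

ls_solve <- function(A, b, ridge) {
  if (ridge > 0) {
    M <- crossprod(A) + diag(ridge, ncol(A))
    drop(solve(M, crossprod(A, b)))
  } else {
    drop(qr.coef(qr(A), b))
  }
}

#' Sequential thresholded least squares
#'
#' Iterates ordinary least squares on the active term set, zeroing
#' coefficients whose magnitude falls below the threshold, until the active
#' set stops changing or the iteration cap is hit. The returned matrix has
#' no nonzero entry smaller in magnitude than the threshold.
#'
#' @param theta `n x l` matrix of library evaluations.
#' @param xdot `n x d` matrix of (estimated) derivatives.
#' @param config an [stlsq_control()].
#' @return `l x d` sparse coefficient matrix.
#' @export
stlsq <- function(theta, xdot, config = stlsq_control()) {
  theta <- as.matrix(theta); xdot <- as.matrix(xdot)
  n <- nrow(theta); l <- ncol(theta); d <- ncol(xdot)
  if (n < l) {
    warning("fewer snapshots than library terms; fit is underdetermined")
  }
  Xi <- matrix(0, l, d)
  for (j in seq_len(d)) {
    active <- rep(TRUE, l)
    coef <- ls_solve(theta, xdot[, j], config$ridge_penalty)
    coef[is.na(coef)] <- 0
    for (it in seq_len(config$max_iterations)) {
      drop_set <- active & (abs(coef) < config$threshold)
      coef[drop_set] <- 0
      active_new <- active & !drop_set
      if (!any(active_new)) {
        warning(sprintf(
          "all terms eliminated for equation %d; returning zero column", j))
        active <- active_new
        break
      }
      coef_new <- numeric(l)
      coef_new[active_new] <- ls_solve(theta[, active_new, drop = FALSE],
                                       xdot[, j], config$ridge_penalty)
      coef_new[is.na(coef_new)] <- 0
      if (identical(active_new, active) && it > 1) {
        coef <- coef_new
        break
      }
      active <- active_new
      coef <- coef_new
    }
    coef[abs(coef) < config$threshold] <- 0
    Xi[, j] <- coef
  }
  if (!is.null(colnames(theta))) rownames(Xi) <- colnames(theta)
  if (!is.null(colnames(xdot))) colnames(Xi) <- colnames(xdot)
  Xi
}

#' Point-estimate SINDy fit (STLSQ baseline)
#'
#' Composes finite-difference derivative estimation, library evaluation at
#' the snapshots, and [stlsq()], returning an integrable model for
#' comparison against the Bayesian fits.
#'
#' @param data a `uq_ts`.
#' @param library a `sindy_library`.
#' @param config an [stlsq_control()].
#' @return a `sindy_model` (no stabilization term; `x0` set to the first
#'   snapshot).
#' @export
sindy_fit <- function(data, library, config = stlsq_control()) {
  stopifnot(inherits(data, "uq_ts"), inherits(library, "sindy_library"))
  xdot <- finite_difference_derivatives(data)
  theta <- evaluate_library(library, data$states)
  Xi <- stlsq(theta, xdot, config)
  sindy_model(library, Xi, data$states[1, ], stab_coeff = 0)
}
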