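#' Multivariate time series of state snapshots
#'
#' Container for `n` observed (or predicted) snapshots of a `d`-dimensional
#' state at strictly increasing times.
#'
#' @param times strictly increasing numeric vector of length `n >= 2`.
#' @param states `n x d` numeric matrix of snapshots (rows are time points).
#' @param names optional character vector of `d` state names; defaults to the
#'   column names of `states` or `x1, x2, ...`.
#' @return an object of class `uq_ts`: list with `times`, `states`, `names`.
#' @export
time_series <- function(times, states, names = NULL) {
  times <- as.numeric(times)
  states <- as.matrix(states)
  if (length(times) < 2L) stop("need at least two snapshots", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (nrow(states) != length(times)) {
    stop("`states` must have one row per time point", call. = FALSE)
  }
  if (!all(is.finite(states))) stop("non-finite state values", call. = FALSE)
  if (is.null(names)) {
    names <- colnames(states)
    if (is.null(names)) names <- paste0("x", seq_len(ncol(states)))
  }
  colnames(states) <- names
  structure(list(times = times, states = states, names = names),
            class = "uq_ts")
}

#' @export
print.uq_ts <- function(x, ...) {
  cat(sprintf("Time series: %d snapshots of (%s) over t in [%g, %g]\n",
              length(x$times), paste(x$names, collapse = ", "),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Read / write time series as CSV
#'
#' The on-disk format is a plain CSV with header `t,<name1>,...,<named>` and
#' one row per snapshot, written at full double precision.
#'
#' @param path file path.
#' @return `read_time_series` returns a `uq_ts`.
#' @export
read_time_series <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "t") {
    stop("expected CSV with a leading `t` column", call. = FALSE)
  }
  time_series(df[[1]], as.matrix(df[-1]), names(df)[-1])
}

#' @rdname read_time_series
#' @param ts a `uq_ts`.
#' @export
write_time_series <- function(ts, path) {
  stopifnot(inherits(ts, "uq_ts"))
  df <- data.frame(t = ts$times, check.names = FALSE)
  for (j in seq_along(ts$names)) df[[ts$names[j]]] <- ts$states[, j]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' SINDy forward model
#'
#' Bundles a candidate library, an `l x d` coefficient matrix \eqn{\Xi}, an
#' initial state, and the stabilizing damping term into an integrable ODE
#' model \eqn{\dot x_j = \sum_i \theta_i(x)\,\xi_{ij} - \varepsilon x_j^m}.
#'
#' @param library a `sindy_library`.
#' @param coefficients numeric `l x d` matrix \eqn{\Xi} (finite entries).
#' @param x0 numeric `d`-vector initial state.
#' @param stab_coeff non-negative damping coefficient \eqn{\varepsilon};
#'   0 disables stabilization. See [default_stab_coeff()] for the scale-aware
#'   default used during inference.
#' @return an object of class `sindy_model`.
#' @export
sindy_model <- function(library, coefficients, x0, stab_coeff = 0) {
  stopifnot(inherits(library, "sindy_library"))
  coefficients <- as.matrix(coefficients)
  if (!identical(dim(coefficients), c(library$l, library$d)) &&
      !(nrow(coefficients) == library$l && ncol(coefficients) == library$d)) {
    stop(sprintf("coefficients must be %d x %d", library$l, library$d),
         call. = FALSE)
  }
  if (!all(is.finite(coefficients))) {
    stop("non-finite coefficients", call. = FALSE)
  }
  if (length(x0) != library$d || !all(is.finite(x0))) {
    stop(sprintf("`x0` must be a finite vector of length %d", library$d),
         call. = FALSE)
  }
  if (length(stab_coeff) != 1L || stab_coeff < 0) {
    stop("`stab_coeff` must be a single non-negative number", call. = FALSE)
  }
  dimnames(coefficients) <- list(library$labels, library$state_names)
  structure(list(library = library, coefficients = coefficients,
                 x0 = as.numeric(x0), stab_coeff = as.numeric(stab_coeff),
                 stab_degree = stabilization_degree(library$max_degree)),
            class = "sindy_model")
}

#' @export
print.sindy_model <- function(x, ...) {
  cat(sprintf("SINDy model: %d candidate terms, %d states, %d nonzero\n",
              x$library$l, x$library$d, sum(x$coefficients != 0)))
  if (x$stab_coeff > 0) {
    cat(sprintf("  damping: -%g * x^%d\n", x$stab_coeff, x$stab_degree))
  }
  invisible(x)
}

#' Scale-aware default damping coefficient
#'
#' Chooses \eqn{\varepsilon} so that the damping term
#' \eqn{\varepsilon x^m} equals `1e-4 * scale` at the edge of the data range
#' (`|x| = scale`): negligible wherever the data live, but growing as the
#' odd power `m` beyond it, which keeps candidate models bounded during
#' sampling.
#'
#' @param scale positive data scale, typically `max(abs(states))`.
#' @param stab_degree the odd damping degree, from [stabilization_degree()].
#' @return \eqn{10^{-4}\, \mathrm{scale}^{\,1-m}}.
#' @export
default_stab_coeff <- function(scale, stab_degree) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  1e-4 * scale^(1 - stab_degree)
}

#' Right-hand side of a SINDy model
#'
#' @param model a `sindy_model`.
#' @param state finite numeric `d`-vector.
#' @return the `d`-vector \eqn{\Theta(x)\Xi - \varepsilon x^m} (componentwise
#'   damping).
#' @export
sindy_rhs <- function(model, state) {
  stopifnot(inherits(model, "sindy_model"))
  if (length(state) != model$library$d || !all(is.finite(state))) {
    stop("`state` must be a finite vector matching the model dimension",
         call. = FALSE)
  }
  th <- evaluate_library(model$library, state)
  drop(th %*% model$coefficients) -
    model$stab_coeff * state^model$stab_degree
}

#' Solver settings for SINDy model integration
#'
#' @param method `"lsoda"` (adaptive, stiff-capable, via \pkg{deSolve} --
#'   the reporting default) or `"rk4"` (the deterministic fixed-step
#'   integrator used inside the samplers).
#' @param rtol,atol relative/absolute tolerances for the adaptive solver.
#' @param h maximum step for the fixed-step integrator (each inter-output
#'   interval is subdivided into equal steps no longer than `h`).
#' @param guard divergence guard: integration aborts with a divergence signal
#'   once any `|x_j|` exceeds this bound.
#' @return a list of settings.
#' @export
solver_control <- function(method = c("lsoda", "rk4"), rtol = 1e-8,
                           atol = 1e-8, h = 0.01, guard = 1e6) {
  method <- match.arg(method)
  stopifnot(rtol > 0, atol > 0, h > 0, guard > 0)
  list(method = method, rtol = rtol, atol = atol, h = h, guard = guard)
}

divergence_error <- function(t_last, draw = NULL) {
  msg <- sprintf(
    "trajectory exceeded the divergence guard near t = %g", t_last)
  structure(class = c("uqsindy_divergence", "error", "condition"),
            list(message = msg, call = NULL, t_last = t_last, draw = draw))
}

#' Integrate a SINDy model
#'
#' Computes the model prediction \eqn{\hat x(t;\Xi,x_0)} at the requested
#' times, starting from `x0` at `t0`. A trajectory whose state norm exceeds
#' the guard bound raises a condition of class `"uqsindy_divergence"`, so a
#' sampler can reject the offending draw instead of crashing.
#'
#' @param model a `sindy_model`.
#' @param times strictly increasing output times with `times[1] >= t0`.
#' @param t0 time at which the state equals `x0` (defaults to `times[1]`).
#' @param control a [solver_control()] list.
#' @return a `uq_ts` of predictions; its first row equals `x0` when
#'   `times[1] == t0`.
#' @export
simulate_sindy <- function(model, times, t0 = times[1],
                           control = solver_control()) {
  stopifnot(inherits(model, "sindy_model"))
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (times[1] < t0) stop("`times` must start at or after `t0`", call. = FALSE)

  if (control$method == "rk4") {
    out <- cpp_simulate(model$library$exponents, model$coefficients,
                        model$x0, times, t0, model$stab_coeff,
                        model$stab_degree, control$h, control$guard)
    if (out$diverged) {
      stop(divergence_error(if (out$n_ok > 0) times[out$n_ok] else t0))
    }
    states <- out$states
  } else {
    rhs <- function(t, y, p) {
      th <- drop(cpp_eval_library(matrix(y, 1L), model$library$exponents))
      list(drop(th %*% model$coefficients) -
             model$stab_coeff * y^model$stab_degree)
    }
    tt <- if (times[1] > t0) c(t0, times) else times
    sol <- deSolve::ode(y = model$x0, times = tt, func = rhs, parms = NULL,
                        method = "lsoda", rtol = control$rtol,
                        atol = control$atol)
    states <- unname(sol[, -1, drop = FALSE])
    if (times[1] > t0) states <- states[-1, , drop = FALSE]
    bad <- !is.finite(states) | abs(states) > control$guard
    if (any(bad)) {
      stop(divergence_error(times[which(apply(bad, 1, any))[1]]))
    }
  }
  time_series(times, states, model$library$state_names)
}

#' Integrate a SINDy model with forward sensitivities
#'
#' Augments the state with the forward sensitivity system
#' \eqn{\dot S = J(x) S + F(x)} and integrates both with the fixed-step RK4
#' scheme, yielding the gradients of every predicted snapshot with respect to
#' `vec(Xi)` (column-major: all terms of equation 1, then equation 2, ...)
#' and to `x0`. These gradients drive the gradient-based MCMC transitions.
#'
#' @inheritParams simulate_sindy
#' @return list with `ts` (a `uq_ts`), `sens` (an `n x d x P` array,
#'   `P = l*d + d`, slices ordered as `vec(Xi)` then `x0`), and `param_names`.
#' @export
simulate_with_sensitivities <- function(model, times, t0 = times[1],
                                        control = solver_control(method = "rk4")) {
  stopifnot(inherits(model, "sindy_model"))
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  out <- cpp_simulate_sens(model$library$exponents, model$coefficients,
                           model$x0, times, t0, model$stab_coeff,
                           model$stab_degree, control$h, control$guard)
  if (out$diverged) {
    stop(divergence_error(if (out$n_ok > 0) times[out$n_ok] else t0))
  }
  lib <- model$library
  pn <- c(paste(rep(lib$state_names, each = lib$l), lib$labels, sep = ":"),
          paste0("x0:", lib$state_names))
  list(ts = time_series(times, out$states, lib$state_names),
       sens = out$sens, param_names = pn)
}
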