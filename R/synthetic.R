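# Seeded generators for the reference experiments, plus the normalization
# preprocessing and the exponent algebra mapping coefficients between
# original and normalized coordinates.

#' True coefficient matrix of the predator-prey system
#'
#' Places `u' = alpha*u - beta*u*v`, `v' = -gamma*v + delta*u*v` into the
#' quadratic candidate library over `(u, v)`.
#'
#' @param params named vector with `alpha`, `beta`, `gamma`, `delta`.
#' @return list with the `sindy_library` and the `6 x 2` coefficient matrix.
#' @export
lotka_volterra_truth <- function(params = c(alpha = 1, beta = 0.1,
                                            gamma = 1.5, delta = 0.075)) {
  lib <- build_polynomial_library(c("u", "v"), 2)
  Xi <- matrix(0, lib$l, 2, dimnames = list(lib$labels, c("u", "v")))
  Xi["u", "u"] <- params[["alpha"]]
  Xi["uv", "u"] <- -params[["beta"]]
  Xi["v", "v"] <- -params[["gamma"]]
  Xi["uv", "v"] <- params[["delta"]]
  list(library = lib, Xi = Xi)
}

#' Generate the noisy predator-prey dataset
#'
#' Integrates the Lotka--Volterra system (`alpha = 1`, `beta = 0.1`,
#' `gamma = 1.5`, `delta = 0.075`, `x0 = (10, 5)`) at tight solver
#' tolerance, samples `n` uniform snapshots over `[0, t_end]` (endpoints
#' included), and multiplies every entry by an independent
#' `Lognormal(0, noise_sdlog)` factor -- multiplicative noise appropriate
#' for non-negative population measurements, amounting to roughly 10%
#' additive noise at the default `noise_sdlog = 0.1`. Optionally also
#' generates a held-out noisy test window `(t_end, 2*t_end]` at the same
#' sampling rate, for forecasting experiments.
#'
#' @param seed integer seed (all randomness is derived from it).
#' @param n number of training snapshots.
#' @param t_end end of the training window.
#' @param x0 initial state `(u0, v0)`.
#' @param params system parameters (see [lotka_volterra_truth()]).
#' @param noise_sdlog log-scale sd of the multiplicative noise; 0 gives the
#'   clean trajectory.
#' @param test if `TRUE`, also return the noisy test window.
#' @return list with `train` (`uq_ts`), `clean` (noise-free `uq_ts`),
#'   `test` (or NULL), `library`, `Xi` (true coefficients), and the spec
#'   echo `spec`.
#' @export
generate_lotka_volterra <- function(seed, n = 50, t_end = 24,
                                    x0 = c(10, 5),
                                    params = c(alpha = 1, beta = 0.1,
                                               gamma = 1.5, delta = 0.075),
                                    noise_sdlog = 0.1, test = FALSE) {
  truth <- lotka_volterra_truth(params)
  model <- sindy_model(truth$library, truth$Xi, x0)
  times <- seq(0, t_end, length.out = n)
  n_test <- n - 1 # same sampling rate over (t_end, 2*t_end]
  times_all <- c(times, t_end + (t_end / (n - 1)) * seq_len(n_test))
  clean_all <- simulate_sindy(model, times_all,
                              control = solver_control(rtol = 1e-10,
                                                       atol = 1e-10))
  set.seed(seed)
  noisy <- clean_all$states *
    exp(matrix(stats::rnorm(length(times_all) * 2, 0, noise_sdlog),
               ncol = 2))
  stopifnot(all(noisy > 0)) # lognormal noise on a positive trajectory
  train <- time_series(times, noisy[seq_len(n), ], c("u", "v"))
  list(train = train,
       clean = time_series(times, clean_all$states[seq_len(n), ],
                           c("u", "v")),
       test = if (test) time_series(times_all[-seq_len(n)],
                                    noisy[-seq_len(n), , drop = FALSE],
                                    c("u", "v")),
       library = truth$library, Xi = truth$Xi,
       spec = list(system = "lotka_volterra", n = n, t_end = t_end,
                   x0 = x0, params = params, noise_sdlog = noise_sdlog,
                   seed = seed))
}

#' True coefficient matrix of the cubic oscillator
#'
#' Places the damped cubic oscillator
#' `u' = alpha*u^3 + beta*v^3`, `v' = gamma*u^3 + delta*v^3` into the cubic
#' candidate library over `(u, v)`. At the defaults the antisymmetric pair
#' (`beta = -2`, `gamma = 2`) rotates the state while the two
#' order-of-magnitude smaller self-terms (`alpha = delta = -0.1`) damp it:
#' `d/dt (u^4 + v^4)/4 = alpha*u^6 + delta*v^6 <= 0`.
#'
#' @param params named vector with `alpha`, `beta`, `gamma`, `delta`.
#' @return list with the `sindy_library` and the `10 x 2` coefficient
#'   matrix.
#' @export
oscillator_truth <- function(params = c(alpha = -0.1, beta = -2,
                                        gamma = 2, delta = -0.1)) {
  lib <- build_polynomial_library(c("u", "v"), 3)
  Xi <- matrix(0, lib$l, 2, dimnames = list(lib$labels, c("u", "v")))
  Xi["u3", "u"] <- params[["alpha"]]
  Xi["v3", "u"] <- params[["beta"]]
  Xi["u3", "v"] <- params[["gamma"]]
  Xi["v3", "v"] <- params[["delta"]]
  list(library = lib, Xi = Xi)
}

#' Generate the noisy cubic-oscillator dataset
#'
#' Integrates the damped cubic oscillator of [oscillator_truth()]
#' (`x0 = (2, 0)`) and samples it with period
#' `dt` over `[0, t_end]` (101 snapshots at the defaults), adding iid
#' Gaussian noise of standard deviation `noise_sd`.
#'
#' @param seed integer seed.
#' @param dt sampling period.
#' @param t_end end of the training window.
#' @param x0 initial state.
#' @param params system parameters (see [oscillator_truth()]).
#' @param noise_sd additive noise standard deviation; 0 gives the clean
#'   trajectory.
#' @param test if `TRUE`, also return a noisy test window
#'   `(t_end, 2*t_end]` at the same rate.
#' @return list as in [generate_lotka_volterra()].
#' @export
generate_oscillator <- function(seed, dt = 0.2, t_end = 20, x0 = c(2, 0),
                                params = c(alpha = -0.1, beta = -2,
                                           gamma = 2, delta = -0.1),
                                noise_sd = 0.02, test = FALSE) {
  truth <- oscillator_truth(params)
  model <- sindy_model(truth$library, truth$Xi, x0)
  times <- seq(0, t_end, by = dt)
  times_all <- c(times, seq(t_end + dt, 2 * t_end, by = dt))
  clean_all <- simulate_sindy(model, times_all,
                              control = solver_control(rtol = 1e-10,
                                                       atol = 1e-10))
  set.seed(seed)
  noisy <- clean_all$states +
    matrix(stats::rnorm(length(times_all) * 2, 0, noise_sd), ncol = 2)
  n <- length(times)
  list(train = time_series(times, noisy[seq_len(n), ], c("u", "v")),
       clean = time_series(times, clean_all$states[seq_len(n), ],
                           c("u", "v")),
       test = if (test) time_series(times_all[-seq_len(n)],
                                    noisy[-seq_len(n), , drop = FALSE],
                                    c("u", "v")),
       library = truth$library, Xi = truth$Xi,
       spec = list(system = "cubic_oscillator", dt = dt, t_end = t_end,
                   x0 = x0, params = params, noise_sd = noise_sd,
                   seed = seed))
}

#' Generate the 10-predictor sparse regression toy problem
#'
#' `n` samples with iid standard-normal predictors, Gaussian noise of sd
#' `sigma`, and the sparse truth
#' `beta = (0.3, 0.2, -0.3, 0, ..., 0)` (three active out of ten).
#'
#' @param seed integer seed.
#' @param n number of samples.
#' @param sigma noise standard deviation.
#' @return list with `problem` (a [regression_problem()], `noise_sigma`
#'   unset so sigma is inferred), `beta` (the truth), and `sigma`.
#' @export
generate_regression_toy <- function(seed, n = 400, sigma = 0.5) {
  beta <- c(0.3, 0.2, -0.3, rep(0, 7))
  set.seed(seed)
  X <- matrix(stats::rnorm(n * 10), n, 10)
  y <- drop(X %*% beta) + stats::rnorm(n, 0, sigma)
  list(problem = regression_problem(X, y), beta = beta, sigma = sigma)
}

#' Normalize a time series by per-dimension standard deviation
#'
#' Divides each state column by its own sample standard deviation (n-1
#' denominator, computed from the noisy observations -- the only series a
#' practitioner has). Brings parameters of different orders of magnitude
#' onto comparable scales before inference.
#'
#' @param data a `uq_ts`.
#' @return list with `data` (normalized `uq_ts`, unit column sds) and
#'   `stds` (the divisors, for the inverse map).
#' @export
normalize_ts <- function(data) {
  stopifnot(inherits(data, "uq_ts"))
  stds <- apply(data$states, 2, stats::sd)
  if (any(stds == 0)) stop("zero-variance state column", call. = FALSE)
  list(data = time_series(data$times,
                          sweep(data$states, 2L, stds, "/"), data$names),
       stds = stds)
}

#' @rdname normalize_ts
#' @param stds the divisors returned by `normalize_ts`.
#' @export
denormalize_ts <- function(data, stds) {
  stopifnot(inherits(data, "uq_ts"))
  time_series(data$times, sweep(data$states, 2L, stds, "*"), data$names)
}

#' Map polynomial coefficients between original and normalized coordinates
#'
#' If each state is rescaled as \eqn{\tilde x_k = x_k / s_k}, the governing
#' equations keep their polynomial form with each monomial coefficient
#' multiplied by \eqn{\prod_k s_k^{e_k} / s_j} (term exponents `e`, equation
#' `j`). Simulating the mapped coefficients on normalized axes is
#' equivalent to normalizing the original simulation. Linear self-terms
#' (`x_j` in equation `j`) are invariant.
#'
#' @param Xi `l x d` coefficient matrix.
#' @param stds positive `d`-vector of scales.
#' @param library the polynomial `sindy_library` indexing the rows.
#' @param direction `"to_normalized"` or `"to_original"`.
#' @return the mapped `l x d` matrix.
#' @export
rescale_coefficients <- function(Xi, stds, library,
                                 direction = c("to_normalized",
                                               "to_original")) {
  direction <- match.arg(direction)
  stopifnot(inherits(library, "sindy_library"), length(stds) == library$d,
            all(stds > 0))
  Xi <- as.matrix(Xi)
  E <- library$exponents
  fac <- outer(seq_len(library$l), seq_len(library$d),
               Vectorize(function(i, j) prod(stds^E[i, ]) / stds[j]))
  if (direction == "to_normalized") Xi * fac else Xi / fac
}
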