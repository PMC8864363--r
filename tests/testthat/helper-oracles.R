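# Independent oracles used across the suite. These deliberately avoid the
# package's own integration and library-evaluation code paths.

# naive per-exponent monomial evaluation
naive_library_eval <- function(exponents, state) {
  apply(exponents, 1L, function(e) prod(state^e))
}

# fixed-step classical RK4 for an arbitrary R-level rhs
rk4_oracle <- function(rhs, x0, times, h) {
  out <- matrix(NA_real_, length(times), length(x0))
  x <- x0
  t <- times[1]
  out[1, ] <- x
  for (r in 2:length(times)) {
    span <- times[r] - t
    nsub <- ceiling(span / h)
    hs <- span / nsub
    for (s in seq_len(nsub)) {
      k1 <- rhs(t, x)
      k2 <- rhs(t + hs / 2, x + hs / 2 * k1)
      k3 <- rhs(t + hs / 2, x + hs / 2 * k2)
      k4 <- rhs(t + hs, x + hs * k3)
      x <- x + hs / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + hs
    }
    t <- times[r]
    out[r, ] <- x
  }
  out
}

lv_rhs <- function(t, x, a = 1, b = 0.1, g = 1.5, d = 0.075) {
  c(a * x[1] - b * x[1] * x[2], -g * x[2] + d * x[1] * x[2])
}

# minimal hand-built uq_samples object for diagnostics-level tests
fake_samples <- function(Xi, family = "reg_horseshoe", lambda = NULL,
                         term_labels = NULL, state_names = NULL) {
  dm <- dim(Xi) # chains x draws x l x d
  if (is.null(term_labels)) term_labels <- paste0("t", seq_len(dm[3]))
  if (is.null(state_names)) state_names <- paste0("x", seq_len(dm[4]))
  structure(list(
    draws = list(Xi = Xi, lambda = lambda,
                 sigma = array(1, c(dm[1], dm[2], dm[4])),
                 x0 = array(1, c(dm[1], dm[2], dm[4])),
                 lp = matrix(0, dm[1], dm[2])),
    family = family, kind = "ode", term_labels = term_labels,
    state_names = state_names, chains = dm[1], n_draws = dm[2],
    seed = 1, divergences = rep(0L, dm[1]),
    accept_rate = rep(1, dm[1]), meta = list()),
    class = "uq_samples")
}

# Monte-Carlo standard error of an inclusion-probability estimate from
# correlated draws: binomial variance inflated by the ESS deficit
inclusion_mcse <- function(lambda_draws_matrix) {
  p <- mean(lambda_draws_matrix)
  ess <- ess_basic(lambda_draws_matrix)
  if (!is.finite(ess) || ess < 1) ess <- 1
  sqrt(max(p * (1 - p), 1e-6) / ess)
}
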