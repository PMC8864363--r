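quick_ctl <- sampler_control(chains = 2, draws = 1000, tune = 500,
                             max_treedepth = 6)

test_that("normal-prior regression matches the conjugate posterior", {
  set.seed(1)
  n <- 30
  X <- matrix(rnorm(n), n, 1)
  y <- drop(X * 0.8) + rnorm(n, 0, 0.5)
  prob <- regression_problem(X, y, noise_sigma = 0.5)
  fit <- fit_regression(prob, prior_config("normal_reference"), quick_ctl,
                        seed = 3)
  v_post <- 1 / (sum(X^2) / 0.25 + 1)
  m_post <- v_post * sum(X * y) / 0.25
  dr <- as.vector(fit$draws$Xi)
  mcse <- stats::sd(dr) / sqrt(max(ess_basic(fit$draws$Xi[, , 1, 1]), 10))
  expect_lt(abs(mean(dr) - m_post), 4 * mcse + 0.002)
  expect_lt(abs(stats::sd(dr) - sqrt(v_post)), 0.1 * sqrt(v_post))
})

test_that("fits are bit-reproducible under a fixed seed", {
  set.seed(2)
  X <- matrix(rnorm(40), 20, 2)
  y <- drop(X %*% c(1, 0)) + rnorm(20, 0, 0.5)
  prob <- regression_problem(X, y, noise_sigma = 0.5)
  ctl <- sampler_control(chains = 2, draws = 50, tune = 50)
  f1 <- fit_regression(prob, prior_config("spike_slab"), ctl, seed = 9)
  f2 <- fit_regression(prob, prior_config("spike_slab"), ctl, seed = 9)
  expect_identical(f1$draws$Xi, f2$draws$Xi)
  expect_identical(f1$draws$lambda, f2$draws$lambda)
  f3 <- fit_regression(prob, prior_config("spike_slab"), ctl, seed = 10)
  expect_false(identical(f1$draws$Xi, f3$draws$Xi))
})

test_that("enumeration oracle obeys exact symmetries", {
  set.seed(4)
  X <- matrix(rnorm(60), 30, 2)
  y <- drop(X %*% c(1, 0.5)) + rnorm(30, 0, 0.5)
  prob <- regression_problem(X, y, noise_sigma = 0.5)
  en1 <- enumerate_spike_slab(prob, pi = 1 - 1e-12)
  expect_equal(unname(en1$inclusion), c(1, 1), tolerance = 1e-9)

  # two identical predictors get identical inclusion probabilities
  Xd <- cbind(X[, 1], X[, 1])
  probd <- regression_problem(Xd, y, noise_sigma = 0.5)
  end <- enumerate_spike_slab(probd, pi = 0.5)
  expect_equal(end$inclusion[[1]], end$inclusion[[2]], tolerance = 1e-12)

  expect_error(enumerate_spike_slab(
    regression_problem(matrix(rnorm(32), 2, 16), rnorm(2),
                       noise_sigma = 1)), "p <= 15")
  expect_error(enumerate_spike_slab(regression_problem(X, y)), "known")
})

test_that("enumeration agrees with brute-force numerical integration", {
  set.seed(5)
  n <- 25
  X <- matrix(rnorm(2 * n), n, 2)
  y <- drop(X %*% c(0.8, 0)) + rnorm(n, 0, 0.6)
  prob <- regression_problem(X, y, noise_sigma = 0.6)
  en <- enumerate_spike_slab(prob, pi = 0.4, c = 1.2)
  # direct 2-D quadrature of each configuration's marginal likelihood
  margs <- vapply(1:4, function(k) {
    g <- en$configs[k, ]
    lik <- function(b1, b2) {
      mu <- drop(X %*% c(b1, b2))
      exp(sum(stats::dnorm(y, mu, 0.6, log = TRUE)))
    }
    val <- if (sum(g) == 0) lik(0, 0) else if (all(g == c(1, 0))) {
      stats::integrate(function(b1) {
        vapply(b1, function(bb) lik(bb, 0) * stats::dnorm(bb, 0, 1.2),
               numeric(1))
      }, -8, 8, rel.tol = 1e-9)$value
    } else if (all(g == c(0, 1))) {
      stats::integrate(function(b2) {
        vapply(b2, function(bb) lik(0, bb) * stats::dnorm(bb, 0, 1.2),
               numeric(1))
      }, -8, 8, rel.tol = 1e-9)$value
    } else {
      stats::integrate(function(b1) {
        vapply(b1, function(bb) {
          stats::integrate(function(b2) {
            vapply(b2, function(cc) lik(bb, cc) *
                     stats::dnorm(cc, 0, 1.2), numeric(1))
          }, -8, 8, rel.tol = 1e-8)$value * stats::dnorm(bb, 0, 1.2)
        }, numeric(1))
      }, -8, 8, rel.tol = 1e-8)$value
    }
    log(val) + sum(g) * log(0.4) + sum(1 - g) * log(0.6)
  }, numeric(1))
  post_bf <- exp(margs - max(margs)); post_bf <- post_bf / sum(post_bf)
  expect_equal(unname(en$post[order(en$configs[, 1], en$configs[, 2])]),
               unname(post_bf[order(en$configs[, 1], en$configs[, 2])]),
               tolerance = 0.005) # nested quadrature is good to ~0.1%
})

test_that("compound sampler matches the enumeration oracle", {
  set.seed(6)
  n <- 50; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% c(1, 0, 0.4, 0)) + rnorm(n, 0, 0.7)
  prob <- regression_problem(X, y, noise_sigma = 0.7)
  en <- enumerate_spike_slab(prob)
  fit <- fit_regression(prob, prior_config("spike_slab"),
                        sampler_control(chains = 2, draws = 2000,
                                        tune = 500), seed = 7)
  ip <- inclusion_probabilities(fit)
  for (j in seq_len(p)) {
    se <- inclusion_mcse(fit$draws$lambda[, , j, 1])
    expect_lt(abs(ip$probability[j] - en$inclusion[j]),
              3 * se + 0.01)
  }
})

test_that("Dirac-spike coefficient draws are exactly zero when excluded", {
  set.seed(8)
  X <- matrix(rnorm(80), 40, 2)
  y <- drop(X %*% c(1.5, 0)) + rnorm(40, 0, 0.5)
  prob <- regression_problem(X, y, noise_sigma = 0.5)
  fit <- fit_regression(prob, prior_config("spike_slab"),
                        sampler_control(chains = 2, draws = 300,
                                        tune = 200), seed = 11)
  lam <- fit$draws$lambda
  Xi <- fit$draws$Xi
  expect_true(all(Xi[lam == 0] == 0))
  expect_gt(sum(lam == 0), 0) # the null coefficient is actually excluded
})

test_that("a flat likelihood returns the prior (zero-information limit)", {
  set.seed(12)
  X <- matrix(rnorm(20), 20, 1)
  y <- rnorm(20)
  prob <- regression_problem(X, y, noise_sigma = 1e6)
  fit <- fit_regression(prob, prior_config("normal_reference"),
                        sampler_control(chains = 2, draws = 1500,
                                        tune = 300), seed = 13)
  dr <- as.vector(fit$draws$Xi)
  ess <- max(ess_basic(fit$draws$Xi[, , 1, 1]), 10)
  expect_equal(mean(dr), 0, tolerance = 4 / sqrt(ess))
  expect_equal(stats::sd(dr), 1, tolerance = 0.2)
})

test_that("a one-parameter linear ODE posterior recovers the truth", {
  lib1 <- build_polynomial_library("x", 1)
  m <- sindy_model(lib1, matrix(c(0, -1), 2, 1), 1)
  times <- seq(0, 4, length.out = 20)
  clean <- simulate_sindy(m, times)
  set.seed(14)
  data <- time_series(times, clean$states + rnorm(20, 0, 0.05))
  A <- matrix(c(0.01, 1), 2, 1) # pin the constant term near zero
  fit <- fit_ode(data, lib1,
                 prior_config("normal_reference", alpha = A,
                              x0_prior = dist_spec("normal", mean = 0,
                                                   sd = 10)),
                 noise_model("gaussian",
                             dist_spec("halfnormal", sd = 0.2)),
                 sampler_control(chains = 2, draws = 400, tune = 300),
                 seed = 15, h = 0.01)
  dr <- as.vector(fit$draws$Xi[, , 2, 1])
  expect_lt(abs(mean(dr) - (-1)), 3 * stats::sd(dr))
  expect_lt(abs(mean(as.vector(fit$draws$x0)) - 1),
            3 * stats::sd(as.vector(fit$draws$x0)))
})

test_that("sampler metadata records seeds, divergences and acceptance", {
  set.seed(16)
  X <- matrix(rnorm(20), 20, 1)
  y <- drop(X * 1) + rnorm(20, 0, 0.5)
  fit <- fit_regression(regression_problem(X, y, noise_sigma = 0.5),
                        prior_config("laplace"),
                        sampler_control(chains = 2, draws = 100,
                                        tune = 100), seed = 17)
  expect_equal(fit$seed, 17)
  expect_length(fit$divergences, 2)
  expect_true(all(fit$accept_rate > 0.5))
  expect_true(all(c("rhat", "ess") %in% names(fit$diagnostics)))
})

test_that("posterior stores round-trip through the on-disk format", {
  set.seed(18)
  X <- matrix(rnorm(20), 20, 1)
  y <- drop(X * 1) + rnorm(20, 0, 0.5)
  fit <- fit_regression(regression_problem(X, y, noise_sigma = 0.5),
                        prior_config("spike_slab"),
                        sampler_control(chains = 2, draws = 50, tune = 50),
                        seed = 19)
  d <- withr::local_tempdir()
  write_samples(fit, d)
  back <- read_samples(d)
  expect_equal(back$draws$Xi, fit$draws$Xi, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$family, "spike_slab")
  expect_equal(back$chains, 2)
})
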