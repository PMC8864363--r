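test_that("predator-prey generator reproduces the preset conditions", {
  gen <- generate_lotka_volterra(seed = 1)
  expect_equal(length(gen$train$times), 50)
  expect_equal(range(gen$train$times), c(0, 24))
  expect_true(all(gen$train$states > 0))
  # seed determinism
  gen2 <- generate_lotka_volterra(seed = 1)
  expect_identical(gen$train$states, gen2$train$states)
  gen3 <- generate_lotka_volterra(seed = 2)
  expect_false(identical(gen$train$states, gen3$train$states))
  # zero-noise limit equals the deterministic trajectory
  clean <- generate_lotka_volterra(seed = 1, noise_sdlog = 0)
  expect_equal(clean$train$states, clean$clean$states, tolerance = 1e-12)
  # test window continues past training at the same rate
  gt <- generate_lotka_volterra(seed = 1, test = TRUE)
  expect_equal(length(gt$test$times), 49)
  expect_true(all(gt$test$times > 24 & gt$test$times <= 48))
})

test_that("multiplicative noise has ~10% coefficient of variation", {
  ratios <- unlist(lapply(1:100, function(s) {
    g <- generate_lotka_volterra(seed = s)
    g$train$states / g$clean$states
  }))
  expect_gte(length(ratios), 1e4)
  expect_equal(stats::sd(ratios) / mean(ratios), 0.10, tolerance = 0.005)
})

test_that("oscillator generator reproduces the preset conditions", {
  gen <- generate_oscillator(seed = 1)
  expect_equal(length(gen$train$times), 101)
  expect_equal(diff(gen$train$times)[1], 0.2)
  expect_equal(unname(gen$clean$states[1, ]), c(2, 0))
  expect_equal(unname(gen$train$states[1, ]), c(2, 0), tolerance = 0.1)
  # additive noise sd recovered empirically
  resid <- unlist(lapply(1:50, function(s) {
    g <- generate_oscillator(seed = s)
    g$train$states - g$clean$states
  }))
  expect_equal(stats::sd(resid), 0.02, tolerance = 0.05)
  clean <- generate_oscillator(seed = 1, noise_sd = 0)
  expect_equal(clean$train$states, clean$clean$states, tolerance = 1e-12)
})

test_that("regression toy has the printed sparse truth", {
  gen <- generate_regression_toy(seed = 3)
  expect_equal(sum(gen$beta != 0), 3)
  expect_equal(gen$beta[1:3], c(0.3, 0.2, -0.3))
  expect_equal(gen$problem$n, 400)
  expect_equal(gen$problem$p, 10)
  ols <- stats::lm.fit(gen$problem$X, gen$problem$y)
  se <- sqrt(diag(solve(crossprod(gen$problem$X))) *
               sum(ols$residuals^2) / (400 - 10))
  expect_true(all(abs(ols$coefficients - gen$beta) < 4 * se))
  expect_equal(mean((gen$problem$y -
                       gen$problem$X %*% gen$beta)^2), 0.25,
               tolerance = 0.1)
})

test_that("normalization yields unit sds and round-trips", {
  gen <- generate_lotka_volterra(seed = 4)
  nrm <- normalize_ts(gen$train)
  expect_equal(unname(apply(nrm$data$states, 2, stats::sd)), c(1, 1))
  back <- denormalize_ts(nrm$data, nrm$stds)
  expect_equal(back$states, gen$train$states, tolerance = 1e-12)
  flat <- time_series(1:5, cbind(1:5, rep(2, 5)))
  expect_error(normalize_ts(flat), "zero-variance")
})

test_that("normalized governing coefficients match the reference values", {
  vals <- t(vapply(1:10, function(s) {
    gen <- generate_lotka_volterra(seed = s)
    nrm <- normalize_ts(gen$train)
    XiN <- rescale_coefficients(gen$Xi, nrm$stds, gen$library)
    c(XiN["u", "u"], XiN["uv", "u"], XiN["v", "v"], XiN["uv", "v"])
  }, numeric(4)))
  means <- colMeans(vals)
  # linear self-terms are scale-invariant: exact
  expect_equal(means[1], 1)
  expect_equal(means[3], -1.5)
  # interaction terms depend on the noisy sample sds: within 10%
  expect_equal(means[2], -0.68, tolerance = 0.10 * 0.68)
  expect_equal(means[4], 0.82, tolerance = 0.10 * 0.82)
})

test_that("coefficient rescaling is exact exponent algebra", {
  lib <- build_polynomial_library(c("u", "v"), 2)
  Xi <- matrix(rnorm(12), 6, 2)
  expect_equal(rescale_coefficients(Xi, c(1, 1), lib), Xi)
  stds <- c(2.5, 0.4)
  fwd <- rescale_coefficients(Xi, stds, lib, "to_normalized")
  back <- rescale_coefficients(fwd, stds, lib, "to_original")
  expect_equal(back, Xi, tolerance = 1e-12)
})

test_that("rescaled coefficients commute with simulation", {
  truth <- lotka_volterra_truth()
  stds <- c(3, 1.7)
  XiN <- rescale_coefficients(truth$Xi, stds, truth$library)
  times <- seq(0, 10, length.out = 21)
  orig <- simulate_sindy(sindy_model(truth$library, truth$Xi, c(10, 5)),
                         times)
  nrm <- simulate_sindy(sindy_model(truth$library, XiN, c(10, 5) / stds),
                        times)
  expect_equal(nrm$states, sweep(orig$states, 2, stds, "/"),
               tolerance = 1e-6)
})
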