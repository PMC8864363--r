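test_that("posterior mode estimation handles atoms and smooth draws", {
  expect_equal(posterior_mode(rep(0.42, 200)), 0.42)
  set.seed(1)
  expect_equal(posterior_mode(rnorm(1e5)), 0, tolerance = 0.05)
  mix <- c(rep(0, 900), rnorm(100, 2, 0.1))
  expect_equal(posterior_mode(mix), 0, tolerance = 0.02)
  expect_error(posterior_mode(rnorm(50)), "100")
})

test_that("inclusion probabilities are per-term indicator means", {
  lam <- array(1, c(2, 200, 3, 1))
  lam[, , 2, 1] <- rep(c(0, 1), each = 100) # 0.5 for term 2
  Xi <- array(rnorm(1200), c(2, 200, 3, 1))
  s <- fake_samples(Xi, family = "spike_slab", lambda = lam)
  ip <- inclusion_probabilities(s)
  expect_equal(ip$probability, c(1, 0.5, 1))

  srh <- fake_samples(Xi, family = "reg_horseshoe")
  expect_error(inclusion_probabilities(srh), "shrinkage_factors")
})

test_that("shrinkage factors are mode ratios with an undefined guard", {
  set.seed(2)
  Xi <- array(rnorm(2 * 300 * 2 * 1, mean = 1), c(2, 300, 2, 1))
  s_rh <- fake_samples(Xi, family = "reg_horseshoe")
  s_ref <- fake_samples(Xi, family = "normal_reference")
  sf <- shrinkage_factors(s_rh, s_ref)
  expect_equal(sf$kappa, c(1, 1), tolerance = 1e-9)

  XiZ <- Xi
  XiZ[, , 1, 1] <- 0 # rh mode exactly 0, ref mode ~1
  sfz <- shrinkage_factors(fake_samples(XiZ, family = "reg_horseshoe"),
                           s_ref)
  expect_equal(sfz$kappa[1], 0)

  XiR <- Xi
  XiR[, , 1, 1] <- 0 # reference degenerate at 0
  sfu <- shrinkage_factors(s_rh,
                           fake_samples(XiR, family = "normal_reference"))
  expect_true(sfu$undefined[1])
  expect_true(is.na(sfu$kappa[1]))

  expect_error(shrinkage_factors(s_ref, s_ref), "reg_horseshoe")
})

test_that("kappa is invariant to a common rescaling of both fits", {
  set.seed(3)
  Xi <- array(rnorm(2 * 300 * 2 * 1, mean = 0.7, sd = 0.2),
              c(2, 300, 2, 1))
  Xi2 <- array(rnorm(2 * 300 * 2 * 1, mean = 1.2, sd = 0.2),
               c(2, 300, 2, 1))
  k1 <- shrinkage_factors(fake_samples(Xi, family = "reg_horseshoe"),
                          fake_samples(Xi2,
                                       family = "normal_reference"))$kappa
  k2 <- shrinkage_factors(fake_samples(5 * Xi, family = "reg_horseshoe"),
                          fake_samples(5 * Xi2,
                                       family = "normal_reference"))$kappa
  expect_equal(k1, k2, tolerance = 1e-9)
})

# a tiny genuine ODE fit shared by the PPD tests below
make_tiny_fit <- function() {
  lib1 <- build_polynomial_library("x", 1)
  m <- sindy_model(lib1, matrix(c(0, -0.5), 2, 1), 2)
  times <- seq(0, 4, length.out = 15)
  clean <- simulate_sindy(m, times)
  set.seed(4)
  data <- time_series(times, clean$states + rnorm(15, 0, 0.05))
  fit_ode(data, lib1,
          prior_config("normal_reference",
                       alpha = matrix(c(0.01, 1), 2, 1),
                       x0_prior = dist_spec("normal", mean = 0, sd = 10)),
          noise_model("gaussian", dist_spec("halfnormal", sd = 0.2)),
          sampler_control(chains = 2, draws = 200, tune = 200),
          seed = 5, h = 0.01)
}
tiny_fit <- make_tiny_fit()

test_that("a single-draw PPD is that draw's trajectory with zero width", {
  ppd <- posterior_predictive(tiny_fit, seq(0, 4, length.out = 9),
                              with_noise = FALSE, n_draws = 1, seed = 1)
  expect_equal(ppd$mean, ppd$lo, tolerance = 1e-12)
  expect_equal(ppd$mean, ppd$hi, tolerance = 1e-12)
  expect_equal(ppd$n_used, 1)
})

test_that("credibility bands widen with level and with noise", {
  times <- seq(0, 6, length.out = 13) # extends past training: forecast
  p50 <- posterior_predictive(tiny_fit, times, level = 0.5,
                              with_noise = FALSE, n_draws = 150, seed = 2)
  p90 <- posterior_predictive(tiny_fit, times, level = 0.9,
                              with_noise = FALSE, n_draws = 150, seed = 2)
  expect_true(all(p90$lo <= p50$lo + 1e-12))
  expect_true(all(p90$hi >= p50$hi - 1e-12))

  pn <- posterior_predictive(tiny_fit, times, level = 0.9,
                             with_noise = TRUE, n_draws = 150, seed = 2)
  expect_true(mean(pn$hi - pn$lo) > mean(p90$hi - p90$lo))
  expect_error(posterior_predictive(tiny_fit, times, level = 1.2),
               "level")
  expect_error(posterior_predictive(tiny_fit, times, n_draws = 1e6),
               "exceeds")
})

test_that("coverage counts test points inside the band", {
  times <- seq(0, 4, length.out = 9)
  ppd <- posterior_predictive(tiny_fit, times, with_noise = TRUE,
                              n_draws = 150, seed = 3)
  inside <- time_series(times, ppd$mean)
  expect_equal(ppd_coverage(ppd, inside), 1)
  outside <- time_series(times, ppd$hi + 10)
  expect_equal(ppd_coverage(ppd, outside), 0)
})

test_that("coefficient reports combine modes and probabilities", {
  lam <- array(rbinom(2 * 200 * 2, 1, 0.9), c(2, 200, 2, 1))
  Xi <- array(rnorm(800), c(2, 200, 2, 1)) * lam
  s <- fake_samples(Xi, family = "spike_slab", lambda = lam,
                    term_labels = c("a", "b"), state_names = "x")
  rep <- coefficient_report(s)
  expect_equal(names(rep), c("term", "x_mode", "x_prob", "x_identified"))
  expect_true(all(rep$x_identified))
})
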