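small_sampler <- sampler_control(chains = 2, draws = 150, tune = 150)

test_that("run configuration validation enumerates all problems at once", {
  err <- tryCatch(run_config(preset = "volterra", prior = "ridge",
                             likelihood = "poisson"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "unknown preset")
  expect_match(err, "unknown prior family")
  expect_match(err, "lognormal")
  expect_error(run_config(), "required")
})

test_that("preset defaults are resolved by experiment", {
  lv <- run_config(preset = "lotka_volterra", seed = 1)
  expect_equal(lv$degree, 2L)
  expect_equal(lv$likelihood, "lognormal")
  expect_true(lv$normalize)
  os <- run_config(preset = "oscillator", seed = 1)
  expect_equal(os$degree, 3L)
  expect_equal(os$likelihood, "gaussian")
  expect_false(os$normalize)
})

test_that("discovery on the regression preset writes the artifact set", {
  d <- withr::local_tempdir()
  cfg <- run_config(preset = "regression_toy",
                    prior = c("laplace", "spike_slab"),
                    sampler = small_sampler, seed = 2, out_dir = d)
  run <- run_discover(cfg)
  expect_true(file.exists(file.path(d, "config.json")))
  expect_true(file.exists(file.path(d, "data.csv")))
  expect_true(file.exists(file.path(d, "coefficients_laplace.csv")))
  expect_true(file.exists(file.path(d, "coefficients_spike_slab.csv")))
  expect_true(file.exists(file.path(d, "run_log.txt")))
  tab <- utils::read.csv(file.path(d, "coefficients_spike_slab.csv"))
  expect_equal(nrow(tab), 10)
})

test_that("discovery on an ODE preset writes posterior stores and bands", {
  d <- withr::local_tempdir()
  cfg <- run_config(preset = "oscillator", prior = "spike_slab",
                    sampler = sampler_control(chains = 2, draws = 100,
                                              tune = 100,
                                              max_treedepth = 5),
                    seed = 4, out_dir = d)
  run <- run_discover(cfg)
  expect_true(dir.exists(file.path(d, "samples_spike_slab")))
  expect_true(file.exists(file.path(d, "coefficients_spike_slab.csv")))
  expect_true(file.exists(file.path(d, "ppd_spike_slab.csv")))
  tab <- utils::read.csv(file.path(d, "coefficients_spike_slab.csv"))
  expect_equal(nrow(tab), 10) # degree-3 library terms
  expect_true(all(c("u_mode", "u_prob", "v_mode", "v_prob") %in%
                    names(tab)))
  ppd <- utils::read.csv(file.path(d, "ppd_spike_slab.csv"))
  expect_true(all(ppd$u_lo <= ppd$u_mean & ppd$u_mean <= ppd$u_hi))
})

test_that("rerunning an identical configuration reproduces the tables", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    run_discover(run_config(preset = "regression_toy", prior = "laplace",
                            sampler = small_sampler, seed = 3,
                            out_dir = d))
  }
  expect_identical(readLines(file.path(d1, "coefficients_laplace.csv")),
                   readLines(file.path(d2, "coefficients_laplace.csv")))
})

test_that("alpha overrides address terms by equation and label", {
  lib <- build_polynomial_library(c("u", "v"), 3)
  A <- uqsindy:::resolve_alpha(c("u:u3" = 0.1, "v:v3" = 0.1), lib)
  expect_equal(A["u3", "u"], 0.1)
  expect_equal(A["v3", "v"], 0.1)
  expect_equal(sum(A == 0.1), 2)
  expect_error(uqsindy:::resolve_alpha(c("w:u3" = 0.1), lib),
               "equation:term")
})

test_that("forecasting extends the band and scores coverage", {
  d <- withr::local_tempdir()
  lib1 <- build_polynomial_library("x", 1)
  m <- sindy_model(lib1, matrix(c(0, -0.4), 2, 1), 2)
  times <- seq(0, 4, length.out = 15)
  set.seed(4)
  clean <- simulate_sindy(m, times)
  data <- time_series(times, clean$states + rnorm(15, 0, 0.05))
  fit <- fit_ode(data, lib1,
                 prior_config("normal_reference",
                              alpha = matrix(c(0.01, 1), 2, 1),
                              x0_prior = dist_spec("normal", mean = 0,
                                                   sd = 10)),
                 noise_model("gaussian", dist_spec("halfnormal", sd = 0.2)),
                 small_sampler, seed = 5, h = 0.01)
  run <- list(fits = list(normal_reference = fit),
              config = list(), out_dir = d,
              data = list(kind = "ode"))
  expect_null(run_forecast(run, horizon = 0))
  test_times <- seq(4.25, 6, length.out = 8)
  test_ts <- time_series(
    test_times,
    simulate_sindy(m, test_times, t0 = 0,
                   control = solver_control())$states +
      rnorm(8, 0, 0.05))
  out <- run_forecast(run, horizon = 2, family = "normal_reference",
                      test = test_ts)
  expect_s3_class(out$ppd, "uq_ppd")
  expect_gte(out$coverage, 0)
  expect_true(file.exists(file.path(d, "forecast_normal_reference.csv")))
})

test_that("preset generation writes CSVs and a manifest", {
  d <- withr::local_tempdir()
  man <- generate_preset("oscillator", seed = 6, out_dir = d)
  expect_true(file.exists(file.path(d, "oscillator_train.csv")))
  expect_true(file.exists(file.path(d, "manifest.json")))
  expect_equal(man$seed, 6)
  back <- read_time_series(file.path(d, "oscillator_train.csv"))
  expect_equal(length(back$times), 101)
})
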