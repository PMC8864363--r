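lib2 <- build_polynomial_library(c("u", "v"), 2)

test_that("rhs evaluates the coefficient combination and damping", {
  m0 <- sindy_model(lib2, matrix(0, 6, 2), c(1, 2))
  expect_equal(unname(sindy_rhs(m0, c(3, -4))), c(0, 0))

  truth <- lotka_volterra_truth()
  m <- sindy_model(truth$library, truth$Xi, c(10, 5))
  expect_equal(unname(sindy_rhs(m, c(10, 5))), c(5, -3.75))

  md <- sindy_model(lib2, matrix(0, 6, 2), c(1, 1), stab_coeff = 1e-4)
  expect_equal(unname(sindy_rhs(md, c(2, -2))), c(-8e-4, 8e-4))
  expect_error(sindy_rhs(md, c(Inf, 0)), "finite")
})

test_that("simulation reproduces closed-form linear decay", {
  lib1 <- build_polynomial_library("x", 1)
  m <- sindy_model(lib1, matrix(c(0, -1), 2, 1), 1)
  for (ctl in list(solver_control(), solver_control("rk4", h = 0.001))) {
    ts <- simulate_sindy(m, c(0, 1, 2), control = ctl)
    expect_equal(drop(ts$states), exp(-c(0, 1, 2)), tolerance = 1e-6)
  }
})

test_that("zero dynamics yield a constant trajectory equal to x0", {
  m <- sindy_model(lib2, matrix(0, 6, 2), c(3, -1))
  ts <- simulate_sindy(m, seq(0, 5, by = 1))
  expect_equal(unname(ts$states), matrix(rep(c(3, -1), each = 6), 6, 2))
  expect_equal(unname(ts$states[1, ]), c(3, -1)) # first row is x0
})

test_that("predator-prey integration matches an independent RK4 oracle", {
  truth <- lotka_volterra_truth()
  m <- sindy_model(truth$library, truth$Xi, c(10, 5))
  times <- seq(0, 24, length.out = 25)
  got <- simulate_sindy(m, times)$states
  ref <- rk4_oracle(lv_rhs, c(10, 5), times, h = 1e-4)
  expect_lt(max(abs(got - ref) / pmax(abs(ref), 1)), 1e-5)
})

test_that("fixed-step output is consistent under step refinement", {
  truth <- lotka_volterra_truth()
  m <- sindy_model(truth$library, truth$Xi, c(10, 5))
  times <- seq(0, 12, length.out = 13)
  a <- simulate_sindy(m, times, control = solver_control("rk4", h = 0.02))
  b <- simulate_sindy(m, times, control = solver_control("rk4", h = 0.01))
  expect_lt(max(abs(a$states - b$states)), 1e-5)
})

test_that("divergent trajectories raise a rejectable condition", {
  lib1 <- build_polynomial_library("x", 1)
  m <- sindy_model(lib1, matrix(c(0, 5), 2, 1), 1) # x' = 5x explodes
  expect_error(
    simulate_sindy(m, seq(0, 10, by = 1),
                   control = solver_control("rk4", h = 0.01, guard = 100)),
    class = "uqsindy_divergence")
})

test_that("sensitivities match the closed form for linear 1-D dynamics", {
  lib1 <- build_polynomial_library("x", 1)
  xi <- -1
  m <- sindy_model(lib1, matrix(c(0, xi), 2, 1), 1)
  sw <- simulate_with_sensitivities(m, c(0, 1),
                                    control = solver_control("rk4",
                                                             h = 1e-3))
  # d xhat(t)/d xi = t * x0 * exp(xi t) at t = 1
  expect_equal(sw$sens[2, 1, 2], 1 * exp(-1), tolerance = 1e-6)
  # d xhat/d x0 at t = 0 is the identity
  expect_equal(sw$sens[1, 1, 3], 1)
})

test_that("sensitivities agree with central finite differences", {
  set.seed(11)
  Xi <- matrix(rnorm(12, 0, 0.3), 6, 2)
  x0 <- c(1, 0.5)
  times <- seq(0, 3, length.out = 5)
  ctl <- solver_control("rk4", h = 0.005)
  m <- sindy_model(lib2, Xi, x0, stab_coeff = 1e-4)
  sw <- simulate_with_sensitivities(m, times, control = ctl)
  hstep <- 1e-6
  worst <- 0
  for (p in seq_len(12)) {
    Xp <- Xi; Xp[p] <- Xp[p] + hstep
    Xm <- Xi; Xm[p] <- Xm[p] - hstep
    fp <- simulate_sindy(sindy_model(lib2, Xp, x0, 1e-4), times,
                         control = ctl)$states
    fm <- simulate_sindy(sindy_model(lib2, Xm, x0, 1e-4), times,
                         control = ctl)$states
    fd <- (fp - fm) / (2 * hstep)
    worst <- max(worst, max(abs(fd - sw$sens[, , p]) / pmax(abs(fd), 1)))
  }
  for (k in 1:2) {
    xp <- x0; xp[k] <- xp[k] + hstep
    xm <- x0; xm[k] <- xm[k] - hstep
    fp <- simulate_sindy(sindy_model(lib2, Xi, xp, 1e-4), times,
                         control = ctl)$states
    fm <- simulate_sindy(sindy_model(lib2, Xi, xm, 1e-4), times,
                         control = ctl)$states
    fd <- (fp - fm) / (2 * hstep)
    worst <- max(worst, max(abs(fd - sw$sens[, , 12 + k]) /
                              pmax(abs(fd), 1)))
  }
  expect_lt(worst, 1e-4)
})

test_that("odd-degree damping opposes large states componentwise", {
  md <- sindy_model(lib2, matrix(0.1, 6, 2), c(1, 1), stab_coeff = 1e-3)
  # damping degree exceeds the library degree, so beyond |x| ~ max(theta)/eps
  # the damping term dominates every library contribution
  for (big in c(1000, -1000)) {
    f <- unname(sindy_rhs(md, c(big, 1)))
    expect_equal(sign(f[1]), -sign(big))
  }
})

test_that("time series CSV round-trips at full precision", {
  ts <- time_series(c(0, 0.5, 1.25), matrix(rnorm(6), 3, 2),
                    c("u", "v"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_time_series(ts, f)
  back <- read_time_series(f)
  expect_equal(back$states, ts$states, tolerance = 1e-12)
  expect_equal(back$names, c("u", "v"))
  expect_equal(readLines(f, n = 1), "t,u,v")
})

test_that("time series construction enforces its invariants", {
  expect_error(time_series(c(0, 0), matrix(0, 2, 1)), "increasing")
  expect_error(time_series(c(0, 1), matrix(c(1, NA), 2, 1)), "finite")
  expect_error(time_series(0, matrix(0, 1, 1)), "two")
})
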