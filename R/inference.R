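# Posterior inference for SINDy models and linear regression under
# sparsifying priors. The coefficient hierarchies are parameterized
# non-centrally (raw z ~ N(0,1) multiplied by the hierarchical scale) and all
# positive latents are sampled on the log scale, which keeps the horseshoe
# funnel tractable for gradient-based transitions.

# ---- coefficient prior blocks -------------------------------------------

coef_npar <- function(family, ld) {
  switch(family, spike_slab = ld, reg_horseshoe = 2L * ld + 2L,
         laplace = ld, normal_reference = ld)
}

coef_init <- function(prior, ld) {
  switch(prior$family,
    spike_slab = rep(0, ld),
    reg_horseshoe = c(rep(0, ld), rep(log(0.1), ld), log(prior$tau0),
                      log(prior$s^2)),
    laplace = rep(0, ld),
    normal_reference = rep(0, ld))
}

# natural coefficient matrix only (cheap path for indicator flips);
# operates on plain vectors and sets dims once (hot path)
coef_to_xi <- function(prior, alpha, qc, disc, l, d) {
  ld <- l * d
  xi <- switch(prior$family,
    spike_slab = {
      sdm <- alpha * (disc * prior$c + (1 - disc) * prior$eps_spike)
      qc[seq_len(ld)] * sdm
    },
    reg_horseshoe = {
      lam <- exp(qc[ld + seq_len(ld)])
      tau <- exp(qc[2 * ld + 1]); cc <- exp(qc[2 * ld + 2] / 2)
      A <- lam * tau
      qc[seq_len(ld)] * alpha * cc * A / sqrt(cc^2 + A^2)
    },
    qc[seq_len(ld)])
  dim(xi) <- c(l, d)
  xi
}

# prior log density + chain-ruled gradient. dXi may be NULL (prior only).
coef_eval <- function(prior, alpha, qc, disc, l, d, dXi = NULL) {
  ld <- l * d
  fam <- prior$family
  grad <- numeric(length(qc))
  extras <- list()
  if (fam == "spike_slab") {
    z <- qc[seq_len(ld)]
    lam <- disc
    sdm <- alpha * (lam * prior$c + (1 - lam) * prior$eps_spike)
    Xi <- z * sdm
    dim(Xi) <- c(l, d)
    lp <- -0.5 * sum(z^2) - 0.5 * ld * log(2 * pi) +
      sum(lam) * log(prior$pi) + sum(1 - lam) * log(1 - prior$pi)
    g <- -z
    if (!is.null(dXi)) g <- g + dXi * sdm
    grad[seq_len(ld)] <- g
    extras$lambda <- matrix(lam, l, d)
  } else if (fam == "reg_horseshoe") {
    z <- qc[seq_len(ld)]
    eta <- qc[ld + seq_len(ld)]
    ltau <- qc[2 * ld + 1]; lc2 <- qc[2 * ld + 2]
    lam <- exp(eta); tau <- exp(ltau); c2 <- exp(lc2); cc <- sqrt(c2)
    A <- lam * tau
    den <- sqrt(c2 + A^2)
    ltb <- cc * A / den                       # lambda_tilde * tau
    Xi <- z * alpha * ltb
    dim(Xi) <- c(l, d)
    a_ig <- prior$nu / 2; b_ig <- prior$nu * prior$s^2 / 2
    rt <- (tau / prior$tau0)^2
    lp <- -0.5 * sum(z^2) - 0.5 * ld * log(2 * pi) +
      sum(log(2 / pi) - log1p(lam^2) + eta) +
      (log(2 / pi) - log(prior$tau0) - log1p(rt) + ltau) +
      (a_ig * log(b_ig) - lgamma(a_ig) - a_ig * lc2 - b_ig / c2)
    gz <- -z
    geta <- 1 - 2 * lam^2 / (1 + lam^2)
    gtau <- 1 - 2 * rt / (1 + rt)
    gc2 <- -a_ig + b_ig / c2
    if (!is.null(dXi)) {
      gz <- gz + dXi * alpha * ltb
      dA <- dXi * z * alpha * cc^3 * A / den^3   # d lp / d eta_ij (lik part)
      geta <- geta + dA
      gtau <- gtau + sum(dA)
      gc2 <- gc2 + sum(dXi * z * alpha * A^3 / den^3) * cc / 2
    }
    grad[seq_len(ld)] <- gz
    grad[ld + seq_len(ld)] <- geta
    grad[2 * ld + 1] <- gtau
    grad[2 * ld + 2] <- gc2
    extras <- list(lambda = matrix(lam, l, d), tau = tau, c2 = c2)
  } else if (fam == "laplace") {
    xi <- matrix(qc[seq_len(ld)], l, d)
    Xi <- xi
    bm <- prior$b * alpha
    lp <- sum(-abs(xi - prior$mu) / bm - log(2 * bm))
    g <- -sign(xi - prior$mu) / bm
    if (!is.null(dXi)) g <- g + dXi
    grad[seq_len(ld)] <- g
  } else { # normal_reference
    xi <- matrix(qc[seq_len(ld)], l, d)
    Xi <- xi
    lp <- sum(stats::dnorm(xi, 0, alpha, log = TRUE))
    g <- -xi / alpha^2
    if (!is.null(dXi)) g <- g + dXi
    grad[seq_len(ld)] <- g
  }
  list(Xi = Xi, lp = lp, grad = grad, extras = extras)
}

as_spec_list <- function(spec, d) {
  if (inherits(spec, "dist_spec")) rep(list(spec), d) else {
    stopifnot(is.list(spec), length(spec) == d)
    spec
  }
}

# ---- ODE target ----------------------------------------------------------

# ridge least-squares coefficient estimate from finite-difference
# derivatives; the warm start that places chains in the basin of the
# data-fitting mode (the ODE posterior is multimodal in Xi)
ls_xi_estimate <- function(data, library, ridge = 1e-3) {
  xdot <- finite_difference_derivatives(data)
  th <- evaluate_library(library, data$states)
  M <- crossprod(th) + diag(ridge, ncol(th))
  solve(M, crossprod(th, xdot))
}

# invert the non-centred map at the warm-start coefficient estimate
coef_warm_init <- function(prior, alpha, xi_hat, l, d) {
  ld <- l * d
  switch(prior$family,
    spike_slab = {
      z <- xi_hat / (prior$c * alpha)
      as.vector(pmin(pmax(z, -3), 3))
    },
    reg_horseshoe = {
      A <- pmax(abs(xi_hat) / alpha, 0.05)
      cc <- prior$s
      ltb <- cc * A / sqrt(cc^2 + A^2)
      z <- pmin(pmax(xi_hat / (alpha * ltb), -3), 3)
      c(as.vector(z), as.vector(log(A / prior$tau0)), log(prior$tau0),
        log(prior$s^2))
    },
    as.vector(xi_hat))
}

make_ode_target <- function(data, library, prior, noise, eps_stab, h, guard,
                            t0, init_xi = "ls") {
  Y <- data$states; times <- data$times
  n <- nrow(Y); d <- ncol(Y); l <- library$l; ld <- l * d
  E <- library$exponents
  m <- stabilization_degree(library$max_degree)
  alpha <- alpha_matrix(prior, l, d)
  sig_specs <- as_spec_list(
    if (!is.null(prior$noise_prior)) prior$noise_prior else noise$sigma_prior,
    d)
  x0_specs <- as_spec_list(
    if (!is.null(prior$x0_prior)) prior$x0_prior else
      dist_spec("normal", mean = 0, sd = 10), d)
  x0_pos <- vapply(x0_specs, dist_is_positive, logical(1))
  lognorm <- noise$family == "lognormal"
  if (lognorm && any(Y <= 0)) {
    stop("lognormal likelihood requires strictly positive data",
         call. = FALSE)
  }
  logY <- if (lognorm) log(Y)
  nc <- coef_npar(prior$family, ld)
  i_coef <- seq_len(nc); i_sig <- nc + seq_len(d); i_x0 <- nc + d + seq_len(d)
  const_ll <- -0.5 * n * d * log(2 * pi) - (if (lognorm) sum(logY) else 0)

  all_pos <- all(x0_pos); none_pos <- !any(x0_pos)
  same_sig <- length(unique(vapply(sig_specs, function(s)
    paste(unlist(s), collapse = "|"), character(1)))) == 1L
  same_x0 <- length(unique(vapply(x0_specs, function(s)
    paste(unlist(s), collapse = "|"), character(1)))) == 1L

  unpack <- function(q) {
    sigma <- exp(q[i_sig])
    x0 <- if (all_pos) exp(q[i_x0]) else if (none_pos) q[i_x0] else
      ifelse(x0_pos, exp(q[i_x0]), q[i_x0])
    list(qc = q[i_coef], sigma = sigma, x0 = x0)
  }

  loglik_of <- function(xhat, sigma) {
    if (lognorm) {
      if (any(xhat <= 0)) return(-Inf)
      rs <- sweep(logY - log(xhat), 2L, sigma, "/")
    } else {
      rs <- sweep(Y - xhat, 2L, sigma, "/")
    }
    -0.5 * sum(rs^2) - n * sum(log(sigma)) + const_ll
  }

  coef_init_vec <- if (identical(init_xi, "zero")) {
    coef_init(prior, ld)
  } else {
    xi_hat <- if (is.matrix(init_xi)) init_xi else
      ls_xi_estimate(data, library)
    coef_warm_init(prior, alpha, xi_hat, l, d)
  }

  list(
    n_cont = nc + 2L * d,
    init = function() {
      y1 <- Y[1, ]
      x0i <- ifelse(x0_pos, log(pmax(y1, 1e-3)), y1)
      sigi <- vapply(sig_specs, function(s) log(dist_median(s)), numeric(1))
      c(coef_init_vec, sigi, x0i)
    },
    disc_init = function() {
      if (prior$family == "spike_slab") rep(1L, ld) else NULL
    },
    disc_logodds = if (prior$family == "spike_slab") {
      log(prior$pi / (1 - prior$pi))
    } else 0,
    loglik = function(q, disc) {
      u <- unpack(q)
      Xi <- coef_to_xi(prior, alpha, u$qc, disc, l, d)
      out <- cpp_simulate(E, Xi, u$x0, times, t0, eps_stab, m, h, guard)
      if (out$diverged) return(-Inf)
      loglik_of(out$states, u$sigma)
    },
    logp_grad = function(q, disc) {
      u <- unpack(q)
      Xi <- coef_to_xi(prior, alpha, u$qc, disc, l, d)
      out <- cpp_ode_loglik_grad(E, Xi, u$x0, times, t0, eps_stab, m, h,
                                 guard, Y, u$sigma,
                                 if (lognorm) 1L else 0L)
      if (!isTRUE(out$ok)) {
        return(list(lp = -Inf, grad = NULL, loglik = -Inf))
      }
      ll <- out$loglik
      dXi <- matrix(out$gpar[seq_len(ld)], l, d)
      dx0 <- out$gpar[ld + seq_len(d)]

      ce <- coef_eval(prior, alpha, u$qc, disc, l, d, dXi)
      grad <- numeric(length(q))
      grad[i_coef] <- ce$grad
      lp <- ll + ce$lp
      # noise scales (log parameterization); vectorized over dims when the
      # specs coincide, accumulating lp in the same per-dimension order
      gsig <- out$gsig
      if (same_sig) {
        pr <- dist_logpdf_u(sig_specs[[1]], q[i_sig])
        for (j in seq_len(d)) lp <- lp + pr$lp[j]
        gsig <- gsig + pr$grad
      } else {
        for (j in seq_len(d)) {
          pr <- dist_logpdf_u(sig_specs[[j]], q[i_sig[j]])
          lp <- lp + pr$lp
          gsig[j] <- gsig[j] + pr$grad
        }
      }
      grad[i_sig] <- gsig
      # initial conditions
      gx0 <- if (all_pos) dx0 * u$x0 else if (none_pos) dx0 else
        ifelse(x0_pos, dx0 * u$x0, dx0)
      if (same_x0) {
        pr <- dist_logpdf_u(x0_specs[[1]], q[i_x0])
        for (j in seq_len(d)) lp <- lp + pr$lp[j]
        gx0 <- gx0 + pr$grad
      } else {
        for (j in seq_len(d)) {
          pr <- dist_logpdf_u(x0_specs[[j]], q[i_x0[j]])
          lp <- lp + pr$lp
          gx0[j] <- gx0[j] + pr$grad
        }
      }
      grad[i_x0] <- gx0
      list(lp = lp, grad = grad, loglik = ll)
    },
    extract = function(q, disc) {
      u <- unpack(q)
      ce <- coef_eval(prior, alpha, u$qc, disc, l, d)
      c(list(Xi = ce$Xi, sigma = u$sigma, x0 = u$x0), ce$extras)
    })
}

# ---- regression target ---------------------------------------------------

#' Linear regression problem
#'
#' @param X `n x p` design matrix.
#' @param y response vector of length `n`.
#' @param noise_sigma known noise standard deviation, or `NULL` to treat it
#'   as a latent with prior `sigma_prior`.
#' @param sigma_prior [dist_spec()] for the noise scale when latent.
#' @return object of class `regression_problem`.
#' @export
regression_problem <- function(X, y, noise_sigma = NULL,
                               sigma_prior = dist_spec("halfnormal", sd = 1)) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y sizes differ", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite entries", call. = FALSE)
  }
  if (!is.null(noise_sigma) && noise_sigma <= 0) {
    stop("`noise_sigma` must be positive", call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)))
  structure(list(X = X, y = as.numeric(y), n = nrow(X), p = ncol(X),
                 noise_sigma = noise_sigma, sigma_prior = sigma_prior),
            class = "regression_problem")
}

make_regression_target <- function(problem, prior) {
  X <- problem$X; y <- problem$y
  n <- problem$n; p <- problem$p
  XtX <- crossprod(X); Xty <- drop(crossprod(X, y)); yty <- sum(y^2)
  alpha <- alpha_matrix(prior, p, 1L)
  known_sig <- !is.null(problem$noise_sigma)
  nc <- coef_npar(prior$family, p)
  i_coef <- seq_len(nc)
  i_sig <- if (known_sig) integer(0) else nc + 1L
  const_ll <- -0.5 * n * log(2 * pi)

  qform <- function(beta) {
    yty - 2 * sum(beta * Xty) + drop(crossprod(beta, XtX %*% beta))
  }

  list(
    n_cont = nc + length(i_sig),
    init = function() {
      sigi <- if (known_sig) numeric(0) else
        log(dist_median(problem$sigma_prior))
      c(coef_init(prior, p), sigi)
    },
    disc_init = function() {
      if (prior$family == "spike_slab") rep(1L, p) else NULL
    },
    disc_logodds = if (prior$family == "spike_slab") {
      log(prior$pi / (1 - prior$pi))
    } else 0,
    loglik = function(q, disc) {
      beta <- drop(coef_to_xi(prior, alpha, q[i_coef], disc, p, 1L))
      sigma <- if (known_sig) problem$noise_sigma else exp(q[i_sig])
      -n * log(sigma) - qform(beta) / (2 * sigma^2) + const_ll
    },
    logp_grad = function(q, disc) {
      sigma <- if (known_sig) problem$noise_sigma else exp(q[i_sig])
      qc <- q[i_coef]
      Xi <- coef_to_xi(prior, alpha, qc, disc, p, 1L)
      beta <- drop(Xi)
      qf <- qform(beta)
      ll <- -n * log(sigma) - qf / (2 * sigma^2) + const_ll
      dbeta <- matrix((Xty - drop(XtX %*% beta)) / sigma^2, p, 1L)
      ce <- coef_eval(prior, alpha, qc, disc, p, 1L, dbeta)
      grad <- numeric(length(q))
      grad[i_coef] <- ce$grad
      lp <- ll + ce$lp
      if (!known_sig) {
        pr <- dist_logpdf_u(problem$sigma_prior, q[i_sig])
        lp <- lp + pr$lp
        grad[i_sig] <- -n + qf / sigma^2 + pr$grad
      }
      list(lp = lp, grad = grad, loglik = ll)
    },
    extract = function(q, disc) {
      sigma <- if (known_sig) problem$noise_sigma else exp(q[i_sig])
      ce <- coef_eval(prior, alpha, q[i_coef], disc, p, 1L)
      c(list(Xi = ce$Xi, sigma = sigma), ce$extras)
    })
}

# ---- fit drivers ---------------------------------------------------------

assemble_samples <- function(chains_out, target, control, seed, kind,
                             term_labels, state_names, family, meta) {
  n_ch <- length(chains_out); n_dr <- control$draws
  l <- length(term_labels); d <- length(state_names)
  has_disc <- !is.null(chains_out[[1]]$disc)
  first <- target$extract(chains_out[[1]]$q[1, ],
                          if (has_disc) chains_out[[1]]$disc[1, ])
  has_x0 <- !is.null(first$x0)
  arr <- function(k) array(NA_real_, c(n_ch, n_dr, l, d))
  Xi <- arr(); lambda <- if (!is.null(first$lambda)) arr()
  sigma <- array(NA_real_, c(n_ch, n_dr, length(first$sigma)))
  x0 <- if (has_x0) array(NA_real_, c(n_ch, n_dr, d))
  tau <- if (!is.null(first$tau)) matrix(NA_real_, n_ch, n_dr)
  c2 <- if (!is.null(first$c2)) matrix(NA_real_, n_ch, n_dr)
  lp <- matrix(NA_real_, n_ch, n_dr)
  for (ch in seq_len(n_ch)) {
    co <- chains_out[[ch]]
    for (k in seq_len(n_dr)) {
      ex <- target$extract(co$q[k, ], if (has_disc) co$disc[k, ])
      Xi[ch, k, , ] <- ex$Xi
      if (!is.null(lambda)) lambda[ch, k, , ] <- ex$lambda
      sigma[ch, k, ] <- ex$sigma
      if (has_x0) x0[ch, k, ] <- ex$x0
      if (!is.null(tau)) tau[ch, k] <- ex$tau
      if (!is.null(c2)) c2[ch, k] <- ex$c2
      lp[ch, k] <- co$lp[k]
    }
  }
  dimnames(Xi) <- list(NULL, NULL, term_labels, state_names)
  res <- structure(list(
    draws = list(Xi = Xi, lambda = lambda, sigma = sigma, x0 = x0,
                 tau = tau, c2 = c2, lp = lp),
    family = family, kind = kind,
    term_labels = term_labels, state_names = state_names,
    chains = n_ch, n_draws = n_dr, seed = seed, control = control,
    divergences = vapply(chains_out, `[[`, integer(1), "divergences"),
    accept_rate = vapply(chains_out, `[[`, numeric(1), "accept_rate"),
    flip_accept_rate = vapply(chains_out, `[[`, numeric(1),
                              "flip_accept_rate"),
    meta = meta), class = "uq_samples")
  res$diagnostics <- convergence_diagnostics(res)
  res
}

#' Fit a SINDy model to a noisy time series by MCMC
#'
#' Samples the joint posterior of the SINDy coefficients, initial state and
#' noise scales given noisy snapshots, under the configured coefficient
#' prior and observation model. Regularized-horseshoe, Laplace and
#' normal-reference fits use gradient-based (Hamiltonian) transitions over
#' all continuous latents, driven by forward sensitivities of the ODE
#' solution; spike-and-slab fits alternate single-site Metropolized Gibbs
#' updates of the Bernoulli inclusion indicators with the gradient-based
#' updates of the continuous latents (compound stepping). With the Dirac
#' spike, coefficient draws for excluded terms are exactly zero.
#'
#' @param data a `uq_ts` of noisy snapshots.
#' @param library a `sindy_library`.
#' @param prior a [prior_config()]; its `noise_prior`/`x0_prior` fields, if
#'   set, override `noise$sigma_prior` and the default initial-state prior.
#' @param noise a [noise_model()].
#' @param control a [sampler_control()].
#' @param seed integer seed; fits are reproducible given
#'   (data, configuration, seed).
#' @param eps_stab stabilization coefficient; default from
#'   [default_stab_coeff()] at the observed data scale.
#' @param h fixed RK4 step bound for the in-sampler integrator.
#' @param guard divergence guard; default `1000 * max(abs(data))`. A draw
#'   whose trajectory exceeds it gets log density `-Inf` and is rejected.
#' @param t0 model time origin at which `x0` applies (default: first
#'   observation time).
#' @param init_xi chain initialization strategy. `"map"` (default) seeds the
#'   coefficients from a finite-difference ridge least-squares estimate and
#'   then runs deterministic gradient ascent (BFGS on the log posterior) to
#'   a mode, starting all chains jittered around it -- the coefficient
#'   posterior of a periodic trajectory is multimodal and cold-started
#'   chains tend to settle in non-oscillatory basins. `"ls"` skips the
#'   ascent, `"zero"` starts from the sparse origin, and an explicit
#'   `l x d` matrix is used in place of the least-squares estimate.
#' @return a `uq_samples` object; see [summary.uq_samples()].
#' @export
fit_ode <- function(data, library, prior, noise, control = sampler_control(),
                    seed = 1, eps_stab = NULL, h = 0.02, guard = NULL,
                    t0 = data$times[1], init_xi = "map") {
  stopifnot(inherits(data, "uq_ts"), inherits(library, "sindy_library"),
            inherits(prior, "prior_config"), inherits(noise, "noise_model"))
  if (ncol(data$states) != library$d) {
    stop("data dimension does not match library", call. = FALSE)
  }
  scale <- max(abs(data$states))
  m <- stabilization_degree(library$max_degree)
  if (is.null(eps_stab)) eps_stab <- default_stab_coeff(scale, m)
  if (is.null(guard)) guard <- 1e3 * scale
  target <- make_ode_target(data, library, prior, noise, eps_stab, h, guard,
                            t0, if (identical(init_xi, "map")) "ls" else
                              init_xi)
  if (identical(init_xi, "map")) {
    # gradient ascent from the least-squares warm start to a posterior
    # mode, with a few jittered restarts (BFGS can stall in a local mode
    # of the multimodal trajectory fit); chains start jittered around the
    # best mode found
    disc0 <- target$disc_init()
    fn <- function(q) {
      r <- target$logp_grad(q, disc0)
      if (is.finite(r$lp)) -r$lp else 1e10
    }
    gr <- function(q) {
      r <- target$logp_grad(q, disc0)
      if (is.finite(r$lp)) -r$grad else numeric(target$n_cont)
    }
    q_ls <- target$init()
    nc_coef <- coef_npar(prior$family, library$l * library$d)
    set.seed(chain_seed(seed, 0L))
    best <- NULL; best_lp <- -Inf
    for (k in 1:6) {
      q0 <- q_ls
      if (k > 1) {
        # jitter only the coefficient block: x0 and sigma starts are
        # data-informed, and large jitters there just hit the divergence
        # guard; redraw a start that lands on a finite density
        for (try in 1:5) {
          q0 <- q_ls
          q0[seq_len(nc_coef)] <- q0[seq_len(nc_coef)] +
            stats::rnorm(nc_coef, 0, 0.3)
          if (fn(q0) < 1e9) break
        }
        if (fn(q0) >= 1e9) next
      }
      q_map <- tryCatch(
        stats::optim(q0, fn, gr, method = "BFGS",
                     control = list(maxit = 400))$par,
        error = function(e) NULL)
      if (is.null(q_map)) next
      lp <- target$logp_grad(q_map, disc0)$lp
      if (is.finite(lp) && lp > best_lp) {
        best <- q_map; best_lp <- lp
      }
    }
    if (!is.null(best)) {
      target$init <- local({
        qm <- best
        function() qm
      })
    }
  }
  chains_out <- run_sampler(target, control, seed)
  assemble_samples(
    chains_out, target, control, seed, "ode",
    library$labels, library$state_names, prior$family,
    meta = list(library = library, data = data, noise = noise, prior = prior,
                eps_stab = eps_stab, stab_degree = m, h = h, guard = guard,
                t0 = t0))
}

#' Bayesian linear regression under a sparsifying prior
#'
#' The regression pathway of the same machinery: `y = X beta + eps` with
#' iid Gaussian noise, `beta` under the configured prior. Used for the
#' 10-predictor sparse-recovery comparison and for validating the samplers
#' against [enumerate_spike_slab()].
#'
#' @param problem a [regression_problem()].
#' @inheritParams fit_ode
#' @return a `uq_samples` object (single "equation", terms = predictors).
#' @export
fit_regression <- function(problem, prior, control = sampler_control(),
                           seed = 1) {
  stopifnot(inherits(problem, "regression_problem"),
            inherits(prior, "prior_config"))
  target <- make_regression_target(problem, prior)
  chains_out <- run_sampler(target, control, seed)
  assemble_samples(
    chains_out, target, control, seed, "regression",
    colnames(problem$X), "y", prior$family,
    meta = list(problem = problem, prior = prior))
}

#' Exact spike-and-slab posterior by model enumeration
#'
#' For a linear-Gaussian regression with known noise scale and a Dirac
#' spike, the posterior over the `2^p` inclusion configurations is available
#' in closed form: each configuration's Gaussian marginal likelihood
#' (slab-integrated) times its Bernoulli prior mass, normalized. Per-term
#' inclusion probabilities follow by marginalization. This is the
#' independent oracle against which the compound sampler is validated.
#'
#' @param problem a [regression_problem()] with `noise_sigma` set.
#' @param pi prior inclusion probability.
#' @param c slab standard deviation.
#' @param alpha optional per-term scale multipliers (length `p`).
#' @return list with `inclusion` (named per-term posterior inclusion
#'   probabilities), `log_marginal` (per-configuration log marginal
#'   likelihood + prior), `post` (normalized configuration probabilities)
#'   and `configs` (the `2^p x p` 0/1 matrix).
#' @export
enumerate_spike_slab <- function(problem, pi = 0.5, c = 1, alpha = 1) {
  stopifnot(inherits(problem, "regression_problem"))
  if (is.null(problem$noise_sigma)) {
    stop("enumeration requires a known `noise_sigma`", call. = FALSE)
  }
  p <- problem$p
  if (p > 15) {
    stop("enumeration over 2^p models is limited to p <= 15", call. = FALSE)
  }
  if (length(alpha) == 1L) alpha <- rep(alpha, p)
  sig2 <- problem$noise_sigma^2
  X <- problem$X; y <- problem$y; n <- problem$n
  XtX <- crossprod(X); Xty <- drop(crossprod(X, y)); yty <- sum(y^2)
  v <- (c * alpha)^2
  configs <- as.matrix(expand.grid(rep(list(0:1), p)))[, p:1, drop = FALSE]
  colnames(configs) <- colnames(problem$X)
  logml <- apply(configs, 1L, function(g) {
    k <- sum(g)
    base <- -0.5 * n * log(2 * pi * sig2) - 0.5 * yty / sig2
    lm <- if (k == 0) base else {
      idx <- which(g == 1)
      M <- diag(1 / v[idx], k) + XtX[idx, idx, drop = FALSE] / sig2
      b <- Xty[idx] / sig2
      ch <- chol(M)
      u <- backsolve(ch, forwardsolve(t(ch), b))
      base - 0.5 * sum(log(v[idx])) - sum(log(diag(ch))) + 0.5 * sum(b * u)
    }
    lm + k * log(pi) + (p - k) * log(1 - pi)
  })
  post <- exp(logml - max(logml))
  post <- post / sum(post)
  inclusion <- drop(crossprod(configs, post))
  names(inclusion) <- colnames(configs)
  list(inclusion = inclusion, log_marginal = logml, post = post,
       configs = configs)
}

# ---- summaries -----------------------------------------------------------

#' @export
print.uq_samples <- function(x, ...) {
  cat(sprintf(
    "Posterior samples (%s, %s): %d chains x %d draws, seed %d\n",
    x$family, x$kind, x$chains, x$n_draws, x$seed))
  cat(sprintf("  divergences: %s; mean acceptance: %.2f\n",
              paste(x$divergences, collapse = "/"),
              mean(x$accept_rate)))
  invisible(x)
}

# chains x draws matrix for one flattened parameter of the Xi array
xi_matrix <- function(samples, i, j) {
  samples$draws$Xi[, , i, j, drop = FALSE][, , 1, 1]
}

#' Convergence diagnostics for a fit
#'
#' @param samples a `uq_samples`.
#' @return data frame with one row per monitored scalar (each coefficient,
#'   each noise scale, each initial condition): split-Rhat and effective
#'   sample size.
#' @export
convergence_diagnostics <- function(samples) {
  l <- length(samples$term_labels); d <- length(samples$state_names)
  rows <- list()
  for (j in seq_len(d)) {
    for (i in seq_len(l)) {
      m <- xi_matrix(samples, i, j)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = paste0(samples$state_names[j], ":",
                           samples$term_labels[i]),
        rhat = split_rhat(m), ess = ess_basic(m))
    }
  }
  sig <- samples$draws$sigma
  for (j in seq_len(dim(sig)[3])) {
    m <- sig[, , j, drop = FALSE][, , 1]
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = paste0("sigma[", j, "]"),
      rhat = split_rhat(m), ess = ess_basic(m))
  }
  if (!is.null(samples$draws$x0)) {
    for (j in seq_len(d)) {
      m <- samples$draws$x0[, , j, drop = FALSE][, , 1]
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = paste0("x0[", j, "]"),
        rhat = split_rhat(m), ess = ess_basic(m))
    }
  }
  do.call(rbind, rows)
}

#' Posterior summary table
#'
#' @param object a `uq_samples`.
#' @param ... unused.
#' @return data frame with one row per (equation, term): posterior mean, sd,
#'   central quantiles, smoothed-density mode, and (spike-and-slab fits)
#'   inclusion probability.
#' @export
summary.uq_samples <- function(object, ...) {
  l <- length(object$term_labels); d <- length(object$state_names)
  rows <- list()
  for (j in seq_len(d)) {
    for (i in seq_len(l)) {
      v <- as.vector(object$draws$Xi[, , i, j])
      qs <- stats::quantile(v, c(0.05, 0.5, 0.95), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        equation = object$state_names[j], term = object$term_labels[i],
        mean = mean(v), sd = stats::sd(v), q5 = qs[1], q50 = qs[2],
        q95 = qs[3], mode = posterior_mode(v),
        inclusion = if (object$family == "spike_slab") {
          mean(object$draws$lambda[, , i, j])
        } else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Save / load posterior samples as plain text
#'
#' Writes the draw arrays as CSVs plus a JSON metadata file into a
#' directory, so a fit can be reloaded by the diagnostics tooling without
#' any binary serialization.
#'
#' @param samples a `uq_samples`.
#' @param dir target directory (created if missing).
#' @return `write_samples` returns `dir` invisibly; `read_samples` a
#'   `uq_samples` (draw arrays and metadata fields; closures such as prior
#'   configs are restored as plain lists).
#' @export
write_samples <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dr <- samples$draws
  flat <- function(a) {
    dm <- dim(a)
    matrix(a, nrow = dm[1] * dm[2])
  }
  for (nm in names(dr)) {
    if (is.null(dr[[nm]])) next
    a <- dr[[nm]]
    if (is.matrix(a)) a <- array(a, c(dim(a), 1))
    utils::write.csv(flat(a), file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  meta <- list(family = samples$family, kind = samples$kind,
               term_labels = samples$term_labels,
               state_names = samples$state_names,
               chains = samples$chains, n_draws = samples$n_draws,
               seed = samples$seed, divergences = samples$divergences,
               dims = lapply(dr[!vapply(dr, is.null, logical(1))], dim))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_samples
#' @export
read_samples <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  draws <- list()
  for (nm in names(meta$dims)) {
    m <- as.matrix(utils::read.csv(file.path(dir, paste0(nm, ".csv"))))
    draws[[nm]] <- array(m, unlist(meta$dims[[nm]]))
  }
  if (!is.null(draws$Xi)) {
    dimnames(draws$Xi) <- list(NULL, NULL, meta$term_labels,
                               meta$state_names)
  }
  structure(list(draws = draws, family = meta$family, kind = meta$kind,
                 term_labels = meta$term_labels,
                 state_names = meta$state_names, chains = meta$chains,
                 n_draws = meta$n_draws, seed = meta$seed,
                 divergences = meta$divergences, meta = list()),
            class = "uq_samples")
}
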