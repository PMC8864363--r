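#' Distribution specification for noise and initial-condition priors
#'
#' A small tagged list naming a univariate prior family and its parameters.
#' Supported families: `lognormal(meanlog, sdlog)`, `normal(mean, sd)`,
#' `gamma(shape, rate)` (shape--rate convention, mean `shape/rate`),
#' `laplace(mu, b)`, `halfnormal(sd)`, `halfcauchy(scale)`.
#'
#' @param family family name.
#' @param ... named numeric parameters for the family.
#' @return object of class `dist_spec`.
#' @export
dist_spec <- function(family = c("lognormal", "normal", "gamma", "laplace",
                                 "halfnormal", "halfcauchy"), ...) {
  family <- match.arg(family)
  pars <- list(...)
  need <- switch(family,
    lognormal = c("meanlog", "sdlog"), normal = c("mean", "sd"),
    gamma = c("shape", "rate"), laplace = c("mu", "b"),
    halfnormal = c("sd"), halfcauchy = c("scale"))
  if (!setequal(names(pars), need)) {
    stop(sprintf("`%s` needs parameters: %s", family,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  pos <- setdiff(need, c("mean", "meanlog", "mu"))
  for (p in pos) {
    if (pars[[p]] <= 0) stop(sprintf("`%s` must be positive", p),
                             call. = FALSE)
  }
  structure(c(list(family = family), pars), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat(sprintf("%s(%s)\n", x$family,
              paste(sprintf("%s=%g", names(pars), unlist(pars)),
                    collapse = ", ")))
  invisible(x)
}

dist_draw <- function(spec, n) {
  switch(spec$family,
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    normal = stats::rnorm(n, spec$mean, spec$sd),
    gamma = stats::rgamma(n, shape = spec$shape, rate = spec$rate),
    laplace = spec$mu + sample(c(-1, 1), n, replace = TRUE) *
      stats::rexp(n, rate = 1 / spec$b),
    halfnormal = abs(stats::rnorm(n, 0, spec$sd)),
    halfcauchy = abs(stats::rcauchy(n, 0, spec$scale)))
}

dist_is_positive <- function(spec) {
  spec$family %in% c("lognormal", "gamma", "halfnormal", "halfcauchy")
}

dist_median <- function(spec) {
  switch(spec$family,
    lognormal = exp(spec$meanlog),
    normal = spec$mean,
    gamma = stats::qgamma(0.5, shape = spec$shape, rate = spec$rate),
    laplace = spec$mu,
    halfnormal = stats::qnorm(0.75) * spec$sd,
    halfcauchy = spec$scale)
}

# log prior density and gradient in the sampling parameterization:
# positive-support families are sampled as u = log(x) (Jacobian included),
# real-support families directly. Returns list(lp, grad), vectorized over u.
dist_logpdf_u <- function(spec, u) {
  switch(spec$family,
    lognormal = { # log x ~ N(meanlog, sdlog): normal in u
      z <- (u - spec$meanlog) / spec$sdlog
      list(lp = -0.5 * z^2 - log(spec$sdlog) - 0.5 * log(2 * pi),
           grad = -z / spec$sdlog)
    },
    normal = {
      z <- (u - spec$mean) / spec$sd
      list(lp = -0.5 * z^2 - log(spec$sd) - 0.5 * log(2 * pi),
           grad = -z / spec$sd)
    },
    gamma = { # x = exp(u); lp = shape*u - rate*exp(u) + const (with Jacobian)
      x <- exp(u)
      list(lp = spec$shape * u - spec$rate * x +
             spec$shape * log(spec$rate) - lgamma(spec$shape),
           grad = spec$shape - spec$rate * x)
    },
    laplace = {
      list(lp = -abs(u - spec$mu) / spec$b - log(2 * spec$b),
           grad = -sign(u - spec$mu) / spec$b)
    },
    halfnormal = { # x = exp(u)
      x <- exp(u)
      list(lp = -0.5 * (x / spec$sd)^2 + u +
             0.5 * log(2 / pi) - log(spec$sd),
           grad = 1 - (x / spec$sd)^2)
    },
    halfcauchy = { # x = exp(u)
      x <- exp(u)
      r2 <- (x / spec$scale)^2
      list(lp = log(2 / pi) - log(spec$scale) - log1p(r2) + u,
           grad = 1 - 2 * r2 / (1 + r2))
    })
}

#' Laplace (double-exponential) log density
#'
#' \eqn{f(x \mid \mu, b) = \exp(-|x-\mu|/b) / (2b)}; the prior whose MAP
#' estimate corresponds to l1-penalized (lasso) regression, used here as the
#' non-sparsifying Bayesian comparator.
#'
#' @param x numeric vector of evaluation points.
#' @param mu location.
#' @param b positive scale.
#' @return log density, vectorized over `x`.
#' @export
laplace_logpdf <- function(x, mu = 0, b = 1) {
  if (length(b) != 1L || !is.finite(b) || b <= 0) {
    stop("`b` must be a single positive number", call. = FALSE)
  }
  -abs(x - mu) / b - log(2 * b)
}

#' Draw from the spike-and-slab prior
#'
#' Each coefficient is gated by a Bernoulli indicator \eqn{\lambda}: with
#' probability `pi` it follows the wide slab `N(0, (alpha_scale*c)^2)`, and
#' otherwise the spike -- exactly zero for the Dirac spike
#' (`eps_spike = 0`), or `N(0, (alpha_scale*eps_spike)^2)` for the relaxed
#' spike.
#'
#' @param pi inclusion prior probability in `[0, 1]`.
#' @param c slab standard deviation, positive.
#' @param eps_spike relaxed spike standard deviation in `[0, c)`; 0 gives the
#'   Dirac spike.
#' @param alpha_scale positive per-term scale multiplier.
#' @param n number of draws.
#' @return list with integer vector `lambda` (0/1) and numeric
#'   `coefficient` draws.
#' @export
spike_slab_draw <- function(pi, c = 1, eps_spike = 0, alpha_scale = 1,
                            n = 1) {
  if (pi < 0 || pi > 1) stop("`pi` must lie in [0, 1]", call. = FALSE)
  if (c <= 0) stop("`c` must be positive", call. = FALSE)
  if (eps_spike < 0 || eps_spike >= c) {
    stop("`eps_spike` must lie in [0, c): the spike must be narrower than ",
         "the slab", call. = FALSE)
  }
  if (alpha_scale <= 0) stop("`alpha_scale` must be positive", call. = FALSE)
  lambda <- stats::rbinom(n, 1L, pi)
  sd <- ifelse(lambda == 1L, alpha_scale * c, alpha_scale * eps_spike)
  coef <- ifelse(sd > 0, stats::rnorm(n, 0, pmax(sd, .Machine$double.xmin)), 0)
  list(lambda = lambda, coefficient = coef)
}

#' Regularized local shrinkage scale
#'
#' The regularized (Finnish) horseshoe replaces the local half-Cauchy scale
#' \eqn{\lambda} with
#' \eqn{\tilde\lambda = c\lambda / \sqrt{c^2 + \tau^2\lambda^2}}: for
#' \eqn{\tau\lambda \ll c} it approaches \eqn{\lambda} (plain horseshoe
#' behaviour), and for \eqn{\tau\lambda \gg c} it saturates at \eqn{c/\tau},
#' so escaped coefficients stay on the order of the slab width `c`.
#'
#' @param lambda,tau,c positive numerics (`lambda` may be a vector).
#' @return \eqn{\tilde\lambda}, strictly between 0 and
#'   \eqn{\min(\lambda, c/\tau)} and increasing in `lambda`.
#' @export
regularized_lambda <- function(lambda, tau, c) {
  if (any(lambda <= 0) || tau <= 0 || c <= 0) {
    stop("all arguments must be positive", call. = FALSE)
  }
  c * lambda / sqrt(c^2 + tau^2 * lambda^2)
}

#' Configure a sparsifying prior over SINDy coefficients
#'
#' @param family one of `"spike_slab"`, `"reg_horseshoe"`, `"laplace"`,
#'   `"normal_reference"`. The reference family (`xi ~ N(0, alpha^2)`) is the
#'   non-sparsifying comparator whose posterior modes form the denominator of
#'   shrinkage-factor pseudo-probabilities.
#' @param alpha per-term scale coefficients: a positive scalar, or an
#'   `l x d` matrix aligned with the library (how prior knowledge of
#'   coefficient magnitudes enters). Default 1 for every term.
#' @param pi spike-and-slab prior inclusion probability.
#' @param c spike-and-slab slab standard deviation.
#' @param eps_spike relaxed spike sd (0 = Dirac spike, the default).
#' @param tau0 regularized-horseshoe global scale: `tau ~ HalfCauchy(tau0)`;
#'   smaller values promote sparser models.
#' @param nu,s slab shape: `c^2 ~ Inv-Gamma(nu/2, nu*s^2/2)`.
#' @param b,mu Laplace prior scale and location.
#' @param noise_prior,x0_prior optional [dist_spec()]s (scalars or lists, one
#'   per state dimension) consumed by [fit_ode()].
#' @return object of class `prior_config`.
#' @export
prior_config <- function(family = c("spike_slab", "reg_horseshoe", "laplace",
                                    "normal_reference"),
                         alpha = 1, pi = 0.5, c = 1, eps_spike = 0,
                         tau0 = 0.1, nu = 4, s = 2, b = 1, mu = 0,
                         noise_prior = NULL, x0_prior = NULL) {
  family <- match.arg(family)
  if (any(alpha <= 0)) stop("`alpha` must be strictly positive", call. = FALSE)
  if (family == "spike_slab") {
    if (pi <= 0 || pi >= 1) {
      stop("`pi` must lie in (0, 1)", call. = FALSE)
    }
    if (c <= 0) stop("`c` must be positive", call. = FALSE)
    if (eps_spike < 0 || eps_spike >= c) {
      stop("`eps_spike` must lie in [0, c)", call. = FALSE)
    }
  }
  if (family == "reg_horseshoe" && (tau0 <= 0 || nu <= 0 || s <= 0)) {
    stop("`tau0`, `nu`, `s` must be positive", call. = FALSE)
  }
  if (family == "laplace" && b <= 0) {
    stop("`b` must be positive", call. = FALSE)
  }
  structure(list(family = family, alpha = alpha, pi = pi, c = c,
                 eps_spike = eps_spike, tau0 = tau0, nu = nu, s = s,
                 b = b, mu = mu, noise_prior = noise_prior,
                 x0_prior = x0_prior),
            class = "prior_config")
}

#' @export
print.prior_config <- function(x, ...) {
  hp <- switch(x$family,
    spike_slab = sprintf("pi=%g, c=%g, eps_spike=%g", x$pi, x$c, x$eps_spike),
    reg_horseshoe = sprintf("tau0=%g, nu=%g, s=%g", x$tau0, x$nu, x$s),
    laplace = sprintf("mu=%g, b=%g", x$mu, x$b),
    normal_reference = "sd=alpha")
  cat(sprintf("Prior: %s (%s)\n", x$family, hp))
  invisible(x)
}

# expand the alpha specification to an l x d matrix aligned with a library
alpha_matrix <- function(config, l, d) {
  a <- config$alpha
  if (length(a) == 1L) a <- matrix(a, l, d)
  a <- as.matrix(a)
  if (nrow(a) != l || ncol(a) != d) {
    stop(sprintf("`alpha` must be a scalar or %d x %d matrix", l, d),
         call. = FALSE)
  }
  a
}

#' Declare the latent-variable hierarchy of a sparsifying prior
#'
#' Assembles, for a given prior configuration and candidate library, the
#' non-centred latent hierarchy used by the samplers and for
#' prior-predictive simulation:
#' \itemize{
#' \item spike-and-slab: \eqn{\xi_{ij} = z_{ij}\lambda_{ij} c\,\alpha_{ij}},
#'   \eqn{z \sim N(0,1)}, \eqn{\lambda_{ij} \sim \mathrm{Ber}(\pi)};
#' \item regularized horseshoe:
#'   \eqn{\xi_{ij} = z_{ij}\tilde\lambda_{ij}\tau\,\alpha_{ij}},
#'   \eqn{\lambda_{ij} \sim C^+(0,1)}, \eqn{\tau \sim C^+(0,\tau_0)},
#'   \eqn{c^2 \sim \mathrm{Inv\mbox{-}Gamma}(\nu/2, \nu s^2/2)};
#' \item Laplace: \eqn{\xi_{ij} \sim \mathrm{Laplace}(\mu, b\,\alpha_{ij})};
#' \item normal reference: \eqn{\xi_{ij} \sim N(0, \alpha_{ij}^2)}.
#' }
#'
#' @param config a [prior_config()].
#' @param library a `sindy_library`.
#' @return object of class `uq_prior_model` with the resolved `alpha` matrix,
#'   latent-variable names, and a `draw(n)` closure returning
#'   prior-predictive draws of `xi` (an `n x l x d` array) and the
#'   family-specific latents.
#' @export
build_prior_model <- function(config, library) {
  stopifnot(inherits(config, "prior_config"),
            inherits(library, "sindy_library"))
  l <- library$l; d <- library$d
  alpha <- alpha_matrix(config, l, d)
  latents <- switch(config$family,
    spike_slab = c("z", "lambda"),
    reg_horseshoe = c("z", "lambda", "tau", "c2"),
    laplace = "xi", normal_reference = "xi")
  draw <- function(n) {
    xi <- array(0, c(n, l, d))
    extra <- list()
    if (config$family == "spike_slab") {
      lam <- array(stats::rbinom(n * l * d, 1L, config$pi), c(n, l, d))
      z <- array(stats::rnorm(n * l * d), c(n, l, d))
      spike <- config$eps_spike
      sdm <- array(rep(alpha, each = n), c(n, l, d)) *
        ifelse(lam == 1L, config$c, spike)
      xi <- z * sdm
      extra <- list(lambda = lam)
    } else if (config$family == "reg_horseshoe") {
      tau <- abs(stats::rcauchy(n, 0, config$tau0))
      c2 <- 1 / stats::rgamma(n, shape = config$nu / 2,
                              rate = config$nu * config$s^2 / 2)
      lam <- array(abs(stats::rcauchy(n * l * d)), c(n, l, d))
      lt <- sqrt(c2) * lam / sqrt(c2 + tau^2 * lam^2) # recycles over n
      z <- array(stats::rnorm(n * l * d), c(n, l, d))
      xi <- z * lt * tau * array(rep(alpha, each = n), c(n, l, d))
      extra <- list(lambda = lam, tau = tau, c2 = c2)
    } else if (config$family == "laplace") {
      b <- config$b * array(rep(alpha, each = n), c(n, l, d))
      u <- array(stats::runif(n * l * d, -0.5, 0.5), c(n, l, d))
      xi <- config$mu - b * sign(u) * log1p(-2 * abs(u))
    } else {
      xi <- array(stats::rnorm(n * l * d), c(n, l, d)) *
        array(rep(alpha, each = n), c(n, l, d))
    }
    c(list(xi = xi), extra)
  }
  structure(list(config = config, library = library, alpha = alpha,
                 latents = latents, draw = draw),
            class = "uq_prior_model")
}
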