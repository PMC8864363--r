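# MCMC engines.
#
# Continuous latents move by the No-U-Turn Sampler (multinomial NUTS with a
# generalized U-turn criterion) over a diagonal mass matrix, with
# dual-averaging step-size adaptation during warmup. Discrete inclusion
# indicators (spike-and-slab) move by single-site Metropolized Gibbs sweeps
# alternated with the NUTS transitions ("compound" stepping). A target
# object supplies:
#   $n_cont            number of unconstrained continuous parameters
#   $init()            initial continuous vector
#   $logp_grad(q,disc) list(lp, grad, loglik) of the log posterior
#   $loglik(q,disc)    likelihood only (cheap path for indicator flips)
#   $disc_init()       initial 0/1 indicator vector, or NULL
#   $disc_logodds      log(pi/(1-pi)) prior odds per indicator
#   $extract(q,disc)   named list of natural-scale latents

#' Sampler settings
#'
#' @param chains number of chains (>= 2 for split-Rhat to be meaningful).
#' @param draws kept draws per chain.
#' @param tune warmup iterations per chain (adaptation only, discarded).
#' @param target_accept dual-averaging acceptance target; high values suit
#'   the strongly curved horseshoe geometry.
#' @param max_treedepth NUTS doubling cap: trajectories use at most
#'   `2^max_treedepth` leapfrog steps.
#' @param init_jitter sd of the Gaussian jitter applied to the continuous
#'   initialization of each chain.
#' @param flip_sweeps number of single-site Metropolized Gibbs sweeps over
#'   the inclusion indicators per iteration (spike-and-slab fits).
#' @param swap_moves number of pair-swap proposals per iteration
#'   (deactivate one active term, activate one inactive term,
#'   simultaneously): lets the sampler exchange strongly correlated
#'   candidate terms that single-site flips cannot swap.
#' @return a list of settings.
#' @export
sampler_control <- function(chains = 4, draws = 1000, tune = 1000,
                            target_accept = 0.95, max_treedepth = 8,
                            init_jitter = 0.05, flip_sweeps = 1,
                            swap_moves = 0) {
  stopifnot(chains >= 1, draws >= 1, tune >= 1, target_accept > 0,
            target_accept < 1, max_treedepth >= 1, flip_sweeps >= 1,
            swap_moves >= 0)
  list(chains = as.integer(chains), draws = as.integer(draws),
       tune = as.integer(tune), target_accept = target_accept,
       max_treedepth = as.integer(max_treedepth),
       init_jitter = init_jitter, flip_sweeps = as.integer(flip_sweeps),
       swap_moves = as.integer(swap_moves))
}

chain_seed <- function(seed, chain) {
  (as.integer(seed) %% 1000003L) * 2011L + 7919L * as.integer(chain)
}

# one leapfrog step; returns NULL on a non-finite state
leapfrog1 <- function(q, p, grad, eps, inv_mass, grad_fn) {
  p_half <- p + 0.5 * eps * grad
  q_new <- q + eps * inv_mass * p_half
  gr <- grad_fn(q_new)
  if (!is.finite(gr$lp) || any(!is.finite(gr$grad))) return(NULL)
  list(q = q_new, p = p_half + 0.5 * eps * gr$grad, gr = gr)
}

# multinomial NUTS transition (generalized U-turn criterion, biased
# progressive sampling toward the new subtree), diagonal mass matrix
nuts_transition <- function(q, cur, eps, inv_mass, grad_fn, max_depth,
                            delta_max = 1000) {
  kin <- function(p) 0.5 * sum(p^2 * inv_mass)
  p0 <- stats::rnorm(length(q), 0, sqrt(1 / inv_mass))
  h0 <- -cur$lp + kin(p0)

  uturn <- function(qm, pm, qp, pp) {
    dq <- qp - qm
    (sum(dq * (inv_mass * pm)) < 0) || (sum(dq * (inv_mass * pp)) < 0)
  }

  build <- function(q, p, gr, dir, depth) {
    if (depth == 0L) {
      st <- leapfrog1(q, p, gr$grad, dir * eps, inv_mass, grad_fn)
      if (is.null(st)) {
        return(list(ok = FALSE, div = 1L, sum_a = 0, n_a = 1L))
      }
      h <- -st$gr$lp + kin(st$p)
      dh <- h - h0
      if (!is.finite(dh) || dh > delta_max) {
        return(list(ok = FALSE, div = 1L,
                    sum_a = if (is.finite(dh)) exp(min(-dh, 0)) else 0,
                    n_a = 1L))
      }
      list(ok = TRUE, div = 0L,
           qm = st$q, pm = st$p, gm = st$gr,
           qp = st$q, pp = st$p, gp = st$gr,
           q_prop = st$q, g_prop = st$gr, logw = -dh,
           sum_a = exp(min(-dh, 0)), n_a = 1L)
    } else {
      t1 <- build(q, p, gr, dir, depth - 1L)
      if (!t1$ok) return(t1)
      t2 <- if (dir == 1L) {
        build(t1$qp, t1$pp, t1$gp, dir, depth - 1L)
      } else {
        build(t1$qm, t1$pm, t1$gm, dir, depth - 1L)
      }
      sum_a <- t1$sum_a + t2$sum_a
      n_a <- t1$n_a + t2$n_a
      if (!t2$ok) {
        return(list(ok = FALSE, div = t1$div + t2$div, sum_a = sum_a,
                    n_a = n_a))
      }
      if (dir == 1L) {
        qm <- t1$qm; pm <- t1$pm; gm <- t1$gm
        qp <- t2$qp; pp <- t2$pp; gp <- t2$gp
      } else {
        qm <- t2$qm; pm <- t2$pm; gm <- t2$gm
        qp <- t1$qp; pp <- t1$pp; gp <- t1$gp
      }
      logw <- max(t1$logw, t2$logw) +
        log(exp(t1$logw - max(t1$logw, t2$logw)) +
              exp(t2$logw - max(t1$logw, t2$logw)))
      pick2 <- log(stats::runif(1)) < t2$logw - logw
      prop <- if (pick2) list(q = t2$q_prop, g = t2$g_prop) else
        list(q = t1$q_prop, g = t1$g_prop)
      list(ok = !uturn(qm, pm, qp, pp), div = t1$div + t2$div,
           qm = qm, pm = pm, gm = gm, qp = qp, pp = pp, gp = gp,
           q_prop = prop$q, g_prop = prop$g, logw = logw,
           sum_a = sum_a, n_a = n_a)
    }
  }

  state <- list(qm = q, pm = p0, gm = cur, qp = q, pp = p0, gp = cur,
                q_prop = q, g_prop = cur, logw = 0)
  sum_a <- 0; n_a <- 0L; n_div <- 0L
  depth <- 0L
  while (depth < max_depth) {
    dir <- if (stats::runif(1) < 0.5) -1L else 1L
    sub <- if (dir == 1L) {
      build(state$qp, state$pp, state$gp, dir, depth)
    } else {
      build(state$qm, state$pm, state$gm, dir, depth)
    }
    sum_a <- sum_a + sub$sum_a; n_a <- n_a + sub$n_a
    n_div <- n_div + sub$div
    if (!sub$ok) break
    # biased progressive sampling toward the new half of the trajectory
    if (log(stats::runif(1)) < sub$logw - state$logw) {
      state$q_prop <- sub$q_prop
      state$g_prop <- sub$g_prop
    }
    state$logw <- max(state$logw, sub$logw) +
      log(exp(state$logw - max(state$logw, sub$logw)) +
            exp(sub$logw - max(state$logw, sub$logw)))
    if (dir == 1L) {
      state$qp <- sub$qp; state$pp <- sub$pp; state$gp <- sub$gp
    } else {
      state$qm <- sub$qm; state$pm <- sub$pm; state$gm <- sub$gm
    }
    if (uturn(state$qm, state$pm, state$qp, state$pp)) break
    depth <- depth + 1L
  }
  list(q = state$q_prop, gr = state$g_prop,
       alpha = if (n_a > 0) sum_a / n_a else 0, divergent = n_div > 0L)
}

run_chain <- function(target, control, chain, seed) {
  set.seed(chain_seed(seed, chain))
  n_tune <- control$tune; n_draws <- control$draws
  nq <- target$n_cont
  q <- target$init() + stats::rnorm(nq, 0, control$init_jitter)
  disc <- target$disc_init()
  has_disc <- !is.null(disc)

  cur <- target$logp_grad(q, disc)
  if (!is.finite(cur$lp)) {
    # retry a few jitters before giving up
    for (k in 1:20) {
      q <- target$init() + stats::rnorm(nq, 0, control$init_jitter)
      cur <- target$logp_grad(q, disc)
      if (is.finite(cur$lp)) break
    }
    if (!is.finite(cur$lp)) {
      stop("non-finite log density at initialization", call. = FALSE)
    }
  }

  mass <- rep(1, nq); inv_mass <- 1 / mass
  # shrink the initial step until a single leapfrog step is acceptable,
  # so early warmup cannot jump out of the initialization basin
  eps <- 0.1
  for (k in 1:15) {
    p0 <- stats::rnorm(nq, 0, sqrt(mass))
    st <- leapfrog1(q, p0, cur$grad, eps, inv_mass,
                    function(qq) target$logp_grad(qq, disc))
    if (!is.null(st)) {
      dh <- (-cur$lp + 0.5 * sum(p0^2 * inv_mass)) -
        (-st$gr$lp + 0.5 * sum(st$p^2 * inv_mass))
      if (is.finite(dh) && dh > log(0.5)) break
    }
    eps <- eps / 2
  }
  # dual averaging state
  da_mu <- log(10 * eps); da_h <- 0; da_logeps_bar <- log(eps); da_t <- 0
  da_gamma <- 0.05; da_t0 <- 10; da_kappa <- 0.75
  mass_pts <- sort(unique(pmax(2L, floor(n_tune * c(0.4, 0.75)))))
  window_draws <- matrix(NA_real_, n_tune, nq)
  window_n <- 0L

  total <- n_tune + n_draws
  keep_q <- matrix(NA_real_, n_draws, nq)
  keep_disc <- if (has_disc) matrix(NA_integer_, n_draws, length(disc))
  keep_lp <- numeric(n_draws)
  n_div <- 0L; acc_sum <- 0; acc_n <- 0
  flip_acc <- 0L; flip_n <- 0L

  for (it in seq_len(total)) {
    tuning <- it <= n_tune

    if (has_disc && length(disc)) {
      cur_ll <- cur$loglik
      changed <- FALSE
      # Metropolized Gibbs sweep(s) over inclusion indicators, random order
      for (sw in seq_len(control$flip_sweeps)) {
        for (s in sample.int(length(disc))) {
          prop <- disc; prop[s] <- 1L - disc[s]
          new_ll <- target$loglik(q, prop)
          dlp <- new_ll - cur_ll +
            (if (prop[s] == 1L) target$disc_logodds else
               -target$disc_logodds)
          flip_n <- flip_n + 1L
          if (is.finite(dlp) && log(stats::runif(1)) < dlp) {
            disc <- prop; cur_ll <- new_ll; flip_acc <- flip_acc + 1L
            changed <- TRUE
          }
        }
      }
      # pair swaps: exchange one active and one inactive term (symmetric
      # proposal, Bernoulli prior mass unchanged)
      if (control$swap_moves > 0L && length(disc) >= 2L) {
        for (k in seq_len(control$swap_moves)) {
          act <- which(disc == 1L); inact <- which(disc == 0L)
          if (!length(act) || !length(inact)) break
          s1 <- act[sample.int(length(act), 1L)]
          s0 <- inact[sample.int(length(inact), 1L)]
          prop <- disc; prop[s1] <- 0L; prop[s0] <- 1L
          new_ll <- target$loglik(q, prop)
          flip_n <- flip_n + 1L
          if (is.finite(new_ll) &&
              log(stats::runif(1)) < new_ll - cur_ll) {
            disc <- prop; cur_ll <- new_ll; flip_acc <- flip_acc + 1L
            changed <- TRUE
          }
        }
      }
      if (changed) cur <- target$logp_grad(q, disc)
    }

    # NUTS transition over the continuous latents
    grad_fn <- function(qq) target$logp_grad(qq, disc)
    tr <- nuts_transition(q, cur, eps, inv_mass, grad_fn,
                          control$max_treedepth)
    q <- tr$q; cur <- tr$gr
    alpha <- tr$alpha
    if (tr$divergent && !tuning) n_div <- n_div + 1L
    acc_sum <- acc_sum + alpha; acc_n <- acc_n + 1

    if (tuning) {
      # dual averaging toward target acceptance
      da_t <- da_t + 1
      da_h <- (1 - 1 / (da_t + da_t0)) * da_h +
        (control$target_accept - alpha) / (da_t + da_t0)
      logeps <- da_mu - sqrt(da_t) / da_gamma * da_h
      w <- da_t^(-da_kappa)
      da_logeps_bar <- w * logeps + (1 - w) * da_logeps_bar
      eps <- exp(logeps)
      window_n <- window_n + 1L
      window_draws[window_n, ] <- q
      if (it %in% mass_pts && window_n >= 10) {
        v <- apply(window_draws[seq_len(window_n), , drop = FALSE], 2,
                   stats::var)
        mass2 <- 1 / pmax(0.8 * v + 0.2 * mean(v) + 1e-10, 1e-8)
        mass <- mass2; inv_mass <- 1 / mass
        window_n <- 0L
        eps <- exp(da_logeps_bar)
        da_mu <- log(10 * eps); da_h <- 0; da_t <- 0
        da_logeps_bar <- log(eps)
      }
      if (it == n_tune) eps <- exp(da_logeps_bar)
    } else {
      k <- it - n_tune
      keep_q[k, ] <- q
      if (has_disc) keep_disc[k, ] <- disc
      keep_lp[k] <- cur$lp
    }
  }

  list(q = keep_q, disc = keep_disc, lp = keep_lp,
       divergences = n_div, accept_rate = acc_sum / acc_n,
       flip_accept_rate = if (flip_n > 0) flip_acc / flip_n else NA_real_,
       step_size = eps)
}

run_sampler <- function(target, control, seed) {
  chains <- lapply(seq_len(control$chains), function(ch) {
    run_chain(target, control, ch, seed)
  })
  chains
}

#' Split-chain potential scale reduction factor
#'
#' Computes split-\eqn{\hat R} for a chains-by-draws matrix: each chain is
#' halved, and the usual between/within variance ratio is formed over the
#' resulting half-chains. Values near 1 indicate mixing.
#'
#' @param x a `chains x draws` numeric matrix (or vector for one chain).
#' @return scalar \eqn{\hat R} (NA for constant input).
#' @export
split_rhat <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  half <- floor(ncol(x) / 2)
  if (half < 2) return(NA_real_)
  parts <- rbind(x[, seq_len(half), drop = FALSE],
                 x[, half + seq_len(half), drop = FALSE])
  if (stats::sd(parts) == 0) return(NA_real_)
  m <- nrow(parts); n <- ncol(parts)
  means <- rowMeans(parts)
  w <- mean(apply(parts, 1, stats::var))
  b <- n * stats::var(means)
  if (w <= 0) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Effective sample size
#'
#' Autocorrelation-based effective sample size pooled across chains, using
#' Geyer's initial positive sequence truncation on the chain-averaged
#' autocorrelations.
#'
#' @inheritParams split_rhat
#' @return estimated number of independent draws.
#' @export
ess_basic <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  m <- nrow(x); n <- ncol(x)
  if (n < 4) return(NA_real_)
  if (stats::sd(x) == 0) return(NA_real_)
  acs <- vapply(seq_len(m), function(i) {
    if (stats::sd(x[i, ]) == 0) return(c(1, rep(0, 200)))
    a <- stats::acf(x[i, ], lag.max = min(n - 1, 200), plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
    a[!is.finite(a)] <- 0
    if (length(a) < 2) c(1, rep(0, 200)) else
      c(a, rep(0, 201 - length(a)))
  }, numeric(201))
  rho <- rowMeans(acs)
  # initial positive-pair truncation
  s <- 0; k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k + 1] + (if (k + 2 <= length(rho)) rho[k + 2] else 0)
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  ess <- m * n / (1 + 2 * s)
  min(ess, m * n)
}
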