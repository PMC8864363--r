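# Post-inference quantities: inclusion (pseudo-)probabilities, posterior
# modes, and posterior-predictive reconstruction/forecast summaries.

#' Marginal posterior mode of a sample vector
#'
#' Argmax of a Gaussian-kernel density estimate evaluated on a 512-point
#' grid over the draw range. Point masses (e.g. exact zeros under the Dirac
#' spike) dominate the smoothed density, so a term excluded in most draws
#' has mode 0. Degenerate all-equal draws return that value.
#'
#' @param draws numeric vector of at least 100 posterior draws.
#' @return the estimated mode.
#' @export
posterior_mode <- function(draws) {
  draws <- as.numeric(draws)
  if (length(draws) < 100) {
    stop("need at least 100 draws for a stable mode estimate", call. = FALSE)
  }
  if (stats::sd(draws) == 0) return(draws[1])
  dens <- stats::density(draws, n = 512)
  dens$x[which.max(dens$y)]
}

#' Spike-and-slab inclusion probabilities
#'
#' The posterior mean of each term's Bernoulli inclusion indicator,
#' estimated across all chains and draws.
#'
#' @param samples a `uq_samples` from a spike-and-slab fit.
#' @return data frame (class `inclusion_report`) with one row per
#'   (equation, term): `probability` and `method = "spike_slab"`.
#' @export
inclusion_probabilities <- function(samples) {
  stopifnot(inherits(samples, "uq_samples"))
  if (samples$family != "spike_slab") {
    stop("inclusion probabilities are defined for spike-and-slab fits; ",
         "use `shrinkage_factors()` for regularized-horseshoe fits",
         call. = FALSE)
  }
  l <- length(samples$term_labels); d <- length(samples$state_names)
  out <- expand.grid(term = samples$term_labels,
                     equation = samples$state_names,
                     stringsAsFactors = FALSE)[, c(2, 1)]
  out$probability <- as.vector(vapply(seq_len(d), function(j) {
    vapply(seq_len(l), function(i) mean(samples$draws$lambda[, , i, j]),
           numeric(1))
  }, numeric(l)))
  out$method <- "spike_slab"
  class(out) <- c("inclusion_report", "data.frame")
  out
}

#' Shrinkage-factor pseudo-probabilities
#'
#' For the regularized horseshoe there is no explicit inclusion indicator;
#' instead each coefficient's posterior mode under the horseshoe fit is
#' divided by its mode under a non-sparsifying reference fit (normal prior)
#' of the identical model and data:
#' \eqn{\kappa_i = \hat\xi_i^{RH} / \hat\xi_i^{ref}}. Relevant terms escape
#' shrinkage (\eqn{\kappa} near or above 1); irrelevant terms are shrunk
#' (\eqn{\kappa \ll 1}). The ratios need not lie in `[0, 1]`.
#'
#' @param samples_rh `uq_samples` from a `reg_horseshoe` fit.
#' @param samples_ref `uq_samples` from a `normal_reference` fit of the same
#'   model/data.
#' @param zero_tol reference modes with `|mode| < zero_tol` yield an
#'   undefined-kappa flag for that term (reported, not dropped): the ratio
#'   of two near-zero modes carries no shrinkage information. Default: 5%
#'   of the largest reference-mode magnitude across terms.
#' @return data frame (class `inclusion_report`) with per-(equation, term)
#'   `kappa`, the two modes, and an `undefined` flag.
#' @export
shrinkage_factors <- function(samples_rh, samples_ref, zero_tol = NULL) {
  stopifnot(inherits(samples_rh, "uq_samples"),
            inherits(samples_ref, "uq_samples"))
  if (samples_rh$family != "reg_horseshoe") {
    stop("`samples_rh` must come from a reg_horseshoe fit", call. = FALSE)
  }
  if (samples_ref$family != "normal_reference") {
    stop("`samples_ref` must come from a normal_reference fit",
         call. = FALSE)
  }
  if (!identical(samples_rh$term_labels, samples_ref$term_labels)) {
    stop("the two fits use different libraries", call. = FALSE)
  }
  l <- length(samples_rh$term_labels); d <- length(samples_rh$state_names)
  modes_rh <- modes_ref <- matrix(NA_real_, l, d)
  for (j in seq_len(d)) {
    for (i in seq_len(l)) {
      modes_rh[i, j] <- posterior_mode(as.vector(samples_rh$draws$Xi[, , i, j]))
      modes_ref[i, j] <- posterior_mode(as.vector(samples_ref$draws$Xi[, , i, j]))
    }
  }
  if (is.null(zero_tol)) zero_tol <- 0.05 * max(abs(modes_ref))
  rows <- list()
  for (j in seq_len(d)) {
    for (i in seq_len(l)) {
      m_rh <- modes_rh[i, j]
      m_ref <- modes_ref[i, j]
      undef <- abs(m_ref) < zero_tol
      rows[[length(rows) + 1L]] <- data.frame(
        equation = samples_rh$state_names[j],
        term = samples_rh$term_labels[i],
        kappa = if (undef) NA_real_ else m_rh / m_ref,
        mode_rh = m_rh, mode_ref = m_ref, undefined = undef,
        method = "reg_horseshoe")
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("inclusion_report", "data.frame")
  out
}

#' Posterior-predictive distribution of trajectories
#'
#' For a subset of posterior draws, integrates the drawn SINDy model over
#' the requested times (which may extend beyond the training window:
#' forecasting) and, optionally, adds observation noise from the drawn
#' noise scales under the fit's likelihood family. Pointwise means and
#' central credibility bounds summarize the resulting ensemble. Draws whose
#' trajectories diverge are excluded and counted, never silently dropped.
#'
#' @param samples a `uq_samples` from [fit_ode()].
#' @param times output times (start at or after the training origin).
#' @param level credibility level of the central interval (default 0.9).
#' @param with_noise if `TRUE`, intervals describe new noisy observations;
#'   if `FALSE`, the latent reconstructed states.
#' @param n_draws number of posterior draws to propagate.
#' @param seed seed for draw subsampling and noise simulation.
#' @return object of class `uq_ppd`: list with `times`, per-dimension
#'   `mean`, `lo`, `hi` matrices, `level`, `with_noise`, `n_used`,
#'   `n_excluded`.
#' @export
posterior_predictive <- function(samples, times, level = 0.9,
                                 with_noise = TRUE, n_draws = 200,
                                 seed = 1) {
  stopifnot(inherits(samples, "uq_samples"))
  if (samples$kind != "ode") {
    stop("posterior_predictive requires an ODE fit", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("`level` must be in (0,1)",
                                     call. = FALSE)
  meta <- samples$meta
  lib <- meta$library
  times <- as.numeric(times)
  n_total <- samples$chains * samples$n_draws
  if (n_draws > n_total) {
    stop("`n_draws` exceeds the available posterior draws", call. = FALSE)
  }
  set.seed(seed)
  pick <- if (n_draws == n_total) seq_len(n_total) else
    sort(sample.int(n_total, n_draws))
  ch <- (pick - 1L) %/% samples$n_draws + 1L
  dr <- (pick - 1L) %% samples$n_draws + 1L
  nt <- length(times); d <- lib$d
  paths <- array(NA_real_, c(n_draws, nt, d))
  excluded <- 0L
  for (k in seq_len(n_draws)) {
    Xi <- matrix(samples$draws$Xi[ch[k], dr[k], , ], lib$l, d)
    x0 <- samples$draws$x0[ch[k], dr[k], ]
    out <- cpp_simulate(lib$exponents, Xi, x0, times, meta$t0,
                        meta$eps_stab, meta$stab_degree, meta$h, meta$guard)
    if (out$diverged) { excluded <- excluded + 1L; next }
    st <- out$states
    if (with_noise) {
      sig <- samples$draws$sigma[ch[k], dr[k], ]
      eps <- matrix(stats::rnorm(nt * d), nt, d)
      st <- if (meta$noise$family == "lognormal") {
        st * exp(sweep(eps, 2L, sig, "*"))
      } else {
        st + sweep(eps, 2L, sig, "*")
      }
    }
    paths[k, , ] <- st
  }
  ok <- which(!is.na(paths[, 1, 1]))
  if (!length(ok)) stop("all posterior draws diverged", call. = FALSE)
  a <- (1 - level) / 2
  qs <- apply(paths[ok, , , drop = FALSE], c(2, 3), stats::quantile,
              probs = c(a, 1 - a), na.rm = TRUE)
  mean_m <- apply(paths[ok, , , drop = FALSE], c(2, 3), mean)
  colnames(mean_m) <- lib$state_names
  structure(list(times = times, mean = mean_m,
                 lo = matrix(qs[1, , ], nt, d,
                             dimnames = list(NULL, lib$state_names)),
                 hi = matrix(qs[2, , ], nt, d,
                             dimnames = list(NULL, lib$state_names)),
                 level = level, with_noise = with_noise,
                 n_used = length(ok), n_excluded = excluded),
            class = "uq_ppd")
}

#' @export
print.uq_ppd <- function(x, ...) {
  cat(sprintf(
    "PPD summary: %d times, %.0f%% central interval, %s noise, %d draws",
    length(x$times), 100 * x$level,
    if (x$with_noise) "with" else "without", x$n_used))
  if (x$n_excluded > 0) cat(sprintf(" (%d divergent excluded)",
                                    x$n_excluded))
  cat("\n")
  invisible(x)
}

#' Fraction of test points covered by a PPD band
#'
#' @param ppd a `uq_ppd` evaluated at the test times.
#' @param test a `uq_ts` of held-out observations.
#' @return scalar coverage fraction over all (time, dimension) points.
#' @export
ppd_coverage <- function(ppd, test) {
  stopifnot(inherits(ppd, "uq_ppd"), inherits(test, "uq_ts"))
  idx <- match(round(test$times, 10), round(ppd$times, 10))
  if (anyNA(idx)) stop("PPD was not evaluated at the test times",
                       call. = FALSE)
  inside <- test$states >= ppd$lo[idx, , drop = FALSE] &
    test$states <= ppd$hi[idx, , drop = FALSE]
  mean(inside)
}

#' Tabulate a PPD as a plain data frame
#'
#' @param x a `uq_ppd`.
#' @param ... unused.
#' @return data frame with `t` and, per dimension, `mean`, `lo`, `hi`
#'   columns.
#' @export
as.data.frame.uq_ppd <- function(x, ...) {
  out <- data.frame(t = x$times)
  for (nm in colnames(x$mean)) {
    out[[paste0(nm, "_mean")]] <- x$mean[, nm]
    out[[paste0(nm, "_lo")]] <- x$lo[, nm]
    out[[paste0(nm, "_hi")]] <- x$hi[, nm]
  }
  out
}

#' Coefficient report table
#'
#' Mirrors the reference tables' layout: rows are library terms, and per
#' state equation a posterior-mode column and an inclusion
#' (pseudo-)probability column. A term is labelled identified when its
#' probability (or kappa) is at least `threshold`.
#'
#' @param samples a `uq_samples` (spike-and-slab or regularized horseshoe).
#' @param samples_ref for horseshoe fits, the matching `normal_reference`
#'   fit used for shrinkage factors.
#' @param threshold identification threshold on the (pseudo-)probability.
#' @return data frame with one row per term and per-equation mode /
#'   probability / identified columns.
#' @export
coefficient_report <- function(samples, samples_ref = NULL,
                               threshold = 0.5) {
  sm <- summary(samples)
  incl <- if (samples$family == "spike_slab") {
    inclusion_probabilities(samples)
  } else if (samples$family == "reg_horseshoe") {
    if (is.null(samples_ref)) {
      stop("horseshoe reports need `samples_ref`", call. = FALSE)
    }
    sf <- shrinkage_factors(samples, samples_ref)
    data.frame(equation = sf$equation, term = sf$term,
               probability = sf$kappa)
  } else {
    data.frame(equation = sm$equation, term = sm$term,
               probability = NA_real_)
  }
  out <- data.frame(term = samples$term_labels)
  for (eq in samples$state_names) {
    mo <- sm$mode[sm$equation == eq]
    pr <- incl$probability[incl$equation == eq]
    out[[paste0(eq, "_mode")]] <- mo
    out[[paste0(eq, "_prob")]] <- pr
    out[[paste0(eq, "_identified")]] <- !is.na(pr) & pr >= threshold
  }
  out
}
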