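# Pipeline orchestration: resolved run configurations, artifact
# directories, and the generate/discover/forecast/compare entry points that
# the command-line wrapper (inst/cli/uqsindy.R) exposes.

#' Assemble and validate a run configuration
#'
#' @param preset one of `"lotka_volterra"`, `"oscillator"`,
#'   `"regression_toy"`, or `NULL` when `input` is given.
#' @param input path to a time-series CSV (`t,<names...>`) when not using a
#'   preset.
#' @param degree polynomial library degree (default: 2, or 3 for the
#'   oscillator preset).
#' @param prior one or more prior families to fit
#'   (`"spike_slab"`, `"reg_horseshoe"`, `"laplace"`,
#'   `"normal_reference"`).
#' @param likelihood `"gaussian"` or `"lognormal"`; default chosen by
#'   preset (lognormal for the positive predator-prey data, gaussian
#'   otherwise).
#' @param normalize divide each series by its sample sd before inference;
#'   default `TRUE` for the predator-prey preset, `FALSE` otherwise.
#' @param alpha named numeric vector of per-term prior-scale overrides,
#'   names of the form `"equation:term"` (e.g. `c("u:u3" = 0.1)`); unnamed
#'   scalar applies everywhere.
#' @param pi,c,tau0,nu,s,b prior hyperparameters (see [prior_config()]).
#' @param sampler a [sampler_control()].
#' @param eps_stab stabilization coefficient override.
#' @param seed root seed; every random quantity in the run derives from it.
#' @param out_dir artifact directory.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(preset = NULL, input = NULL, degree = NULL,
                       prior = "reg_horseshoe", likelihood = NULL,
                       normalize = NULL, alpha = 1, pi = 0.5, c = 1,
                       tau0 = 0.1, nu = 4, s = 2, b = 1,
                       sampler = sampler_control(), eps_stab = NULL,
                       seed = 1, out_dir = tempfile("uqsindy_run_")) {
  problems <- character(0)
  presets <- c("lotka_volterra", "oscillator", "regression_toy")
  if (is.null(preset) && is.null(input)) {
    problems <- c(problems, "one of `preset` or `input` is required")
  }
  if (!is.null(preset) && !preset %in% presets) {
    problems <- c(problems, sprintf("unknown preset '%s' (known: %s)",
                                    preset, paste(presets, collapse = ", ")))
  }
  fams <- c("spike_slab", "reg_horseshoe", "laplace", "normal_reference")
  bad <- setdiff(prior, fams)
  if (length(bad)) {
    problems <- c(problems, sprintf("unknown prior family '%s' (known: %s)",
                                    paste(bad, collapse = ", "),
                                    paste(fams, collapse = ", ")))
  }
  if (!is.null(likelihood) && !likelihood %in% c("gaussian", "lognormal")) {
    problems <- c(problems, "likelihood must be 'gaussian' or 'lognormal'")
  }
  if (length(problems)) {
    stop(paste(c("invalid run configuration:", problems),
               collapse = "\n  - "), call. = FALSE)
  }
  if (is.null(degree)) {
    degree <- if (identical(preset, "oscillator")) 3L else 2L
  }
  if (is.null(likelihood)) {
    likelihood <- if (identical(preset, "lotka_volterra")) "lognormal"
      else "gaussian"
  }
  if (is.null(normalize)) normalize <- identical(preset, "lotka_volterra")
  structure(list(preset = preset, input = input, degree = degree,
                 prior = prior, likelihood = likelihood,
                 normalize = normalize, alpha = alpha, pi = pi, c = c,
                 tau0 = tau0, nu = nu, s = s, b = b, sampler = sampler,
                 eps_stab = eps_stab, seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Flags present in `overrides` take precedence over file values; unknown
#' keys are rejected.
#'
#' @param path YAML file.
#' @param overrides named list of values overriding the file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the `yaml` package is required to read YAML configs",
         call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  vals[names(overrides)] <- overrides
  if (!is.null(vals$sampler)) vals$sampler <- do.call(sampler_control,
                                                      vals$sampler)
  if (!is.null(vals$alpha)) vals$alpha <- unlist(vals$alpha)
  do.call(run_config, vals)
}

resolve_alpha <- function(alpha_spec, lib) {
  A <- matrix(1, lib$l, lib$d,
              dimnames = list(lib$labels, lib$state_names))
  if (is.null(names(alpha_spec))) {
    A[] <- alpha_spec
    return(A)
  }
  for (nm in names(alpha_spec)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[1] %in% lib$state_names ||
        !parts[2] %in% lib$labels) {
      stop(sprintf("alpha override '%s' is not 'equation:term'", nm),
           call. = FALSE)
    }
    A[parts[2], parts[1]] <- alpha_spec[[nm]]
  }
  A
}

resolve_data <- function(config) {
  if (!is.null(config$preset) && config$preset == "regression_toy") {
    gen <- generate_regression_toy(config$seed)
    return(list(kind = "regression", problem = gen$problem,
                truth = gen$beta))
  }
  if (!is.null(config$preset)) {
    gen <- switch(config$preset,
      lotka_volterra = generate_lotka_volterra(config$seed, test = TRUE),
      oscillator = generate_oscillator(config$seed, test = TRUE))
    pri <- default_priors(config$preset)
    return(list(kind = "ode", train = gen$train, test = gen$test,
                truth = gen$Xi, sigma_prior = pri$sigma_prior,
                x0_prior = pri$x0_prior))
  }
  list(kind = "ode", train = read_time_series(config$input), test = NULL,
       truth = NULL,
       sigma_prior = dist_spec("halfnormal", sd = 1),
       x0_prior = dist_spec("normal", mean = 0, sd = 10))
}

config_prior <- function(config, family, lib) {
  prior_config(family, alpha = resolve_alpha(config$alpha, lib),
               pi = config$pi, c = config$c, tau0 = config$tau0,
               nu = config$nu, s = config$s, b = config$b)
}

#' Run the full discovery pipeline
#'
#' Resolves the configuration, generates or loads the data, fits the
#' requested prior families, and writes a self-contained artifact
#' directory: the resolved configuration echo, the data snapshot, posterior
#' stores, coefficient/inclusion tables, posterior-predictive
#' reconstruction curves, convergence diagnostics, and a run log.
#' Rerunning with an identical configuration and seed reproduces all
#' tables.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the fits and the artifact directory.
#' @export
run_discover <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("uqsindy run, seed %d", config$seed),
                 sprintf("R %s", getRversion()))
  cfg_echo <- config
  cfg_echo$sampler <- unclass(config$sampler)
  jsonlite::write_json(unclass(cfg_echo),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  res <- resolve_data(config)
  fits <- list()

  if (res$kind == "regression") {
    utils::write.csv(data.frame(y = res$problem$y, res$problem$X),
                     file.path(config$out_dir, "data.csv"),
                     row.names = FALSE)
    for (fam in config$prior) {
      prior <- prior_config(fam, pi = config$pi, c = config$c,
                            tau0 = config$tau0, nu = config$nu,
                            s = config$s, b = config$b)
      fit <- fit_regression(res$problem, prior, config$sampler, config$seed)
      utils::write.csv(summary(fit),
                       file.path(config$out_dir,
                                 paste0("coefficients_", fam, ".csv")),
                       row.names = FALSE)
      utils::write.csv(fit$diagnostics,
                       file.path(config$out_dir,
                                 paste0("diagnostics_", fam, ".csv")),
                       row.names = FALSE)
      fits[[fam]] <- fit
      log_lines <- c(log_lines, sprintf("fit %s: %d x %d draws", fam,
                                        fit$chains, fit$n_draws))
    }
  } else {
    data <- res$train
    stds <- NULL
    if (config$normalize) {
      nrm <- normalize_ts(data)
      data <- nrm$data; stds <- nrm$stds
      log_lines <- c(log_lines, sprintf("normalized by stds: %s",
                                        paste(signif(stds, 6),
                                              collapse = ", ")))
    }
    write_time_series(data, file.path(config$out_dir, "data.csv"))
    lib <- build_polynomial_library(data$names, config$degree)
    noise <- noise_model(config$likelihood, res$sigma_prior)
    for (fam in config$prior) {
      prior <- config_prior(config, fam, lib)
      prior$x0_prior <- res$x0_prior
      fit <- fit_ode(data, lib, prior, noise, config$sampler, config$seed,
                     eps_stab = config$eps_stab)
      write_samples(fit, file.path(config$out_dir, paste0("samples_", fam)))
      ref <- NULL
      if (fam == "reg_horseshoe") {
        refprior <- config_prior(config, "normal_reference", lib)
        refprior$x0_prior <- res$x0_prior
        ref <- fit_ode(data, lib, refprior, noise, config$sampler,
                       config$seed + 1L, eps_stab = config$eps_stab)
        fits[[paste0(fam, "_reference")]] <- ref
      }
      tab <- if (fam %in% c("spike_slab", "reg_horseshoe")) {
        coefficient_report(fit, ref)
      } else summary(fit)
      utils::write.csv(tab,
                       file.path(config$out_dir,
                                 paste0("coefficients_", fam, ".csv")),
                       row.names = FALSE)
      utils::write.csv(fit$diagnostics,
                       file.path(config$out_dir,
                                 paste0("diagnostics_", fam, ".csv")),
                       row.names = FALSE)
      ppd <- posterior_predictive(fit, data$times, with_noise = FALSE,
                                  n_draws = min(200, fit$chains *
                                                  fit$n_draws),
                                  seed = config$seed)
      utils::write.csv(as.data.frame(ppd),
                       file.path(config$out_dir, paste0("ppd_", fam,
                                                        ".csv")),
                       row.names = FALSE)
      fits[[fam]] <- fit
      log_lines <- c(log_lines,
                     sprintf("fit %s: %d x %d draws, divergences %s", fam,
                             fit$chains, fit$n_draws,
                             paste(fit$divergences, collapse = "/")))
    }
    if (!is.null(stds)) {
      utils::write.csv(data.frame(state = data$names, std = stds),
                       file.path(config$out_dir, "normalization.csv"),
                       row.names = FALSE)
    }
  }
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(fits = fits, config = config, data = res,
                 out_dir = config$out_dir))
}

#' Forecast from a completed discovery run
#'
#' Extends the posterior-predictive distribution of a trained fit beyond
#' the training window and, when held-out observations are supplied,
#' reports the fraction falling inside the credibility band.
#'
#' @param run the list returned by [run_discover()].
#' @param horizon forecast length past the end of training (must be
#'   positive; 0 is a valid no-op returning NULL).
#' @param family which fitted prior family to forecast with (default: the
#'   first fitted).
#' @param test optional `uq_ts` of held-out noisy observations inside the
#'   forecast window.
#' @param level credibility level.
#' @param n_draws posterior draws to propagate.
#' @return list with the `uq_ppd` over `[t0, t_end + horizon]` and, when
#'   `test` is given, the `coverage` fraction; the forecast curves are also
#'   written to the run's artifact directory.
#' @export
run_forecast <- function(run, horizon, family = NULL, test = NULL,
                         level = 0.9, n_draws = 200) {
  if (horizon < 0) stop("`horizon` must be non-negative", call. = FALSE)
  if (horizon == 0) return(invisible(NULL))
  fams <- setdiff(names(run$fits), grep("_reference$", names(run$fits),
                                        value = TRUE))
  if (is.null(family)) family <- fams[1]
  fit <- run$fits[[family]]
  if (is.null(fit)) stop("no fit for family ", family, call. = FALSE)
  tr_times <- fit$meta$data$times
  t_end <- max(tr_times)
  dt <- mean(diff(tr_times))
  extra <- seq(t_end + dt, t_end + horizon, by = dt)
  times <- c(tr_times, extra)
  if (!is.null(test)) {
    times <- sort(unique(c(times, test$times)))
  }
  ppd <- posterior_predictive(fit, times, level = level, with_noise = TRUE,
                              n_draws = min(n_draws,
                                            fit$chains * fit$n_draws),
                              seed = fit$seed)
  out <- list(ppd = ppd)
  if (!is.null(test)) out$coverage <- ppd_coverage(ppd, test)
  utils::write.csv(as.data.frame(ppd),
                   file.path(run$out_dir,
                             paste0("forecast_", family, ".csv")),
                   row.names = FALSE)
  invisible(out)
}

#' Compare Bayesian discovery with the STLSQ baseline
#'
#' Runs the point-estimate SINDy baseline on the same (possibly normalized)
#' data used by a discovery run and writes a side-by-side coefficient
#' table tagged by method.
#'
#' @param run the list returned by [run_discover()] (an ODE run).
#' @param stlsq_cfg an [stlsq_control()].
#' @return invisibly, the combined table (also written to the artifact
#'   directory as `compare_stlsq.csv`).
#' @export
run_compare <- function(run, stlsq_cfg = stlsq_control()) {
  if (run$data$kind != "ode") {
    stop("comparison requires an ODE run", call. = FALSE)
  }
  fams <- setdiff(names(run$fits), grep("_reference$", names(run$fits),
                                        value = TRUE))
  fit1 <- run$fits[[fams[1]]]
  data <- fit1$meta$data
  lib <- fit1$meta$library
  base <- sindy_fit(data, lib, stlsq_cfg)
  rows <- data.frame(method = "STLSQ",
                     equation = rep(lib$state_names, each = lib$l),
                     term = rep(lib$labels, lib$d),
                     value = as.vector(base$coefficients))
  for (fam in fams) {
    sm <- summary(run$fits[[fam]])
    rows <- rbind(rows, data.frame(method = fam, equation = sm$equation,
                                   term = sm$term, value = sm$mode))
  }
  utils::write.csv(rows, file.path(run$out_dir, "compare_stlsq.csv"),
                   row.names = FALSE)
  invisible(rows)
}

#' Write a synthetic preset to CSV files
#'
#' Generates a named preset and writes train/test CSVs plus a manifest
#' (seed, settings, file hashes) into a directory.
#'
#' @param preset `"lotka_volterra"`, `"oscillator"` or `"regression_toy"`.
#' @param seed integer seed.
#' @param out_dir target directory.
#' @return invisibly, the manifest list.
#' @export
generate_preset <- function(preset, seed, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (preset == "regression_toy") {
    gen <- generate_regression_toy(seed)
    f <- file.path(out_dir, "regression_toy.csv")
    utils::write.csv(data.frame(y = gen$problem$y, gen$problem$X), f,
                     row.names = FALSE)
    files <- f
    spec <- list(system = "linear_regression", n = gen$problem$n,
                 p = gen$problem$p, beta = gen$beta, sigma = gen$sigma,
                 seed = seed)
  } else {
    gen <- switch(preset,
      lotka_volterra = generate_lotka_volterra(seed, test = TRUE),
      oscillator = generate_oscillator(seed, test = TRUE),
      stop("unknown preset ", preset, call. = FALSE))
    f1 <- file.path(out_dir, paste0(preset, "_train.csv"))
    f2 <- file.path(out_dir, paste0(preset, "_test.csv"))
    write_time_series(gen$train, f1)
    write_time_series(gen$test, f2)
    files <- c(f1, f2)
    spec <- gen$spec
  }
  manifest <- list(preset = preset, seed = seed, spec = spec,
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(files)), basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
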