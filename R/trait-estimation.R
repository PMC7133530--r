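#' Control settings for growth-curve fitting
#'
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @param ptol Convergence tolerance on relative parameter change.
#' @param restarts Number of deterministically jittered restarts tried before
#'   a fit is declared failed.
#' @param estimate_f0 For [fit_monod()]: if `TRUE`, estimate a single shared
#'   initial fluorescence F0 as a free parameter instead of fixing F0 per
#'   resource level at that level's earliest reading.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(maxiter = 100L, ptol = 1e-8, restarts = 5L,
                        estimate_f0 = FALSE) {
  stopifnot(maxiter >= 1, ptol > 0, restarts >= 1)
  structure(list(maxiter = as.integer(maxiter), ptol = ptol,
                 restarts = as.integer(restarts), estimate_f0 = estimate_f0),
            class = "fit_control")
}

# Deterministic multiplicative jitter factors for multi-start fitting: the
# first start is the data-driven guess, later starts scan ks (or c) over a
# coarse grid around it.
jitter_grid <- function(n) {
  base <- cbind(mu = c(1, 1.2, 0.8, 1.5, 0.6, 1.1, 0.9),
                k  = c(1, 0.4, 2.5, 0.15, 6, 0.7, 1.4))
  base[rep_len(seq_len(nrow(base)), n), , drop = FALSE]
}

run_lm <- function(par0, lower, fn, jac, control) {
  # non-convergence (info outside 1:4, incl. maxiter) is handled explicitly
  # by the caller, so the solver's own warnings are muffled
  fit <- try(suppressWarnings(minpack.lm::nls.lm(
    par = par0, lower = lower, fn = fn, jac = jac,
    control = minpack.lm::nls.lm.control(maxiter = control$maxiter,
                                         ptol = control$ptol))), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  if (!(fit$info %in% 1:4)) return(NULL)
  fit
}

# Multi-start LM driver: returns the best converged fit or NULL.
lm_multistart <- function(par0, lower, fn, jac, control, jitter_cols) {
  grid <- jitter_grid(control$restarts)
  best <- NULL
  for (i in seq_len(control$restarts)) {
    par_i <- par0
    par_i[jitter_cols$mu] <- par0[jitter_cols$mu] * grid[i, "mu"]
    par_i[jitter_cols$k] <- par0[jitter_cols$k] * grid[i, "k"]
    par_i <- pmax(par_i, lower + 1e-10)
    fit <- run_lm(par_i, lower, fn, jac, control)
    if (!is.null(fit)) {
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
      # Accept the data-driven start immediately when it converges cleanly;
      # later starts only matter as a rescue.
      if (i == 1L) break
    }
  }
  best
}

#' Exponential growth rate from a fluorescence time series
#'
#' Ordinary least-squares slope of `log(rfu)` on time: the per-capita
#' exponential growth rate under the model `F(t) = F(0) exp(mu t)`.
#'
#' @param time_days Times in days (at least two distinct values).
#' @param rfu Positive chlorophyll-a relative fluorescence readings.
#' @return Growth rate in day⁻¹.
#' @examples
#' exponential_growth_rate(0:2, c(100, 200, 400)) # doubling per day: log(2)
#' @export
exponential_growth_rate <- function(time_days, rfu) {
  if (length(time_days) < 2 || length(unique(time_days)) < 2) {
    stop("insufficient data: need at least 2 distinct time points", call. = FALSE)
  }
  if (any(rfu <= 0)) stop("`rfu` must be positive", call. = FALSE)
  unname(stats::coef(stats::lm.fit(cbind(1, time_days), log(rfu)))[2])
}

#' Per-level exponential growth rates for one population and resource
#'
#' @param obs Long-format growth observations with columns `level`,
#'   `time_days`, `rfu` (one population, one resource).
#' @return A tibble with one row per resource level: `level`, `rate` (day⁻¹),
#'   `n_obs`.
#' @export
growth_rates <- function(obs) {
  obs <- check_obs(obs, min_levels = 1L)
  obs |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(rate = exponential_growth_rate(.data$time_days, .data$rfu),
                     n_obs = dplyr::n(), .groups = "drop")
}

#' Consumption-vector slope from biomass stoichiometry
#'
#' The P:N molar ratio of exponentially growing biomass, used as the slope
#' (P consumed per N consumed, with N on the x-axis) of the population's
#' consumption vector in the nitrogen-phosphorus resource plane.
#'
#' @param molar_n,molar_p Molar N and P per unit biomass, both positive.
#' @return Dimensionless molar P:N ratio(s).
#' @examples
#' consumption_vector(16, 1) # Redfield-like biomass: 1/16
#' @export
consumption_vector <- function(molar_n, molar_p) {
  if (any(molar_n <= 0) || any(molar_p <= 0)) {
    stop("molar N and P must both be positive", call. = FALSE)
  }
  molar_p / molar_n
}

check_obs <- function(obs, min_levels = 3L, min_times = 2L) {
  need <- c("level", "time_days", "rfu")
  if (!all(need %in% names(obs))) {
    stop("observations must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  obs <- dplyr::as_tibble(obs)
  if (any(obs$rfu <= 0)) stop("`rfu` must be positive", call. = FALSE)
  if (any(obs$time_days < 0)) stop("`time_days` must be non-negative", call. = FALSE)
  for (col in c("population_id", "resource")) {
    if (col %in% names(obs) && dplyr::n_distinct(obs[[col]]) > 1) {
      stop("observations must come from a single ", col, call. = FALSE)
    }
  }
  if (dplyr::n_distinct(obs$level) < min_levels) {
    stop("need at least ", min_levels, " distinct resource levels", call. = FALSE)
  }
  tpl <- obs |> dplyr::count(.data$level)
  if (any(tpl$n < min_times)) {
    stop("need at least ", min_times, " time points per resource level", call. = FALSE)
  }
  dplyr::arrange(obs, .data$level, .data$time_days)
}

#' Fit a Monod growth curve to fluorescence time series over a resource gradient
#'
#' Estimates `(mu_max, ks)` by Levenberg-Marquardt least squares on the raw
#' fluorescence scale, minimising
#' \deqn{\sum_i \left( F_i - F_0(R_i)\, e^{\mu(R_i) t_i} \right)^2}
#' where \eqn{\mu(R)} is the Monod curve ([monod_mu()]). By default the
#' initial fluorescence \eqn{F_0} for each resource level is fixed at that
#' level's earliest observed reading; set `estimate_f0 = TRUE` in
#' [fit_control()] to estimate a shared free \eqn{F_0} instead. The minimum
#' resource requirement R* ([rstar()]) is attached as the derived trait
#' whenever the fitted population is persistent (`mu_max > m`).
#'
#' Starting values are data-driven (`mu_max`: largest per-level log-linear
#' slope; `ks`: median gradient level), with deterministic jittered restarts
#' on failure.
#'
#' @param obs Long-format observations for one population and one resource:
#'   columns `level`, `time_days`, `rfu` (optionally `population_id`,
#'   `resource`, which must be constant).
#' @param m Mortality (dilution) rate, day⁻¹, used only for the derived R*.
#' @param control A [fit_control()] list.
#' @return An object of class `monod_fit`: point estimates, per-level F0
#'   values, fitted values, residuals, convergence diagnostics, persistence
#'   flag and derived R*. Use [bootstrap_ci()] to attach uncertainty and
#'   [tidy()]/[glance()] to extract tables.
#' @examples
#' obs <- tidyr::expand_grid(level = c(1, 2, 5, 10, 20, 50), time_days = 0:3) |>
#'   dplyr::mutate(rfu = 50 * exp(monod_mu(level, 1.2, 8) * time_days))
#' fit <- fit_monod(obs)
#' coef(fit)
#' @export
fit_monod <- function(obs, m = 0.56, control = fit_control()) {
  obs <- check_obs(obs, min_levels = 3L, min_times = 2L)
  level <- obs$level
  tt <- obs$time_days
  rfu <- obs$rfu

  f0_tbl <- obs |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(f0 = .data$rfu[which.min(.data$time_days)], .groups = "drop")
  f0 <- f0_tbl$f0[match(level, f0_tbl$level)]

  rates <- growth_rates(obs)
  mu0 <- max(rates$rate, 0.1)
  ks0 <- stats::median(unique(level))

  if (!control$estimate_f0) {
    fn <- function(p) rfu - f0 * exp(p[1] * level / (p[2] + level) * tt)
    jac <- function(p) {
      g <- p[1] * level / (p[2] + level)
      e <- f0 * exp(g * tt)
      cbind(-e * tt * level / (p[2] + level),
            e * tt * p[1] * level / (p[2] + level)^2)
    }
    par0 <- c(mu_max = mu0, ks = ks0)
    lower <- c(1e-8, 1e-8)
    jcols <- list(mu = 1L, k = 2L)
  } else {
    fn <- function(p) rfu - p[3] * exp(p[1] * level / (p[2] + level) * tt)
    jac <- function(p) {
      g <- p[1] * level / (p[2] + level)
      e <- exp(g * tt)
      cbind(-p[3] * e * tt * level / (p[2] + level),
            p[3] * e * tt * p[1] * level / (p[2] + level)^2,
            -e)
    }
    par0 <- c(mu_max = mu0, ks = ks0, f0 = mean(f0_tbl$f0))
    lower <- c(1e-8, 1e-8, 1e-8)
    jcols <- list(mu = 1L, k = 2L)
  }

  best <- lm_multistart(par0, lower, fn, jac, control, jcols)
  if (is.null(best)) {
    stop("fit failure: Monod fit did not converge after ", control$restarts,
         " starts", call. = FALSE)
  }
  est <- stats::setNames(best$par, names(par0))
  persistent <- unname(est["mu_max"]) > m
  derived <- if (persistent) rstar(est[["mu_max"]], est[["ks"]], m = m) else NA_real_
  fitted <- rfu - fn(best$par)

  structure(list(
    model = "monod",
    estimate = est,
    derived_trait = c(rstar = derived),
    persistent = persistent,
    m = m,
    f0 = f0_tbl,
    data = obs,
    fitted = fitted,
    residuals = rfu - fitted,
    rss = best$deviance,
    iterations = best$niter,
    converged = TRUE,
    control = control
  ), class = c("monod_fit", "growth_fit"))
}

#' Fit a logistic salt-tolerance curve to growth over a salt gradient
#'
#' Per-level exponential growth rates are first extracted from the
#' fluorescence time series ([growth_rates()]); the declining logistic
#' [salt_mu()] is then fitted to rate versus salt concentration by
#' Levenberg-Marquardt least squares. The derived trait is `c`, the salt
#' tolerance: the concentration at which growth is half its zero-salt
#' maximum. If growth increases rather than declines over the gradient the
#' result is flagged `no_detectable_tolerance`.
#'
#' @param obs Long-format observations over a salt gradient (`level` = salt
#'   concentration in g L⁻¹), at least 4 distinct levels including a low-salt
#'   anchor.
#' @param control A [fit_control()] list.
#' @return An object of class `salt_fit` with estimates `(a, b, c)`, the
#'   per-level rates used, residual diagnostics and the derived salt
#'   tolerance.
#' @export
fit_salt <- function(obs, control = fit_control()) {
  obs <- check_obs(obs, min_levels = 4L, min_times = 2L)
  rates <- growth_rates(obs)
  S <- rates$level
  r <- rates$rate

  a0 <- max(r[which.min(S)], 0.1)
  c0 <- (min(S) + max(S)) / 2
  par0 <- c(a = a0, b = 1, c = c0)
  lower <- c(1e-8, 1e-8, 1e-8)

  fn <- function(p) r - p[1] / (1 + exp(p[2] * (S - p[3])))
  jac <- function(p) {
    eb <- exp(p[2] * (S - p[3]))
    D <- 1 + eb
    cbind(-1 / D,
          p[1] * eb * (S - p[3]) / D^2,
          -p[1] * eb * p[2] / D^2)
  }

  best <- lm_multistart(par0, lower, fn, jac, control,
                        jitter_cols = list(mu = 1L, k = 3L))
  if (is.null(best)) {
    stop("fit failure: salt-logistic fit did not converge after ",
         control$restarts, " starts", call. = FALSE)
  }
  est <- stats::setNames(best$par, c("a", "b", "c"))
  increasing <- unname(stats::coef(stats::lm.fit(cbind(1, S), r))[2]) > 0
  fitted <- r - fn(best$par)

  structure(list(
    model = "salt_logistic",
    estimate = est,
    derived_trait = c(salt_tolerance = unname(est["c"])),
    no_detectable_tolerance = increasing,
    rates = rates,
    data = obs,
    fitted = fitted,
    residuals = r - fitted,
    rss = best$deviance,
    iterations = best$niter,
    converged = TRUE,
    control = control
  ), class = c("salt_fit", "growth_fit"))
}

# Refit a monod_fit against perturbed pseudo-responses (internal, used by the
# bootstrap). F0 per level is re-derived from the pseudo-data's earliest
# readings, mirroring the original fitting procedure. Starts at the original
# point estimates; single start.
refit_monod <- function(fit, rfu_new, anchor_idx) {
  obs <- fit$data
  level <- obs$level
  tt <- obs$time_days
  f0_new <- rfu_new[anchor_idx]
  f0 <- f0_new[match(level, level[anchor_idx])]
  fn <- function(p) rfu_new - f0 * exp(p[1] * level / (p[2] + level) * tt)
  jac <- function(p) {
    g <- p[1] * level / (p[2] + level)
    e <- f0 * exp(g * tt)
    cbind(-e * tt * level / (p[2] + level),
          e * tt * p[1] * level / (p[2] + level)^2)
  }
  res <- run_lm(unname(fit$estimate[1:2]), c(1e-8, 1e-8), fn, jac, fit$control)
  if (is.null(res)) return(NULL)
  stats::setNames(res$par, c("mu_max", "ks"))
}

refit_salt <- function(fit, rate_new) {
  S <- fit$rates$level
  fn <- function(p) rate_new - p[1] / (1 + exp(p[2] * (S - p[3])))
  jac <- function(p) {
    eb <- exp(p[2] * (S - p[3]))
    D <- 1 + eb
    cbind(-1 / D,
          p[1] * eb * (S - p[3]) / D^2,
          -p[1] * eb * p[2] / D^2)
  }
  res <- run_lm(unname(fit$estimate), c(1e-8, 1e-8, 1e-8), fn, jac, fit$control)
  if (is.null(res)) return(NULL)
  stats::setNames(res$par, c("a", "b", "c"))
}

#' Attach residual-bootstrap confidence intervals to a growth-curve fit
#'
#' Non-parametric bootstrap of mean-centred residuals: residuals of the fit
#' are centred, resampled with replacement, recombined with the fitted
#' values, and the model refitted; 95% confidence intervals are the 2.5th and
#' 97.5th percentiles of each parameter and of the derived trait (R* for
#' Monod fits, salt tolerance for salt fits) across converged replicates.
#' Replicates that fail to converge — or, for Monod fits, are non-persistent
#' so R* is undefined — are dropped and counted; if more than half are
#' dropped the interval is flagged unreliable.
#'
#' For Monod fits the residuals are taken on the log-fluorescence scale
#' (relative residuals) because fluorescence measurement error is
#' scale-dependent. Under the per-level-F0 design each level's anchor
#' reading reproduces its fitted value exactly, so every non-anchor
#' log-residual is the *difference* between that reading's noise and its
#' level's anchor noise: the anchors' structurally zero residuals are
#' excluded from the pool and the remaining centred residuals are scaled by
#' 1/sqrt(2) to recover the per-reading noise scale. Pseudo-data are then
#' `fitted * exp(eps*)` with `eps*` resampled for every reading — anchors
#' included — and the refit re-derives F0 from the perturbed anchors exactly
#' as the original fit did from the data, so each replicate passes through
#' the same pipeline the data did. For salt fits the bootstrap operates on
#' the additive residuals of the rate-versus-salt regression, whose errors
#' are approximately homoskedastic.
#'
#' @param fit A `monod_fit` or `salt_fit`.
#' @param n_iter Number of bootstrap iterations (the study design used 999;
#'   must be at least 100).
#' @param seed Integer seed; required, so every interval is reproducible.
#' @param level Confidence level (default 0.95).
#' @return The fit, augmented with `boot` (a tibble of replicate parameter
#'   and derived-trait values), `ci` (a tibble `term`, `ci_low`, `ci_high`),
#'   `n_discarded`, and `ci_unreliable`.
#' @export
bootstrap_ci <- function(fit, n_iter = 999L, seed, level = 0.95) {
  if (missing(seed)) stop("`seed` is required for a reproducible bootstrap", call. = FALSE)
  if (n_iter < 100) stop("`n_iter` must be at least 100", call. = FALSE)
  if (!fit$converged) stop("cannot bootstrap a non-converged fit", call. = FALSE)
  UseMethod("bootstrap_ci")
}

boot_percentiles <- function(reps, level) {
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  if (nrow(reps) == 0) {
    return(tibble::tibble(term = colnames(reps),
                          ci_low = NA_real_, ci_high = NA_real_))
  }
  tibble::tibble(term = colnames(reps),
                 ci_low = apply(reps, 2, stats::quantile, probs[1], names = FALSE),
                 ci_high = apply(reps, 2, stats::quantile, probs[2], names = FALSE))
}

#' @export
bootstrap_ci.monod_fit <- function(fit, n_iter = 999L, seed, level = 0.95) {
  withr::local_seed(seed)
  obs <- fit$data
  n <- nrow(obs)
  # earliest reading per level: the F0 anchors, whose residuals are
  # structurally zero under the per-level-F0 scheme
  anchor_idx <- obs |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$level) |>
    dplyr::slice_min(.data$time_days, n = 1, with_ties = FALSE) |>
    dplyr::pull(".row")
  log_res <- log(obs$rfu) - log(fit$fitted)
  if (fit$control$estimate_f0) {
    pool <- log_res - mean(log_res)
  } else {
    # non-anchor residuals are (reading noise - anchor noise): rescale the
    # pool back to the per-reading noise scale
    pool <- log_res[-anchor_idx]
    pool <- (pool - mean(pool)) / sqrt(2)
  }
  reps <- matrix(NA_real_, n_iter, 3,
                 dimnames = list(NULL, c("mu_max", "ks", "rstar")))
  for (i in seq_len(n_iter)) {
    eps <- sample(pool, n, replace = TRUE)
    pseudo <- fit$fitted * exp(eps)
    if (fit$control$estimate_f0) {
      obs_i <- obs
      obs_i$rfu <- pseudo
      refit <- try(fit_monod(obs_i, m = fit$m, control = fit$control), silent = TRUE)
      if (inherits(refit, "try-error")) next
      par <- refit$estimate[c("mu_max", "ks")]
    } else {
      par <- refit_monod(fit, pseudo, anchor_idx)
    }
    if (is.null(par) || par[["mu_max"]] <= fit$m) next
    reps[i, ] <- c(par, rstar(par[["mu_max"]], par[["ks"]], m = fit$m))
  }
  ok <- stats::complete.cases(reps)
  fit$boot <- tibble::as_tibble(as.data.frame(reps[ok, , drop = FALSE]))
  fit$n_discarded <- sum(!ok)
  fit$ci_unreliable <- fit$n_discarded > n_iter / 2
  fit$ci <- boot_percentiles(reps[ok, , drop = FALSE], level = level)
  fit$ci_level <- level
  fit
}

#' @export
bootstrap_ci.salt_fit <- function(fit, n_iter = 999L, seed, level = 0.95) {
  withr::local_seed(seed)
  res <- fit$residuals - mean(fit$residuals)
  n <- length(res)
  reps <- matrix(NA_real_, n_iter, 4,
                 dimnames = list(NULL, c("a", "b", "c", "salt_tolerance")))
  for (i in seq_len(n_iter)) {
    pseudo <- fit$fitted + sample(res, n, replace = TRUE)
    par <- refit_salt(fit, pseudo)
    if (is.null(par)) next
    reps[i, ] <- c(par, par[["c"]])
  }
  ok <- stats::complete.cases(reps)
  fit$boot <- tibble::as_tibble(as.data.frame(reps[ok, , drop = FALSE]))
  fit$n_discarded <- sum(!ok)
  fit$ci_unreliable <- fit$n_discarded > n_iter / 2
  fit$ci <- boot_percentiles(reps[ok, , drop = FALSE], level = level)
  fit$ci_level <- level
  fit
}

# --- S3 conveniences ---------------------------------------------------------

#' @export
coef.growth_fit <- function(object, ...) object$estimate

#' @export
print.monod_fit <- function(x, ...) {
  cat("Monod growth fit\n")
  cat(sprintf("  mu_max = %.4g /day, ks = %.4g\n",
              x$estimate[["mu_max"]], x$estimate[["ks"]]))
  if (x$persistent) {
    cat(sprintf("  R* = %.4g (m = %.3g /day)\n", x$derived_trait[["rstar"]], x$m))
  } else {
    cat("  non-persistent (mu_max <= m): R* undefined\n")
  }
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap: %d replicates kept, %d discarded\n",
                nrow(x$boot), x$n_discarded))
  }
  invisible(x)
}

#' @export
print.salt_fit <- function(x, ...) {
  cat("Salt-tolerance logistic fit\n")
  cat(sprintf("  a = %.4g /day, b = %.4g L/g, c (salt tolerance) = %.4g g/L\n",
              x$estimate[["a"]], x$estimate[["b"]], x$estimate[["c"]]))
  if (x$no_detectable_tolerance) cat("  flagged: no detectable tolerance (growth increases with salt)\n")
  invisible(x)
}

#' Tidy a growth-curve fit into a one-row-per-term tibble
#'
#' @param x A `monod_fit` or `salt_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` and, when [bootstrap_ci()] has
#'   been run, `ci_low` and `ci_high`.
#' @export
tidy.growth_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = c(names(x$estimate), names(x$derived_trait)),
    estimate = c(unname(x$estimate), unname(x$derived_trait)))
  if (!is.null(x$ci)) out <- dplyr::left_join(out, x$ci, by = "term")
  out
}

#' One-row fit summary
#'
#' @param x A `monod_fit` or `salt_fit`.
#' @param ... Unused.
#' @return A one-row tibble of convergence diagnostics.
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    rss = x$rss,
    iterations = x$iterations,
    converged = x$converged,
    persistent = if (!is.null(x$persistent)) x$persistent else NA,
    n_boot = if (!is.null(x$boot)) nrow(x$boot) else NA_integer_,
    n_discarded = if (!is.null(x$n_discarded)) x$n_discarded else NA_integer_)
}
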