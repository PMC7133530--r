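#' Configuration for the synthetic selection-experiment scenario
#'
#' Describes the simulated study design the generator emulates: five
#' ancestral populations (four isoclonal, one genotypically diverse), each
#' seeding descendants in seven selection environments (COMBO control C,
#' N-limitation, P-limitation, low light L, high salt S, biotically depleted
#' medium B, and salt plus depleted medium BS), with a configurable number of
#' descendant lines lost to contamination. Growth is assayed over gradients
#' of 10 levels per resource for 3 days (readings on days 0-3), with
#' multiplicative lognormal measurement noise on fluorescence.
#'
#' Environment effects are multiplicative shifts on the true traits and
#' default to stylized versions of the qualitative outcomes the pipeline is
#' designed to detect: P-limitation lowers true P* by 43-85%, salt selection
#' raises salt tolerance by 93-369%, N and light effects are mixed and
#' smaller, and consumption vectors shift down under N-limitation and up
#' under P-limitation. Shifts in the three minimum requirements share a
#' latent factor with correlation `rho_traits`, emulating positively
#' associated trait change.
#'
#' @param n_ancestors Number of ancestral populations (one is flagged
#'   genotypically diverse).
#' @param environments Selection environment codes.
#' @param lost_populations Number of descendant lines lost to contamination.
#' @param gradients Named list of resource gradients (levels per resource).
#' @param times Assay reading times in days.
#' @param f0 Mean initial fluorescence (RFU).
#' @param sigma Lognormal noise standard deviation on RFU.
#' @param ancestor_cv Coefficient of variation of ancestral trait draws.
#' @param rho_traits Correlation of latent R* shifts across resources.
#' @param shift_sd Standard deviation of the latent log-scale R* shift.
#' @param effects Named list of per-environment effect ranges (see defaults).
#' @param truth_means Central values of ancestral traits.
#' @param seed Integer seed; every generated artifact is deterministic in it.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(
    n_ancestors = 5L,
    environments = c("C", "N", "P", "L", "S", "B", "BS"),
    lost_populations = 3L,
    gradients = list(
      N = exp(seq(log(0.5), log(500), length.out = 10)),
      P = exp(seq(log(0.05), log(50), length.out = 10)),
      light = exp(seq(log(2), log(600), length.out = 10)),
      salt = seq(0, 16, length.out = 10)),
    times = 0:3,
    f0 = 50,
    sigma = 0.05,
    ancestor_cv = 0.05,
    rho_traits = 0.5,
    shift_sd = 0.1,
    effects = list(
      p_star_P = c(0.15, 0.57),        # 43-85% decline in P* under P-limitation
      n_star_N = c(log(0.9), 0.15),    # lognormal(meanlog, sdlog): mixed N* change
      i_star_L = c(log(1.15), 0.08),   # mild I* increase under low light
      salt_c_S = c(1.93, 4.69),        # 93-369% salt-tolerance increase
      pn_slope_N = c(0.70, 0.95),      # biomass P:N drops under N-limitation
      pn_slope_P = c(1.05, 1.40)),     # and rises under P-limitation
    truth_means = list(
      mu_max_n = 1.2, ks_n = 3,
      mu_max_p = 1.1, ks_p = 0.3,
      mu_max_i = 1.3, ks_i = 60,
      salt_a = 1.3, salt_b = 1.5, salt_c = 3,
      pn_slope = 0.0625, cell_length_um = 6),
    seed = 1L) {
  stopifnot(n_ancestors >= 1, lost_populations >= 0, sigma >= 0,
            length(times) >= 2, all(lengths(gradients) >= 2))
  if (any(purrr::map_lgl(gradients, \(g) any(diff(sort(g)) <= 0)))) {
    stop("config error: each gradient must have strictly increasing distinct levels",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "scenario_config")
}

#' Simulate a fluorescence time series over a Monod resource gradient
#'
#' Readings follow `F0 * exp(mu(R) t) * eps` with `mu(R)` the Monod curve and
#' `eps` lognormal with sdlog `sigma`. Uses the current RNG state; set a seed
#' before calling for reproducibility.
#'
#' @inheritParams monod_mu
#' @param levels Resource gradient.
#' @param times Reading times (days).
#' @param f0 Initial fluorescence.
#' @param sigma Lognormal noise sd (0 for noiseless data).
#' @return A tibble with columns `level`, `time_days`, `rfu`.
#' @export
simulate_monod_series <- function(mu_max, ks, levels, times = 0:3, f0 = 50,
                                  sigma = 0.05) {
  grid <- tidyr::expand_grid(level = levels, time_days = times)
  mu <- monod_mu(grid$level, mu_max, ks)
  eps <- if (sigma > 0) exp(stats::rnorm(nrow(grid), 0, sigma)) else 1
  dplyr::mutate(grid, rfu = f0 * exp(mu * .data$time_days) * eps)
}

#' Simulate a fluorescence time series over a salt gradient
#'
#' @inheritParams salt_mu
#' @inheritParams simulate_monod_series
#' @return A tibble with columns `level` (salt, g L⁻¹), `time_days`, `rfu`.
#' @export
simulate_salt_series <- function(a, b, c, levels, times = 0:3, f0 = 50,
                                 sigma = 0.05) {
  grid <- tidyr::expand_grid(level = levels, time_days = times)
  mu <- salt_mu(grid$level, a, b, c)
  eps <- if (sigma > 0) exp(stats::rnorm(nrow(grid), 0, sigma)) else 1
  dplyr::mutate(grid, rfu = f0 * exp(mu * .data$time_days) * eps)
}

draw_range <- function(n, range) stats::runif(n, range[1], range[2])

#' Generate a full synthetic selection-experiment scenario
#'
#' Draws ancestral truths (lognormal around the configured central values),
#' derives descendant truths by applying environment-specific multiplicative
#' shifts with cross-resource correlation, removes the configured number of
#' contamination-lost lines, and emits the fluorescence time series and
#' stoichiometry tables the estimation pipeline consumes. Everything is
#' deterministic given `config$seed`.
#'
#' @param config A [scenario_config()].
#' @return A list of class `scenario`: `truth` (one row per population with
#'   all true parameters and derived traits), `observations` (long RFU table
#'   with `population_id`, `resource`, `level`, `time_days`, `rfu`),
#'   `stoichiometry` (`population_id`, `molar_n`, `molar_p`,
#'   `cell_length_um`), and `config`.
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  withr::local_seed(config$seed)
  tm <- config$truth_means
  anc_ids <- c(paste0("anc_", seq_len(config$n_ancestors - 1)), "cc_div")

  ln <- function(n, mean, cv) stats::rlnorm(n, log(mean) - log(1 + cv^2) / 2,
                                            sqrt(log(1 + cv^2)))
  nA <- config$n_ancestors
  anc <- tibble::tibble(
    population_id = anc_ids,
    ancestor_id = anc_ids,
    environment = "A",
    diverse_flag = anc_ids == "cc_div",
    mu_max_n = ln(nA, tm$mu_max_n, config$ancestor_cv),
    ks_n = ln(nA, tm$ks_n, config$ancestor_cv),
    mu_max_p = ln(nA, tm$mu_max_p, config$ancestor_cv),
    ks_p = ln(nA, tm$ks_p, config$ancestor_cv),
    mu_max_i = ln(nA, tm$mu_max_i, config$ancestor_cv),
    ks_i = ln(nA, tm$ks_i, config$ancestor_cv),
    salt_a = ln(nA, tm$salt_a, config$ancestor_cv),
    salt_b = ln(nA, tm$salt_b, config$ancestor_cv),
    salt_c = ln(nA, tm$salt_c, config$ancestor_cv),
    pn_slope = ln(nA, tm$pn_slope, config$ancestor_cv),
    cell_length_um = ln(nA, tm$cell_length_um, config$ancestor_cv))

  desc <- tidyr::expand_grid(ancestor_id = anc_ids,
                             environment = config$environments) |>
    dplyr::mutate(population_id = paste0(.data$ancestor_id, "_", .data$environment))
  nd <- nrow(desc)
  ef <- config$effects

  # correlated lognormal shifts on the three minimum requirements, realised
  # as multipliers on ks (mu_max unchanged, so R* scales with ks)
  z0 <- stats::rnorm(nd)
  shift <- function() {
    z <- sqrt(config$rho_traits) * z0 +
      sqrt(1 - config$rho_traits) * stats::rnorm(nd)
    exp(config$shift_sd * z)
  }
  mult_n <- shift() * ifelse(desc$environment == "N",
                             stats::rlnorm(nd, ef$n_star_N[1], ef$n_star_N[2]), 1)
  mult_p <- shift() * ifelse(desc$environment == "P",
                             draw_range(nd, ef$p_star_P), 1)
  mult_i <- shift() * ifelse(desc$environment == "L",
                             stats::rlnorm(nd, ef$i_star_L[1], ef$i_star_L[2]), 1)
  mult_salt <- ifelse(desc$environment %in% c("S", "BS"),
                      draw_range(nd, ef$salt_c_S), 1)
  mult_pn <- ifelse(desc$environment == "N", draw_range(nd, ef$pn_slope_N),
                    ifelse(desc$environment == "P", draw_range(nd, ef$pn_slope_P), 1))

  desc <- desc |>
    dplyr::left_join(dplyr::select(anc, -"population_id", -"environment"),
                     by = "ancestor_id") |>
    dplyr::mutate(ks_n = .data$ks_n * mult_n,
                  ks_p = .data$ks_p * mult_p,
                  ks_i = .data$ks_i * mult_i,
                  salt_c = .data$salt_c * mult_salt,
                  pn_slope = .data$pn_slope * mult_pn)

  if (config$lost_populations > 0) {
    lost <- sample(desc$population_id, config$lost_populations)
    desc <- dplyr::filter(desc, !.data$population_id %in% lost)
  }

  truth <- dplyr::bind_rows(anc, desc) |>
    dplyr::mutate(
      n_star = rstar(.data$mu_max_n, .data$ks_n),
      p_star = rstar(.data$mu_max_p, .data$ks_p),
      i_star = rstar(.data$mu_max_i, .data$ks_i),
      biovolume = biovolume_from_length(.data$cell_length_um)) |>
    dplyr::relocate("population_id", "ancestor_id", "environment", "diverse_flag")

  g <- config$gradients
  observations <- purrr::pmap_dfr(truth, function(...) {
    p <- list(...)
    dplyr::bind_rows(
      simulate_monod_series(p$mu_max_n, p$ks_n, g$N, config$times,
                            config$f0, config$sigma) |>
        dplyr::mutate(resource = "N"),
      simulate_monod_series(p$mu_max_p, p$ks_p, g$P, config$times,
                            config$f0, config$sigma) |>
        dplyr::mutate(resource = "P"),
      simulate_monod_series(p$mu_max_i, p$ks_i, g$light, config$times,
                            config$f0, config$sigma) |>
        dplyr::mutate(resource = "light"),
      simulate_salt_series(p$salt_a, p$salt_b, p$salt_c, g$salt, config$times,
                           config$f0, config$sigma) |>
        dplyr::mutate(resource = "salt")) |>
      dplyr::mutate(population_id = p$population_id)
  }) |>
    dplyr::select("population_id", "resource", "level", "time_days", "rfu")

  stoichiometry <- truth |>
    dplyr::transmute(.data$population_id,
                     molar_n = 16,
                     molar_p = 16 * .data$pn_slope,
                     cell_length_um = .data$cell_length_um)

  structure(list(truth = truth, observations = observations,
                 stoichiometry = stoichiometry, config = config),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Synthetic scenario: %d populations (%d ancestors), %d observations\n",
              nrow(x$truth), sum(x$truth$environment == "A"),
              nrow(x$observations)))
  invisible(x)
}

#' Generate a null pair: two assays of the same true population
#'
#' Two observation sets drawn from identical true parameters with
#' independent measurement noise, used to calibrate the false-positive rate
#' of [trait_change()].
#'
#' @param config A [scenario_config()]; its central truth values, gradient,
#'   times, `f0`, `sigma` and `seed` are used.
#' @param resource Which assay to simulate (`"N"`, `"P"`, `"light"` or
#'   `"salt"`).
#' @return A list: `truth` (named list of the shared true parameters),
#'   `obs_1`, `obs_2` (observation tibbles).
#' @export
generate_null_pair <- function(config = scenario_config(), resource = "P") {
  stopifnot(inherits(config, "scenario_config"))
  withr::local_seed(config$seed)
  tm <- config$truth_means
  g <- config$gradients
  sim <- function() {
    switch(resource,
      N = simulate_monod_series(tm$mu_max_n, tm$ks_n, g$N, config$times,
                                config$f0, config$sigma),
      P = simulate_monod_series(tm$mu_max_p, tm$ks_p, g$P, config$times,
                                config$f0, config$sigma),
      light = simulate_monod_series(tm$mu_max_i, tm$ks_i, g$light, config$times,
                                    config$f0, config$sigma),
      salt = simulate_salt_series(tm$salt_a, tm$salt_b, tm$salt_c, g$salt,
                                  config$times, config$f0, config$sigma),
      stop("unknown resource: ", resource, call. = FALSE))
  }
  list(truth = tm, obs_1 = sim(), obs_2 = sim())
}

#' Constructed resource-competition fixtures with known outcomes
#'
#' Small trait tables built so that [classify_pair()] /
#' [enumerate_outcomes()] produce a requested outcome pattern:
#' * `"stable"`, `"unstable"`, `"exclusion"`: one pair of populations plus a
#'   supply point with that outcome;
#' * `"fig6_pattern"`: an ancestor and two descendants (selected in low
#'   light and high salt) whose requirements diverged so the two descendants
#'   coexist stably while neither coexists with the ancestor;
#' * `"ancestral_1_4_5"`: five ancestral populations whose 10 pairs split
#'   into exactly 1 stable, 4 unstable and 5 exclusion outcomes in
#'   feasibility mode.
#'
#' With `verify = TRUE` (the default) the construction is checked at
#' generation time: the graphical classification must match the requested
#' pattern, and for the supply-point kinds the mechanistic chemostat oracle
#' ([chemostat_verdict()]) must agree.
#'
#' @param kind Fixture kind (see above).
#' @param verify Re-check the construction before returning.
#' @return A list: `traits` (tibble with `population_id`, `ancestor_id`,
#'   `environment`, `n_star`, `p_star`, `pn_slope`, `mu_max_n`, `mu_max_p`)
#'   and `supply` (list with `s_n`, `s_p`, or `NULL` for
#'   `"ancestral_1_4_5"`).
#' @export
generate_rct_fixture <- function(kind = c("stable", "unstable", "exclusion",
                                          "fig6_pattern", "ancestral_1_4_5"),
                                 verify = TRUE) {
  kind <- match.arg(kind)
  mk <- function(ids, n, p, s, env = "A", anc = ids) {
    tibble::tibble(population_id = ids, ancestor_id = anc, environment = env,
                   n_star = n, p_star = p, pn_slope = s,
                   mu_max_n = 1.12, mu_max_p = 1.12)
  }
  out <- switch(kind,
    stable = list(
      traits = mk(c("glean_P", "glean_N"), n = c(2, 6), p = c(1.0, 0.3),
                  s = c(0.08, 0.02)),
      supply = list(s_n = 36, s_p = 2.5)),
    unstable = list(
      traits = mk(c("hoard_N", "hoard_P"), n = c(2, 6), p = c(1.0, 0.3),
                  s = c(0.02, 0.08)),
      supply = list(s_n = 36, s_p = 2.5)),
    exclusion = list(
      traits = mk(c("dominant", "dominated"), n = c(2, 6), p = c(0.3, 1.0),
                  s = c(0.05, 0.05)),
      supply = list(s_n = 36, s_p = 2.5)),
    fig6_pattern = list(
      traits = mk(c("anc_3", "anc_3_L", "anc_3_S"),
                  n = c(7, 2.5, 6), p = c(0.9, 0.8, 0.3),
                  s = c(0.04, 0.10, 0.02),
                  env = c("A", "L", "S"), anc = "anc_3"),
      supply = list(s_n = 30, s_p = 2.2)),
    ancestral_1_4_5 = list(
      traits = mk(paste0("anc_", 1:5),
                  n = c(2, 4, 8, 3, 9), p = c(1.0, 0.5, 0.25, 1.2, 1.5),
                  s = c(0.06, 0.04, 0.10, 0.02, 0.05)),
      supply = NULL))
  if (verify) verify_rct_fixture(kind, out)
  out
}

verify_rct_fixture <- function(kind, out) {
  tr <- out$traits
  if (kind %in% c("stable", "unstable", "exclusion")) {
    expected <- c(stable = "stable_coexistence",
                  unstable = "unstable_coexistence",
                  exclusion = "exclusion")[[kind]]
    cls <- classify_pair(tr[1, ], tr[2, ], supply = out$supply)
    ok_cls <- cls$outcome == expected
    oracle <- chemostat_verdict(tr, out$supply, seed = 1)
    ok_oracle <- oracle$verdict == expected
    if (!ok_cls || !ok_oracle) {
      stop("fixture verification failed for kind '", kind, "'", call. = FALSE)
    }
  } else if (kind == "fig6_pattern") {
    ds <- classify_pair(tr[2, ], tr[3, ], supply = out$supply)
    al <- classify_pair(tr[1, ], tr[2, ])
    as <- classify_pair(tr[1, ], tr[3, ])
    oracle <- chemostat_verdict(tr[2:3, ], out$supply, seed = 1)
    if (ds$outcome != "stable_coexistence" || al$outcome != "exclusion" ||
        as$outcome != "exclusion" || oracle$verdict != "stable_coexistence") {
      stop("fixture verification failed for kind 'fig6_pattern'", call. = FALSE)
    }
  } else {
    eo <- enumerate_outcomes(tr, scope = "ancestors_only")
    counts <- stats::setNames(eo$summary$n, eo$summary$outcome)
    if (!(counts[["stable_coexistence"]] == 1 &&
          counts[["unstable_coexistence"]] == 4 &&
          counts[["exclusion"]] == 5)) {
      stop("fixture verification failed for kind 'ancestral_1_4_5'", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Random non-degenerate population pairs with supply points
#'
#' Draws pairs of populations with clearly separated minimum requirements
#' and consumption slopes (relative margins of at least 30%) together with a
#' supply point that lies above both ZNGIs and away from the wedge
#' boundaries, for stress-testing the graphical classifier against the
#' chemostat oracle. Roughly half the pairs have crossing ZNGIs (split
#' between consumption-slope orders, i.e. stable and unstable candidates);
#' the rest are dominance (exclusion) configurations.
#'
#' @param n Number of pairs.
#' @param seed Integer seed (required).
#' @return A tibble with one row per pair: traits of both populations
#'   (`n_star_1`, `p_star_1`, `pn_slope_1`, ...) and the supply point
#'   (`s_n`, `s_p`).
#' @export
generate_rct_pairs <- function(n, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  withr::local_seed(seed)
  purrr::map_dfr(seq_len(n), function(i) {
    n_lo <- stats::runif(1, 1, 10)
    n_hi <- n_lo * stats::runif(1, 1.3, 3)
    p_lo <- stats::runif(1, 0.1, 1.5)
    p_hi <- p_lo * stats::runif(1, 1.3, 3)
    s_lo <- stats::runif(1, 0.02, 0.05)
    s_hi <- s_lo * stats::runif(1, 1.5, 3)
    crossing <- stats::runif(1) < 0.5
    if (crossing) {
      # population 1: better N competitor (P-limited at the crossing)
      a <- list(n_star = n_lo, p_star = p_hi)
      b <- list(n_star = n_hi, p_star = p_lo)
      if (stats::runif(1) < 0.5) { # stable candidate
        a$pn_slope <- s_hi; b$pn_slope <- s_lo
      } else {                     # unstable candidate
        a$pn_slope <- s_lo; b$pn_slope <- s_hi
      }
      cr_n <- n_hi; cr_p <- p_hi
      if (stats::runif(1) < 0.7) { # supply inside the wedge
        sl <- s_lo + stats::runif(1, 0.15, 0.85) * (s_hi - s_lo)
      } else if (stats::runif(1) < 0.5) { # above the wedge (N scarce)
        sl <- s_hi * stats::runif(1, 1.5, 3)
      } else {                     # below the wedge (P scarce)
        sl <- s_lo * stats::runif(1, 0.3, 0.65)
      }
      d <- stats::runif(1, 5, 30)
      supply <- list(s_n = cr_n + d, s_p = cr_p + sl * d)
    } else {
      a <- list(n_star = n_lo, p_star = p_lo)
      b <- list(n_star = n_hi, p_star = p_hi)
      a$pn_slope <- s_lo; b$pn_slope <- s_hi
      if (stats::runif(1) < 0.5) { a$pn_slope <- s_hi; b$pn_slope <- s_lo }
      supply <- list(s_n = n_hi * stats::runif(1, 1.5, 3),
                     s_p = p_hi * stats::runif(1, 1.5, 3))
    }
    swap <- stats::runif(1) < 0.5
    if (swap) { tmp <- a; a <- b; b <- tmp }
    tibble::tibble(pair_id = i,
                   n_star_1 = a$n_star, p_star_1 = a$p_star, pn_slope_1 = a$pn_slope,
                   n_star_2 = b$n_star, p_star_2 = b$p_star, pn_slope_2 = b$pn_slope,
                   s_n = supply$s_n, s_p = supply$s_p)
  })
}
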