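# Relative-tolerance comparison helpers for ZNGI geometry. Two values within
# relative tolerance of each other are treated as tied (degenerate), never
# silently ordered.
rel_tie <- function(x, y, tol) {
  abs(x - y) <= tol * max(abs(x), abs(y))
}
rel_gt <- function(x, y, tol) {
  !rel_tie(x, y, tol) && x > y
}

#' Do two zero-net-growth isoclines cross?
#'
#' For two essential resources (nitrogen on the x-axis, phosphorus on the
#' y-axis) a population's ZNGI is the L-shaped boundary at its minimum
#' requirements `(n_star, p_star)`. Two ZNGIs cross exactly when each
#' population requires strictly less of one resource and strictly more of the
#' other; the crossing point is `(max(n_star), max(p_star))`. Differences
#' within the relative tolerance on either axis are reported as degenerate
#' and no crossing is claimed.
#'
#' @param a,b Lists or one-row data frames with elements `n_star`, `p_star`
#'   (both positive, µmol L⁻¹).
#' @param tol Relative tolerance for tie detection (default 1e-6).
#' @return A list: `cross` (logical), `degenerate` (logical), and, when
#'   crossing, `crossing_n`, `crossing_p`.
#' @examples
#' zngis_cross(list(n_star = 5, p_star = 0.5), list(n_star = 10, p_star = 0.25))
#' @export
zngis_cross <- function(a, b, tol = 1e-6) {
  stopifnot(a$n_star > 0, a$p_star > 0, b$n_star > 0, b$p_star > 0)
  if (rel_tie(a$n_star, b$n_star, tol) || rel_tie(a$p_star, b$p_star, tol)) {
    return(list(cross = FALSE, degenerate = TRUE,
                crossing_n = NA_real_, crossing_p = NA_real_))
  }
  cross <- (a$n_star < b$n_star) != (a$p_star < b$p_star)
  list(cross = cross, degenerate = FALSE,
       crossing_n = if (cross) max(a$n_star, b$n_star) else NA_real_,
       crossing_p = if (cross) max(a$p_star, b$p_star) else NA_real_)
}

#' Classify the competitive outcome of one population pair
#'
#' Graphical resource-competition-theory classification for two populations
#' competing for nitrogen and phosphorus. Stable coexistence requires three
#' conditions: (1) the ZNGIs cross, so each population is most limited by a
#' different resource (at the crossing, the population with the lower N
#' requirement is P-limited and vice versa); (2) each population consumes
#' proportionally more of the resource that limits it — the P-limited
#' population has the steeper (larger) P:N consumption slope; and (3) the
#' resource supply point lies strictly above both ZNGIs and inside the wedge
#' spanned by the two consumption vectors anchored at the crossing point.
#' All three conditions give stable coexistence; conditions 1 and 3 without
#' 2 give unstable coexistence (priority effects); anything else is
#' competitive exclusion.
#'
#' When `supply` is `NULL` the pair is classified in "feasibility" mode:
#' condition 3 is replaced by the existence of a qualifying supply point
#' (a non-empty wedge above both ZNGIs, which holds whenever the ZNGIs cross
#' and the consumption slopes differ beyond tolerance).
#'
#' Winner determination under exclusion with a supply point: if the supply
#' point supports only one population, that population wins; if it supports
#' both but lies outside the wedge, resources are drawn down until the
#' effectively scarce resource (N when the supply direction is steeper than
#' both consumption vectors, P when shallower) decides, so the population
#' with the lower requirement for that resource wins; if it supports
#' neither, both wash out and the winner is `NA`.
#'
#' @param a,b Lists or one-row data frames with `n_star`, `p_star`,
#'   `pn_slope` and optionally `population_id`.
#' @param supply Optional list with `s_n`, `s_p` (µmol L⁻¹), or `NULL` for
#'   feasibility mode.
#' @param tol Relative tolerance for tie detection.
#' @return A one-row tibble: ids, `outcome` (one of `stable_coexistence`,
#'   `unstable_coexistence`, `exclusion`, `degenerate`), `winner`,
#'   `crossing_n`, `crossing_p`, per-population limiting resources at the
#'   crossing, the three condition flags and the classification `mode`.
#' @export
classify_pair <- function(a, b, supply = NULL, tol = 1e-6) {
  id_a <- if (!is.null(a$population_id)) as.character(a$population_id) else "a"
  id_b <- if (!is.null(b$population_id)) as.character(b$population_id) else "b"
  stopifnot(a$pn_slope > 0, b$pn_slope > 0)
  mode <- if (is.null(supply)) "feasible" else "supply_point"

  zc <- zngis_cross(a, b, tol)
  row <- function(outcome, winner = NA_character_, limiting_a = NA_character_,
                  limiting_b = NA_character_, cond_cross = zc$cross,
                  cond_consumption = NA, cond_supply = NA) {
    tibble::tibble(id_1 = id_a, id_2 = id_b, outcome = outcome, winner = winner,
                   crossing_n = zc$crossing_n, crossing_p = zc$crossing_p,
                   limiting_1 = limiting_a, limiting_2 = limiting_b,
                   cond_cross = cond_cross, cond_consumption = cond_consumption,
                   cond_supply = cond_supply, mode = mode)
  }

  if (zc$degenerate) return(row("degenerate"))

  if (!zc$cross) {
    # one population requires less of both resources: classic R* dominance
    dom <- if (a$n_star < b$n_star) list(id = id_a, p = a) else list(id = id_b, p = b)
    winner <- dom$id
    if (!is.null(supply)) {
      check_supply(supply)
      if (!(supply$s_n > dom$p$n_star && supply$s_p > dom$p$p_star)) {
        winner <- NA_character_ # supply supports neither population
      }
      return(row("exclusion", winner = winner, cond_supply = FALSE))
    }
    return(row("exclusion", winner = winner))
  }

  # at the crossing, the population with the lower N* sits on its own P* arm
  a_p_limited <- a$n_star < b$n_star
  lim_a <- if (a_p_limited) "P" else "N"
  lim_b <- if (a_p_limited) "N" else "P"
  p_lim <- if (a_p_limited) a else b
  n_lim <- if (a_p_limited) b else a

  if (rel_tie(a$pn_slope, b$pn_slope, tol)) {
    return(row("degenerate", limiting_a = lim_a, limiting_b = lim_b))
  }
  cond2 <- rel_gt(p_lim$pn_slope, n_lim$pn_slope, tol)

  if (is.null(supply)) {
    cond3 <- TRUE # slopes differ, so the wedge above both ZNGIs is non-empty
    outcome <- if (cond2) "stable_coexistence" else "unstable_coexistence"
    return(row(outcome, limiting_a = lim_a, limiting_b = lim_b,
               cond_consumption = cond2, cond_supply = cond3))
  }

  check_supply(supply)
  above <- supply$s_n > zc$crossing_n && supply$s_p > zc$crossing_p
  cond3 <- FALSE
  if (above) {
    sup_slope <- (supply$s_p - zc$crossing_p) / (supply$s_n - zc$crossing_n)
    lo <- min(a$pn_slope, b$pn_slope)
    hi <- max(a$pn_slope, b$pn_slope)
    if (rel_tie(sup_slope, lo, tol) || rel_tie(sup_slope, hi, tol)) {
      return(row("degenerate", limiting_a = lim_a, limiting_b = lim_b,
                 cond_consumption = cond2))
    }
    cond3 <- sup_slope > lo && sup_slope < hi
  }

  if (cond3 && cond2) {
    return(row("stable_coexistence", limiting_a = lim_a, limiting_b = lim_b,
               cond_consumption = cond2, cond_supply = cond3))
  }
  if (cond3 && !cond2) {
    return(row("unstable_coexistence", limiting_a = lim_a, limiting_b = lim_b,
               cond_consumption = cond2, cond_supply = cond3))
  }

  # exclusion: decide the winner from the supply position
  grows_a <- supply$s_n > a$n_star && supply$s_p > a$p_star
  grows_b <- supply$s_n > b$n_star && supply$s_p > b$p_star
  winner <- NA_character_
  if (grows_a && grows_b) {
    sup_slope <- (supply$s_p - zc$crossing_p) / (supply$s_n - zc$crossing_n)
    if (sup_slope > max(a$pn_slope, b$pn_slope)) {
      winner <- if (a$n_star < b$n_star) id_a else id_b # N effectively scarce
    } else {
      winner <- if (a$p_star < b$p_star) id_a else id_b # P effectively scarce
    }
  } else if (grows_a) {
    winner <- id_a
  } else if (grows_b) {
    winner <- id_b
  }
  row("exclusion", winner = winner, limiting_a = lim_a, limiting_b = lim_b,
      cond_consumption = cond2, cond_supply = cond3)
}

check_supply <- function(supply) {
  if (is.null(supply$s_n) || is.null(supply$s_p) ||
      supply$s_n <= 0 || supply$s_p <= 0) {
    stop("`supply` must have positive elements `s_n` and `s_p`", call. = FALSE)
  }
  invisible(TRUE)
}

#' Classify every population pair in a trait table
#'
#' Applies [classify_pair()] to every unordered pair of populations in scope
#' and tabulates the outcome proportions. Populations missing any of
#' `n_star`, `p_star`, `pn_slope` are skipped and listed.
#'
#' @param traits Trait table with `population_id`, `n_star`, `p_star`,
#'   `pn_slope`, and (for the non-default scopes) `environment`.
#' @param scope `"all"` (every pair), `"same_environment"` (pairs sharing a
#'   selection environment), or `"ancestors_only"` (pairs among populations
#'   with `environment == "A"`).
#' @param supply Optional supply point (list with `s_n`, `s_p`) applied to
#'   every pair; `NULL` for feasibility mode.
#' @param tol Relative tolerance for tie detection.
#' @return A list of class `pair_outcomes`: `pairs` (one row per pair, the
#'   [classify_pair()] columns), `summary` (counts and percentages per
#'   outcome class), `skipped` (character vector of skipped populations),
#'   `scope`, `mode`.
#' @export
enumerate_outcomes <- function(traits, scope = c("all", "same_environment",
                                                 "ancestors_only"),
                               supply = NULL, tol = 1e-6) {
  scope <- match.arg(scope)
  need <- c("population_id", "n_star", "p_star", "pn_slope")
  stopifnot(all(need %in% names(traits)))
  complete <- stats::complete.cases(traits[c("n_star", "p_star", "pn_slope")])
  skipped <- as.character(traits$population_id[!complete])
  tab <- traits[complete, ]
  if (scope == "ancestors_only") {
    stopifnot("environment" %in% names(tab))
    tab <- tab[tab$environment == "A", ]
  }
  if (nrow(tab) < 2) stop("need at least 2 populations with complete traits", call. = FALSE)

  idx <- utils::combn(nrow(tab), 2)
  if (scope == "same_environment") {
    stopifnot("environment" %in% names(tab))
    keep <- tab$environment[idx[1, ]] == tab$environment[idx[2, ]]
    idx <- idx[, keep, drop = FALSE]
  }
  pairs <- purrr::map_dfr(seq_len(ncol(idx)), function(k) {
    classify_pair(tab[idx[1, k], ], tab[idx[2, k], ], supply = supply, tol = tol)
  })
  summary <- pairs |>
    dplyr::count(.data$outcome, name = "n") |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    tidyr::complete(outcome = c("stable_coexistence", "unstable_coexistence",
                                "exclusion", "degenerate"),
                    fill = list(n = 0L, percent = 0)) |>
    dplyr::arrange(match(.data$outcome,
                         c("stable_coexistence", "unstable_coexistence",
                           "exclusion", "degenerate")))
  structure(list(pairs = pairs, summary = summary, skipped = skipped,
                 scope = scope, mode = if (is.null(supply)) "feasible" else "supply_point"),
            class = "pair_outcomes")
}

#' @export
print.pair_outcomes <- function(x, ...) {
  cat(sprintf("Pairwise competitive outcomes (%d pairs, scope = %s, mode = %s)\n",
              nrow(x$pairs), x$scope, x$mode))
  print(x$summary)
  if (length(x$skipped)) {
    cat("skipped (incomplete traits):", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.pair_outcomes <- function(x, ...) x$pairs

#' @export
glance.pair_outcomes <- function(x, ...) {
  x$summary |>
    dplyr::select("outcome", "percent") |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "percent") |>
    dplyr::mutate(n_pairs = nrow(x$pairs), scope = x$scope, mode = x$mode)
}

# --- mechanistic chemostat oracle -------------------------------------------

#' Simulate a two-resource chemostat community
#'
#' Mechanistic counterpart to the graphical classification: populations grow
#' on nitrogen and phosphorus under Liebig's law of the minimum
#' (`mu = min(Monod_N, Monod_P)`) in a chemostat with dilution rate `D`:
#' \deqn{dR_N/dt = D (s_N - R_N) - \sum_j q_{N,j} \mu_j B_j}
#' \deqn{dB_j/dt = B_j (\mu_j - D)}
#' Half-saturation constants are back-computed from each population's
#' measured `n_star`/`p_star` via [rstar_to_ks()]; consumption quotas default
#' to `q_N = 1`, `q_P = pn_slope` so that the biomass stoichiometry matches
#' the consumption-vector slope.
#'
#' @param pops Tibble with one row per population: `population_id`,
#'   `n_star`, `p_star`, `pn_slope`, and `mu_max_n`, `mu_max_p` (a single
#'   `mu_max` column is used for both if the per-resource ones are absent).
#' @param supply List with `s_n`, `s_p`: resource supply concentrations.
#' @param init_b Initial biomasses (recycled to the number of populations).
#' @param t_end Integration horizon in days.
#' @param D Dilution (mortality) rate, day⁻¹.
#' @param extinction_frac A population is extinct when its final biomass is
#'   below `extinction_frac` times its initial biomass.
#' @param n_times Number of output time points.
#' @return A list: `trajectory` (long tibble of state over time), `final`
#'   (final state), `persists` (named logical per population),
#'   `equilibrium_resources` (final `R_N`, `R_P`).
#' @export
simulate_chemostat <- function(pops, supply, init_b = 1, t_end = 2000,
                               D = 0.56, extinction_frac = 1e-6,
                               n_times = 9) {
  check_supply(supply)
  k <- nrow(pops)
  stopifnot(k >= 1, all(init_b >= 0))
  init_b <- rep_len(init_b, k)
  mu_n <- if ("mu_max_n" %in% names(pops)) pops$mu_max_n else pops$mu_max
  mu_p <- if ("mu_max_p" %in% names(pops)) pops$mu_max_p else pops$mu_max
  ks_n <- rstar_to_ks(pops$n_star, mu_n, m = D)
  ks_p <- rstar_to_ks(pops$p_star, mu_p, m = D)
  q_n <- rep(1, k)
  q_p <- pops$pn_slope

  deriv <- function(t, y, parms) {
    RN <- max(y[1], 0); RP <- max(y[2], 0)
    B <- pmax(y[-(1:2)], 0)
    mu <- pmin(mu_n * RN / (ks_n + RN), mu_p * RP / (ks_p + RP))
    list(c(D * (supply$s_n - RN) - sum(q_n * mu * B),
           D * (supply$s_p - RP) - sum(q_p * mu * B),
           B * (mu - D)))
  }
  y0 <- c(RN = supply$s_n, RP = supply$s_p,
          stats::setNames(init_b, paste0("B", seq_len(k))))
  times <- seq(0, t_end, length.out = n_times)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0) {
    stop("solver error: chemostat integration failed (istate = ",
         attr(sol, "istate")[1], ")", call. = FALSE)
  }
  final <- sol[nrow(sol), ]
  persists <- stats::setNames(
    final[paste0("B", seq_len(k))] > extinction_frac * init_b,
    as.character(pops$population_id))
  traj <- tibble::as_tibble(as.data.frame(sol)) |>
    tidyr::pivot_longer(-"time", names_to = "state", values_to = "value")
  list(trajectory = traj, final = final, persists = persists,
       equilibrium_resources = c(R_N = unname(final["RN"]),
                                 R_P = unname(final["RP"])))
}

#' Competitive verdict from repeated chemostat simulations
#'
#' Runs [simulate_chemostat()] for a pair of populations from several
#' initial biomass configurations and maps the persistence pattern to a
#' verdict: `stable_coexistence` when both populations persist from every
#' start, `unstable_coexistence` when the surviving set depends on the start
#' (a priority effect), `exclusion` when the same single population survives
#' from every start, and `washout` when both always go extinct. The first
#' two starts are the extreme asymmetric configurations (each population in
#' turn starting with a 10^4-fold advantage), which probe both basins of a
#' priority effect even when one basin is small; the remaining starts are
#' random log-uniform draws.
#'
#' @inheritParams simulate_chemostat
#' @param n_init Total number of initial-condition configurations (two
#'   extreme starts plus `n_init - 2` random draws).
#' @param seed Integer seed for the initial-condition draws (required).
#' @return A list: `verdict`, `survivors` (list of persistence vectors per
#'   start), `winner` (population id under exclusion, else `NA`).
#' @export
chemostat_verdict <- function(pops, supply, n_init = 10, seed, t_end = 2000,
                              D = 0.56, extinction_frac = 1e-6) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(nrow(pops) == 2)
  withr::local_seed(seed)
  inits <- rbind(c(10, 1e-3), c(1e-3, 10),
                 matrix(10^stats::runif(2 * max(n_init - 2, 0), -3, 1), ncol = 2))
  survivors <- vector("list", n_init)
  for (i in seq_len(n_init)) {
    sim <- simulate_chemostat(pops, supply, init_b = inits[i, ], t_end = t_end,
                              D = D, extinction_frac = extinction_frac,
                              n_times = 2)
    survivors[[i]] <- sim$persists
  }
  patterns <- unique(purrr::map_chr(survivors, \(s) paste(as.integer(s), collapse = "")))
  ids <- as.character(pops$population_id)
  if (length(patterns) > 1) {
    verdict <- "unstable_coexistence"; winner <- NA_character_
  } else if (patterns == "11") {
    verdict <- "stable_coexistence"; winner <- NA_character_
  } else if (patterns == "00") {
    verdict <- "washout"; winner <- NA_character_
  } else {
    verdict <- "exclusion"
    winner <- ids[which(survivors[[1]])]
  }
  list(verdict = verdict, survivors = survivors, winner = winner)
}
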