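GROWTH_COLS <- c("population_id", "resource", "level", "time_days", "rfu")
STOICH_COLS <- c("population_id", "molar_n", "molar_p", "cell_length_um")

#' Read a long-format growth-assay CSV
#'
#' Strictly validated comma-separated input (UTF-8, `.` decimal, header
#' required) with exactly the columns `population_id`, `resource`, `level`,
#' `time_days`, `rfu`.
#'
#' @param path Path to the CSV file.
#' @return A tibble of growth observations.
#' @export
read_growth_data <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!identical(sort(names(df)), sort(GROWTH_COLS))) {
    stop("schema error: expected columns {", paste(GROWTH_COLS, collapse = ", "),
         "}, found {", paste(names(df), collapse = ", "), "}", call. = FALSE)
  }
  df[GROWTH_COLS]
}

#' Read a stoichiometry/biovolume CSV
#'
#' Columns: `population_id`, `molar_n`, `molar_p`, `cell_length_um`.
#'
#' @param path Path to the CSV file.
#' @return A tibble.
#' @export
read_stoichiometry <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!identical(sort(names(df)), sort(STOICH_COLS))) {
    stop("schema error: expected columns {", paste(STOICH_COLS, collapse = ", "),
         "}, found {", paste(names(df), collapse = ", "), "}", call. = FALSE)
  }
  df[STOICH_COLS]
}

#' Validate a growth-observation table
#'
#' Checks schema, positivity, duplicate keys and gradient coverage. Returns
#' every violation found rather than stopping at the first.
#'
#' @param obs A growth-observation tibble ([read_growth_data()] schema).
#' @return A tibble with columns `severity` (`"error"`/`"warning"`),
#'   `check`, `detail`; zero rows when the table is clean.
#' @export
validate_growth_data <- function(obs) {
  v <- list()
  add <- function(severity, check, detail) {
    v[[length(v) + 1]] <<- tibble::tibble(severity = severity, check = check,
                                          detail = detail)
  }
  missing_cols <- setdiff(GROWTH_COLS, names(obs))
  if (length(missing_cols)) {
    add("error", "schema", paste("missing columns:", paste(missing_cols, collapse = ", ")))
    return(dplyr::bind_rows(v))
  }
  bad_rfu <- which(!is.finite(obs$rfu) | obs$rfu <= 0)
  if (length(bad_rfu)) {
    add("error", "positivity",
        paste("non-positive rfu at rows:", paste(utils::head(bad_rfu, 10), collapse = ", ")))
  }
  bad_t <- which(!is.finite(obs$time_days) | obs$time_days < 0)
  if (length(bad_t)) {
    add("error", "time", paste("negative time at rows:", paste(utils::head(bad_t, 10), collapse = ", ")))
  }
  dup <- duplicated(obs[c("population_id", "resource", "level", "time_days")])
  if (any(dup)) {
    add("error", "duplicate_keys",
        paste("duplicated (population, resource, level, time) at rows:",
              paste(utils::head(which(dup), 10), collapse = ", ")))
  }
  cov <- obs |>
    dplyr::group_by(.data$population_id, .data$resource) |>
    dplyr::summarise(n_levels = dplyr::n_distinct(.data$level), .groups = "drop") |>
    dplyr::filter(.data$n_levels < 3)
  if (nrow(cov)) {
    add("warning", "gradient_coverage",
        paste("fewer than 3 resource levels for:",
              paste(paste0(cov$population_id, "/", cov$resource), collapse = ", ")))
  }
  if (length(v)) dplyr::bind_rows(v) else {
    tibble::tibble(severity = character(), check = character(), detail = character())
  }
}

#' Validate a stoichiometry table
#'
#' @param stoich A stoichiometry tibble ([read_stoichiometry()] schema).
#' @return A violations tibble as in [validate_growth_data()].
#' @export
validate_stoichiometry <- function(stoich) {
  v <- list()
  missing_cols <- setdiff(STOICH_COLS, names(stoich))
  if (length(missing_cols)) {
    return(tibble::tibble(severity = "error", check = "schema",
                          detail = paste("missing columns:",
                                         paste(missing_cols, collapse = ", "))))
  }
  for (col in c("molar_n", "molar_p", "cell_length_um")) {
    bad <- which(!is.finite(stoich[[col]]) | stoich[[col]] <= 0)
    if (length(bad)) {
      v[[length(v) + 1]] <- tibble::tibble(
        severity = "error", check = "positivity",
        detail = paste0("non-positive ", col, " at rows: ",
                        paste(utils::head(bad, 10), collapse = ", ")))
    }
  }
  if (anyDuplicated(stoich$population_id)) {
    v[[length(v) + 1]] <- tibble::tibble(severity = "error", check = "duplicate_keys",
                                         detail = "duplicated population_id")
  }
  if (length(v)) dplyr::bind_rows(v) else {
    tibble::tibble(severity = character(), check = character(), detail = character())
  }
}

#' Fit growth models to every population in an observation table
#'
#' Fits a Monod curve per population for each nutrient/light assay and the
#' salt logistic for salt assays.
#'
#' @param obs Growth observations (`population_id`, `resource`, `level`,
#'   `time_days`, `rfu`); `resource` values `"N"`, `"P"`, `"light"` get
#'   Monod fits, `"salt"` gets the logistic.
#' @param m Mortality rate for derived R*.
#' @param control A [fit_control()].
#' @return A tibble with `population_id`, `resource`, `model` and a `fit`
#'   list-column of fit objects.
#' @export
fit_growth_curves <- function(obs, m = 0.56, control = fit_control()) {
  obs |>
    dplyr::group_by(.data$population_id, .data$resource) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::mutate(
      model = ifelse(.data$resource == "salt", "salt_logistic", "monod"),
      fit = purrr::map2(.data$data, .data$model, function(d, mdl) {
        if (mdl == "monod") fit_monod(d, m = m, control = control)
        else fit_salt(d, control = control)
      })) |>
    dplyr::select("population_id", "resource", "model", "fit")
}

#' Attach bootstrap intervals to every fit in a fit table
#'
#' Expands a single root seed into one reproducible sub-seed per fit.
#'
#' @param fits A fit table from [fit_growth_curves()].
#' @param n_iter Bootstrap iterations per fit.
#' @param seed Root integer seed.
#' @param level Confidence level.
#' @return The fit table with bootstrap-augmented fit objects.
#' @export
add_bootstrap <- function(fits, n_iter = 999L, seed, level = 0.95) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  sub_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, nrow(fits)))
  fits$fit <- purrr::map2(fits$fit, sub_seeds,
                          \(f, s) bootstrap_ci(f, n_iter = n_iter, seed = s,
                                               level = level))
  fits
}

resource_trait <- c(N = "n_star", P = "p_star", light = "i_star",
                    salt = "salt_tolerance")

#' Assemble the per-population trait table
#'
#' One row per population: minimum resource requirements with bootstrap CIs,
#' salt tolerance, maximum growth rates per resource, consumption-vector
#' slope and biovolume from stoichiometry, and lineage metadata when given.
#' Derived competitive abilities `c_n`, `c_p`, `c_i` (`1/R*`) are included.
#'
#' @param fits Fit table from [fit_growth_curves()] (optionally through
#'   [add_bootstrap()]).
#' @param stoichiometry Optional stoichiometry tibble.
#' @param lineage Optional tibble with `population_id`, `ancestor_id`,
#'   `environment` and optionally `diverse_flag`.
#' @return A trait tibble, one row per population.
#' @export
trait_table <- function(fits, stoichiometry = NULL, lineage = NULL) {
  rows <- purrr::pmap_dfr(fits, function(population_id, resource, model, fit) {
    trait <- resource_trait[[resource]]
    est <- unname(fit$derived_trait[1])
    ci <- fit$ci
    lo <- hi <- NA_real_
    if (!is.null(ci)) {
      key <- names(fit$derived_trait)[1]
      lo <- ci$ci_low[ci$term == key]
      hi <- ci$ci_high[ci$term == key]
    }
    mu <- if (model == "monod") unname(fit$estimate[["mu_max"]]) else unname(fit$estimate[["a"]])
    tibble::tibble(population_id = population_id, resource = resource,
                   trait = trait, estimate = est, ci_low = lo, ci_high = hi,
                   mu_max = mu)
  })
  wide <- rows |>
    tidyr::pivot_wider(
      id_cols = "population_id", names_from = "trait",
      values_from = c("estimate", "ci_low", "ci_high", "mu_max"),
      names_glue = "{trait}__{.value}")
  ren <- function(x) {
    x <- sub("^(.*)__estimate$", "\\1", x)
    x <- sub("^(.*)__ci_low$", "\\1_low", x)
    x <- sub("^(.*)__ci_high$", "\\1_high", x)
    x <- sub("^n_star__mu_max$", "mu_max_n", x)
    x <- sub("^p_star__mu_max$", "mu_max_p", x)
    x <- sub("^i_star__mu_max$", "mu_max_i", x)
    x <- sub("^salt_tolerance__mu_max$", "salt_a", x)
    x
  }
  names(wide) <- ren(names(wide))
  out <- wide
  if (!is.null(stoichiometry)) {
    out <- out |>
      dplyr::left_join(
        stoichiometry |>
          dplyr::mutate(pn_slope = consumption_vector(.data$molar_n, .data$molar_p),
                        biovolume = biovolume_from_length(.data$cell_length_um)) |>
          dplyr::select("population_id", "pn_slope", "biovolume"),
        by = "population_id")
  }
  if (!is.null(lineage)) {
    out <- dplyr::left_join(out, lineage, by = "population_id") |>
      dplyr::relocate(dplyr::any_of(c("population_id", "ancestor_id",
                                      "environment", "diverse_flag")))
  }
  if (all(c("n_star", "p_star", "i_star") %in% names(out))) {
    out <- dplyr::mutate(out,
                         c_n = competitive_ability(.data$n_star),
                         c_p = competitive_ability(.data$p_star),
                         c_i = competitive_ability(.data$i_star))
  }
  out
}

#' Descendant-minus-ancestor changes for every population and trait
#'
#' Pairs each descendant fit with the corresponding fit of its ancestor
#' (same resource) and applies [trait_change()].
#'
#' @param fits Bootstrap-augmented fit table ([add_bootstrap()]).
#' @param lineage Tibble with `population_id`, `ancestor_id`, `environment`.
#' @return A tibble with one row per descendant x trait.
#' @export
trait_changes <- function(fits, lineage) {
  stopifnot(all(c("population_id", "ancestor_id") %in% names(lineage)))
  meta <- lineage[c("population_id", "ancestor_id",
                    intersect("environment", names(lineage)))]
  fits <- dplyr::left_join(fits, meta, by = "population_id")
  desc <- dplyr::filter(fits, .data$population_id != .data$ancestor_id)
  purrr::pmap_dfr(desc, function(...) {
    r <- list(...)
    anc_fit <- fits$fit[fits$population_id == r$ancestor_id &
                          fits$resource == r$resource]
    if (length(anc_fit) != 1) {
      stop("no unique ancestor fit for ", r$population_id, " / ", r$resource,
           call. = FALSE)
    }
    tc <- trait_change(r$fit, anc_fit[[1]])
    tc$trait <- resource_trait[[r$resource]]
    dplyr::bind_cols(
      tibble::tibble(population_id = r$population_id,
                     ancestor_id = r$ancestor_id,
                     environment = if (!is.null(r$environment)) r$environment else NA),
      tc)
  })
}

#' Pipeline configuration
#'
#' @param m Mortality (chemostat dilution) rate, day⁻¹.
#' @param n_boot Bootstrap iterations per fit (study design value: 999).
#' @param ci_level Confidence level for all intervals.
#' @param seed Root seed; all stage randomness derives from it.
#' @param tol Relative tolerance for RCT tie detection.
#' @param supply_mode `"feasible"` (classify pairs by existence of a
#'   qualifying supply point) or `"point"` (use `supply`).
#' @param supply Supply point list (`s_n`, `s_p`) for `supply_mode = "point"`.
#' @param scenario A [scenario_config()] used to generate inputs when no
#'   files are given.
#' @param growth_csv,stoichiometry_csv,lineage_csv Optional input paths; when
#'   supplied they replace the synthetic scenario.
#' @param out_dir Output directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(m = 0.56, n_boot = 999L, ci_level = 0.95,
                            seed = 1L, tol = 1e-6,
                            supply_mode = c("feasible", "point"),
                            supply = NULL, scenario = scenario_config(seed = seed),
                            growth_csv = NULL, stoichiometry_csv = NULL,
                            lineage_csv = NULL, out_dir = tempfile("rstarevo_run_")) {
  supply_mode <- match.arg(supply_mode)
  if (supply_mode == "point") check_supply(supply)
  stopifnot(m > 0, n_boot >= 100, ci_level > 0, ci_level < 1, tol > 0)
  structure(list(m = m, n_boot = as.integer(n_boot), ci_level = ci_level,
                 seed = as.integer(seed), tol = tol, supply_mode = supply_mode,
                 supply = supply, scenario = scenario, growth_csv = growth_csv,
                 stoichiometry_csv = stoichiometry_csv, lineage_csv = lineage_csv,
                 out_dir = out_dir), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages end to end: obtain inputs (synthetic scenario or CSV
#' files), validate, fit growth curves, attach bootstrap intervals, assemble
#' the trait table, compute descendant-ancestor trait changes, run the
#' trade-off analyses (gleaner-opportunist tests, multiple regression of
#' competitive abilities, trait PCA), and classify all pairwise competitive
#' outcomes. Writes `traits.csv`, `trait_changes.csv`, `regressions.json`,
#' `pair_outcomes.csv`, `summary.json` and a deterministic `run_log.json`
#' (seed, config hash, stage counts) plus a timing log `pipeline.log` to
#' `config$out_dir`. Identical seed and config give byte-identical outputs
#' (timing log aside).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  stage <- function(msg) {
    log_lines <<- c(log_lines,
                    sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%OS2"), msg))
  }

  if (is.null(config$growth_csv)) {
    stage("simulate: generating synthetic scenario")
    scen <- generate_scenario(config$scenario)
    obs <- scen$observations
    stoich <- scen$stoichiometry
    lineage <- scen$truth[c("population_id", "ancestor_id", "environment",
                            "diverse_flag")]
  } else {
    stage("load: reading input CSVs")
    obs <- read_growth_data(config$growth_csv)
    stoich <- if (!is.null(config$stoichiometry_csv)) {
      read_stoichiometry(config$stoichiometry_csv)
    } else NULL
    lineage <- if (!is.null(config$lineage_csv)) {
      readr::read_csv(config$lineage_csv, show_col_types = FALSE)
    } else NULL
  }

  viol <- validate_growth_data(obs)
  if (any(viol$severity == "error")) {
    stop("schema error in growth data:\n",
         paste(viol$detail[viol$severity == "error"], collapse = "\n"),
         call. = FALSE)
  }
  if (!is.null(stoich)) {
    sv <- validate_stoichiometry(stoich)
    if (any(sv$severity == "error")) {
      stop("schema error in stoichiometry data:\n",
           paste(sv$detail[sv$severity == "error"], collapse = "\n"), call. = FALSE)
    }
  }
  stage(sprintf("validate: %d observations, %d warnings", nrow(obs),
                sum(viol$severity == "warning")))

  stage("fit-growth: fitting growth models")
  fits <- fit_growth_curves(obs, m = config$m)
  stage(sprintf("fit-growth: %d fits", nrow(fits)))

  stage(sprintf("bootstrap: %d iterations per fit", config$n_boot))
  fits <- add_bootstrap(fits, n_iter = config$n_boot, seed = config$seed,
                        level = config$ci_level)

  traits <- trait_table(fits, stoichiometry = stoich, lineage = lineage)
  readr::write_csv(traits, file.path(config$out_dir, "traits.csv"))
  stage(sprintf("traits: %d populations", nrow(traits)))

  changes <- NULL
  if (!is.null(lineage)) {
    changes <- trait_changes(fits, lineage)
    readr::write_csv(changes, file.path(config$out_dir, "trait_changes.csv"))
    stage(sprintf("trait-change: %d contrasts", nrow(changes)))
  }

  stage("tradeoffs: regressions and PCA")
  gleaner <- purrr::map_dfr(c("N", "P", "light"),
                            \(r) gleaner_opportunist_test(traits, r))
  tradeoff <- tradeoff_regression(traits, "c_p", c("c_n", "c_i", "biovolume"))
  pca <- trait_pca(traits, c("c_n", "c_p", "c_i", "biovolume"))
  regressions <- list(
    gleaner_opportunist = gleaner,
    tradeoff_multiple_regression = list(
      response = tradeoff$response,
      coefficients = tradeoff$coef,
      n = tradeoff$n,
      condition_number = tradeoff$condition_number,
      note = "no multiple-testing correction applied; per-trait intervals"),
    pca = list(loadings = as.data.frame(pca$loadings),
               variance = pca$variance))
  jsonlite::write_json(regressions, file.path(config$out_dir, "regressions.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  stage(sprintf("rct-classify: mode %s", config$supply_mode))
  supply <- if (config$supply_mode == "point") config$supply else NULL
  scopes <- c("all", if (!is.null(lineage)) c("same_environment", "ancestors_only"))
  outcomes <- purrr::map(stats::setNames(scopes, scopes),
                         \(s) enumerate_outcomes(traits, scope = s,
                                                 supply = supply, tol = config$tol))
  readr::write_csv(outcomes$all$pairs, file.path(config$out_dir, "pair_outcomes.csv"))

  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  config_hash <- rlang::hash(cfg_for_hash)
  summary <- list(
    seed = config$seed,
    config_hash = config_hash,
    supply_mode = config$supply_mode,
    n_populations = nrow(traits),
    outcome_percentages = purrr::map(outcomes, \(o) {
      stats::setNames(as.list(o$summary$percent), o$summary$outcome)
    }))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  run_log <- list(seed = config$seed, config_hash = config_hash,
                  n_observations = nrow(obs), n_fits = nrow(fits),
                  n_populations = nrow(traits),
                  n_trait_changes = if (!is.null(changes)) nrow(changes) else 0L,
                  n_pairs = nrow(outcomes$all$pairs))
  jsonlite::write_json(run_log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage(sprintf("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(log_lines, file.path(config$out_dir, "pipeline.log"))

  invisible(list(traits = traits, changes = changes, fits = fits,
                 gleaner = gleaner, tradeoff = tradeoff, pca = pca,
                 outcomes = outcomes, out_dir = config$out_dir,
                 config_hash = config_hash))
}
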