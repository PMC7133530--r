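#' Competitive ability for a resource
#'
#' Competitive ability is the inverse of the minimum resource requirement:
#' `1 / R*`. Lower R* means the population can keep growing at lower resource
#' levels, i.e. it is the stronger competitor for that resource.
#'
#' @param r_star Minimum resource requirement(s), > 0.
#' @return `1 / r_star`, in inverse resource units.
#' @examples
#' competitive_ability(c(0.5, 10))
#' @export
competitive_ability <- function(r_star) {
  if (any(r_star <= 0)) stop("`r_star` must be positive", call. = FALSE)
  1 / r_star
}

#' Descendant-minus-ancestor trait change with a bootstrap confidence interval
#'
#' Computes the change in a derived trait (R* or salt tolerance) between a
#' descendant and its ancestor. The sampling distribution of the difference
#' is formed by pairing independent bootstrap replicates of the two fits
#' (descendant replicate minus ancestor replicate); the 95% interval is the
#' 2.5th-97.5th percentile range of that distribution, and the change is
#' flagged significant when the interval excludes zero. Percent change is
#' reported on the point estimates.
#'
#' @param descendant,ancestor Growth fits (same model and trait) that have
#'   been augmented with [bootstrap_ci()].
#' @param trait Name of the trait column in the bootstrap replicate table;
#'   defaults to the fit's derived trait (`"rstar"` or `"salt_tolerance"`).
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `trait`, `ancestor_value`, `descendant_value`,
#'   `delta`, `ci_low`, `ci_high`, `significant`, `percent_change`.
#' @export
trait_change <- function(descendant, ancestor, trait = NULL, level = 0.95) {
  if (is.null(descendant$boot) || is.null(ancestor$boot)) {
    stop("insufficient uncertainty: run bootstrap_ci() on both fits first",
         call. = FALSE)
  }
  if (is.null(trait)) trait <- names(descendant$derived_trait)[1]
  if (!trait %in% names(descendant$boot) || !trait %in% names(ancestor$boot)) {
    stop("trait `", trait, "` has no bootstrap replicates in both fits",
         call. = FALSE)
  }
  point_d <- trait_point(descendant, trait)
  point_a <- trait_point(ancestor, trait)
  n <- min(nrow(descendant$boot), nrow(ancestor$boot))
  if (n < 50) stop("insufficient uncertainty: fewer than 50 usable replicate pairs",
                   call. = FALSE)
  deltas <- descendant$boot[[trait]][seq_len(n)] - ancestor$boot[[trait]][seq_len(n)]
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- stats::quantile(deltas, probs, names = FALSE)
  tibble::tibble(
    trait = trait,
    ancestor_value = point_a,
    descendant_value = point_d,
    delta = point_d - point_a,
    ci_low = ci[1],
    ci_high = ci[2],
    significant = ci[1] > 0 || ci[2] < 0,
    percent_change = 100 * (point_d - point_a) / point_a)
}

trait_point <- function(fit, trait) {
  if (trait %in% names(fit$derived_trait)) return(unname(fit$derived_trait[[trait]]))
  if (trait %in% names(fit$estimate)) return(unname(fit$estimate[[trait]]))
  stop("trait `", trait, "` not found in fit", call. = FALSE)
}

rstar_column <- function(resource) {
  switch(resource,
         N = "n_star", P = "p_star", light = "i_star",
         stop("`resource` must be one of 'N', 'P', 'light'", call. = FALSE))
}

mu_max_column <- function(resource) {
  switch(resource,
         N = "mu_max_n", P = "mu_max_p", light = "mu_max_i",
         stop("`resource` must be one of 'N', 'P', 'light'", call. = FALSE))
}

#' Test for a gleaner-opportunist trade-off
#'
#' A gleaner-opportunist trade-off is a positive association between the
#' maximum growth rate at saturating resource supply and the minimum resource
#' requirement R*: opportunists grow fast when the resource is abundant but
#' need more of it to persist. The test is an ordinary least-squares
#' regression of `mu_max` on R* across populations; a positive slope whose
#' 95% confidence interval excludes zero is reported as a trade-off.
#'
#' @param traits A trait table (one row per population) containing the
#'   relevant `*_star` and `mu_max_*` columns, e.g. from [trait_table()].
#' @param resource `"N"`, `"P"` or `"light"`.
#' @return A one-row tibble: `resource`, `slope`, `ci_low`, `ci_high`,
#'   `adj_r_squared`, `n`, `tradeoff_detected`.
#' @export
gleaner_opportunist_test <- function(traits, resource = c("N", "P", "light")) {
  resource <- match.arg(resource)
  xcol <- rstar_column(resource)
  ycol <- mu_max_column(resource)
  dat <- tibble::tibble(x = traits[[xcol]], y = traits[[ycol]]) |>
    tidyr::drop_na()
  if (nrow(dat) < 3) stop("need at least 3 populations with both traits", call. = FALSE)
  if (stats::sd(dat$x) == 0) {
    stop("rank-deficient design: predictor R* is constant across populations",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x, data = dat)
  ci <- stats::confint(fit, "x", level = 0.95)
  slope <- unname(stats::coef(fit)["x"])
  tibble::tibble(
    resource = resource,
    slope = slope,
    ci_low = ci[1],
    ci_high = ci[2],
    adj_r_squared = summary(fit)$adj.r.squared,
    n = nrow(dat),
    tradeoff_detected = slope > 0 && ci[1] > 0)
}

#' Multiple regression among (changes in) traits, with ancestor fixed effects
#'
#' Tests how one trait relates to others across populations while accounting
#' for shared ancestry. All trait variables are centred and scaled
#' (mean 0, sd 1) so partial slopes are comparable across traits; ancestor
#' identity enters as treatment-contrast indicators (first ancestor by sorted
#' label as reference). Partial-regression (added-variable) data are returned
#' for each predictor: residuals of the response and of that predictor, each
#' regressed on everything else in the model.
#'
#' @param traits Trait table with one row per population; must contain
#'   `ancestor_id`, the response and the predictors.
#' @param response Name of the response trait column.
#' @param predictors Character vector of predictor trait columns.
#' @return An object of class `tradeoff_fit`: list with `coef` (tibble of
#'   partial slopes, 95% CIs and p-values for the trait predictors), `partial`
#'   (added-variable plot data), `condition_number`, `n`, and the underlying
#'   `lm` fit. `tidy()` returns the coefficient table.
#' @export
tradeoff_regression <- function(traits, response, predictors) {
  stopifnot("ancestor_id" %in% names(traits))
  cols <- c(response, predictors)
  missing_cols <- setdiff(cols, names(traits))
  if (length(missing_cols)) {
    stop("trait columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dat <- traits |>
    dplyr::select(dplyr::all_of(c("ancestor_id", cols))) |>
    tidyr::drop_na()
  if (dplyr::n_distinct(dat$ancestor_id) < 2) {
    stop("need at least 2 ancestors represented", call. = FALSE)
  }
  dat <- dat |>
    dplyr::mutate(dplyr::across(dplyr::all_of(cols), ~ as.numeric(scale(.x))),
                  ancestor_id = factor(.data$ancestor_id,
                                       levels = sort(unique(.data$ancestor_id))))

  fml <- stats::reformulate(c(predictors, "ancestor_id"), response = response)
  fit <- stats::lm(fml, data = dat)

  X <- stats::model.matrix(fit)[, predictors, drop = FALSE]
  cond <- if (ncol(X) > 1) kappa(stats::cor(X), exact = TRUE) else 1
  if (cond > 1e3) {
    warning("predictors are nearly collinear (condition number ",
            format(cond, digits = 3), ")", call. = FALSE)
  }

  # predictors dropped by lm as aliased (exact collinearity) get NA rows
  est <- stats::coef(fit)[predictors]
  estimable <- predictors[!is.na(est)]
  ci <- matrix(NA_real_, length(predictors), 2,
               dimnames = list(predictors, NULL))
  ci[estimable, ] <- stats::confint(fit, estimable, level = 0.95)
  sm <- summary(fit)$coefficients
  pv <- stats::setNames(rep(NA_real_, length(predictors)), predictors)
  pv[estimable] <- sm[estimable, "Pr(>|t|)"]
  coef_tbl <- tibble::tibble(
    term = predictors,
    estimate = unname(est),
    ci_low = ci[, 1],
    ci_high = ci[, 2],
    p_value = unname(pv))

  partial <- purrr::map_dfr(predictors, function(p) {
    others <- setdiff(c(predictors, "ancestor_id"), p)
    ry <- stats::residuals(stats::lm(stats::reformulate(others, response), data = dat))
    rx <- stats::residuals(stats::lm(stats::reformulate(others, p), data = dat))
    tibble::tibble(predictor = p, x_resid = unname(rx), y_resid = unname(ry))
  })

  structure(list(coef = coef_tbl, partial = partial, condition_number = cond,
                 n = nrow(dat), response = response, lm = fit),
            class = "tradeoff_fit")
}

#' @export
tidy.tradeoff_fit <- function(x, ...) x$coef

#' @export
glance.tradeoff_fit <- function(x, ...) {
  s <- summary(x$lm)
  tibble::tibble(n = x$n, adj_r_squared = s$adj.r.squared,
                 sigma = s$sigma, condition_number = x$condition_number)
}

#' @export
print.tradeoff_fit <- function(x, ...) {
  cat("Trait trade-off regression (", x$response, " ~ ",
      paste(x$coef$term, collapse = " + "), " + ancestor)\n", sep = "")
  print(x$coef)
  invisible(x)
}

#' Principal component analysis of competitive abilities and cell size
#'
#' PCA on z-scaled traits via eigendecomposition of the correlation matrix.
#' Typical usage is on the competitive abilities `1/N*`, `1/P*`, `1/I*` and
#' cell biovolume to summarise the covariance structure of resource-use
#' phenotypes. Loadings follow the sign convention that the
#' largest-magnitude element of each axis is positive.
#'
#' @param traits Trait table, one row per population.
#' @param trait_cols Columns to include (complete cases only).
#' @return An object of class `trait_pca`: `loadings` (traits x axes matrix),
#'   `scores` (tibble, one row per population), `variance` (tibble of
#'   eigenvalues and variance-explained fractions, which sum to 1).
#' @export
trait_pca <- function(traits, trait_cols) {
  dat <- traits |>
    dplyr::select(dplyr::any_of("population_id"), dplyr::all_of(trait_cols)) |>
    tidyr::drop_na()
  if (nrow(dat) < 3) stop("need at least 3 complete-case populations", call. = FALSE)
  X <- as.matrix(dat[trait_cols])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate variance: constant trait column(s): ",
         paste(trait_cols[sds == 0], collapse = ", "), call. = FALSE)
  }
  Z <- scale(X)
  attr(Z, "scaled:center") <- attr(Z, "scaled:scale") <- NULL
  eig <- eigen(stats::cor(X), symmetric = TRUE)
  V <- eig$vectors
  # sign convention: largest-|loading| entry of each axis positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(trait_cols, paste0("PC", seq_len(ncol(V))))
  scores <- Z %*% V
  scores_tbl <- tibble::as_tibble(as.data.frame(scores))
  if ("population_id" %in% names(dat)) {
    scores_tbl <- dplyr::bind_cols(dat["population_id"], scores_tbl)
  }
  structure(list(
    loadings = V,
    scores = scores_tbl,
    variance = tibble::tibble(
      axis = colnames(V),
      eigenvalue = eig$values,
      var_explained = eig$values / sum(eig$values)),
    z = Z), class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("Trait PCA (", nrow(x$loadings), " traits)\n", sep = "")
  pc12 <- sum(x$variance$var_explained[1:min(2, nrow(x$variance))])
  cat(sprintf("  first two axes explain %.1f%% of the variance\n", 100 * pc12))
  print(round(x$loadings, 3))
  invisible(x)
}

#' @export
tidy.trait_pca <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$loadings), rownames = "trait") |>
    tidyr::pivot_longer(-"trait", names_to = "axis", values_to = "loading")
}

#' @export
glance.trait_pca <- function(x, ...) {
  tibble::tibble(n_traits = nrow(x$loadings),
                 pc12_var_explained = sum(x$variance$var_explained[1:2]))
}
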