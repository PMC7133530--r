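test_that("exponential growth rate is the log-linear slope", {
  expect_equal(exponential_growth_rate(0:2, c(100, 200, 400)), log(2))
  expect_equal(exponential_growth_rate(0:3, rep(55, 4)), 0)
  expect_equal(exponential_growth_rate(0:2, c(100, 150, 225)), log(1.5))
  expect_error(exponential_growth_rate(0, 100), "insufficient")
  expect_error(exponential_growth_rate(0:1, c(-1, 2)), "positive")
})

test_that("consumption vector is the scale-invariant P:N molar ratio", {
  expect_equal(consumption_vector(3, 3), 1)
  expect_equal(consumption_vector(16, 1), 0.0625)
  expect_equal(consumption_vector(16 * 7, 1 * 7), 0.0625)
  expect_error(consumption_vector(0, 1), "positive")
})

test_that("Monod fit recovers exact parameters from noiseless data", {
  obs <- noiseless_monod_obs(mu_max = 1.2, ks = 8)
  fit <- fit_monod(obs)
  expect_equal(unname(coef(fit)[["mu_max"]]), 1.2, tolerance = 1e-6)
  expect_equal(unname(coef(fit)[["ks"]]), 8, tolerance = 1e-6)
  expect_equal(unname(fit$derived_trait[["rstar"]]), rstar(1.2, 8),
               tolerance = 1e-6)
  expect_true(fit$persistent)
  # row order never matters
  fit2 <- fit_monod(obs[sample(nrow(obs)), ])
  expect_equal(coef(fit2), coef(fit))
})

test_that("one-stage Monod fit agrees with a two-stage oracle on exact data", {
  obs <- noiseless_monod_obs(mu_max = 1.35, ks = 12)
  one <- fit_monod(obs)
  # independent two-stage route: per-level log-linear slopes, then Monod NLS
  # on the slopes via a coarse grid + optim refinement
  rates <- growth_rates(obs)
  sse <- function(p) sum((rates$rate - monod_mu(rates$level, p[1], p[2]))^2)
  two <- optim(c(1, 10), sse, method = "L-BFGS-B", lower = c(1e-6, 1e-6),
               control = list(factr = 1e3))$par
  expect_equal(unname(coef(one)[["mu_max"]]), two[1], tolerance = 1e-4)
  expect_equal(unname(coef(one)[["ks"]]), two[2], tolerance = 1e-4)
})

test_that("shared-F0 estimation recovers the true initial fluorescence", {
  obs <- noiseless_monod_obs(mu_max = 1.2, ks = 8)
  fit <- fit_monod(obs, control = fit_control(estimate_f0 = TRUE))
  expect_equal(unname(coef(fit)[["f0"]]), 50, tolerance = 1e-5)
  expect_equal(unname(coef(fit)[["mu_max"]]), 1.2, tolerance = 1e-5)
})

test_that("non-persistent populations are flagged and carry no R*", {
  obs <- noiseless_monod_obs(mu_max = 0.4, ks = 8) # below m = 0.56
  fit <- fit_monod(obs)
  expect_false(fit$persistent)
  expect_true(is.na(fit$derived_trait[["rstar"]]))
})

test_that("Monod fit enforces its data preconditions", {
  obs <- noiseless_monod_obs()
  expect_error(fit_monod(dplyr::filter(obs, level < obs$level[3])), "levels")
  expect_error(fit_monod(dplyr::filter(obs, time_days == 0)), "time points")
  bad <- obs; bad$rfu[3] <- -1
  expect_error(fit_monod(bad), "positive")
  two_pop <- dplyr::mutate(obs, population_id = rep_len(c("x", "y"), nrow(obs)))
  expect_error(fit_monod(two_pop), "single")
})

test_that("salt fit recovers exact parameters and its defining half-maximum", {
  fit <- fit_salt(noiseless_salt_obs(a = 1.4, b = 2, c = 3))
  expect_equal(unname(coef(fit)), c(1.4, 2, 3), tolerance = 1e-6)
  a <- coef(fit)[["a"]]; cc <- coef(fit)[["c"]]
  expect_equal(salt_mu(cc, a, coef(fit)[["b"]], cc), a / 2)
  expect_false(fit$no_detectable_tolerance)
})

test_that("growth increasing with salt is flagged as no detectable tolerance", {
  obs <- noiseless_salt_obs(a = 1.4, b = 2, c = 3) |>
    dplyr::mutate(level = max(level) - level) # reverse the gradient
  fit <- fit_salt(obs)
  expect_true(fit$no_detectable_tolerance)
})

test_that("bootstrap is reproducible, collapses on noiseless data, needs a seed", {
  obs <- noiseless_monod_obs(mu_max = 1.2, ks = 8)
  fit <- fit_monod(obs)
  b1 <- bootstrap_ci(fit, n_iter = 100, seed = 11)
  b2 <- bootstrap_ci(fit, n_iter = 100, seed = 11)
  expect_identical(b1$boot, b2$boot)
  expect_identical(b1$ci, b2$ci)
  # zero noise: all replicates identical, CI width ~ 0
  width <- b1$ci$ci_high - b1$ci$ci_low
  expect_true(all(width < 1e-6))
  expect_equal(b1$n_discarded, 0)
  expect_false(b1$ci_unreliable)
  expect_error(bootstrap_ci(fit, n_iter = 100), "seed")
  expect_error(bootstrap_ci(fit, n_iter = 50, seed = 1), "at least 100")
})

test_that("bootstrap CIs are ordered and tidy/glance expose them", {
  set.seed(42)
  obs <- simulate_monod_series(1.2, 8, n_gradient, 0:3, sigma = 0.05)
  fit <- bootstrap_ci(fit_monod(obs), n_iter = 100, seed = 2)
  expect_true(all(fit$ci$ci_low <= fit$ci$ci_high))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "ci_low", "ci_high"))
  expect_setequal(td$term, c("mu_max", "ks", "rstar"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_boot + gl$n_discarded, 100)
})
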