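boot_fit_pair <- function(sigma = 0.05, ks_desc = 8, seed = 1) {
  withr::with_seed(seed, {
    oa <- simulate_monod_series(1.2, 8, n_gradient, 0:3, sigma = sigma)
    od <- simulate_monod_series(1.2, ks_desc, n_gradient, 0:3, sigma = sigma)
  })
  list(anc = bootstrap_ci(fit_monod(oa), n_iter = 100, seed = seed + 1000),
       desc = bootstrap_ci(fit_monod(od), n_iter = 100, seed = seed + 2000))
}

test_that("identical replicate sets give a null trait change", {
  fits <- boot_fit_pair(sigma = 0, seed = 3)
  tc <- trait_change(fits$anc, fits$anc)
  expect_equal(tc$delta, 0)
  expect_true(tc$ci_low <= 0 && tc$ci_high >= 0)
  expect_false(tc$significant)
})

test_that("trait change is antisymmetric in descendant and ancestor", {
  fits <- boot_fit_pair(sigma = 0.05, ks_desc = 5, seed = 4)
  fwd <- trait_change(fits$desc, fits$anc)
  rev <- trait_change(fits$anc, fits$desc)
  expect_equal(rev$delta, -fwd$delta)
  expect_equal(rev$ci_low, -fwd$ci_high)
  expect_equal(rev$ci_high, -fwd$ci_low)
  expect_equal(rev$significant, fwd$significant)
  # the significance flag is exactly "CI excludes zero"
  expect_equal(fwd$significant, fwd$ci_low > 0 || fwd$ci_high < 0)
})

test_that("trait change requires bootstrap replicates", {
  obs <- noiseless_monod_obs()
  expect_error(trait_change(fit_monod(obs), fit_monod(obs)), "bootstrap")
})

test_that("competitive ability is the inverse requirement", {
  expect_equal(competitive_ability(0.5), 2)
  expect_equal(competitive_ability(10), 0.1)
  r <- seq(0.2, 5, by = 0.2)
  expect_true(all(diff(competitive_ability(r)) < 0))
  expect_error(competitive_ability(0), "positive")
})

test_that("gleaner-opportunist regression matches closed-form OLS", {
  # exactly collinear points: perfect fit
  tab <- tibble::tibble(n_star = c(10, 20, 30, 40, 50),
                        mu_max_n = 0.02 * n_star + 1)
  # base R warns that a zero-residual fit makes its summary unreliable;
  # the point estimates checked here are exact
  g <- suppressWarnings(gleaner_opportunist_test(tab, "N"))
  expect_equal(g$slope, 0.02, tolerance = 1e-12)
  expect_equal(g$adj_r_squared, 1, tolerance = 1e-9)
  expect_true(g$tradeoff_detected)

  # 5-point toy table against hand-computed normal equations
  x <- c(2, 4, 5, 7, 9); y <- c(0.9, 1.3, 1.1, 1.6, 1.8)
  tab2 <- tibble::tibble(p_star = x, mu_max_p = y)
  g2 <- gleaner_opportunist_test(tab2, "P")
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(g2$slope, beta, tolerance = 1e-12)
  resid <- y - (mean(y) - beta * mean(x)) - beta * x
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  expect_equal(g2$adj_r_squared, 1 - (1 - r2) * 4 / 3, tolerance = 1e-12)
  se <- sqrt(sum(resid^2) / 3 / sum((x - mean(x))^2))
  expect_equal(g2$ci_low, beta - qt(0.975, 3) * se, tolerance = 1e-12)

  # permutation invariance
  g3 <- gleaner_opportunist_test(tab2[c(4, 1, 5, 2, 3), ], "P")
  expect_equal(g3, g2)
  expect_error(gleaner_opportunist_test(tibble::tibble(p_star = rep(1, 5),
                                                       mu_max_p = 1:5), "P"),
               "rank-deficient")
})

test_that("trade-off regression z-scales, recovers shared structure, flags collinearity", {
  set.seed(5)
  n <- 40
  latent <- rnorm(n)
  tab <- tibble::tibble(
    ancestor_id = rep(c("a1", "a2"), each = n / 2),
    d_nstar = latent + rnorm(n, sd = 0.4),
    d_pstar = latent + rnorm(n, sd = 0.4),
    d_istar = rnorm(n))
  fit <- tradeoff_regression(tab, "d_pstar", c("d_nstar", "d_istar"))
  co <- tidy(fit)
  sl <- co[co$term == "d_nstar", ]
  expect_gt(sl$estimate, 0)
  expect_gt(sl$ci_low, 0) # shared latent factor detected
  # partial-regression data exists for every predictor
  expect_setequal(unique(fit$partial$predictor), c("d_nstar", "d_istar"))
  # z-scaling: model frame columns have mean 0, sd 1
  mf <- fit$lm$model
  for (v in c("d_pstar", "d_nstar", "d_istar")) {
    expect_equal(mean(mf[[v]]), 0, tolerance = 1e-12)
    expect_equal(sd(mf[[v]]), 1, tolerance = 1e-12)
  }
  tab$d_dup <- tab$d_nstar + rnorm(n, sd = 1e-8)
  expect_warning(tradeoff_regression(tab, "d_pstar", c("d_nstar", "d_dup")),
                 "collinear")
  expect_error(tradeoff_regression(dplyr::mutate(tab, ancestor_id = "a1"),
                                   "d_pstar", "d_nstar"), "2 ancestors")
})

test_that("partial slopes cover zero for independent traits at the nominal rate", {
  set.seed(6)
  hits <- 0; runs <- 200
  for (i in 1:runs) {
    tab <- tibble::tibble(ancestor_id = rep(c("a1", "a2"), each = 10),
                          x = rnorm(20), z = rnorm(20), y = rnorm(20))
    co <- tidy(tradeoff_regression(tab, "y", c("x", "z")))
    hits <- hits + (co$ci_low[1] <= 0 && co$ci_high[1] >= 0)
  }
  expect_gt(hits / runs, 0.90)
  expect_lt(hits / runs, 0.99)
})

test_that("trait PCA has orthogonal reconstruction and unit-sum variance", {
  set.seed(7)
  tab <- tibble::tibble(population_id = paste0("p", 1:20),
                        c_n = rlnorm(20), c_p = rlnorm(20),
                        c_i = rlnorm(20), biovolume = rlnorm(20))
  pca <- trait_pca(tab, c("c_n", "c_p", "c_i", "biovolume"))
  expect_equal(sum(pca$variance$var_explained), 1, tolerance = 1e-12)
  S <- as.matrix(pca$scores[, -1])
  expect_equal(unname(S %*% t(pca$loadings)), unname(pca$z), tolerance = 1e-10)
  # sign convention: dominant loading of each axis is positive
  for (j in 1:4) expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
  # cross-check against prcomp up to sign
  pr <- prcomp(tab[, -1], scale. = TRUE)
  expect_equal(abs(unname(pca$loadings)), abs(unname(pr$rotation)),
               tolerance = 1e-9)
  expect_equal(pca$variance$eigenvalue, unname(pr$sdev^2), tolerance = 1e-9)
})

test_that("perfectly correlated traits load on a single axis", {
  tab <- tibble::tibble(a = 1:10, b = 2 * (1:10) + 3)
  pca <- trait_pca(tab, c("a", "b"))
  expect_equal(pca$variance$var_explained[1], 1, tolerance = 1e-12)
  expect_error(trait_pca(tibble::tibble(a = rep(1, 5), b = 1:5), c("a", "b")),
               "degenerate")
})
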