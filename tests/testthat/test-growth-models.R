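test_that("Monod curve has its defining values and limits", {
  expect_equal(monod_mu(0, mu_max = 1.0, ks = 5), 0)
  expect_equal(monod_mu(5, mu_max = 1.0, ks = 5), 0.5) # half-saturation
  expect_equal(monod_mu(40, mu_max = 1.12, ks = 10), 1.12 * 40 / 50)
  expect_error(monod_mu(-1, 1, 5), "non-negative")
  expect_error(monod_mu(1, -1, 5), "positive")
  expect_error(monod_mu(1, 1, 0), "positive")
})

test_that("Monod curve is increasing, concave and bounded by mu_max", {
  set.seed(1)
  for (i in 1:20) {
    mu <- runif(1, 0.5, 3); ks <- runif(1, 0.1, 100)
    R <- sort(runif(50, 0, 500))
    y <- monod_mu(R, mu, ks)
    expect_true(all(diff(y) > 0))
    expect_true(all(diff(diff(y) / diff(R)) < 1e-12)) # concave
    expect_true(all(y < mu))
  }
})

test_that("R* satisfies its closed form and defining equation", {
  expect_equal(rstar(mu_max = 1.12, ks = 10, m = 0.56), 10) # mu_max = 2m
  expect_error(rstar(mu_max = 0.50, ks = 10, m = 0.56), "non-persistent")
  # independent oracle: bracketed root of mu(R) - m on [0, 1000]
  root <- uniroot(function(R) monod_mu(R, 1.5, 20) - 0.56, c(0, 1000),
                  tol = 1e-12)$root
  expect_equal(rstar(1.5, 20, m = 0.56), root, tolerance = 1e-9)
  expect_equal(rstar(1.5, 20, m = 0.56), 0.56 * 20 / 0.94, tolerance = 1e-12)
})

test_that("R* responds monotonically to its parameters", {
  set.seed(2)
  for (i in 1:30) {
    mu <- runif(1, 0.7, 3); ks <- runif(1, 0.1, 50); m <- runif(1, 0.1, mu * 0.9)
    h <- 1e-6
    expect_gt(rstar(mu, ks, m + h), rstar(mu, ks, m))
    expect_gt(rstar(mu, ks + h, m), rstar(mu, ks, m))
    expect_lt(rstar(mu + h, ks, m), rstar(mu, ks, m))
    # unit-scale equivariance
    k <- runif(1, 0.1, 10)
    expect_equal(monod_mu(k * 7, mu, k * ks), monod_mu(7, mu, ks))
    expect_equal(rstar(mu, k * ks, m), k * rstar(mu, ks, m))
  }
})

test_that("kinetics inversion round-trips with R*", {
  expect_equal(rstar_to_ks(10, mu_max = 1.12), 10)
  expect_equal(rstar_to_ks(0.5, mu_max = 1.5), 0.5 * 0.94 / 0.56)
  set.seed(3)
  for (i in 1:20) {
    mu <- runif(1, 0.7, 3); r <- runif(1, 0.01, 50)
    expect_equal(rstar(mu, rstar_to_ks(r, mu)), r, tolerance = 1e-12)
  }
  expect_error(rstar_to_ks(1, mu_max = 0.5), "non-persistent")
})

test_that("salt logistic declines with salt and halves at c", {
  expect_equal(salt_mu(3, a = 1.4, b = 2, c = 3), 0.7)
  expect_equal(salt_mu(0, a = 1.4, b = 2, c = 3), 1.4 / (1 + exp(-6)))
  expect_lt(salt_mu(100, a = 1.4, b = 2, c = 3), 1e-6)
  set.seed(4)
  for (i in 1:20) {
    a <- runif(1, 0.5, 2); b <- runif(1, 0.5, 5); cc <- runif(1, 0.5, 8)
    expect_equal(salt_mu(cc, a, b, cc), a / 2)
    S <- sort(runif(20, 0, 12))
    expect_true(all(diff(salt_mu(S, a, b, cc)) < 0))
  }
  expect_error(salt_mu(-1, 1.4, 2, 3), "non-negative")
  expect_error(salt_mu(1, 1.4, -2, 3), "positive")
})

test_that("Eilers-Peeters curve is zero at darkness with one interior peak", {
  p <- ep_from_peak(mu_opt = 1.12, I_opt = 100, alpha = 0.05)
  expect_equal(eilers_peeters_mu(0, p$p1, p$p2, p$p3), 0)
  expect_equal(eilers_peeters_mu(100, p$p1, p$p2, p$p3), 1.12, tolerance = 1e-12)
  # numerical optimum agrees with the closed-form peak location
  opt <- optimize(function(I) eilers_peeters_mu(I, p$p1, p$p2, p$p3),
                  c(0, 1000), maximum = TRUE)
  expect_equal(opt$maximum, 100, tolerance = 1e-4)
  # monotone increasing below the optimum
  I <- seq(0, 100, length.out = 50)
  expect_true(all(diff(eilers_peeters_mu(I, p$p1, p$p2, p$p3)) > 0))
  expect_error(eilers_peeters_mu(1, p1 = -1, p2 = 0, p3 = 1), "invalid")
})

test_that("I* is the smaller root of mu(I) = m, and the Monod form matches R*", {
  expect_equal(istar(mu_max = 1.12, ks = 10), rstar(1.12, 10))
  p <- ep_from_peak(mu_opt = 1.12, I_opt = 100, alpha = 0.05)
  is <- istar(p1 = p$p1, p2 = p$p2, p3 = p$p3, m = 0.56)
  expect_equal(eilers_peeters_mu(is, p$p1, p$p2, p$p3), 0.56, tolerance = 1e-9)
  expect_lt(is, 100) # smaller root lies below the optimum
  expect_error(istar(p1 = p$p1, p2 = p$p2, p3 = p$p3, m = 2), "non-persistent")
  expect_error(istar(mu_max = 1, ks = 5, p1 = 1, p2 = 1, p3 = 1), "either")
})

test_that("biovolume assumes spherical cells and scales cubically", {
  expect_equal(biovolume_from_length(2), 4 * pi / 3)
  expect_equal(biovolume_from_length(10), 4 / 3 * pi * 125)
  expect_equal(biovolume_from_length(6) / biovolume_from_length(3), 8)
  expect_error(biovolume_from_length(0), "positive")
})
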