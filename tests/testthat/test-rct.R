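test_that("ZNGI crossing follows the L-shaped isocline geometry", {
  zc <- zngis_cross(list(n_star = 5, p_star = 0.5), list(n_star = 10, p_star = 0.25))
  expect_true(zc$cross)
  expect_equal(c(zc$crossing_n, zc$crossing_p), c(10, 0.5))
  # dominance: one population lower on both axes
  zc2 <- zngis_cross(list(n_star = 5, p_star = 0.5), list(n_star = 10, p_star = 0.6))
  expect_false(zc2$cross)
  expect_false(zc2$degenerate)
  # ties are degenerate, never resolved silently
  zc3 <- zngis_cross(list(n_star = 5, p_star = 0.5), list(n_star = 5, p_star = 0.5))
  expect_true(zc3$degenerate)
})

test_that("pair classification matches the three textbook configurations", {
  a <- list(population_id = "a", n_star = 5, p_star = 0.5, pn_slope = 0.05)
  b <- list(population_id = "b", n_star = 10, p_star = 0.25, pn_slope = 0.02)
  # supply inside the wedge spanned by the consumption vectors at (10, 0.5)
  supply <- list(s_n = 50, s_p = 1.9)
  out <- classify_pair(a, b, supply = supply)
  expect_equal(out$outcome, "stable_coexistence")
  expect_equal(out$limiting_1, "P") # lower N* population is P-limited
  expect_equal(out$limiting_2, "N")
  # a P-rich supply above the wedge leaves N effectively scarce: the better
  # N competitor excludes (interior equilibrium infeasible there)
  rich <- classify_pair(a, b, supply = list(s_n = 50, s_p = 5))
  expect_equal(rich$outcome, "exclusion")
  expect_equal(rich$winner, "a")

  a2 <- a; a2$pn_slope <- 0.02; b2 <- b; b2$pn_slope <- 0.05
  expect_equal(classify_pair(a2, b2, supply = supply)$outcome,
               "unstable_coexistence")

  b3 <- list(population_id = "b", n_star = 10, p_star = 0.6, pn_slope = 0.02)
  out3 <- classify_pair(a, b3, supply = supply)
  expect_equal(out3$outcome, "exclusion")
  expect_equal(out3$winner, "a")

  expect_equal(classify_pair(a, a)$outcome, "degenerate")
})

test_that("classification is symmetric and invariant to unit rescaling", {
  pairs <- generate_rct_pairs(25, seed = 9)
  for (i in seq_len(nrow(pairs))) {
    pr <- pair_from_row(pairs[i, ])
    fwd <- classify_pair(pr$a, pr$b, supply = pr$supply)
    rev <- classify_pair(pr$b, pr$a, supply = pr$supply)
    expect_equal(rev$outcome, fwd$outcome)
    expect_equal(rev$winner, fwd$winner)
    # rescale N by kn and P by kp consistently everywhere
    kn <- 3.7; kp <- 0.21
    resc <- function(p) list(population_id = p$population_id,
                             n_star = kn * p$n_star, p_star = kp * p$p_star,
                             pn_slope = p$pn_slope * kp / kn)
    sc <- classify_pair(resc(pr$a), resc(pr$b),
                        supply = list(s_n = kn * pr$supply$s_n,
                                      s_p = kp * pr$supply$s_p))
    expect_equal(sc$outcome, fwd$outcome)
    expect_equal(sc$winner, fwd$winner)
  }
})

test_that("feasibility mode reports coexistence when a qualifying supply exists", {
  a <- list(population_id = "a", n_star = 5, p_star = 0.5, pn_slope = 0.05)
  b <- list(population_id = "b", n_star = 10, p_star = 0.25, pn_slope = 0.02)
  out <- classify_pair(a, b)
  expect_equal(out$outcome, "stable_coexistence")
  expect_equal(out$mode, "feasible")
  a$pn_slope <- 0.02; b$pn_slope <- 0.05
  expect_equal(classify_pair(a, b)$outcome, "unstable_coexistence")
})

test_that("enumerate_outcomes covers all pairs and reports degeneracy", {
  fx <- generate_rct_fixture("ancestral_1_4_5", verify = FALSE)
  eo <- enumerate_outcomes(fx$traits, scope = "ancestors_only")
  expect_equal(nrow(eo$pairs), 10) # 5 choose 2
  pct <- setNames(eo$summary$percent, eo$summary$outcome)
  expect_equal(unname(pct[c("stable_coexistence", "unstable_coexistence",
                            "exclusion")]), c(10, 40, 50))
  # identical populations: everything degenerate
  same <- tibble::tibble(population_id = paste0("p", 1:4), n_star = 5,
                         p_star = 0.5, pn_slope = 0.05)
  eo2 <- enumerate_outcomes(same)
  expect_equal(eo2$summary$percent[eo2$summary$outcome == "degenerate"], 100)
  # populations with missing traits are skipped and reported
  with_na <- dplyr::bind_rows(same, tibble::tibble(population_id = "p5",
                                                   n_star = NA_real_,
                                                   p_star = 1, pn_slope = 0.1))
  expect_equal(enumerate_outcomes(with_na)$skipped, "p5")
})

test_that("single-population chemostat equilibrates at its R*", {
  pop <- tibble::tibble(population_id = "solo", n_star = 5, p_star = 2,
                        pn_slope = 0.5, mu_max_n = 1.12, mu_max_p = 1.12)
  # supply above the ZNGI: persists, and the limiting resource is drawn
  # down to the population's minimum requirement
  sim <- simulate_chemostat(pop, supply = list(s_n = 40, s_p = 30), init_b = 1)
  expect_true(sim$persists[["solo"]])
  # N is limiting here (consumption of N large relative to its excess supply)
  expect_equal(unname(sim$equilibrium_resources[["R_N"]]), 5, tolerance = 0.01)
  # supply below the ZNGI: washes out
  sim2 <- simulate_chemostat(pop, supply = list(s_n = 3, s_p = 30), init_b = 1)
  expect_false(sim2$persists[["solo"]])
})

test_that("chemostat verdicts match the constructed fixtures", {
  expected <- c(stable = "stable_coexistence",
                unstable = "unstable_coexistence",
                exclusion = "exclusion")
  for (kind in names(expected)) {
    fx <- generate_rct_fixture(kind, verify = FALSE)
    v <- chemostat_verdict(fx$traits, fx$supply, seed = 21)
    expect_equal(v$verdict, expected[[kind]])
  }
  fx <- generate_rct_fixture("exclusion", verify = FALSE)
  v <- chemostat_verdict(fx$traits, fx$supply, seed = 22)
  expect_equal(v$winner, "dominant")
  expect_error(chemostat_verdict(fx$traits, fx$supply), "seed")
})

test_that("the diverged-descendants pattern classifies as constructed", {
  fx <- generate_rct_fixture("fig6_pattern", verify = FALSE)
  tr <- fx$traits
  # the two descendants coexist stably at the chosen supply point
  ds <- classify_pair(tr[2, ], tr[3, ], supply = fx$supply)
  expect_equal(ds$outcome, "stable_coexistence")
  # neither descendant can coexist with the ancestor
  expect_equal(classify_pair(tr[1, ], tr[2, ])$outcome, "exclusion")
  expect_equal(classify_pair(tr[1, ], tr[3, ])$outcome, "exclusion")
})
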