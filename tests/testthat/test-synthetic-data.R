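test_that("the default scenario reproduces the study design", {
  scen <- generate_scenario(scenario_config(seed = 3))
  # 5 ancestors + 7 x 5 descendants - 3 lost = 37 populations
  expect_equal(nrow(scen$truth), 37)
  expect_equal(sum(scen$truth$environment == "A"), 5)
  expect_equal(sum(scen$truth$diverse_flag & scen$truth$environment == "A"), 1)
  # 4 assays x 10 levels x 4 days per population
  expect_equal(nrow(scen$observations), 37 * 4 * 10 * 4)
  expect_setequal(unique(scen$observations$resource), c("N", "P", "light", "salt"))
  # every descendant's ancestor exists
  expect_true(all(scen$truth$ancestor_id %in%
                    scen$truth$population_id[scen$truth$environment == "A"]))
  # truths are persistent by construction
  expect_true(all(scen$truth$mu_max_n > 0.56 & scen$truth$mu_max_p > 0.56))
})

test_that("generation is deterministic in the seed", {
  s1 <- generate_scenario(scenario_config(seed = 12))
  s2 <- generate_scenario(scenario_config(seed = 12))
  s3 <- generate_scenario(scenario_config(seed = 13))
  expect_identical(s1$observations, s2$observations)
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(s1$observations, s3$observations))
})

test_that("generated data satisfies the estimation schema with no findings", {
  scen <- generate_scenario(scenario_config(seed = 5))
  expect_equal(nrow(validate_growth_data(scen$observations)), 0)
  expect_equal(nrow(validate_stoichiometry(scen$stoichiometry)), 0)
})

test_that("noiseless truths round-trip through the fitting pipeline", {
  cfg <- scenario_config(seed = 8, sigma = 0, lost_populations = 0L,
                         n_ancestors = 2L, environments = c("P", "S"))
  scen <- generate_scenario(cfg)
  for (pid in scen$truth$population_id) {
    tr <- scen$truth[scen$truth$population_id == pid, ]
    obs_p <- dplyr::filter(scen$observations, population_id == pid, resource == "P")
    fit <- fit_monod(obs_p)
    expect_equal(unname(coef(fit)[["mu_max"]]), tr$mu_max_p, tolerance = 1e-5)
    expect_equal(unname(coef(fit)[["ks"]]), tr$ks_p, tolerance = 1e-5)
    obs_s <- dplyr::filter(scen$observations, population_id == pid, resource == "salt")
    fs <- fit_salt(obs_s)
    expect_equal(unname(coef(fs)[["c"]]), tr$salt_c, tolerance = 1e-4)
  }
  # P-limitation lowers true P* relative to the ancestor in every line
  p_desc <- dplyr::filter(scen$truth, environment == "P")
  p_anc <- scen$truth[match(p_desc$ancestor_id, scen$truth$population_id), ]
  expect_true(all(p_desc$p_star < p_anc$p_star))
  # salt selection raises true tolerance
  s_desc <- dplyr::filter(scen$truth, environment == "S")
  s_anc <- scen$truth[match(s_desc$ancestor_id, scen$truth$population_id), ]
  expect_true(all(s_desc$salt_c > s_anc$salt_c))
})

test_that("null pairs share the truth but not the noise", {
  np <- generate_null_pair(scenario_config(seed = 31), resource = "P")
  expect_identical(np$obs_1$level, np$obs_2$level)
  expect_false(identical(np$obs_1$rfu, np$obs_2$rfu))
  np2 <- generate_null_pair(scenario_config(seed = 32), resource = "P")
  expect_false(identical(np$obs_1$rfu, np2$obs_1$rfu))
})

test_that("random pair generation keeps margins away from degeneracy", {
  pairs <- generate_rct_pairs(50, seed = 14)
  rel <- function(x, y) abs(x - y) / pmax(x, y)
  expect_true(all(rel(pairs$n_star_1, pairs$n_star_2) > 0.2))
  expect_true(all(rel(pairs$p_star_1, pairs$p_star_2) > 0.2))
  expect_true(all(rel(pairs$pn_slope_1, pairs$pn_slope_2) > 0.2))
  # supply above both ZNGIs in every pair
  expect_true(all(pairs$s_n > pmax(pairs$n_star_1, pairs$n_star_2)))
  expect_true(all(pairs$s_p > pmax(pairs$p_star_1, pairs$p_star_2)))
  # no degenerate classifications
  for (i in seq_len(nrow(pairs))) {
    pr <- pair_from_row(pairs[i, ])
    expect_false(classify_pair(pr$a, pr$b, supply = pr$supply)$outcome ==
                   "degenerate")
  }
})

test_that("fixture generation self-verifies against classifier and oracle", {
  expect_silent(fx <- generate_rct_fixture("stable", verify = TRUE))
  expect_equal(classify_pair(fx$traits[1, ], fx$traits[2, ],
                             supply = fx$supply)$outcome, "stable_coexistence")
  expect_silent(generate_rct_fixture("ancestral_1_4_5", verify = TRUE))
})
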