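# shared fixtures built in code: default assay design and quick simulators

default_design <- scenario_config()

n_gradient <- default_design$gradients$N
p_gradient <- default_design$gradients$P
salt_gradient <- default_design$gradients$salt

noiseless_monod_obs <- function(mu_max = 1.2, ks = 8, levels = n_gradient) {
  simulate_monod_series(mu_max, ks, levels, times = 0:3, f0 = 50, sigma = 0)
}

noiseless_salt_obs <- function(a = 1.4, b = 2, c = 3, levels = salt_gradient) {
  simulate_salt_series(a, b, c, levels, times = 0:3, f0 = 50, sigma = 0)
}

pair_from_row <- function(p) {
  list(
    a = list(population_id = "a", n_star = p$n_star_1, p_star = p$p_star_1,
             pn_slope = p$pn_slope_1),
    b = list(population_id = "b", n_star = p$n_star_2, p_star = p$p_star_2,
             pn_slope = p$pn_slope_2),
    supply = list(s_n = p$s_n, s_p = p$s_p))
}

pair_traits_tbl <- function(pr) {
  tibble::tibble(
    population_id = c(pr$a$population_id, pr$b$population_id),
    n_star = c(pr$a$n_star, pr$b$n_star),
    p_star = c(pr$a$p_star, pr$b$p_star),
    pn_slope = c(pr$a$pn_slope, pr$b$pn_slope),
    mu_max_n = 1.12, mu_max_p = 1.12)
}
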