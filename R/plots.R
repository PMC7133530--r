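#' @export
autoplot.monod_fit <- function(object, n_grid = 200, ...) {
  rates <- growth_rates(object$data)
  grid <- tibble::tibble(
    level = seq(0, max(rates$level), length.out = n_grid),
    mu = monod_mu(.data$level, object$estimate[["mu_max"]], object$estimate[["ks"]]))
  p <- ggplot2::ggplot(rates, ggplot2::aes(x = .data$level, y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$mu), colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$m, linetype = "dashed") +
    ggplot2::labs(x = "resource level", y = "growth rate (per day)",
                  title = "Monod fit (dashed: mortality rate)")
  if (object$persistent) {
    p <- p + ggplot2::geom_vline(xintercept = object$derived_trait[["rstar"]],
                                 linetype = "dotted", colour = "firebrick")
  }
  p
}

#' @export
autoplot.salt_fit <- function(object, n_grid = 200, ...) {
  grid <- tibble::tibble(
    level = seq(min(object$rates$level), max(object$rates$level),
                length.out = n_grid),
    mu = salt_mu(.data$level, object$estimate[["a"]], object$estimate[["b"]],
                 object$estimate[["c"]]))
  ggplot2::ggplot(object$rates, ggplot2::aes(x = .data$level, y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$mu), colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$estimate[["c"]],
                        linetype = "dotted", colour = "firebrick") +
    ggplot2::labs(x = "salt (g/L)", y = "growth rate (per day)",
                  title = "Salt-tolerance fit (dotted: half-maximum c)")
}

#' @export
autoplot.trait_pca <- function(object, ...) {
  load_tbl <- tidy(object) |> dplyr::filter(.data$axis %in% c("PC1", "PC2")) |>
    tidyr::pivot_wider(names_from = "axis", values_from = "loading")
  scale_arrows <- 2.5
  p <- ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_segment(data = load_tbl,
                          ggplot2::aes(x = 0, y = 0,
                                       xend = scale_arrows * .data$PC1,
                                       yend = scale_arrows * .data$PC2),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "firebrick") +
    ggplot2::geom_text(data = load_tbl,
                       ggplot2::aes(x = scale_arrows * 1.12 * .data$PC1,
                                    y = scale_arrows * 1.12 * .data$PC2,
                                    label = .data$trait),
                       colour = "firebrick", size = 3)
  ve <- object$variance$var_explained
  p + ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
                    y = sprintf("PC2 (%.1f%%)", 100 * ve[2]))
}

#' Plot zero-net-growth isoclines, consumption vectors and a supply point
#'
#' The nitrogen-phosphorus resource plane for a small set of populations:
#' each population's L-shaped ZNGI (solid), its consumption vector through
#' the ZNGI corner (dashed), and optionally the supply point.
#'
#' @param traits Trait table with `population_id`, `n_star`, `p_star`,
#'   `pn_slope` (typically 2-3 populations).
#' @param supply Optional list with `s_n`, `s_p`.
#' @return A ggplot object.
#' @export
plot_zngi <- function(traits, supply = NULL) {
  n_max <- max(traits$n_star, if (!is.null(supply)) supply$s_n) * 1.15
  p_max <- max(traits$p_star, if (!is.null(supply)) supply$s_p) * 1.15
  zngi <- traits |>
    dplyr::group_by(.data$population_id) |>
    dplyr::reframe(x = c(.data$n_star, .data$n_star, n_max),
                   y = c(p_max, .data$p_star, .data$p_star))
  cons <- traits |>
    dplyr::mutate(
      xend = pmin(n_max, .data$n_star + (p_max - .data$p_star) / .data$pn_slope),
      yend = .data$p_star + .data$pn_slope * (.data$xend - .data$n_star))
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = zngi,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$population_id)) +
    ggplot2::geom_segment(data = cons,
                          ggplot2::aes(x = .data$n_star, y = .data$p_star,
                                       xend = .data$xend, yend = .data$yend,
                                       colour = .data$population_id),
                          linetype = "dashed") +
    ggplot2::labs(x = "nitrogen (umol/L)", y = "phosphorus (umol/L)",
                  colour = "population")
  if (!is.null(supply)) {
    p <- p + ggplot2::annotate("point", x = supply$s_n, y = supply$s_p,
                               size = 3, colour = "goldenrod")
  }
  p
}

#' Plot trait changes per selection environment
#'
#' Descendant-minus-ancestor changes with their bootstrap intervals, one
#' panel per trait, populations grouped by selection environment.
#'
#' @param changes Output of [trait_changes()].
#' @return A ggplot object.
#' @export
plot_trait_changes <- function(changes) {
  ggplot2::ggplot(changes,
                  ggplot2::aes(x = .data$environment, y = .data$delta,
                               colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             position = ggplot2::position_jitter(width = 0.15,
                                                                 height = 0),
                             fatten = 1.5) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = "selection environment",
                  y = "descendant - ancestor trait change")
}
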