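#' Monod resource-dependent growth rate
#'
#' Saturating (hyperbolic) dependence of per-capita population growth rate on
#' the concentration of a single limiting resource:
#' \deqn{\mu(R) = \mu_{max} \frac{R}{k_s + R}}
#'
#' @param R Resource concentration(s), same units as `ks` (µmol L⁻¹ for
#'   dissolved nutrients, µmol photons m⁻² s⁻¹ for irradiance). Must be
#'   non-negative.
#' @param mu_max Maximum population growth rate (day⁻¹), > 0.
#' @param ks Half-saturation constant (resource units), > 0. Growth is
#'   `mu_max / 2` at `R = ks`.
#'
#' @return Growth rate(s) in day⁻¹; strictly increasing in `R` and bounded
#'   above by `mu_max`.
#' @examples
#' monod_mu(c(0, 5, 50), mu_max = 1.0, ks = 5)
#' @family growth models
#' @export
monod_mu <- function(R, mu_max, ks) {
  check_monod_params(mu_max, ks)
  if (any(R < 0)) stop("resource concentration `R` must be non-negative", call. = FALSE)
  mu_max * R / (ks + R)
}

#' Minimum resource requirement R*
#'
#' The resource concentration at which Monod growth exactly balances a
#' constant per-capita mortality rate `m` (in a chemostat, the dilution
#' rate). Solving \eqn{\mu(R^*) = m} gives
#' \deqn{R^* = \frac{m \, k_s}{\mu_{max} - m}.}
#' Populations with `mu_max <= m` wash out at any resource level and have no
#' finite R*.
#'
#' @inheritParams monod_mu
#' @param m Mortality (dilution) rate in day⁻¹; defaults to 0.56, the
#'   chemostat dilution rate of the selection experiment the package emulates.
#'
#' @return R* in the units of `ks`. Satisfies
#'   `monod_mu(rstar(...), mu_max, ks) == m` to machine precision.
#' @examples
#' rstar(mu_max = 1.12, ks = 10) # mu_max = 2 m, so R* = ks
#' @family growth models
#' @export
rstar <- function(mu_max, ks, m = 0.56) {
  check_monod_params(mu_max, ks)
  if (any(m <= 0)) stop("mortality rate `m` must be positive", call. = FALSE)
  if (any(mu_max <= m)) {
    stop("non-persistent: `mu_max` must exceed the mortality rate `m` for R* to exist",
         call. = FALSE)
  }
  m * ks / (mu_max - m)
}

#' Invert R* back to a half-saturation constant
#'
#' Algebraic inverse of [rstar()]: given a population's minimum resource
#' requirement and maximum growth rate, recover the half-saturation constant
#' `ks = R* (mu_max - m) / m`. Used to parameterize the mechanistic chemostat
#' model from measured traits; round-trips exactly with [rstar()].
#'
#' @param r_star Minimum resource requirement (resource units), > 0.
#' @inheritParams rstar
#' @return Half-saturation constant in the units of `r_star`.
#' @examples
#' rstar_to_ks(10, mu_max = 1.12) # mu_max = 2 m, so ks = R*
#' @family growth models
#' @export
rstar_to_ks <- function(r_star, mu_max, m = 0.56) {
  if (any(r_star <= 0)) stop("`r_star` must be positive", call. = FALSE)
  if (any(m <= 0)) stop("mortality rate `m` must be positive", call. = FALSE)
  if (any(mu_max <= m)) {
    stop("non-persistent: `mu_max` must exceed `m`", call. = FALSE)
  }
  r_star * (mu_max - m) / m
}

#' Logistic decline of growth rate with salt concentration
#'
#' Simplified logistic dose-response for growth over a salt gradient:
#' \deqn{\mu(S) = \frac{a}{1 + e^{b (S - c)}}}
#' with `b > 0` so growth declines with salt. `a` is the maximum growth rate
#' (approached at zero salt), `b` the steepness of the decline (L g⁻¹), and
#' `c` the salt tolerance: the concentration (g L⁻¹) at which growth is half
#' its maximum, `salt_mu(c, a, b, c) == a / 2` exactly.
#'
#' @param S Salt concentration(s) in g L⁻¹, non-negative.
#' @param a Maximum growth rate at zero salt (day⁻¹), > 0.
#' @param b Steepness of decline (L g⁻¹), > 0.
#' @param c Salt concentration at half-maximal growth (g L⁻¹), > 0.
#' @return Growth rate(s) in day⁻¹, non-increasing in `S`.
#' @examples
#' salt_mu(c(0, 3, 10), a = 1.4, b = 2, c = 3)
#' @family growth models
#' @export
salt_mu <- function(S, a, b, c) {
  check_salt_params(a, b, c)
  if (any(S < 0)) stop("salt concentration `S` must be non-negative", call. = FALSE)
  a / (1 + exp(b * (S - c)))
}

#' Eilers-Peeters photoinhibition light-response curve
#'
#' Unimodal dependence of growth on irradiance:
#' \deqn{\mu(I) = \frac{I}{p_1 I^2 + p_2 I + p_3}}
#' Zero at `I = 0`, rising to a single interior maximum at
#' `I_opt = sqrt(p3 / p1)` with height `mu_opt = 1 / (2 sqrt(p1 p3) + p2)`,
#' then declining (photoinhibition). The initial slope at the origin is
#' `1 / p3`. Requires `p1 > 0`, `p3 > 0` and `2 sqrt(p1 p3) + p2 > 0` so that
#' the curve is positive with an interior optimum.
#'
#' @param I Irradiance(s), µmol photons m⁻² s⁻¹, non-negative.
#' @param p1,p2,p3 Shape coefficients (see Details above).
#' @return Growth rate(s) in day⁻¹.
#' @examples
#' p <- ep_from_peak(mu_opt = 1.12, I_opt = 100, alpha = 0.05)
#' eilers_peeters_mu(c(0, 50, 100, 400), p$p1, p$p2, p$p3)
#' @family growth models
#' @export
eilers_peeters_mu <- function(I, p1, p2, p3) {
  check_ep_params(p1, p2, p3)
  if (any(I < 0)) stop("irradiance `I` must be non-negative", call. = FALSE)
  I / (p1 * I^2 + p2 * I + p3)
}

#' Construct Eilers-Peeters coefficients from interpretable quantities
#'
#' Maps (maximum growth rate `mu_opt`, optimal irradiance `I_opt`, initial
#' slope `alpha`) to the (p1, p2, p3) coefficients of
#' [eilers_peeters_mu()]: `p3 = 1/alpha`, `p1 = p3 / I_opt^2`,
#' `p2 = 1/mu_opt - 2 sqrt(p1 p3)`. Requires `alpha * I_opt > mu_opt` (the
#' initial tangent must overshoot the peak) for a valid unimodal curve.
#'
#' @param mu_opt Maximum growth rate at the optimum (day⁻¹), > 0.
#' @param I_opt Irradiance of the optimum (µmol photons m⁻² s⁻¹), > 0.
#' @param alpha Initial slope of the light response (day⁻¹ per µmol photons
#'   m⁻² s⁻¹), > 0.
#' @return A list with elements `p1`, `p2`, `p3`.
#' @family growth models
#' @export
ep_from_peak <- function(mu_opt, I_opt, alpha) {
  if (mu_opt <= 0 || I_opt <= 0 || alpha <= 0) {
    stop("`mu_opt`, `I_opt` and `alpha` must all be positive", call. = FALSE)
  }
  p3 <- 1 / alpha
  p1 <- p3 / I_opt^2
  p2 <- 1 / mu_opt - 2 * sqrt(p1 * p3)
  check_ep_params(p1, p2, p3)
  list(p1 = p1, p2 = p2, p3 = p3)
}

#' Minimum light requirement I*
#'
#' The lowest irradiance at which growth balances mortality. For a Monod
#' light response this is identical to [rstar()]. For an Eilers-Peeters
#' response, \eqn{\mu(I) = m} has two roots flanking the optimum; I* is the
#' smaller one, found by solving the quadratic
#' \eqn{m p_1 I^2 + (m p_2 - 1) I + m p_3 = 0}.
#'
#' @inheritParams rstar
#' @param p1,p2,p3 Eilers-Peeters coefficients; supply either
#'   (`mu_max`, `ks`) for the Monod form or (`p1`, `p2`, `p3`) for the
#'   photoinhibition form, not both.
#' @return I* in µmol photons m⁻² s⁻¹.
#' @examples
#' istar(mu_max = 1.12, ks = 10)          # Monod form: same as rstar()
#' p <- ep_from_peak(1.12, 100, 0.05)
#' istar(p1 = p$p1, p2 = p$p2, p3 = p$p3) # smaller root of mu(I) = m
#' @family growth models
#' @export
istar <- function(mu_max = NULL, ks = NULL, p1 = NULL, p2 = NULL, p3 = NULL,
                  m = 0.56) {
  monod_given <- !is.null(mu_max) && !is.null(ks)
  ep_given <- !is.null(p1) && !is.null(p2) && !is.null(p3)
  if (monod_given == ep_given) {
    stop("supply either (`mu_max`, `ks`) or (`p1`, `p2`, `p3`)", call. = FALSE)
  }
  if (monod_given) {
    return(rstar(mu_max, ks, m = m))
  }
  check_ep_params(p1, p2, p3)
  mu_opt <- 1 / (2 * sqrt(p1 * p3) + p2)
  if (mu_opt <= m) {
    stop("non-persistent: peak growth rate does not exceed mortality `m`", call. = FALSE)
  }
  # m*(p1 I^2 + p2 I + p3) = I  =>  m p1 I^2 + (m p2 - 1) I + m p3 = 0
  A <- m * p1
  B <- m * p2 - 1
  C <- m * p3
  disc <- B^2 - 4 * A * C
  (-B - sqrt(disc)) / (2 * A)
}

#' Cell biovolume from cell length, assuming spherical cells
#'
#' @param length_um Cell length(s) in µm (taken as the sphere diameter), > 0.
#' @return Volume(s) in µm³: `4/3 * pi * (length_um / 2)^3`.
#' @examples
#' biovolume_from_length(10)
#' @family growth models
#' @export
biovolume_from_length <- function(length_um) {
  if (any(length_um <= 0)) stop("`length_um` must be positive", call. = FALSE)
  4 / 3 * pi * (length_um / 2)^3
}

# --- parameter validation helpers (internal) ---------------------------------

check_monod_params <- function(mu_max, ks) {
  if (any(!is.finite(mu_max)) || any(mu_max <= 0)) {
    stop("`mu_max` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(ks)) || any(ks <= 0)) {
    stop("`ks` must be positive and finite", call. = FALSE)
  }
  invisible(TRUE)
}

check_salt_params <- function(a, b, c) {
  if (any(a <= 0)) stop("salt parameter `a` must be positive", call. = FALSE)
  if (any(b <= 0)) stop("salt parameter `b` must be positive (growth declines with salt)", call. = FALSE)
  if (any(c <= 0)) stop("salt parameter `c` must be positive", call. = FALSE)
  invisible(TRUE)
}

check_ep_params <- function(p1, p2, p3) {
  if (any(p1 <= 0) || any(p3 <= 0) || any(2 * sqrt(p1 * p3) + p2 <= 0)) {
    stop("invalid Eilers-Peeters parameters: need p1 > 0, p3 > 0 and an interior maximum",
         call. = FALSE)
  }
  invisible(TRUE)
}
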