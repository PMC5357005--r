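#' Specific surface of bone as a function of porosity
#'
#' Free bone surface area per unit tissue volume (BS/TV, 1/mm). The
#' `"quintic"` variant evaluates the fifth-degree polynomial fit to modern CT
#' measurements,
#' `Sv = 32.26 p - 93.94 p^2 + 133.96 p^3 - 101.4 p^4 + 28.76 p^5`,
#' floored at zero (the polynomial dips slightly negative at p = 1). The
#' `"martin"` variant is the classical parabolic shape, implemented as a
#' parabola through the origin with the same peak location and height as the
#' quintic. Both peak at intermediate porosity: surface-mediated remodelling
#' is most intense in the cancellous-cortical transition zone.
#'
#' @param porosity Porosity `p = 1 - v_b`, in \[0, 1\]; vectorized.
#' @param variant `"quintic"` or `"martin"`.
#'
#' @return Specific surface (1/mm), non-negative.
#' @export
#' @examples
#' specific_surface(0.5)
specific_surface <- function(porosity, variant = c("quintic", "martin")) {
  variant <- match.arg(variant)
  if (any(porosity < 0 | porosity > 1)) stop("porosity must lie in [0, 1]")
  p <- porosity
  if (variant == "quintic") {
    s <- 32.26 * p - 93.94 * p^2 + 133.96 * p^3 - 101.4 * p^4 + 28.76 * p^5
  } else {
    pk <- sv_peak()
    s <- pk$height * p * (2 * pk$location - p) / pk$location^2
  }
  pmax(s, 0)
}

# peak of the quintic specific-surface law, found once and cached
.sv_cache <- new.env(parent = emptyenv())
sv_peak <- function() {
  if (is.null(.sv_cache$peak)) {
    opt <- stats::optimize(function(p) specific_surface(p, "quintic"),
                           interval = c(0, 1), maximum = TRUE)
    .sv_cache$peak <- list(location = opt$maximum, height = opt$objective)
  }
  .sv_cache$peak
}

sv_max <- function(variant = "quintic") {
  # both variants share the same peak height by construction
  sv_peak()$height
}

#' Resorption window length from porosity
#'
#' `t_sr = kappa_sr * Sv(p)`, rounded to the nearest day and floored at one
#' day. The window is recomputed every simulated day from the current
#' porosity, so it co-evolves with the bone volume fraction.
#'
#' @param porosity Porosity `p = 1 - v_b`.
#' @param kappa_sr Window scaling (days).
#' @param variant Specific-surface variant, see [specific_surface()].
#'
#' @return Window length in whole days (>= 1).
#' @export
#' @examples
#' resorption_window_length(0.5, kappa_sr = 200)  # 790 days
resorption_window_length <- function(porosity, kappa_sr = 200,
                                     variant = "quintic") {
  if (any(kappa_sr <= 0)) stop("kappa_sr must be positive")
  pmax(round(kappa_sr * specific_surface(porosity, variant)), 1)
}

#' BMU cross-section as a function of bone volume fraction
#'
#' Osteonal cross-section for cortical bone (`v_b > 0.7`), hemiosteonal for
#' cancellous bone (`v_b < 0.3`), linear interpolation in the transition
#' zone.
#'
#' @param v_b Bone material volume fraction(s), in \[0, 1\].
#' @param params A [bmu_params()] object.
#' @return Cross-section (mm^2).
#' @export
a_bmu <- function(v_b, params = bmu_params()) {
  if (any(v_b < 0 | v_b > 1)) stop("v_b must lie in [0, 1]")
  lo <- params$a_bmu_h
  hi <- params$a_bmu_o
  out <- lo + (pmin(pmax(v_b, 0.3), 0.7) - 0.3) / 0.4 * (hi - lo)
  out
}

#' Osteoblast-to-osteoclast activity ratio
#'
#' Piecewise-linear response of the formation/resorption balance to the
#' unbalanced stimulus `xi - xi_star`: 1 at the set point, linear with slope
#' `0.05 / xi_ref`, clipped to \[0.95, 1.05\] (so the balance saturates at
#' zero stimulus and at twice the reference).
#'
#' @param xi Current mechanical stimulus (same scale as `xi_ref`).
#' @param params A [bmu_params()] object.
#' @param xi_star Current balance set point; defaults to the fixed reference,
#'   but accommodates to the prevailing stimulus during simulations (see
#'   [bmu_params()]).
#' @return Dimensionless ratio `f_b / f_c` in \[0.95, 1.05\].
#' @export
#' @examples
#' fb_fc_ratio(c(0, 2.5e-4, 5e-4))
fb_fc_ratio <- function(xi, params = bmu_params(), xi_star = params$xi_ref) {
  if (any(xi < 0)) stop("stimulus must be non-negative")
  r <- 1 + 0.05 * (xi - xi_star) / params$xi_ref
  pmin(pmax(r, 0.95), 1.05)
}

#' Daily BMU origination rate
#'
#' Number of BMUs activated per unit tissue volume and day:
#' `n0 * Sv(p)/max(Sv) * max(1 - lambda_inh * xi / xi_ref, 0)`.
#' Activation is proportional to the available specific surface (remodelling
#' is a surface phenomenon) and linearly inhibited by the mechanical
#' stimulus: disuse (`xi = 0`) removes the inhibitory signal and enhances
#' activation, while sustained overload suppresses it.
#'
#' @param xi Current mechanical stimulus.
#' @param v_b Current bone material volume fraction.
#' @param params A [bmu_params()] object.
#' @return Origination rate (1/(mm^3 day)), non-negative.
#' @export
bmu_activation_rate <- function(xi, v_b, params = bmu_params()) {
  if (any(xi < 0)) stop("stimulus must be non-negative")
  sv <- specific_surface(1 - v_b, params$sv_variant)
  inhibition <- pmax(1 - params$lambda_inh * xi / params$xi_ref, 0)
  params$n0 * sv / sv_max(params$sv_variant) * inhibition
}

#' Daily resorption and formation volume rates
#'
#' Daily discretization of the BMU rate convolutions. The living-BMU count at
#' day `t'` is the trailing `sigma_l`-day sum of origination rates; the
#' resorption rate integrates it over the trailing resorption period `t_r`,
#' the formation rate over the formation period `t_f` lagged by
#' `t_r + t_i` (resorption and reversal precede deposition within each BMU):
#'
#' `vdot_r(t) = (A_BMU f_c v_BMU / t_r) * sum_(t' in last t_r) living(t')`
#'
#' `vdot_f(t) = (A_BMU f_b v_BMU / t_f) * sum_(t' in formation window) living(t')`
#'
#' Under a constant origination history and `xi = xi_star` the two rates are
#' identical (remodelling equilibrium, `vdot_b = 0`).
#'
#' @param history Numeric vector of daily BMU origination rates, oldest
#'   first, most recent last; must span at least `sigma_l + t_r` days for
#'   resorption and `sigma_l + t_r + t_i + t_f` days for formation.
#' @param v_b Current bone material volume fraction.
#' @param params A [bmu_params()] object.
#' @param xi Current stimulus (formation only, through `f_b`).
#' @param xi_star Current balance set point (formation only).
#'
#' @return Volume fraction per day.
#' @export
resorption_rate <- function(history, v_b, params = bmu_params()) {
  p <- params
  need <- p$sigma_l + p$t_r
  if (length(history) < need) {
    stop("history must span at least sigma_l + t_r = ", need, " days")
  }
  if (any(history < 0)) stop("origination rates must be non-negative")
  s <- window_living_sum(history, lag = 0L, width = p$t_r, sigma_l = p$sigma_l)
  a_bmu(v_b, p) * p$f_c * p$v_bmu * s / p$t_r
}

#' @rdname resorption_rate
#' @export
formation_rate <- function(history, v_b, xi, params = bmu_params(),
                           xi_star = params$xi_ref) {
  p <- params
  need <- p$sigma_l + p$t_r + p$t_i + p$t_f
  if (length(history) < need) {
    stop("history must span at least sigma_l + t_r + t_i + t_f = ", need, " days")
  }
  if (any(history < 0)) stop("origination rates must be non-negative")
  s <- window_living_sum(history, lag = p$t_r + p$t_i, width = p$t_f,
                         sigma_l = p$sigma_l)
  f_b <- fb_fc_ratio(xi, p, xi_star) * p$f_c
  a_bmu(v_b, p) * f_b * p$v_bmu * s / p$t_f
}

# sum over t' in the `width`-day window ending `lag` days before the end of
# `history` of the trailing sigma_l-day sums of origination rates
window_living_sum <- function(history, lag, width, sigma_l) {
  n <- length(history)
  cs <- c(0, cumsum(history))
  tp <- seq.int(n - lag - width + 1L, n - lag)  # days t' in the window
  lo <- pmax(tp - sigma_l, 0L)
  sum(cs[tp + 1L] - cs[lo + 1L])
}
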