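#' Phase densities of the bone material constituents
#'
#' Mass densities of the three constituents of solid bone matrix. The defaults
#' are the standard literature values for apatite mineral, collagenous organic
#' matrix and water.
#'
#' @param rho_m Mineral phase density (g/cm^3).
#' @param rho_o Organic phase density (g/cm^3).
#' @param rho_w Water density (g/cm^3).
#'
#' @return A `phase_densities` list.
#' @export
#' @examples
#' phase_densities()
phase_densities <- function(rho_m = 3.2, rho_o = 1.1, rho_w = 1.0) {
  stopifnot(rho_m > 0, rho_o > 0, rho_w > 0)
  if (!(rho_m > rho_o && rho_o > rho_w)) {
    warning("non-physical ordering of phase densities (expected rho_m > rho_o > rho_w)")
  }
  structure(list(rho_m = rho_m, rho_o = rho_o, rho_w = rho_w),
            class = "phase_densities")
}

#' Parameters of the three-phase mineralization law
#'
#' Controls the mineral volume fraction `vm*(age)` of a bone cohort as a
#' function of its tissue age: no mineral during a lag phase of `t_nm` days,
#' a linear primary phase of `t_prim` days reaching `vm_prim`, then a
#' secondary exponential approach (rate `kappa_m`) towards `vm_max`.
#' Cohorts at or beyond `t_m_max` days are considered fully mineralized and
#' are clamped to exactly `vm_max`.
#'
#' @param t_nm Mineralization lag time (days).
#' @param t_prim Length of the primary phase (days).
#' @param kappa_m Rate constant of the secondary phase (1/day).
#' @param vm_prim Mineral volume fraction at the end of the primary phase.
#' @param vm_max Maximal mineral volume fraction.
#' @param t_m_max Maximum mineralization time (days); also the cohort array
#'   length, so memory and run time grow linearly with it.
#'
#' @return A `mineral_params` list.
#' @export
mineral_params <- function(t_nm = 12, t_prim = 10, kappa_m = 5e-4,
                           vm_prim = 0.121, vm_max = 0.442, t_m_max = 4000) {
  stopifnot(t_nm > 0, t_prim > 0, kappa_m > 0, t_m_max >= 1)
  if (t_nm + t_prim >= t_m_max) {
    stop("t_nm + t_prim must be smaller than t_m_max")
  }
  if (!(vm_prim > 0 && vm_prim < vm_max && vm_max < 1)) {
    stop("need 0 < vm_prim < vm_max < 1")
  }
  structure(list(t_nm = t_nm, t_prim = t_prim, kappa_m = kappa_m,
                 vm_prim = vm_prim, vm_max = vm_max, t_m_max = as.integer(t_m_max)),
            class = "mineral_params")
}

#' Parameters of BMU population dynamics
#'
#' Time spans, geometry and activity of the basic multicellular units (BMUs)
#' driving daily resorption and formation, plus the knobs of the activation
#' law and of the porosity-dependent resorption window.
#'
#' The activation law used here is
#' `N = n0 * Sv(p)/max(Sv) * max(1 - lambda_inh * xi/xi_ref, 0)`:
#' origination is proportional to the available specific surface and is
#' linearly inhibited by the mechanical stimulus, vanishing at `2 xi_ref`.
#' `n0` is the activation scale (BMU per mm^3 per day at maximal surface and
#' zero stimulus); its default is calibrated so that the equilibrium sweep
#' reproduces the observed transition-zone material densities (see the
#' methods vignette). The balance set point accommodates to the prevailing
#' stimulus with time constant `tau_acc`; set `tau_acc = Inf` to disable.
#'
#' @param t_r Resorption period (days).
#' @param t_i Reversal period (days).
#' @param t_f Formation period (days).
#' @param sigma_l BMU lifespan (days).
#' @param v_bmu Speed of BMU progression (mm/day).
#' @param a_bmu_o Osteonal (cortical) BMU cross-section (mm^2).
#' @param a_bmu_h Hemiosteonal (cancellous) BMU cross-section (mm^2).
#' @param f_c Osteoclast activity (dimensionless).
#' @param xi_ref Reference mechanical stimulus at remodelling equilibrium.
#' @param kappa_sr Scaling of the resorption window (days); the window length
#'   is `kappa_sr * Sv(p)`.
#' @param n0 Activation scale of the BMU origination law (1/(mm^3 day)).
#' @param lambda_inh Strength of the stimulus inhibition of activation.
#' @param tau_acc Accommodation time constant of the balance set point (days).
#' @param sv_variant Specific-surface law, `"quintic"` (polynomial fit to
#'   modern CT measurements) or `"martin"` (parabola matched to its peak).
#'
#' @return A `bmu_params` list.
#' @export
bmu_params <- function(t_r = 24, t_i = 8, t_f = 64, sigma_l = 100,
                       v_bmu = 0.04, a_bmu_o = 4.3e-3, a_bmu_h = 1.9e-3,
                       f_c = 1.0, xi_ref = 2.5e-4, kappa_sr = 200,
                       n0 = 0.12, lambda_inh = 0.5, tau_acc = 250,
                       sv_variant = c("quintic", "martin")) {
  sv_variant <- match.arg(sv_variant)
  stopifnot(t_r > 0, t_i > 0, t_f > 0, sigma_l > 0, v_bmu > 0,
            a_bmu_o > 0, a_bmu_h > 0, f_c > 0, xi_ref > 0,
            n0 >= 0, lambda_inh >= 0, tau_acc > 0)
  if (a_bmu_h >= a_bmu_o) stop("a_bmu_h must be smaller than a_bmu_o")
  if (kappa_sr <= 0 || kappa_sr > 1000) {
    stop("kappa_sr must lie in (0, 1000]")
  }
  structure(list(t_r = as.integer(t_r), t_i = as.integer(t_i),
                 t_f = as.integer(t_f), sigma_l = as.integer(sigma_l),
                 v_bmu = v_bmu, a_bmu_o = a_bmu_o, a_bmu_h = a_bmu_h,
                 f_c = f_c, xi_ref = xi_ref, kappa_sr = kappa_sr,
                 n0 = n0, lambda_inh = lambda_inh, tau_acc = tau_acc,
                 sv_variant = sv_variant),
            class = "bmu_params")
}

#' Full model parameter set
#'
#' Bundles phase densities, the mineralization law and the BMU dynamics, plus
#' the constant organic volume fraction of bone material `v_o` (frozen at 3/7:
#' water is replaced by mineral during mineralization, the organic fraction
#' does not evolve).
#'
#' @param phases A [phase_densities()] object.
#' @param mineral A [mineral_params()] object.
#' @param bmu A [bmu_params()] object.
#' @param v_o Organic volume fraction of bone material.
#'
#' @return A `model_params` list.
#' @export
#' @examples
#' p <- model_params(bmu = bmu_params(kappa_sr = 150))
#' p$bmu$kappa_sr
model_params <- function(phases = phase_densities(), mineral = mineral_params(),
                         bmu = bmu_params(), v_o = 3 / 7) {
  stopifnot(inherits(phases, "phase_densities"),
            inherits(mineral, "mineral_params"),
            inherits(bmu, "bmu_params"),
            v_o > 0, v_o < 1)
  if (mineral$vm_max >= 1 - v_o) {
    stop("vm_max must be smaller than 1 - v_o (water cannot be negative)")
  }
  structure(list(phases = phases, mineral = mineral, bmu = bmu, v_o = v_o),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  flat <- flatten_params(x)
  for (nm in names(flat)) cat(sprintf("  %-12s %s\n", nm, format(flat[[nm]])))
  invisible(x)
}

# single-level named list of all scalar parameters (used by print, config io
# and the CLI `params` subcommand)
flatten_params <- function(params) {
  c(params$phases[], params$mineral[], params$bmu[], list(v_o = params$v_o))
}
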