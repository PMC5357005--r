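#' Bone composition state
#'
#' A tibble of instantaneous volume-fraction states of a representative bone
#' tissue volume. `v_b` is the bone material volume fraction (solid matrix
#' over tissue volume, BV/TV); `v_m`, `v_o` and `v_w` are the mineral,
#' organic and water fractions *of the bone material*, which always sum to 1
#' (water is replaced by mineral as the matrix mineralizes, the organic
#' fraction is constant). All arguments are vectorized.
#'
#' @param v_b Bone material volume fraction(s), in \[0, 1\].
#' @param v_m Mineral volume fraction(s) of bone material.
#' @param v_o Organic volume fraction of bone material (constant 3/7).
#'
#' @return A tibble with columns `v_b`, `v_m`, `v_o`, `v_w`.
#' @export
#' @examples
#' bone_composition(v_b = 0.5, v_m = 0.442)
bone_composition <- function(v_b, v_m, v_o = 3 / 7) {
  if (any(v_b < 0 | v_b > 1)) stop("v_b must lie in [0, 1]")
  if (any(v_m < -1e-9 | v_m > 1 + 1e-9)) stop("v_m must lie in [0, 1]")
  v_m <- pmin(pmax(v_m, 0), 1)
  v_w <- 1 - v_m - v_o
  if (any(v_w < -1e-9)) stop("v_m + v_o exceeds 1: water fraction would be negative")
  v_w <- pmax(v_w, 0)
  tibble::tibble(v_b = v_b, v_m = v_m, v_o = v_o, v_w = v_w)
}

#' Material, apparent and ash densities of bone
#'
#' `material_density()` is the density of the solid bone matrix,
#' `rho_mat = rho_m v_m + rho_o v_o + rho_w v_w` (linear and increasing in the
#' mineral fraction). `apparent_density()` is the tissue-level density
#' `rho_app = rho_mat * v_b` (pores are void). `ash_fraction()` is the mineral
#' mass over the dry mass, `alpha = rho_m v_m / (rho_m v_m + rho_o v_o)`, and
#' `ash_density()` the mineral mass over the tissue volume,
#' `rho_ash = rho_m v_m v_b`.
#'
#' @param comp A [bone_composition()] tibble (or any data frame with columns
#'   `v_b`, `v_m`, `v_o`, `v_w`).
#' @param dens A [phase_densities()] object.
#'
#' @return A numeric vector (g/cm^3, except `ash_fraction` which is
#'   dimensionless in \[0, 1)).
#' @export
#' @examples
#' comp <- bone_composition(v_b = 0.5, v_m = 0.442)
#' material_density(comp)  # 2.0153 g/cm^3
#' apparent_density(comp)  # half of that
#' ash_fraction(comp)      # 0.750
material_density <- function(comp, dens = phase_densities()) {
  check_composition(comp)
  dens$rho_m * comp$v_m + dens$rho_o * comp$v_o + dens$rho_w * comp$v_w
}

#' @rdname material_density
#' @export
apparent_density <- function(comp, dens = phase_densities()) {
  material_density(comp, dens) * comp$v_b
}

#' @rdname material_density
#' @export
ash_fraction <- function(comp, dens = phase_densities()) {
  check_composition(comp)
  dry <- dens$rho_m * comp$v_m + dens$rho_o * comp$v_o
  if (any(dry <= 0)) stop("ash fraction undefined when mineral and organic fractions are both zero")
  dens$rho_m * comp$v_m / dry
}

#' @rdname material_density
#' @export
ash_density <- function(comp, dens = phase_densities()) {
  check_composition(comp)
  dens$rho_m * comp$v_m * comp$v_b
}

check_composition <- function(comp) {
  need <- c("v_b", "v_m", "v_o", "v_w")
  if (!all(need %in% names(comp))) {
    stop("composition needs columns ", paste(need, collapse = ", "))
  }
  if (any(abs(comp$v_m + comp$v_o + comp$v_w - 1) > 1e-9)) {
    stop("bone material fractions must sum to 1")
  }
  if (any(comp$v_m < 0 | comp$v_m > 1)) stop("v_m outside [0, 1]")
  invisible(comp)
}

#' Add density columns to a data frame of compositions
#'
#' Convenience tidy wrapper: given any data frame with `v_b` and `v_m`
#' columns, appends `v_w`, `rho_mat`, `rho_app`, `rho_ash` and `alpha`.
#'
#' @param data A data frame with columns `v_b` and `v_m`.
#' @param dens A [phase_densities()] object.
#' @param v_o Organic volume fraction of bone material.
#'
#' @return `data` as a tibble with the density columns appended.
#' @export
add_densities <- function(data, dens = phase_densities(), v_o = 3 / 7) {
  comp <- bone_composition(data$v_b, data$v_m, v_o = v_o)
  dplyr::mutate(tibble::as_tibble(data),
                v_w = comp$v_w,
                rho_mat = material_density(comp, dens),
                rho_app = apparent_density(comp, dens),
                rho_ash = ash_density(comp, dens),
                alpha = ash_fraction(comp, dens))
}
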