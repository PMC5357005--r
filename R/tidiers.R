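#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation into its per-day trace
#'
#' @param x A `remod_sim` object.
#' @param ... Unused.
#' @return The per-day trace tibble.
#' @export
tidy.remod_sim <- function(x, ...) x$trace

#' One-row summary of a simulation
#'
#' Final-day state, run metadata and the detected equilibrium day (with the
#' default [detect_equilibrium()] settings).
#'
#' @param x A `remod_sim` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.remod_sim <- function(x, ...) {
  scn <- x$scenario
  base <- tibble::tibble(
    vb0 = scn$vb0, strategy = scn$strategy,
    kappa_sr = x$params$bmu$kappa_sr, horizon = scn$horizon,
    status = x$status, days_run = nrow(x$trace))
  if (nrow(x$trace) == 0) {
    return(dplyr::mutate(base, v_b = scn$vb0, v_m = NA_real_,
                         rho_mat = NA_real_, rho_app = NA_real_,
                         equilibrium_day = NA_integer_))
  }
  f <- x$trace[nrow(x$trace), ]
  dplyr::mutate(base, v_b = f$v_b, v_m = f$v_m, rho_mat = f$rho_mat,
                rho_app = f$rho_app,
                equilibrium_day = detect_equilibrium(x))
}

#' Plot a simulation trace
#'
#' Net, formation and resorption volume rates against time; the transient
#' and its settling towards `vdot_b = 0` mirror the classical load-change
#' response plots.
#'
#' @param object A `remod_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.remod_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace,
                              c("vdot_b", "vdot_f", "vdot_r"),
                              names_to = "rate", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$value,
                                     colour = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "day", y = "volume fraction per day",
                  colour = NULL,
                  title = sprintf("vb0 = %g, %s", object$scenario$vb0,
                                  object$scenario$strategy)) +
    ggplot2::theme_minimal()
}

#' Plot a boomerang sweep
#'
#' Material density against apparent density over the initial-volume sweep,
#' one curve per `kappa_sr` and strategy.
#'
#' @param object A `remod_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.remod_sweep <- function(object, ...) {
  df <- dplyr::filter(object, .data$status == "ok")
  df$curve <- interaction(df$strategy, df$kappa_sr, sep = ", kappa_sr = ")
  ggplot2::ggplot(df, ggplot2::aes(.data$rho_app, .data$rho_mat,
                                   colour = .data$curve)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$zone)) +
    ggplot2::labs(x = "apparent density (g/cm3)",
                  y = "material density (g/cm3)",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}
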