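#' Define a loading scenario
#'
#' A scenario bundles the initial bone volume fraction, the stimulus
#' schedule, the resorption strategy and the simulation horizon. The three
#' canonical load cases are available as keywords: `"equilibrium"`
#' (`xi = xi_ref`), `"disuse"` (`xi = 0`) and `"overload"` (`xi = 2 xi_ref`).
#' A numeric scalar, a numeric vector of per-day values, or a function
#' `f(day)` may be supplied instead.
#'
#' @param vb0 Initial bone material volume fraction, in (0, 1\].
#' @param xi Stimulus schedule (keyword, scalar, vector or function).
#' @param horizon Number of days to simulate.
#' @param strategy Resorption strategy, see [resorption_window()].
#' @param kappa_sr Optional override of the window scaling in
#'   [bmu_params()].
#'
#' @return A `remod_scenario` list.
#' @export
#' @examples
#' scenario(vb0 = 0.5, xi = "overload", horizon = 2000)
scenario <- function(vb0, xi = "equilibrium", horizon = 8000,
                     strategy = "windowed", kappa_sr = NULL) {
  if (length(vb0) != 1 || vb0 <= 0 || vb0 > 1) stop("vb0 must lie in (0, 1]")
  if (horizon < 0) stop("horizon must be non-negative")
  strategy <- normalize_strategy(strategy)
  if (!is.null(kappa_sr) && (kappa_sr <= 0 || kappa_sr > 1000)) {
    stop("kappa_sr must lie in (0, 1000]")
  }
  structure(list(vb0 = vb0, xi = xi, horizon = as.integer(horizon),
                 strategy = strategy, kappa_sr = kappa_sr),
            class = "remod_scenario")
}

#' @rdname scenario
#' @param ... Passed on to [scenario()].
#' @export
scenario_equilibrium <- function(vb0, ...) scenario(vb0, xi = "equilibrium", ...)

#' @rdname scenario
#' @export
scenario_disuse <- function(vb0, ...) scenario(vb0, xi = "disuse", ...)

#' @rdname scenario
#' @export
scenario_overload <- function(vb0, ...) scenario(vb0, xi = "overload", ...)

resolve_xi_schedule <- function(xi, horizon, xi_ref) {
  if (is.character(xi)) {
    level <- switch(match.arg(xi, c("equilibrium", "disuse", "overload")),
                    equilibrium = xi_ref, disuse = 0, overload = 2 * xi_ref)
    return(function(day) level)
  }
  if (is.function(xi)) return(xi)
  if (is.numeric(xi) && length(xi) == 1) return(function(day) xi)
  if (is.numeric(xi)) {
    if (length(xi) < horizon) stop("xi vector shorter than the horizon")
    return(function(day) xi[[day]])
  }
  stop("xi must be a keyword, a number, a numeric vector or a function")
}

#' Initialize the simulation state
#'
#' Builds the cohort array (uniform over ages) and pre-fills the BMU
#' origination history with its equilibrium value at the initial state, so
#' the rate convolutions are well defined from day 0 (the simulation starts
#' from an already-extant, adapted bone, not from empty tissue).
#'
#' @param vb0 Initial bone material volume fraction.
#' @param params A [model_params()] object.
#' @param strategy Resorption strategy.
#'
#' @return A `remod_state` list.
#' @export
init_state <- function(vb0, params = model_params(), strategy = "windowed") {
  b <- params$bmu
  buffer <- b$sigma_l + b$t_r + b$t_i + b$t_f
  n_eq <- bmu_activation_rate(b$xi_ref, vb0, b)
  structure(list(
    day = 0L,
    cohorts = initialize_cohorts(vb0, params$mineral),
    v_b = vb0,
    n_hist = rep(n_eq, buffer),
    xi_star = b$xi_ref,
    strategy = normalize_strategy(strategy),
    params = params,
    profile = mineral_profile(params$mineral),
    status = "ok",
    last = NULL
  ), class = "remod_state")
}

#' Advance the simulation by one day
#'
#' One daily step, in order: accommodate the balance set point, update the
#' BMU origination history, evaluate the resorption and formation rates from
#' the history convolutions, age the cohort array, deposit the day's
#' formation, remove the day's resorption through the current window
#' (length recomputed from the current porosity), and re-aggregate mineral
#' content and densities. Conservation
#' `v_b(t+1) = v_b(t) + vdot_f - vdot_r` holds to machine precision.
#'
#' @param state A `remod_state` from [init_state()] or a previous step.
#' @param xi The day's mechanical stimulus.
#'
#' @return The advanced `remod_state`; per-day diagnostics are in
#'   `state$last`. If resorption exhausts the bone, `state$status` becomes
#'   `"fully_resorbed"`.
#' @export
step <- function(state, xi) {
  if (state$status != "ok") return(state)
  p <- state$params
  b <- p$bmu
  ph <- p$phases

  xi_star <- state$xi_star + (xi - state$xi_star) / b$tau_acc
  vb <- state$v_b

  n_new <- bmu_activation_rate(xi, vb, b)
  n_hist <- c(state$n_hist[-1L], n_new)
  vdot_r <- resorption_rate(n_hist, vb, b)
  vdot_f <- formation_rate(n_hist, vb, xi, b, xi_star = xi_star)

  a <- age_advance(state$cohorts)
  a <- apply_formation(a, vdot_f)
  t_sr <- resorption_window_length(1 - vb, b$kappa_sr, b$sv_variant)
  win <- resorption_window(t_sr, state$strategy, t_nm = p$mineral$t_nm)
  a <- apply_resorption(a, vdot_r, win)

  day <- state$day + 1L
  if (attr(a, "shortfall") > 0 || sum(a) <= 0) {
    state$day <- day
    state$cohorts <- a
    state$v_b <- 0
    state$status <- "fully_resorbed"
    state$last <- list(day = day, v_b = 0, v_m = NA_real_, v_w = NA_real_,
                       vdot_b = vdot_f - vdot_r, vdot_r = vdot_r,
                       vdot_f = vdot_f, rho_mat = NA_real_, rho_app = 0,
                       rho_ash = 0, alpha = NA_real_, t_sr = t_sr,
                       n_bmu = n_new, xi = xi, xi_star = xi_star)
    return(state)
  }

  vb_new <- vb + vdot_f - vdot_r
  v_m <- sum(as.numeric(a) * state$profile) / vb_new
  v_m <- min(max(v_m, 0), p$mineral$vm_max)
  v_w <- 1 - v_m - p$v_o
  rho_mat <- ph$rho_m * v_m + ph$rho_o * p$v_o + ph$rho_w * v_w

  state$day <- day
  state$cohorts <- a
  state$v_b <- vb_new
  state$n_hist <- n_hist
  state$xi_star <- xi_star
  state$last <- list(
    day = day, v_b = vb_new, v_m = v_m, v_w = v_w,
    vdot_b = vdot_f - vdot_r, vdot_r = vdot_r, vdot_f = vdot_f,
    rho_mat = rho_mat, rho_app = rho_mat * vb_new,
    rho_ash = ph$rho_m * v_m * vb_new,
    alpha = ph$rho_m * v_m / (ph$rho_m * v_m + ph$rho_o * p$v_o),
    t_sr = t_sr, n_bmu = n_new, xi = xi, xi_star = xi_star)
  state
}

#' Run a loading scenario
#'
#' Daily time-stepping of the coupled remodelling-mineralization model.
#'
#' @param scn A [scenario()].
#' @param params A [model_params()] object; the scenario's `kappa_sr`
#'   override, if any, is applied to `params$bmu`.
#'
#' @return A `remod_sim` object: a list with the per-day `trace` tibble
#'   (columns `day`, `v_b`, `v_m`, `v_w`, `vdot_b`, `vdot_r`, `vdot_f`,
#'   `rho_mat`, `rho_app`, `rho_ash`, `alpha`, `t_sr`, `n_bmu`, `xi`,
#'   `xi_star`), the final state, the scenario, the resolved parameters and
#'   a `status` flag. If the bone is fully resorbed the trace ends on that
#'   day and `status` is `"fully_resorbed"`.
#' @export
#' @examples
#' sim <- run_scenario(scenario(vb0 = 0.5, horizon = 50))
#' tail(tidy(sim))
run_scenario <- function(scn, params = model_params()) {
  stopifnot(inherits(scn, "remod_scenario"))
  if (!is.null(scn$kappa_sr)) params$bmu$kappa_sr <- scn$kappa_sr
  xi_fun <- resolve_xi_schedule(scn$xi, scn$horizon, params$bmu$xi_ref)

  state <- init_state(scn$vb0, params, scn$strategy)
  h <- scn$horizon
  cols <- c("day", "v_b", "v_m", "v_w", "vdot_b", "vdot_r", "vdot_f",
            "rho_mat", "rho_app", "rho_ash", "alpha", "t_sr", "n_bmu",
            "xi", "xi_star")
  rec <- lapply(stats::setNames(cols, cols), function(.) numeric(h))
  n_days <- 0L
  if (h > 0) {
    for (d in seq_len(h)) {
      state <- step(state, xi_fun(d))
      n_days <- d
      for (nm in cols) rec[[nm]][d] <- state$last[[nm]]
      if (state$status != "ok") break
    }
  }
  trace <- tibble::as_tibble(lapply(rec, function(v) v[seq_len(n_days)]))
  trace$day <- as.integer(trace$day)
  structure(list(trace = trace, final_state = state, scenario = scn,
                 params = params, status = state$status),
            class = "remod_sim")
}

#' @export
print.remod_sim <- function(x, ...) {
  scn <- x$scenario
  cat(sprintf("<remod_sim> vb0 = %g, strategy = %s, %d day(s), status: %s\n",
              scn$vb0, scn$strategy, nrow(x$trace), x$status))
  if (nrow(x$trace) > 0) {
    f <- x$trace[nrow(x$trace), ]
    cat(sprintf("  final: v_b = %.4f, rho_mat = %.4f, rho_app = %.4f g/cm3\n",
                f$v_b, f$rho_mat, f$rho_app))
  }
  invisible(x)
}

#' Detect remodelling equilibrium in a trace
#'
#' Finds the earliest day after which `|vdot_b|` stays below `tol` for
#' `run_length` consecutive days. Returns 0 for a trace in equilibrium from
#' the start, and `NA` if equilibrium is never reached.
#'
#' @param x A `remod_sim` or a trace data frame with columns `day`,
#'   `vdot_b`.
#' @param tol Equilibrium tolerance on the daily net rate (1/day).
#' @param run_length Required number of consecutive quiet days.
#'
#' @return Day index (0 = from the start) or `NA`.
#' @export
detect_equilibrium <- function(x, tol = 1e-6, run_length = 50) {
  trace <- if (inherits(x, "remod_sim")) x$trace else x
  if (nrow(trace) == 0) stop("empty trace")
  quiet <- abs(trace$vdot_b) < tol
  runs <- rle(quiet)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values & runs$lengths >= run_length)
  if (length(hit) == 0) return(NA_integer_)
  trace$day[starts[hit[1]]] - 1L
}

#' Porosity zone label
#'
#' Classifies a bone volume fraction as cancellous (`v_b < 0.3`), transition
#' (`0.3 <= v_b <= 0.7`) or cortical (`v_b > 0.7`). Reporting aid only.
#'
#' @param v_b Bone material volume fraction(s).
#' @return Character vector of zone labels.
#' @export
zone_label <- function(v_b) {
  ifelse(v_b < 0.3, "cancellous", ifelse(v_b > 0.7, "cortical", "transition"))
}
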