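#' Three-phase mineralization law
#'
#' Mineral volume fraction `vm*` of a piece of bone material as a function of
#' its tissue age: zero during the lag phase (`age <= t_nm`), a linear ramp to
#' `vm_prim` during the primary phase, then an exponential approach to
#' `vm_max` in the secondary phase. Ages at or beyond `t_m_max` are clamped to
#' exactly `vm_max` (such cohorts are considered fully mineralized; without
#' the clamp the exponential would still be noticeably below its asymptote at
#' `t_m_max`).
#'
#' @param age Tissue age(s) in days; vectorized, must be non-negative.
#' @param params A [mineral_params()] object.
#'
#' @return Mineral volume fraction(s) in `[0, vm_max]`, non-decreasing in age.
#' @export
#' @examples
#' mineral_law(c(12, 17, 22, 4000))
mineral_law <- function(age, params = mineral_params()) {
  if (any(age < 0)) stop("age must be non-negative")
  p <- params
  v <- numeric(length(age))
  ramp <- age > p$t_nm & age <= p$t_nm + p$t_prim
  v[ramp] <- p$vm_prim * (age[ramp] - p$t_nm) / p$t_prim
  sec <- age > p$t_nm + p$t_prim
  v[sec] <- p$vm_max -
    (p$vm_max - p$vm_prim) * exp(-p$kappa_m * (age[sec] - p$t_prim - p$t_nm))
  v[age >= p$t_m_max] <- p$vm_max
  v
}

# vm* evaluated on the cohort age grid 0..t_m_max (terminal bin fully
# mineralized); cached by callers that step daily
mineral_profile <- function(params = mineral_params()) {
  mineral_law(seq.int(0L, params$t_m_max), params)
}

#' Cohort array of bone material volume fractions
#'
#' The model's core state: entry `i + 1` holds the bone material volume
#' fraction formed `i` days ago and still present (ages `0..t_m_max`).
#' `initialize_cohorts()` spreads an initial volume fraction `vb0` uniformly
#' over the aged bins (ages `1..t_m_max`); the age-0 bin (today's formation)
#' starts empty. The terminal bin accumulates all bone at or beyond the
#' maximum mineralization age.
#'
#' @param vb0 Initial bone material volume fraction, in (0, 1\].
#' @param params A [mineral_params()] object (supplies `t_m_max`).
#'
#' @return A `cohort_array`: numeric vector of length `t_m_max + 1` summing
#'   to `vb0`.
#' @export
#' @examples
#' a <- initialize_cohorts(0.4)
#' sum(a)
initialize_cohorts <- function(vb0, params = mineral_params()) {
  if (length(vb0) != 1 || vb0 <= 0 || vb0 > 1) stop("vb0 must lie in (0, 1]")
  n <- params$t_m_max
  as_cohort_array(c(0, rep(vb0 / n, n)))
}

as_cohort_array <- function(x) {
  structure(as.numeric(x), class = "cohort_array")
}

#' @export
print.cohort_array <- function(x, ...) {
  cat(sprintf("<cohort_array> %d age bins, total bone volume fraction %.6g\n",
              length(x) - 1L, sum(x)))
  invisible(x)
}

#' Age the cohort array by one day
#'
#' Shifts every bin one index older; the two oldest bins merge into the
#' terminal bin and the age-0 bin empties. The total is conserved exactly.
#'
#' @param a A `cohort_array`.
#' @return The advanced `cohort_array`.
#' @export
age_advance <- function(a) {
  n <- length(a)
  as_cohort_array(c(0, a[seq_len(n - 2L)], a[n - 1L] + a[n]))
}

#' Deposit newly formed bone
#'
#' Adds `amount` to the age-0 bin (today's osteoblastic formation).
#'
#' @param a A `cohort_array`.
#' @param amount Volume fraction formed this day; non-negative.
#' @return The updated `cohort_array`.
#' @export
apply_formation <- function(a, amount) {
  if (amount < 0) stop("formation amount must be non-negative")
  if (sum(a) + amount > 1 + 1e-9) {
    stop("formation would push the bone volume fraction above 1")
  }
  a[1L] <- a[1L] + amount
  as_cohort_array(a)
}

#' Resorption window and strategy
#'
#' Describes how one day's osteoclastic resorption is distributed over cohort
#' ages. Strategies: `"windowed"` (the model's central hypothesis: uniform
#' removal from ages `t_nm .. t_nm + t_sr - 1`, with any per-bin shortfall
#' spilling to successively older bins), `"newest_only"` (youngest bone
#' first), `"age_averaged"` (proportional removal across all ages, emulating
#' the classical non-cohort model). Aliases `"case3"`, `"case2"`, `"case1"`
#' are accepted.
#'
#' @param t_sr Window length in days (integer, at least 1).
#' @param strategy One of `"windowed"`, `"newest_only"`, `"age_averaged"`
#'   (or `"case3"`/`"case2"`/`"case1"`).
#' @param t_nm Lower bound of the window: cohorts younger than this are
#'   ignored by osteoclasts (no mineral yet).
#'
#' @return A `resorption_window` list.
#' @export
resorption_window <- function(t_sr, strategy = "windowed", t_nm = 12) {
  strategy <- normalize_strategy(strategy)
  t_sr <- as.integer(round(t_sr))
  if (t_sr < 1) stop("t_sr must be at least 1 day")
  stopifnot(t_nm >= 1)
  structure(list(t_sr = t_sr, strategy = strategy, t_nm = as.integer(t_nm)),
            class = "resorption_window")
}

normalize_strategy <- function(strategy) {
  canonical <- c("windowed", "newest_only", "age_averaged")
  if (length(strategy) == 1 && strategy %in% canonical) return(strategy)
  map <- c(windowed = "windowed", newest_only = "newest_only",
           age_averaged = "age_averaged",
           case3 = "windowed", case2 = "newest_only", case1 = "age_averaged")
  key <- match.arg(strategy, names(map))
  unname(map[[key]])
}

# greedy removal along x (in the given order): take from each element until
# `amount` is satisfied or x is exhausted
take_greedy <- function(x, amount) {
  cum <- cumsum(x)
  pmin(x, pmax(0, amount - c(0, cum[-length(cum)])))
}

#' Remove resorbed bone from the cohort array
#'
#' Distributes one day's resorbed volume over cohort ages according to the
#' window strategy. For the windowed strategy, `amount / t_sr` is removed
#' from each in-window bin; the shortfall from under-filled bins spills to
#' bins older than the window (ascending age), and, only if those are
#' exhausted too, to bins younger than the window. The total removed always
#' equals `amount` unless the whole array holds less bone, in which case the
#' array empties and the deficit is recorded in the `"shortfall"` attribute.
#'
#' @param a A `cohort_array`.
#' @param amount Volume fraction resorbed this day; non-negative.
#' @param window A [resorption_window()].
#'
#' @return The updated `cohort_array`, with attributes `"removed"` and
#'   `"shortfall"`.
#' @export
apply_resorption <- function(a, amount, window) {
  if (amount < 0) stop("resorption amount must be non-negative")
  x <- as.numeric(a)
  if (amount == 0) {
    return(structure(as_cohort_array(x), removed = 0, shortfall = 0))
  }
  n <- length(x)
  total <- sum(x)
  if (amount >= total) {
    return(structure(as_cohort_array(numeric(n)),
                     removed = total, shortfall = amount - total))
  }
  if (window$strategy == "age_averaged") {
    x <- x * (1 - amount / total)
  } else if (window$strategy == "newest_only") {
    take <- take_greedy(x, amount)
    x <- x - take
  } else {
    # windowed: ages t_nm .. t_nm + t_sr - 1 (indices are age + 1)
    t_sr <- min(window$t_sr, n - 1L - window$t_nm)  # keep window on the grid
    idx <- (window$t_nm:(window$t_nm + t_sr - 1L)) + 1L
    quota <- amount / t_sr
    take <- pmin(x[idx], quota)
    x[idx] <- x[idx] - take
    residual <- amount - sum(take)
    if (residual > 1e-12 * amount) {
      older <- seq.int(window$t_nm + t_sr + 1L, n)
      spill <- take_greedy(x[older], residual)
      x[older] <- x[older] - spill
      residual <- residual - sum(spill)
    }
    if (residual > 1e-12 * amount) {
      younger <- rev(seq_len(window$t_nm))  # ages t_nm - 1 .. 0, oldest first
      spill <- take_greedy(x[younger], residual)
      x[younger] <- x[younger] - spill
      residual <- residual - sum(spill)
    }
  }
  x[x < 0] <- 0  # guard against -1e-22 style float dust
  structure(as_cohort_array(x), removed = amount, shortfall = 0)
}

#' Volume-weighted mineral fraction of the cohort array
#'
#' The mineral volume fraction of the whole bone material: the bone-volume
#' weighted mean of the mineralization law over cohort ages.
#'
#' @param a A `cohort_array`.
#' @param params A [mineral_params()] object.
#' @param profile Optional precomputed [mineral_law()] values on the age grid
#'   (a performance hook for the daily stepping loop).
#'
#' @return Mineral volume fraction in `[0, vm_max]`.
#' @export
aggregate_mineral <- function(a, params = mineral_params(), profile = NULL) {
  vb <- sum(a)
  if (vb <= 0) stop("cohort array is empty: bone fully resorbed")
  if (is.null(profile)) profile <- mineral_profile(params)
  stopifnot(length(profile) == length(a))
  sum(as.numeric(a) * profile) / vb
}

#' Read and write cohort arrays as CSV
#'
#' Plain-text checkpoint format with columns `age_days`, `delta_vb`.
#'
#' @param a A `cohort_array`.
#' @param path File path.
#' @return `write_cohorts()` returns `path` invisibly; `read_cohorts()`
#'   returns a `cohort_array`.
#' @export
write_cohorts <- function(a, path) {
  df <- tibble::tibble(age_days = seq_along(a) - 1L,
                       delta_vb = sprintf("%.17g", as.numeric(a)))
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_cohorts
#' @export
read_cohorts <- function(path) {
  df <- utils::read.csv(path)
  df$age_days <- as.integer(df$age_days)
  if (!identical(df$age_days, seq_len(nrow(df)) - 1L)) {
    stop("age_days must be the contiguous sequence 0..t_m_max")
  }
  as_cohort_array(df$delta_vb)
}
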