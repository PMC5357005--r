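#' Load a run configuration
#'
#' Reads a YAML or JSON mapping (or takes a named list) of parameter
#' overrides and returns a fully resolved configuration: a [model_params()]
#' object plus scenario settings, with defaults applied everywhere else.
#' Unknown keys are rejected by name; parameter values are validated by the
#' constructors (for example a negative `kappa_sr` errors).
#'
#' Recognised keys: every scalar field of [phase_densities()],
#' [mineral_params()] and [bmu_params()], `v_o`, and the scenario fields
#' `vb0`, `xi`, `horizon`, `strategy`.
#'
#' @param config A file path (`.yaml`/`.yml`/`.json`) or a named list;
#'   `NULL` or an empty list gives all defaults.
#'
#' @return A `run_config` list with elements `params` (a `model_params`)
#'   and `scenario` (a `remod_scenario`).
#' @export
#' @examples
#' cfg <- load_config(list(kappa_sr = 150, horizon = 100))
#' cfg$params$bmu$kappa_sr
load_config <- function(config = NULL) {
  if (is.null(config)) config <- list()
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("config must be a named list or a YAML/JSON file")
  if (length(config) > 0 && (is.null(names(config)) || any(names(config) == ""))) {
    stop("all config entries must be named")
  }

  groups <- list(phases = names(formals(phase_densities)),
                 mineral = names(formals(mineral_params)),
                 bmu = names(formals(bmu_params)))
  scenario_keys <- c("vb0", "xi", "horizon", "strategy")
  known <- c(unlist(groups, use.names = FALSE), "v_o", scenario_keys)
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }

  pick <- function(keys) config[intersect(names(config), keys)]
  params <- model_params(
    phases = do.call(phase_densities, pick(groups$phases)),
    mineral = do.call(mineral_params, pick(groups$mineral)),
    bmu = do.call(bmu_params, pick(groups$bmu)),
    v_o = if (!is.null(config$v_o)) config$v_o else 3 / 7)
  scn_args <- pick(scenario_keys)
  if (is.null(scn_args$vb0)) scn_args$vb0 <- 0.5
  scn <- do.call(scenario, scn_args)
  structure(list(params = params, scenario = scn), class = "run_config")
}

#' Save a configuration to YAML
#'
#' Writes the flattened scalar parameters plus the scenario fields, such
#' that `load_config()` on the file round-trips to the same configuration.
#'
#' @param config A `run_config` from [load_config()].
#' @param path Output file path (`.yaml`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  scn <- config$scenario
  flat <- c(flatten_params(config$params),
            list(vb0 = scn$vb0, horizon = scn$horizon,
                 strategy = scn$strategy))
  if (is.character(scn$xi) || (is.numeric(scn$xi) && length(scn$xi) == 1)) {
    flat$xi <- scn$xi
  }
  yaml::write_yaml(flat, path, precision = 17)
  invisible(path)
}

#' Write and read simulation traces
#'
#' `write_trace()` stores the per-day trace as CSV (full float precision,
#' so a reload reproduces identical values) and, optionally, the resolved
#' configuration as a JSON sidecar next to it.
#'
#' @param sim A `remod_sim`.
#' @param path CSV output path.
#' @param sidecar Write `<path>.json` with the resolved scenario and
#'   parameters?
#' @return `path`, invisibly; `read_trace()` returns the trace tibble.
#' @export
write_trace <- function(sim, path, sidecar = TRUE) {
  stopifnot(inherits(sim, "remod_sim"))
  out <- sim$trace
  # 17 significant digits: doubles survive the round trip bit-exactly
  dbl <- vapply(out, is.double, logical(1))
  out[dbl] <- lapply(out[dbl], function(v) sprintf("%.17g", v))
  readr::write_csv(out, path)
  if (sidecar) {
    meta <- list(
      package = "ossify",
      version = as.character(utils::packageVersion("ossify")),
      status = sim$status,
      scenario = sim$scenario[c("vb0", "horizon", "strategy")],
      xi = if (is.character(sim$scenario$xi)) sim$scenario$xi else "custom",
      params = flatten_params(sim$params))
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  # base-R parser: correctly rounded, so the written 17-digit floats come
  # back bit-exact
  df <- utils::read.csv(path)
  df$day <- as.integer(df$day)
  tibble::as_tibble(df)
}

#' Deterministic cohort-array fixtures
#'
#' Small cohort arrays for tests and demonstrations: `"uniform"` (identical
#' to [initialize_cohorts()]), `"single_cohort"` (all mass at one age),
#' `"two_cohort"` (mass split over two ages) and `"random_valid"`
#' (pseudo-random non-negative bins normalized to `vb0`; deterministic for a
#' given `seed`).
#'
#' @param kind Fixture kind.
#' @param seed Integer seed (used by `"random_valid"` only).
#' @param vb0 Total bone volume fraction of the fixture.
#' @param params A [mineral_params()] object.
#' @param age,ages Cohort age(s) for the single-/two-cohort kinds.
#' @return A `cohort_array`.
#' @export
make_fixture <- function(kind = c("uniform", "single_cohort", "two_cohort",
                                  "random_valid"),
                         seed = 1L, vb0 = 0.4, params = mineral_params(),
                         age = 100L, ages = c(20L, 3000L)) {
  kind <- match.arg(kind)
  n <- params$t_m_max + 1L
  if (kind == "uniform") return(initialize_cohorts(vb0, params))
  if (kind == "single_cohort") {
    stopifnot(age >= 0, age <= params$t_m_max)
    a <- numeric(n)
    a[age + 1L] <- vb0
    return(as_cohort_array(a))
  }
  if (kind == "two_cohort") {
    stopifnot(length(ages) == 2, all(ages >= 0), all(ages <= params$t_m_max))
    a <- numeric(n)
    a[ages + 1L] <- vb0 / 2
    return(as_cohort_array(a))
  }
  a <- withr::with_seed(seed, stats::runif(n))
  as_cohort_array(a / sum(a) * vb0)
}
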