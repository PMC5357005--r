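# Independent oracles used across the test files. These deliberately avoid
# the package's vectorized implementations: scalar loops and explicit sums
# only.

# small, fast mineralization parameter set for cohort-level oracles
small_mineral <- function(t_m_max = 50) {
  mineral_params(t_nm = 3, t_prim = 4, kappa_m = 0.05,
                 vm_prim = 0.121, vm_max = 0.442, t_m_max = t_m_max)
}

# greedy scalar re-implementation of windowed resorption with spillover
oracle_windowed_resorption <- function(x, amount, t_nm, t_sr) {
  n <- length(x)
  t_sr <- min(t_sr, n - 1 - t_nm)
  win <- (t_nm:(t_nm + t_sr - 1)) + 1
  quota <- amount / t_sr
  removed <- 0
  for (i in win) {
    take <- min(x[i], quota)
    x[i] <- x[i] - take
    removed <- removed + take
  }
  order_rest <- c(setdiff(seq(min(win), n), win),      # older, ascending age
                  rev(seq_len(t_nm)))                  # younger, oldest first
  for (i in order_rest) {
    if (removed >= amount - 1e-15) break
    take <- min(x[i], amount - removed)
    x[i] <- x[i] - take
    removed <- removed + take
  }
  list(x = x, removed = removed)
}

# naive per-cohort record simulation: one (age, mass) record per formation
# event, no terminal-bin pooling; same step semantics as the cohort array
# (advance, form, resorb windowed)
oracle_cohort_records <- function(vb0, steps, form, resorb, t_nm, t_sr,
                                  params) {
  ages <- seq_len(params$t_m_max)
  mass <- rep(vb0 / params$t_m_max, params$t_m_max)
  for (k in seq_len(steps)) {
    ages <- ages + 1L
    ages <- c(0L, ages)
    mass <- c(form[k], mass)
    amount <- resorb[k]
    if (amount > 0) {
      in_win <- which(ages >= t_nm & ages <= t_nm + t_sr - 1)
      quota <- amount / t_sr
      removed <- 0
      for (i in in_win) {
        take <- min(mass[i], quota)
        mass[i] <- mass[i] - take
        removed <- removed + take
      }
      rest <- c(which(ages >= t_nm + t_sr)[order(ages[ages >= t_nm + t_sr])],
                rev(which(ages < t_nm & ages > 0)), which(ages == 0))
      for (i in rest) {
        if (removed >= amount - 1e-15) break
        take <- min(mass[i], amount - removed)
        mass[i] <- mass[i] - take
        removed <- removed + take
      }
    }
    keep <- mass > 0 | ages == 0
    ages <- ages[keep]
    mass <- mass[keep]
  }
  vm_star <- mineral_law(pmin(ages, params$t_m_max), params)
  list(total = sum(mass), v_m = sum(mass * vm_star) / sum(mass))
}

# explicit double-loop discretization of the BMU rate convolutions
oracle_resorption_rate <- function(history, v_b, p) {
  n <- length(history)
  acc <- 0
  for (tp in (n - p$t_r + 1):n) {
    living <- sum(history[max(tp - p$sigma_l + 1, 1):tp])
    acc <- acc + living
  }
  a_bmu(v_b, p) * p$f_c * p$v_bmu * acc / p$t_r
}

oracle_formation_rate <- function(history, v_b, xi, p, xi_star = p$xi_ref) {
  n <- length(history)
  acc <- 0
  for (tp in (n - p$t_r - p$t_i - p$t_f + 1):(n - p$t_r - p$t_i)) {
    living <- sum(history[max(tp - p$sigma_l + 1, 1):tp])
    acc <- acc + living
  }
  f_b <- fb_fc_ratio(xi, p, xi_star) * p$f_c
  a_bmu(v_b, p) * f_b * p$v_bmu * acc / p$t_f
}
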