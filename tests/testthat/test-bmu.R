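test_that("specific surface evaluates the quintic and floors at zero", {
  expect_equal(specific_surface(0), 0)
  expect_equal(specific_surface(0.5), 3.95125)
  # the raw polynomial is slightly negative at p = 1; the law floors it
  expect_equal(specific_surface(1), 0)
  expect_error(specific_surface(-0.1), "porosity")
  expect_error(specific_surface(1.1), "porosity")
})

test_that("specific surface peaks at intermediate porosity", {
  p <- seq(0, 1, by = 0.001)
  s <- specific_surface(p)
  expect_true(all(s >= 0))
  pk <- p[which.max(s)]
  expect_gt(pk, 0.2)
  expect_lt(pk, 0.6)
  # the parabolic variant shares the peak and is also non-negative
  sm <- specific_surface(p, "martin")
  expect_equal(p[which.max(sm)], pk, tolerance = 5e-3)
  expect_equal(max(sm), max(s), tolerance = 1e-6)
  expect_true(all(sm >= 0))
})

test_that("resorption window length scales with kappa_sr and floors at 1 day", {
  expect_equal(resorption_window_length(0.5, 200), 790)
  expect_equal(resorption_window_length(0, 200), 1)
  expect_equal(resorption_window_length(0.5, 100) * 2,
               resorption_window_length(0.5, 200))
  k <- c(50, 150, 250, 500)
  expect_true(all(diff(resorption_window_length(0.5, k)) > 0))
  expect_error(resorption_window_length(0.5, -5), "kappa_sr")
})

test_that("BMU cross-section interpolates between hemiosteon and osteon", {
  expect_equal(a_bmu(0.8), 4.3e-3)
  expect_equal(a_bmu(0.2), 1.9e-3)
  expect_equal(a_bmu(0.5), 3.1e-3)
  # continuity at the zone boundaries
  expect_equal(a_bmu(0.3 - 1e-12), a_bmu(0.3 + 1e-12), tolerance = 1e-9)
  expect_equal(a_bmu(0.7 - 1e-12), a_bmu(0.7 + 1e-12), tolerance = 1e-9)
  expect_true(all(diff(a_bmu(seq(0.29, 0.71, by = 0.01))) >= 0))
})

test_that("osteoblast/osteoclast balance responds piecewise linearly", {
  b <- bmu_params()
  expect_equal(fb_fc_ratio(b$xi_ref), 1)
  expect_equal(fb_fc_ratio(0), 0.95)
  expect_equal(fb_fc_ratio(2 * b$xi_ref), 1.05)
  expect_equal(fb_fc_ratio(10 * b$xi_ref), 1.05)  # clipped
  expect_equal(fb_fc_ratio(1.5 * b$xi_ref), 1.025)
  expect_error(fb_fc_ratio(-1e-5), "non-negative")
})

test_that("BMU activation is surface-driven and stimulus-inhibited", {
  b <- bmu_params()
  expect_equal(bmu_activation_rate(b$xi_ref, 1, b), 0)  # no surface, no BMUs
  expect_gt(bmu_activation_rate(0, 0.5, b),
            bmu_activation_rate(b$xi_ref, 0.5, b))
  grid <- expand.grid(xi = c(0, b$xi_ref, 2 * b$xi_ref, 4 * b$xi_ref),
                      v_b = seq(0.05, 1, by = 0.05))
  rates <- mapply(bmu_activation_rate, grid$xi, grid$v_b,
                  MoreArgs = list(params = b))
  expect_true(all(rates >= 0))
})

test_that("resorption rate matches the closed form and the brute-force oracle", {
  b <- bmu_params()
  buffer <- b$sigma_l + b$t_r + b$t_i + b$t_f
  expect_equal(resorption_rate(rep(0, buffer), 0.5, b), 0)
  nbar <- 0.037
  const <- rep(nbar, buffer)
  expect_equal(resorption_rate(const, 0.5, b),
               nbar * b$sigma_l * a_bmu(0.5, b) * b$f_c * b$v_bmu,
               tolerance = 1e-12)
  set.seed(11)
  for (k in 1:5) {
    h <- rep(0, buffer)
    h[sample(buffer, 3)] <- runif(3, 0, 0.1)  # sparse impulse histories
    expect_equal(resorption_rate(h, 0.4, b),
                 oracle_resorption_rate(h, 0.4, b), tolerance = 1e-13)
    expect_equal(formation_rate(h, 0.4, b$xi_ref, b),
                 oracle_formation_rate(h, 0.4, b$xi_ref, b), tolerance = 1e-13)
  }
  expect_error(resorption_rate(rep(1, 10), 0.5, b), "history")
})

test_that("formation balances resorption at the reference stimulus", {
  b <- bmu_params()
  buffer <- b$sigma_l + b$t_r + b$t_i + b$t_f
  const <- rep(0.05, buffer)
  vr <- resorption_rate(const, 0.6, b)
  expect_equal(formation_rate(const, 0.6, b$xi_ref, b), vr, tolerance = 1e-12)
  expect_equal(formation_rate(const, 0.6, 2 * b$xi_ref, b), 1.05 * vr,
               tolerance = 1e-12)
  expect_equal(formation_rate(rep(0, buffer), 0.6, b$xi_ref, b), 0)
  # sign of the net rate follows the sign of the unbalanced stimulus
  expect_gt(formation_rate(const, 0.6, 1.2 * b$xi_ref, b), vr)
  expect_lt(formation_rate(const, 0.6, 0.8 * b$xi_ref, b), vr)
})
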