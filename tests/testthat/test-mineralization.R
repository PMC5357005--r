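test_that("mineralization law has the three phases and the terminal clamp", {
  expect_equal(mineral_law(c(0, 5, 12)), c(0, 0, 0))
  expect_equal(mineral_law(22), 0.121)
  expect_equal(mineral_law(17), 0.0605)  # primary-phase midpoint
  expect_equal(mineral_law(c(4000, 5000)), c(0.442, 0.442))
  # without the clamp the exponential is well short of the asymptote at 4000 d
  expect_lt(0.442 - (0.442 - 0.121) * exp(-5e-4 * (4000 - 22)), 0.40)
  expect_error(mineral_law(-1), "non-negative")
})

test_that("mineralization law is continuous and non-decreasing", {
  p <- mineral_params()
  eps <- 1e-9
  expect_equal(mineral_law(p$t_nm + eps, p), 0, tolerance = 1e-9)
  expect_equal(mineral_law(p$t_nm + p$t_prim + eps, p), p$vm_prim,
               tolerance = 1e-7)
  ages <- seq(0, p$t_m_max + 100, by = 0.5)
  v <- mineral_law(ages, p)
  expect_true(all(diff(v) >= -1e-15))
  expect_true(all(v >= 0 & v <= p$vm_max))
})

test_that("cohort initialization is uniform and conserving", {
  a <- initialize_cohorts(0.4)
  expect_length(a, 4001)
  expect_equal(a[1], 0)
  expect_equal(unclass(a[-1]), rep(1e-4, 4000))
  expect_equal(sum(a), 0.4)
  expect_error(initialize_cohorts(0), "vb0")
  expect_error(initialize_cohorts(1.2), "vb0")
})

test_that("aggregate mineral is the volume-weighted mean of the law", {
  p <- mineral_params()
  a <- initialize_cohorts(0.4, p)
  # brute-force average over the uniform age grid 1..t_m_max
  expect_equal(aggregate_mineral(a, p), mean(mineral_law(1:4000, p)),
               tolerance = 1e-12)
  # all mass in the terminal bin: fully mineralized
  expect_equal(aggregate_mineral(make_fixture("single_cohort", age = 4000L), p),
               0.442)
  # all mass in the lag phase: no mineral
  expect_equal(aggregate_mineral(make_fixture("single_cohort", age = 5L), p), 0)
  # two-cohort weighted mean, by hand
  two <- make_fixture("two_cohort", vb0 = 0.4, ages = c(22L, 4000L))
  expect_equal(aggregate_mineral(two, p), (0.121 + 0.442) / 2)
  empty <- initialize_cohorts(0.1, p)
  empty[] <- 0
  expect_error(aggregate_mineral(empty, p), "empty")
})

test_that("age advance shifts, merges the terminal bins and conserves mass", {
  p <- small_mineral()
  a <- make_fixture("random_valid", seed = 7, vb0 = 0.3, params = p)
  b <- age_advance(a)
  expect_equal(sum(b), sum(a))
  expect_equal(b[1], 0)
  expect_equal(unclass(b[2:(p$t_m_max - 1)]),
               unclass(a[1:(p$t_m_max - 2)]))
  expect_equal(b[p$t_m_max + 1], a[p$t_m_max] + a[p$t_m_max + 1])
  # a single cohort reaches the terminal bin after t_m_max advances
  s <- make_fixture("single_cohort", age = 0L, vb0 = 0.2, params = p)
  for (i in seq_len(p$t_m_max)) s <- age_advance(s)
  expect_equal(unclass(s), c(rep(0, p$t_m_max), 0.2))
})

test_that("formation adds to the age-0 bin and is additive", {
  p <- small_mineral()
  a <- initialize_cohorts(0.3, p)
  expect_equal(apply_formation(a, 0), a)
  b <- apply_formation(apply_formation(a, 0.01), 0.02)
  expect_equal(b[1], 0.03)
  expect_equal(sum(b), 0.33)
  expect_equal(b, apply_formation(a, 0.03))
  # yesterday's formation sits at age 1 after advancing
  expect_equal(age_advance(b)[2], 0.03)
  expect_error(apply_formation(a, -0.1), "non-negative")
  expect_error(apply_formation(a, 0.9), "above 1")
})

test_that("windowed resorption removes uniformly inside the window", {
  p <- small_mineral()
  a <- initialize_cohorts(0.4, p)
  win <- resorption_window(10, "windowed", t_nm = p$t_nm)
  amount <- 0.01
  b <- apply_resorption(a, amount, win)
  expect_equal(sum(b), sum(a) - amount)
  idx <- (p$t_nm:(p$t_nm + 9)) + 1
  expect_equal(unclass(b[-idx]), unclass(a[-idx]))  # outside the window untouched
  expect_equal(unclass(a[idx] - b[idx]), rep(amount / 10, 10))
  expect_equal(apply_resorption(a, 0, win), a, ignore_attr = TRUE)
  expect_error(apply_resorption(a, -1e-3, win), "non-negative")
})

test_that("resorption strategies match the greedy scalar oracle", {
  p <- small_mineral()
  win <- resorption_window(10, "windowed", t_nm = p$t_nm)
  set.seed(42)
  for (k in 1:20) {
    a <- make_fixture("random_valid", seed = k, vb0 = 0.4, params = p)
    # punch holes in the window so spillover engages
    a[(p$t_nm + 1):(p$t_nm + 4)] <- 0
    amount <- runif(1, 0, 0.2)
    got <- apply_resorption(a, amount, win)
    ora <- oracle_windowed_resorption(as.numeric(a), amount, p$t_nm, 10)
    expect_equal(as.numeric(got), ora$x, tolerance = 1e-12)
    expect_equal(sum(a) - sum(got), amount, tolerance = 1e-12)
  }
})

test_that("newest-only and age-averaged strategies behave as defined", {
  p <- small_mineral()
  a <- initialize_cohorts(0.4, p)
  a <- apply_formation(a, 0.05)
  new_win <- resorption_window(1, "newest_only", t_nm = p$t_nm)
  b <- apply_resorption(a, 0.03, new_win)
  expect_equal(b[1], 0.02)                       # eaten from age 0 first
  expect_equal(unclass(b[-1]), unclass(a[-1]))
  b2 <- apply_resorption(a, 0.06, new_win)       # spills into age-1 bin
  expect_equal(b2[1], 0)
  expect_equal(sum(b2), sum(a) - 0.06)
  prop_win <- resorption_window(1, "age_averaged", t_nm = p$t_nm)
  c1 <- apply_resorption(a, 0.09, prop_win)
  expect_equal(as.numeric(c1), as.numeric(a) * (1 - 0.09 / sum(a)))
})

test_that("requesting more bone than exists empties the array with a shortfall", {
  p <- small_mineral()
  a <- initialize_cohorts(0.1, p)
  win <- resorption_window(10, "windowed", t_nm = p$t_nm)
  b <- apply_resorption(a, 0.25, win)
  expect_equal(sum(b), 0)
  expect_equal(attr(b, "shortfall"), 0.15, tolerance = 1e-12)
  expect_equal(attr(b, "removed"), 0.1, tolerance = 1e-12)
})

test_that("case aliases map onto the strategy names", {
  expect_equal(resorption_window(5, "case3")$strategy, "windowed")
  expect_equal(resorption_window(5, "case2")$strategy, "newest_only")
  expect_equal(resorption_window(5, "case1")$strategy, "age_averaged")
  expect_error(resorption_window(0, "windowed"), "t_sr")
})

test_that("cohort arrays round-trip through CSV", {
  p <- small_mineral()
  a <- make_fixture("random_valid", seed = 3, vb0 = 0.25, params = p)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohorts(a, path)
  expect_equal(as.numeric(read_cohorts(path)), as.numeric(a))
})
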