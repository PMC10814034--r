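test_that("metrics agree between closed forms and numerical maximization on a rate grid", {
  taus <- seq(0.0080, 0.0090, length.out = 5)
  rhos <- seq(0.0073, 0.0078, length.out = 5)
  for (tau in taus) for (rho in rhos) {
    p <- sir_params(1e7, tau, rho, S0 = 9999999)
    w <- solve_m2(p, t_end = 1, n_points = 2)
    ex <- attr(w, "extras")
    I_fun <- attr(w, "funs")$I
    opt <- stats::optimize(I_fun, c(0.25 * ex$tm, 2 * ex$tm),
                           maximum = TRUE, tol = 1e-7 * ex$tm)
    expect_equal(opt$maximum, ex$tm, tolerance = 1e-6)
    expect_equal(opt$objective, ex$Im, tolerance = 1e-6)
    m <- compute_metrics(w)
    expect_identical(m$Im, ex$Im)
    expect_identical(m$tm, ex$tm)
  }
})

test_that("the reproduction number crosses 1 exactly at an interior peak", {
  p <- fig1_params()
  m <- compute_metrics(solve_m2(p, t_end = 60000, n_points = 601))
  expect_equal(m$t_Rn1, m$tm, tolerance = 1e-4)
  expect_gte(m$Im, p$I0)

  # numeric trajectory takes the grid-refinement path to the same answers
  s <- integrate_sir(p, t_end = 60000, n_points = 1201)
  ms <- compute_metrics(s)
  expect_equal(ms$tm, m$tm, tolerance = 0.01)
  expect_equal(ms$Im, m$Im, tolerance = 0.025)
  expect_equal(ms$t_Rn1, ms$tm, tolerance = 1e-3)
})

test_that("pure-decay waves report a zero horizon and no crossing", {
  pd <- sir_params(1e6, 0, 0.01, S0 = 9e5, I0 = 1e5)
  m <- compute_metrics(integrate_sir(pd, t_end = 500, n_points = 201))
  expect_identical(m$tm, 0)
  expect_equal(m$Im, 1e5)
  expect_true(is.na(m$t_Rn1))
})

test_that("a too-short window is extended automatically past the peak", {
  p <- fig1_params()
  s <- integrate_sir(p, t_end = 2000, n_points = 401)  # peak near t = 22500
  m <- compute_metrics(s)
  expect_equal(m$tm, 22508, tolerance = 1e-3)
})

test_that("sensitivity sweeps reproduce the directional laws of the figure grids", {
  base <- fig1_params()

  # more initial spreaders: bigger, earlier waves
  s0_grid <- c(9999999, 9999990, 9999900, 9999000, 9990000)
  sw <- sensitivity_sweep(base, "I0", 1e7 - s0_grid)
  expect_true(all(diff(sw$Im) > 0))
  expect_true(all(diff(sw$tm) < 0))

  # smaller populations (one initial spreader): smaller, earlier waves
  sw <- sensitivity_sweep(base, "N", c(1e7, 5e6, 2.5e6, 1e6))
  expect_true(all(diff(sw$Im) < 0))
  expect_true(all(diff(sw$tm) < 0))

  # faster transmission: bigger, earlier waves
  sw <- sensitivity_sweep(base, "tau", c(0.008, 0.0085, 0.00875, 0.009))
  expect_true(all(diff(sw$Im) > 0))
  expect_true(all(diff(sw$tm) < 0))

  # faster recovery: smaller waves
  sw <- sensitivity_sweep(base, "rho", c(0.00775, 0.00785, 0.075, 0.7))
  expect_true(all(diff(sw$Im) <= 0))
  expect_gt(sw$Im[1], sw$Im[3])

  # single-value sweep returns a single row
  expect_identical(nrow(sensitivity_sweep(base, "tau", 0.008)), 1L)
  expect_error(sensitivity_sweep(base, "tau", c(-1, 0.01)), "positive")
})

test_that("the A-E typology is total, deterministic and matches its definitions", {
  th <- wave_type_thresholds()
  expect_identical(classify_wave_type(2 * th$tau_hi, th$rho_lo / 2, th), "A")
  expect_identical(classify_wave_type(2 * th$tau_hi, 2 * th$rho_hi, th), "B")
  expect_identical(classify_wave_type(th$tau_lo / 2, 2 * th$rho_hi, th), "C")
  expect_identical(classify_wave_type(th$tau_lo / 2, th$rho_lo / 2, th), "D")
  expect_identical(classify_wave_type(0.008, 0.008, th), "E")

  # totality and determinism over a grid including the exact boundaries
  grid <- expand.grid(tau = c(0.001, th$tau_lo, 0.008, th$tau_hi, 0.02),
                      rho = c(0.001, th$rho_lo, 0.008, th$rho_hi, 0.02))
  types <- mapply(classify_wave_type, grid$tau, grid$rho,
                  MoreArgs = list(thresholds = th))
  expect_true(all(types %in% c("A", "B", "C", "D", "E")))
  types2 <- mapply(classify_wave_type, grid$tau, grid$rho,
                   MoreArgs = list(thresholds = th))
  expect_identical(types, types2)
  # boundary points resolve away from E toward a corner type
  expect_identical(classify_wave_type(th$tau_hi, th$rho_lo, th), "A")

  # E-transitions: raising both rates gives B; raising tau, lowering rho, A
  expect_identical(classify_wave_type(0.008 * 2, 0.008 * 2, th), "B")
  expect_identical(classify_wave_type(0.008 * 2, 0.008 / 4, th), "A")

  expect_error(wave_type_thresholds(tau_lo = 0.02, tau_hi = 0.01), "tau_lo")
  expect_error(classify_wave_type(-1, 0.01, th), "positive")
})
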