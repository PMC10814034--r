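test_that("theta obeys its limits and its discriminant identity", {
  # transmission off: only the (-rho)^2 term survives
  p0 <- sir_params(1e6, 0, 0.01, S0 = 9e5, I0 = 1e5)
  expect_equal(wave_theta(p0), 0.01)
  # fully susceptible population: second term vanishes
  pN <- sir_params(1e6, 0.02, 0.005, S0 = 1e6, I0 = 0)
  expect_equal(wave_theta(pN), abs(0.02 - 0.005))

  # theta^2 = alpha1^2 - 4 alpha0 alpha2 (fig-1 scenario and random sets)
  set.seed(11)
  for (p in c(list(fig1_params()), replicate(10, random_params(),
                                             simplify = FALSE))) {
    a <- compute_alphas(p, 2)$alpha
    th <- wave_theta(p)
    expect_equal(th^2, a[2]^2 - 4 * a[1] * a[3], tolerance = 1e-12)
  }
})

test_that("the quadratic closed form starts at R(0) = 0 and reaches its plateau", {
  p <- fig1_params()
  w <- solve_m2(p, t_end = 80000, n_points = 801)
  ex <- attr(w, "extras")
  a <- ex$alpha
  expect_lt(abs(w$R[1]), 1e-9 * p$N)
  expect_equal(w$I[1], p$I0, tolerance = 1e-9)
  # large-time limit -alpha1/(2 alpha2) - theta/(2 alpha2)
  R_inf <- -a[2] / (2 * a[3]) - ex$theta / (2 * a[3])
  expect_equal(ex$R_inf, R_inf, tolerance = 1e-12)
  expect_equal(attr(w, "funs")$R(1e7), R_inf, tolerance = 1e-9)
  # active counts stay nonnegative on the canonical branch
  expect_true(all(w$I >= 0))
})

test_that("infeasible integration constants are rejected", {
  p <- fig1_params()
  a2 <- compute_alphas(p, 2)$alpha[3]
  th <- wave_theta(p)
  expect_error(solve_m2(p, D = th / (-2 * a2), E = 1, t_end = 10),
               "infeasible")
  expect_error(solve_m2(p, D = 1, E = 0, t_end = 10), "E = 0")
  expect_error(solve_m2(p, D = 0, E = 0, t_end = 10), "degenerate")
  expect_error(solve_m2(p, t_grid = c(-5, 0, 5)), "t >= 0")
})

test_that("closed forms certify against the chain equation by residual", {
  p <- fig1_params()
  expect_lt(residual_m2(p), 1e-5)
  # admissible D != 0 branch certifies too, and the family depends on D/E only
  a2 <- compute_alphas(p, 2)$alpha[3]
  G <- 0.4 * wave_theta(p) / (-2 * a2)
  expect_lt(residual_m2(p, D = G, E = 1), 1e-5)
  w1 <- solve_m2(p, D = G, E = 1, t_end = 50000, n_points = 301)
  w2 <- solve_m2(p, D = 7 * G, E = 7, t_end = 50000, n_points = 301)
  expect_equal(w1$R, w2$R, tolerance = 1e-12)
  expect_lt(abs(w1$R[1]), 1e-9 * p$N)
})

test_that("the general branch converges to the canonical one as D -> 0", {
  p <- fig1_params()
  tg <- seq(0, 60000, length.out = 301)
  w0 <- solve_m2(p, D = 0, E = 1, t_grid = tg)
  wd <- solve_m2(p, D = 1e-6, E = 1, t_grid = tg)
  expect_lt(sup_rel_err(wd, w0, "R"), 1e-5)
  expect_lt(sup_rel_err(wd, w0, "I"), 1e-4)
})

test_that("closed-form peak time and amplitude match numerical maximization", {
  p <- fig1_params()
  w <- solve_m2(p, t_end = 80000, n_points = 801)
  ex <- attr(w, "extras")
  a <- ex$alpha
  expect_equal(ex$tm, (2 / ex$theta) * atanh(a[2] / ex$theta),
               tolerance = 1e-12)
  expect_equal(ex$Im, ex$theta^2 * p$N^2 / (2 * p$tau^2 * p$S0),
               tolerance = 1e-12)
  I_fun <- attr(w, "funs")$I
  opt <- stats::optimize(I_fun, c(0.5 * ex$tm, 1.5 * ex$tm), maximum = TRUE,
                         tol = 1e-6)
  expect_equal(opt$maximum, ex$tm, tolerance = 1e-6)
  expect_equal(opt$objective, ex$Im, tolerance = 1e-6)
})

test_that("the D != 0 correction at t = -C is ordered between its bounds", {
  p <- fig1_params()
  a <- compute_alphas(p, 2)$alpha
  ref <- -a[2] / (2 * a[3])

  cz <- correction_at_minus_C(p, D = 0, E = 1)
  expect_equal(cz$value, cz$reference_D0)
  expect_equal(cz$reference_D0, ref)

  # at the supremum of D/E the value attains the upper bound
  cs <- correction_at_minus_C(p, D = cz$G_max, E = 1)
  expect_equal(cs$value, cs$upper_bound, tolerance = 1e-12)
  expect_equal(cs$upper_bound, ref - wave_theta(p) / (2 * a[3]))

  # any admissible ratio lies strictly between the references
  cm <- correction_at_minus_C(p, D = 0.3 * cz$G_max, E = 1)
  expect_gt(cm$value, cm$reference_D0)
  expect_lt(cm$value, cm$upper_bound)

  pdecay <- sir_params(1e6, 0.005, 0.05, S0 = 1e6 - 10, I0 = 10)
  expect_error(correction_at_minus_C(pdecay, D = 1, E = 1), "alpha1")
})

test_that("the quadratic wave tracks the full SIR oracle near the peak", {
  set.seed(23)
  for (i in 1:8) {
    # gentle waves whose expansion ratio stays below 0.02
    N <- 10^stats::runif(1, 6, 8)
    rho <- 10^stats::runif(1, -3, -1.5)
    tau <- rho * (1 + stats::runif(1, 0.001, 0.004))
    I0 <- ceiling(stats::runif(1, 1, 10))
    p <- sir_params(N, tau, rho, S0 = N - I0, I0 = I0)
    w <- solve_m2(p, t_end = 1, n_points = 2)
    ex <- attr(w, "extras")
    expect_lte(validity_bound(p, ex$R_inf, 2)$x, 0.02)
    s <- integrate_sir(p, 3 * ex$tm, 601)
    I_sir <- stats::splinefun(s$t, s$I)
    expect_lt(abs(I_sir(ex$tm) - ex$Im) / I_sir(ex$tm), 0.02)
  }
})
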