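test_that("chain coefficients match direct evaluation of their formulas", {
  p <- fig1_params()
  co <- compute_alphas(p, M = 2)
  # independent arithmetic, term by term
  expect_equal(co$alpha[1], 0.00775 * (1e7 - 9999999))
  expect_equal(co$alpha[2], 0.00825 * 9999999 / 1e7 - 0.00775)
  expect_equal(co$alpha[2], 4.99999175e-4, tolerance = 1e-9)
  expect_equal(co$alpha[3], -0.00825^2 * 9999999 / (2 * 0.00775 * 1e14))
  expect_lt(co$alpha[3], 0)

  # whole population susceptible: constant term vanishes
  pN <- sir_params(1e6, 0.02, 0.01, S0 = 1e6, I0 = 0)
  expect_equal(compute_alphas(pN, 2)$alpha[1], 0)

  expect_error(compute_alphas(p, M = 1), "order")
  expect_error(compute_alphas(p, M = 2.5), "order")
})

test_that("coefficient signs alternate: negative even, positive odd (j >= 2)", {
  set.seed(7)
  for (i in 1:50) {
    p <- random_params()
    M <- sample(2:6, 1)
    a <- compute_alphas(p, M)$alpha
    expect_gte(a[1], 0)
    j <- 2:M
    expect_true(all(a[j + 1][j %% 2 == 0] < 0))
    if (any(j %% 2 == 1)) expect_true(all(a[j + 1][j %% 2 == 1] > 0))
  }
})

test_that("the polynomial right-hand side evaluates stably", {
  p <- fig1_params()
  co <- compute_alphas(p, 4)
  expect_equal(truncated_rhs(0, co), co$alpha[1])

  # nested evaluation agrees with the naive power sum at moderate R
  R <- c(1, 1e3, 1e5, 5e5)
  naive <- sapply(R, function(r) sum(co$alpha * r^(0:4)))
  expect_equal(truncated_rhs(R, co), naive, tolerance = 1e-12)

  # the Riccati fixed point (the wave plateau) is a root of the quadratic
  co2 <- compute_alphas(p, 2)
  theta <- wave_theta(p)
  root <- (co2$alpha[2] + theta) / (2 * abs(co2$alpha[3]))
  expect_lt(abs(truncated_rhs(root, co2)), 1e-9 * co2$alpha[1])

  # order-2 and order-3 evaluations differ by at most the cubic term
  co3 <- compute_alphas(p, 3)
  Rsmall <- 1e-4 * p$rho * p$N / p$tau
  expect_lte(abs(truncated_rhs(Rsmall, co3) - truncated_rhs(Rsmall, co2)),
             abs(co3$alpha[4]) * Rsmall^3 * (1 + 1e-12))
})

test_that("validity bound reproduces the worked truncation numbers", {
  p <- sir_params(1e7, 0.01, 0.01, S0 = 1e7 - 1)
  expect_equal(validity_bound(p, 0, 2)$bound, 0)
  vb <- validity_bound(p, 1e5, 2)
  expect_equal(vb$x, 0.01)
  expect_equal(exp(vb$x), 1.010050167, tolerance = 1e-9)
  # cubic family at its large-time limit: x = 1, bound = e/4! ~ 0.113
  a <- fig9_args()
  w <- solve_m3(N = a$N, S0 = a$S0, tau = a$tau, t_end = 10, n_points = 2)
  ex <- attr(w, "extras")
  p9 <- attr(w, "params")
  vb3 <- validity_bound(p9, ex$R_inf, M = 3)
  expect_equal(vb3$x, 1, tolerance = 1e-12)
  expect_equal(vb3$bound, exp(1) / factorial(4), tolerance = 1e-12)
  expect_equal(round(vb3$bound, 3), 0.113)
  expect_error(validity_bound(p, -3, 2), ">= 0")
})

test_that("the truncated chain integrates to the same wave as the closed forms", {
  p <- fig1_params()
  w <- solve_m2(p, t_end = 60000, n_points = 801)
  ch <- integrate_chain(compute_alphas(p, 2), t_end = 60000, n_points = 801)
  expect_lt(sup_rel_err(w, ch, "R"), 1e-6)
  expect_lt(sup_rel_err(w, ch, "I"), 1e-6)

  # degenerate chain: all coefficients zero stays at R = 0
  co0 <- structure(list(M = 2L, alpha = c(0, 0, 0), params = p),
                   class = "chain_coefficients")
  tr0 <- integrate_chain(co0, t_end = 100, n_points = 11)
  expect_equal(tr0$R, rep(0, 11))

  # cubic family under its rate constraint
  a <- fig9_args()
  w3 <- solve_m3(N = a$N, S0 = a$S0, tau = a$tau, t_end = 3000,
                 n_points = 801)
  p9 <- attr(w3, "params")
  ch3 <- integrate_chain(compute_alphas(p9, 3), t_end = 3000, n_points = 801)
  expect_lt(sup_rel_err(w3, ch3, "R"), 1e-6)
  expect_lt(sup_rel_err(w3, ch3, "I"), 1e-6)
})

test_that("successive truncation orders converge for small expansion ratios", {
  p <- sir_params(1e7, 0.00778, 0.00775, S0 = 9999999)
  tm <- attr(solve_m2(p, t_end = 1, n_points = 2), "extras")$tm
  runs <- lapply(2:5, function(M)
    integrate_chain(compute_alphas(p, M), t_end = 3 * tm, n_points = 401))
  x_max <- validity_bound(p, max(runs[[1]]$R), 2)$x
  expect_lt(x_max, 0.01)
  d <- sapply(1:3, function(i) sup_rel_err(runs[[i]], runs[[i + 1]], "R"))
  expect_true(all(diff(d) < 0))
})

test_that("chain error against the full SIR system is controlled by the expansion ratio", {
  for (tau in c(0.008, 0.00825)) {
    p <- sir_params(1e7, tau, 0.00775, S0 = 9999999)
    tm <- attr(solve_m2(p, t_end = 1, n_points = 2), "extras")$tm
    ch <- integrate_chain(compute_alphas(p, 2), 3 * tm, 801)
    s <- integrate_sir(p, 3 * tm, 801)
    err <- sup_rel_err(ch, s, "R")
    x_max <- max(validity_bound(p, max(s$R), 2)$x)
    expect_lt(err, 10 * x_max)
  }
})
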