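#' Composite rate of the quadratic (Riccati) wave
#'
#' At truncation order `M = 2` the chain equation is a Riccati equation
#' whose hyperbolic-tangent solution is governed by the composite rate
#' \deqn{\theta = \left[ \left( \frac{\tau S(0)}{N} - \rho \right)^2 +
#'   \frac{2 \tau^2 S(0) [N - S(0)]}{N^2} \right]^{1/2},}
#' the positive square root. Algebraically
#' \eqn{\theta^2 = \alpha_1^2 - 4 \alpha_0 \alpha_2}, the discriminant of the
#' quadratic right-hand side.
#'
#' @param params A [sir_params()] object.
#' @return `theta` (per time unit, >= 0).
#' @export
wave_theta <- function(params) {
  stopifnot(inherits(params, "sir_params"))
  N <- params$N; tau <- params$tau; rho <- params$rho
  S0 <- effective_s0(params)
  sqrt((tau * S0 / N - rho)^2 + 2 * tau^2 * S0 * (N - S0) / N^2)
}

# Numerically safe sech^2: 1/cosh(u)^2 without overflow for large |u|.
sech2 <- function(u) {
  e <- exp(-2 * abs(u))
  4 * e / (1 + e)^2
}

# Solution constants for the M = 2 Riccati family. A nonzero R(0) is
# handled by expanding the chain with the effective S(0)* (so the equation
# holds in the actual, unshifted R) and fitting the time-shift constant C to
# R(0) = R0; this is supported on the D = 0 branch only.
m2_constants <- function(params, D, E) {
  if (!is.numeric(D) || !is.numeric(E) || length(D) != 1L || length(E) != 1L)
    stop("`D` and `E` must be single numbers", call. = FALSE)
  if (E == 0)
    stop(if (D == 0) "D = 0 with E = 0 is degenerate (no solution selected)"
         else "the E = 0 branch is a formal possibility only and is not supported",
         call. = FALSE)
  if (D != 0 && params$R0 != 0)
    stop("nonzero R(0) is supported only on the D = 0 branch", call. = FALSE)
  co <- compute_alphas(params, M = 2L)
  a0 <- co$alpha[1L]; a1 <- co$alpha[2L]; a2 <- co$alpha[3L]
  theta <- wave_theta(params)
  z <- if (D == 0) {
    # tanh(theta C / 2) at t = 0 must place R at R(0)
    -(a1 + 2 * a2 * params$R0) / theta
  } else {
    theta * (a1 * E - 2 * a2 * D) / (2 * a1 * a2 * D - theta^2 * E)
  }
  if (!is.finite(z) || abs(z) >= 1)
    stop("integration constants are infeasible: atanh argument ",
         format(z), " outside (-1, 1)", call. = FALSE)
  C <- (2 / theta) * atanh(z)
  list(a0 = a0, a1 = a1, a2 = a2, theta = theta, C = C, D = D, E = E,
       coeffs = co)
}

#' Closed-form quadratic (M = 2) wave solution
#'
#' Evaluates the exact hyperbolic-tangent solution of the Riccati-truncated
#' chain equation,
#' \deqn{R(t) = -\frac{\alpha_1}{2\alpha_2}
#'   - \frac{\theta}{2\alpha_2} \tanh\frac{\theta (t + C)}{2}
#'   + \frac{D\, \mathrm{sech}^2[\theta (t+C)/2]}
#'          {E - (2\alpha_2 D/\theta) \tanh[\theta (t+C)/2]},}
#' with the time-shift constant `C` fixed by the initial removed count
#' (`R(0) = 0` in the canonical setup). The two-parameter
#' family depends on the integration constants only through `G = D/E`; the
#' canonical news wave is the `D = 0` branch, for which the active count is
#' the symmetric pulse \eqn{I(t) = I_m\, \mathrm{sech}^2[\theta (t - t_m)/2]}.
#' `I` is evaluated from the explicit derivative formula (not numerically)
#' and `S` from the linearized first integral.
#'
#' @param params A [sir_params()] object.
#' @param D,E Integration constants (`D = 0`, `E = 1` canonical). `E = 0` is
#'   rejected; for `D != 0` the atanh-domain feasibility condition must hold.
#' @param t_grid Time grid (>= 0); alternatively give `t_end` (+ `n_points`).
#' @param t_end,n_points Uniform-grid shortcut used when `t_grid` is `NULL`.
#' @return A [wave_trajectory] with `source = "analytic-M2"`; `extras`
#'   records `theta`, `C`, `D`, `E`, the large-time limit `R_inf`, and for
#'   `D = 0` the closed-form peak time `tm` and amplitude `Im`.
#' @examples
#' p <- sir_params(N = 1e7, tau = 0.00825, rho = 0.00775, S0 = 9999999)
#' w <- solve_m2(p, t_end = 60000, n_points = 601)
#' attr(w, "extras")$Im   # peak number of active spreaders
#' @export
solve_m2 <- function(params, D = 0, E = 1, t_grid = NULL,
                     t_end = NULL, n_points = 1001L) {
  stopifnot(inherits(params, "sir_params"))
  k <- m2_constants(params, D, E)
  if (is.null(t_grid)) {
    if (is.null(t_end)) stop("supply `t_grid` or `t_end`", call. = FALSE)
    t_grid <- seq(0, t_end, length.out = n_points)
  }
  if (any(t_grid < 0))
    stop("the closed forms are evaluated for t >= 0 only", call. = FALSE)

  a1 <- k$a1; a2 <- k$a2; theta <- k$theta; C <- k$C
  rho <- params$rho
  R0 <- params$R0
  base <- -a1 / (2 * a2)

  R_fun <- function(t) {
    u <- theta * (t + C) / 2
    Tn <- tanh(u)
    out <- base - theta / (2 * a2) * Tn
    if (D != 0) {
      Q <- E - (2 * a2 * D / theta) * Tn
      out <- out + D * sech2(u) / Q
    }
    out
  }
  # explicit dR/dt (time derivative of the closed form), I = (1/rho) dR/dt
  I_fun <- function(t) {
    u <- theta * (t + C) / 2
    Tn <- tanh(u)
    s2 <- sech2(u)
    dR <- -theta^2 / (4 * a2) * s2
    if (D != 0) {
      Q <- E - (2 * a2 * D / theta) * Tn
      dR <- dR - D * theta * Tn * s2 / Q + a2 * D^2 * s2^2 / Q^2
    }
    dR / rho
  }
  S_fun <- function(t) {
    effective_s0(params) *
      (1 - params$tau * R_fun(t) / (rho * params$N))
  }

  R <- R_fun(t_grid); I <- I_fun(t_grid); S <- S_fun(t_grid)
  if (min(t_grid) == 0 && abs(R[which.min(t_grid)] - R0) > 1e-9 * params$N)
    stop("integration constants are infeasible: R(0) misses its target ",
         "(atanh argument too close to the domain boundary)", call. = FALSE)
  if (D == 0 && any(I < -1e-9 * params$N))
    stop("internal error: negative active count on the D = 0 branch",
         call. = FALSE)

  extras <- list(theta = theta, C = C, D = D, E = E, M = 2L, rate = theta,
                 alpha = k$coeffs$alpha,
                 R_inf = base - theta / (2 * a2))
  if (D == 0) {
    # the peak of I sits where the tanh argument vanishes, t = -C; it lies
    # at t >= 0 only for growing waves (alpha1 + 2 alpha2 R0 > 0).
    # Im = -theta^2 / (4 rho alpha2) = theta^2 N^2 / (2 tau^2 S0*).
    arg <- (a1 + 2 * a2 * R0) / theta
    if (arg > 0) {
      extras$tm <- (2 / theta) * atanh(arg)
      extras$Im <- -theta^2 / (4 * rho * a2)
    } else {
      extras$tm <- 0
      extras$Im <- I_fun(0)
    }
  }
  new_trajectory(t = t_grid, S = S, I = I, R = R, source = "analytic-M2",
                 params = params,
                 funs = list(R = R_fun, I = I_fun, S = S_fun),
                 extras = extras)
}

#' Residual certification of the quadratic closed form
#'
#' Verifies that the closed-form trajectory actually solves the truncated
#' chain equation: computes
#' \eqn{\max_t |dR/dt - (\alpha_0 + \alpha_1 R + \alpha_2 R^2)| / \alpha_0}
#' with `dR/dt` from fourth-order central finite differences (step
#' `0.002 / theta`), so the check is independent of the explicit derivative
#' used inside [solve_m2()]. A certified solution has residual below `1e-5`.
#'
#' @inheritParams solve_m2
#' @return Maximum normalized residual over the grid.
#' @export
residual_m2 <- function(params, D = 0, E = 1, t_grid = NULL,
                        t_end = NULL, n_points = 201L) {
  k <- m2_constants(params, D, E)
  if (is.null(t_grid)) {
    if (is.null(t_end)) t_end <- 3 * abs(k$C) + 6 / k$theta
    t_grid <- seq(0, t_end, length.out = n_points)
  }
  w <- solve_m2(params, D = D, E = E, t_grid = t_grid)
  R_fun <- traj_funs(w)$R
  h <- 0.002 / k$theta
  t <- t_grid  # the closed form extends to t < 0, so the stencil may cross 0
  dR <- (-R_fun(t + 2 * h) + 8 * R_fun(t + h) -
           8 * R_fun(t - h) + R_fun(t - 2 * h)) / (12 * h)
  Ri <- R_fun(t)
  rhs <- k$a0 + k$a1 * Ri + k$a2 * Ri^2
  max(abs(dR - rhs)) / k$a0
}

#' Correction of the general (D != 0) branch at t = -C
#'
#' At the characteristic time `t = -C` the general quadratic solution takes
#' the value \eqn{R(-C) = -\alpha_1/(2\alpha_2) + D/E}. Under the
#' admissibility assumptions `D > 0`, `E > 0`, `alpha_1 > 0` (and
#' `alpha_2 < 0` always), the ratio is bounded by
#' \eqn{D/E < \theta / (-2 \alpha_2)}, so the value lies between the `D = 0`
#' reference \eqn{-\alpha_1/(2\alpha_2)} and the upper bound
#' \eqn{-\alpha_1/(2\alpha_2) - \theta/(2\alpha_2)} (which is also the
#' large-time limit of the wave).
#'
#' @param params A [sir_params()] object with `alpha_1 > 0`.
#' @param D,E Integration constants, `D >= 0`, `E > 0`.
#' @return A list with `value`, `upper_bound`, `reference_D0`, and the
#'   admissible supremum `G_max = theta / (-2 alpha_2)` of `D/E`.
#' @export
correction_at_minus_C <- function(params, D, E) {
  stopifnot(inherits(params, "sir_params"))
  co <- compute_alphas(params, M = 2L)
  a1 <- co$alpha[2L]; a2 <- co$alpha[3L]
  if (a1 <= 0)
    stop("the correction analysis assumes alpha1 > 0 (growing wave)",
         call. = FALSE)
  if (D < 0 || E <= 0)
    stop("the correction analysis assumes D >= 0 and E > 0", call. = FALSE)
  theta <- wave_theta(params)
  G_max <- theta / (-2 * a2)
  if (D / E >= G_max * (1 + 1e-12))
    warning("D/E exceeds its admissible supremum theta / (-2 alpha2)",
            call. = FALSE)
  list(value = -a1 / (2 * a2) + D / E,
       upper_bound = -a1 / (2 * a2) - theta / (2 * a2),
       reference_D0 = -a1 / (2 * a2),
       G_max = G_max)
}
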