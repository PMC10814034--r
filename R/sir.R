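#' Integrate the full SIR news-wave system
#'
#' Solves the SIR system
#' \deqn{dS/dt = -(\tau/N) S I, \quad dI/dt = (\tau/N) S I - \rho I, \quad
#'       dR/dt = \rho I}
#' with an adaptive, stiff-capable integrator (`deSolve::lsoda`, relative
#' tolerance `1e-9`, absolute tolerance `1e-9 * N`) sampled on a uniform time
#' grid. This is the ground-truth oracle against which the closed-form wave
#' solutions are checked.
#'
#' @param params A [sir_params()] object.
#' @param t_end End of the integration window (time units, > 0).
#' @param n_points Number of grid points including `t = 0` (>= 2).
#' @return A [wave_trajectory] with `source = "numeric-SIR"`.
#' @examples
#' p <- sir_params(N = 1e7, tau = 0.00825, rho = 0.00775, S0 = 9999999)
#' traj <- integrate_sir(p, t_end = 60000, n_points = 601)
#' max(traj$I)
#' @export
integrate_sir <- function(params, t_end, n_points = 1001L) {
  stopifnot(inherits(params, "sir_params"))
  if (!is.numeric(t_end) || t_end <= 0) stop("`t_end` must be > 0", call. = FALSE)
  if (n_points < 2L) stop("`n_points` must be >= 2", call. = FALSE)
  times <- seq(0, t_end, length.out = n_points)
  rhs <- function(t, y, p) {
    infection <- p$tau / p$N * y[["S"]] * y[["I"]]
    recovery <- p$rho * y[["I"]]
    list(c(S = -infection, I = infection - recovery, R = recovery))
  }
  sol <- deSolve::lsoda(
    y = c(S = params$S0, I = params$I0, R = params$R0),
    times = times, func = rhs, parms = params,
    rtol = 1e-9, atol = 1e-9 * params$N
  )
  if (nrow(sol) < n_points || any(!is.finite(sol)))
    stop("SIR integration failed near t = ",
         format(sol[nrow(sol), "time"]), call. = FALSE)
  traj <- new_trajectory(t = sol[, "time"], S = sol[, "S"], I = sol[, "I"],
                         R = sol[, "R"], source = "numeric-SIR",
                         params = params)
  validate_trajectory(traj)
}

#' Logarithmic growth rate of the active-spreader count
#'
#' Computes \eqn{\sigma(t) = (1/I) dI/dt}, the logarithmic derivative of the
#' number of active spreaders, by central finite differences of `log(I)` on
#' the trajectory grid (one-sided differences at the endpoints). Central
#' differencing of the logarithm is exact for exponential growth or decay.
#' Grid points where `I` falls below `1e-12 * N` are reported as `NA`: at the
#' wave tail the ratio degenerates to 0/0 noise.
#'
#' @param trajectory A [wave_trajectory].
#' @return Numeric vector of `sigma` values, one per grid point (`NA` where
#'   undefined). If `I` is zero everywhere a warning is issued and all values
#'   are `NA`.
#' @export
growth_rate <- function(trajectory) {
  stopifnot(inherits(trajectory, "wave_trajectory"))
  params <- traj_params(trajectory)
  t <- trajectory$t
  I <- trajectory$I
  floor_I <- 1e-12 * params$N
  ok <- I > floor_I
  if (!any(ok)) {
    warning("active-spreader count is zero on the whole grid; ",
            "growth rate undefined everywhere", call. = FALSE)
    return(rep(NA_real_, length(t)))
  }
  logI <- ifelse(ok, log(pmax(I, floor_I)), NA_real_)
  n <- length(t)
  sigma <- rep(NA_real_, n)
  if (n >= 2L) {
    sigma[1L] <- (logI[2L] - logI[1L]) / (t[2L] - t[1L])
    sigma[n] <- (logI[n] - logI[n - 1L]) / (t[n] - t[n - 1L])
  }
  if (n >= 3L) {
    idx <- 2:(n - 1L)
    sigma[idx] <- (logI[idx + 1L] - logI[idx - 1L]) / (t[idx + 1L] - t[idx - 1L])
  }
  sigma[!ok] <- NA_real_
  sigma
}

#' Time-varying effective reproduction number
#'
#' Computes \eqn{R_n(t) = 1 + \sigma(t)/\rho} from the logarithmic growth
#' rate \eqn{\sigma}. The wave grows while \eqn{R_n > 1}, peaks at
#' \eqn{R_n = 1}, and decays while \eqn{R_n < 1}.
#'
#' @param trajectory A [wave_trajectory].
#' @param rho Recovery rate (> 0); defaults to the trajectory's own.
#' @return Numeric vector of `Rn` values per grid point (`NA` where `sigma`
#'   is undefined).
#' @export
effective_reproduction_number <- function(trajectory,
                                          rho = traj_params(trajectory)$rho) {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0)
    stop("recovery rate `rho` must be a single number > 0", call. = FALSE)
  1 + growth_rate(trajectory) / rho
}

#' Susceptible count as a function of the removed count
#'
#' The SIR system constrains the susceptible pool to
#' \deqn{S = S(0) \exp[-\tau (R - R(0)) / (\rho N)],}
#' an exact first integral. For waves that touch only a small fraction of the
#' population the exponent is small and the first-order (linearized) form
#' \eqn{S = S(0) [1 - \tau (R - R(0)) / (\rho N)]} is adequate; the two agree
#' to second order in \eqn{x = \tau (R - R(0)) / (\rho N)}.
#'
#' @param params A [sir_params()] object.
#' @param R Removed count(s) (persons, `>= R0`).
#' @param linearized If `TRUE`, use the first-order form.
#' @return Susceptible count(s). A warning is raised if the linearized form
#'   goes negative (linearization used outside its validity range).
#' @export
susceptibles_from_R <- function(params, R, linearized = FALSE) {
  stopifnot(inherits(params, "sir_params"))
  if (any(R < params$R0 - 1e-9 * params$N))
    stop("`R` must be >= R(0)", call. = FALSE)
  x <- params$tau * (R - params$R0) / (params$rho * params$N)
  S <- if (linearized) params$S0 * (1 - x) else params$S0 * exp(-x)
  if (linearized && any(S < 0))
    warning("linearized susceptible count is negative: the wave is outside ",
            "the validity range of the first-order form", call. = FALSE)
  S
}
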