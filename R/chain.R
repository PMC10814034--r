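#' Coefficients of the truncated polynomial chain
#'
#' The SIR system reduces to a single equation for the removed count,
#' \deqn{dR/dt = \rho [N - R - S(0) e^{-\tau R /(\rho N)}],}
#' (after a nonzero `R(0)` is absorbed into the effective susceptible
#' coefficient \eqn{S(0)^* = S(0) e^{\tau R(0)/(\rho N)}}). Truncating the
#' exponential at polynomial order `M` yields
#' \deqn{dR/dt = \sum_{j=0}^{M} \alpha_j R^j} with
#' \deqn{\alpha_0 = \rho [N - S(0)], \quad \alpha_1 = \tau S(0)/N - \rho,
#'       \quad \alpha_j = -(-1)^j \frac{\tau^j S(0)}{j!\, \rho^{j-1} N^j},
#'       \ j \ge 2.}
#' The higher coefficients alternate in sign: negative for even `j >= 2`,
#' positive for odd `j >= 3`.
#'
#' @param params A [sir_params()] object.
#' @param M Truncation order (integer >= 2).
#' @return A `chain_coefficients` object: list with `M`, `alpha` (numeric
#'   vector of length `M + 1`, coefficients of `R^0 .. R^M`) and `params`.
#' @examples
#' p <- sir_params(N = 1e7, tau = 0.00825, rho = 0.00775, S0 = 9999999)
#' compute_alphas(p, M = 2)$alpha
#' @export
compute_alphas <- function(params, M = 2L) {
  stopifnot(inherits(params, "sir_params"))
  if (!is.numeric(M) || length(M) != 1L || M != round(M) || M < 2)
    stop("truncation order `M` must be an integer >= 2", call. = FALSE)
  M <- as.integer(M)
  N <- params$N; tau <- params$tau; rho <- params$rho
  S0 <- effective_s0(params)
  alpha <- numeric(M + 1L)
  alpha[1L] <- rho * (N - S0)
  alpha[2L] <- tau * S0 / N - rho
  for (j in 2:M) {
    alpha[j + 1L] <- -(-1)^j * tau^j * S0 / (factorial(j) * rho^(j - 1) * N^j)
  }
  structure(list(M = M, alpha = alpha, params = params),
            class = "chain_coefficients")
}

#' @export
print.chain_coefficients <- function(x, ...) {
  cat(sprintf("<chain_coefficients: M = %d>\n", x$M))
  names(x$alpha) <- paste0("alpha", seq_along(x$alpha) - 1L)
  print(x$alpha, ...)
  invisible(x)
}

#' Right-hand side of the truncated chain equation
#'
#' Evaluates \eqn{\sum_{j=0}^{M} \alpha_j R^j} in nested (Horner) order:
#' the coefficients span many orders of magnitude and naive power sums lose
#' precision.
#'
#' @param R Removed count(s) (persons).
#' @param coeffs A [compute_alphas()] result.
#' @return `dR/dt` at each `R`.
#' @export
truncated_rhs <- function(R, coeffs) {
  stopifnot(inherits(coeffs, "chain_coefficients"))
  a <- coeffs$alpha
  out <- rep(a[length(a)], length(R))
  for (j in rev(seq_len(length(a) - 1L))) {
    out <- out * R + a[j]
  }
  out
}

#' Taylor-truncation validity bound
#'
#' The truncation of \eqn{e^{-\tau R/(\rho N)}} at order `M` is controlled by
#' the Lagrange remainder estimate
#' \deqn{\frac{e}{(M+1)!} \left( \frac{\tau R}{\rho N} \right)^{M+1} \ll 1.}
#' Both the prefactored bound and the raw ratio \eqn{x = \tau R/(\rho N)}
#' are returned, since discussions of validity alternate between them.
#' "Much less than one" is operationalized as a configurable threshold
#' (default 0.1): a bound of about 0.113 (the cubic solution at its
#' large-time limit, where `x = 1`) is still acceptable in practice, so
#' exceeding the threshold is a warning sign, not a hard failure.
#'
#' @param params A [sir_params()] object.
#' @param R Removed count(s) (persons, >= 0).
#' @param M Truncation order (integer >= 2).
#' @return A data frame with columns `x` (raw ratio) and `bound`
#'   (`e/(M+1)! * x^(M+1)`), one row per element of `R`.
#' @examples
#' p <- sir_params(N = 1e7, tau = 0.01, rho = 0.01, S0 = 1e7 - 1)
#' validity_bound(p, R = 1e5, M = 2)   # x = 0.01
#' @export
validity_bound <- function(params, R, M = 2L) {
  stopifnot(inherits(params, "sir_params"))
  if (any(R < 0)) stop("`R` must be >= 0", call. = FALSE)
  x <- params$tau * R / (params$rho * params$N)
  data.frame(x = x, bound = exp(1) / factorial(M + 1) * x^(M + 1))
}

#' Integrate the truncated polynomial chain
#'
#' Numerically integrates \eqn{dR/dt = \sum_j \alpha_j R^j} from `R(0) = R0`
#' (adaptive `lsoda`, same tolerances as [integrate_sir()]); the active
#' count is recovered as \eqn{I = (1/\rho) dR/dt} and the susceptible count
#' from the linearized first integral. This is a second, independent oracle
#' for the closed-form solutions: both solve the same truncated equation, so
#' they must agree to integration tolerance.
#'
#' @param coeffs A [compute_alphas()] result.
#' @param t_end End of the integration window (> 0).
#' @param n_points Grid size (>= 2).
#' @return A [wave_trajectory] with `source = "numeric-chain"`; the chain
#'   order is recorded in `extras$M`.
#' @export
integrate_chain <- function(coeffs, t_end, n_points = 1001L) {
  stopifnot(inherits(coeffs, "chain_coefficients"))
  if (!is.numeric(t_end) || t_end <= 0) stop("`t_end` must be > 0", call. = FALSE)
  if (n_points < 2L) stop("`n_points` must be >= 2", call. = FALSE)
  params <- coeffs$params
  times <- seq(0, t_end, length.out = n_points)
  rhs <- function(t, y, p) list(truncated_rhs(y, p))
  sol <- deSolve::lsoda(y = c(R = params$R0), times = times, func = rhs,
                        parms = coeffs, rtol = 1e-9, atol = 1e-9 * params$N)
  R <- sol[, "R"]
  if (nrow(sol) < n_points || any(!is.finite(R)) || any(R > params$N))
    stop("truncated chain blew up (R exceeded N) near t = ",
         format(sol[nrow(sol), "time"]),
         "; check the Taylor validity bound for this parameter set",
         call. = FALSE)
  I <- truncated_rhs(R, coeffs) / params$rho
  S <- effective_s0(params) * (1 - params$tau * R / (params$rho * params$N))
  new_trajectory(t = sol[, "time"], S = S, I = I, R = R,
                 source = "numeric-chain", params = params,
                 extras = list(M = coeffs$M))
}
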