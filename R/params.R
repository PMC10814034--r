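#' SIR parameter set for a news wave
#'
#' Bundles the population size, the transmission and recovery rates, and the
#' initial compartment counts of the SIR model used to describe the spread of
#' a piece of news. `S` counts potential spreaders (susceptible), `I` active
#' spreaders, and `R` individuals no longer interested (removed).
#'
#' @param N Total population size (persons, > 0). Assumed constant over the
#'   lifetime of the wave.
#' @param tau Transmission rate (per time unit, > 0): rate constant for the
#'   transition from potential to active spreader.
#' @param rho Recovery rate (per time unit, > 0): rate constant for the loss
#'   of interest, active spreader to removed.
#' @param S0,I0,R0 Initial compartment counts (persons, >= 0). Must satisfy
#'   `S0 + I0 + R0 == N` to within `1e-9 * N`. `I0` defaults to `N - S0 - R0`.
#' @return An object of class `sir_params`: a named list with fields
#'   `N`, `tau`, `rho`, `S0`, `I0`, `R0`.
#' @examples
#' p <- sir_params(N = 1e7, tau = 0.00825, rho = 0.00775, S0 = 9999999)
#' p$I0   # 1 initial spreader
#' @export
sir_params <- function(N, tau, rho, S0, I0 = N - S0 - R0, R0 = 0) {
  stopifnot(is.numeric(N), length(N) == 1L, is.finite(N))
  if (N <= 0) stop("population size `N` must be > 0", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau < 0)
    stop("transmission rate `tau` must be a finite number >= 0", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("recovery rate `rho` must be a finite number > 0", call. = FALSE)
  if (S0 < 0 || I0 < 0 || R0 < 0)
    stop("initial compartment counts must be >= 0", call. = FALSE)
  if (abs(S0 + I0 + R0 - N) > 1e-9 * N)
    stop("S0 + I0 + R0 must equal N (tolerance 1e-9 * N); got ",
         format(S0 + I0 + R0, digits = 15), " vs N = ", format(N, digits = 15),
         call. = FALSE)
  structure(
    list(N = as.numeric(N), tau = as.numeric(tau), rho = as.numeric(rho),
         S0 = as.numeric(S0), I0 = as.numeric(I0), R0 = as.numeric(R0)),
    class = "sir_params"
  )
}

#' @export
print.sir_params <- function(x, ...) {
  cat("<sir_params>\n")
  cat(sprintf("  N   = %s\n", format(x$N, big.mark = ",")))
  cat(sprintf("  tau = %g per time unit\n", x$tau))
  cat(sprintf("  rho = %g per time unit\n", x$rho))
  cat(sprintf("  S(0) = %s, I(0) = %s, R(0) = %s\n",
              format(x$S0, big.mark = ","), format(x$I0, big.mark = ","),
              format(x$R0, big.mark = ",")))
  invisible(x)
}

# Effective initial susceptible count when R(0) != 0.
# S(t) = S(0) exp(-tau (R - R(0)) / (rho N)) = S(0)* exp(-tau R / (rho N))
# with S(0)* = S(0) exp(tau R(0) / (rho N)), so a nonzero removed compartment
# at t = 0 is absorbed into the susceptible coefficient and the chain
# coefficients can always be written in terms of exp(-tau R / (rho N)).
effective_s0 <- function(params) {
  if (params$R0 == 0) return(params$S0)
  params$S0 * exp(params$tau * params$R0 / (params$rho * params$N))
}
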