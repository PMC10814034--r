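# Shared fixtures: the canonical scenario parameter sets, built in code.

fig1_params <- function() {
  sir_params(N = 1e7, tau = 0.00825, rho = 0.00775, S0 = 9999999)
}

# cubic basic scenario: N, S0, tau (rho is pinned by the rate constraint)
fig9_args <- function() list(N = 1e6, S0 = 9e5, tau = 0.009)

# sup-norm relative error between two trajectories' column
sup_rel_err <- function(a, b, col = "R") {
  max(abs(a[[col]] - b[[col]])) / max(abs(b[[col]]))
}

# random valid parameter set (growing wave, small outbreak fraction)
random_params <- function() {
  N <- 10^stats::runif(1, 5.5, 7.5)
  rho <- 10^stats::runif(1, -3, -1.5)
  tau <- rho * stats::runif(1, 1.01, 1.2)
  I0 <- ceiling(stats::runif(1, 1, 50))
  sir_params(N = N, tau = tau, rho = rho, S0 = N - I0, I0 = I0)
}
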