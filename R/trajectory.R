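#' Wave trajectory container
#'
#' A `wave_trajectory` is a data frame with columns `t`, `S`, `I`, `R`
#' (time grid and compartment counts) plus attributes recording where the
#' trajectory came from:
#'
#' * `source`: one of `"numeric-SIR"` (adaptive integration of the full SIR
#'   system), `"numeric-chain"` (integration of the truncated polynomial
#'   chain), `"analytic-M2"` (quadratic closed form) or `"analytic-M3"`
#'   (cubic closed form);
#' * `params`: the [sir_params()] that generated it;
#' * `funs`: for analytic (and chain) sources, closures `R`, `I`, `S` of
#'   time, so quantities can be evaluated off the stored grid;
#' * `extras`: solution constants (`theta`, `C`, `D`, `E`, chain order `M`,
#'   large-time limit `R_inf`, ...).
#'
#' @name wave_trajectory
#' @keywords internal
NULL

new_trajectory <- function(t, S, I, R, source, params,
                           funs = NULL, extras = list()) {
  stopifnot(length(t) == length(S), length(S) == length(I),
            length(I) == length(R))
  df <- data.frame(t = t, S = S, I = I, R = R)
  structure(df,
            source = source, params = params, funs = funs, extras = extras,
            class = c("wave_trajectory", "data.frame"))
}

validate_trajectory <- function(traj) {
  params <- attr(traj, "params")
  N <- params$N
  eps <- 1e-6 * N
  if (any(traj$S < -eps) || any(traj$I < -eps) || any(traj$R < -eps))
    stop("trajectory has compartment values below -1e-6 * N", call. = FALSE)
  if (any(diff(traj$R) < -1e-9 * N))
    stop("removed compartment R must be non-decreasing", call. = FALSE)
  if (identical(attr(traj, "source"), "numeric-SIR")) {
    drift <- max(abs(traj$S + traj$I + traj$R - N))
    if (drift > eps)
      stop("conservation violated: max |S+I+R-N| = ", format(drift),
           " exceeds 1e-6 * N", call. = FALSE)
  }
  invisible(traj)
}

#' @export
print.wave_trajectory <- function(x, ...) {
  cat(sprintf("<wave_trajectory: %s, %d grid points, t in [%g, %g]>\n",
              attr(x, "source"), nrow(x), min(x$t), max(x$t)))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

traj_source <- function(traj) attr(traj, "source")
traj_params <- function(traj) attr(traj, "params")
traj_funs   <- function(traj) attr(traj, "funs")
traj_extras <- function(traj) attr(traj, "extras")
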