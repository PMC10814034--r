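#' Wave metrics: amplitude, time horizon, reproduction-number crossing
#'
#' Summarizes a news wave by its peak number of active spreaders `Im`
#' (amplitude), the time `tm` at which the peak occurs (the *time horizon*),
#' the time `t_Rn1` at which the effective reproduction number first crosses
#' 1 from above (coincides with the peak for an interior maximum; absent for
#' purely decaying waves), the large-time limit `R_final` of the removed
#' count, and the maximum Taylor validity bound `validity_max` along the
#' wave.
#'
#' For trajectories carrying closed-form constants (quadratic `D = 0` and
#' cubic solutions) the exact peak formulas are used and cross-checked
#' against golden-section maximization; otherwise the grid argmax is refined
#' by golden-section search. If `I` is still rising at the end of the window
#' the window is doubled (up to `2^10` times — slow waves with small
#' transmission rates have very long horizons) before giving up.
#'
#' @param wave A [wave_trajectory] (any source).
#' @param rho Recovery rate used for the reproduction number; defaults to
#'   the wave's own.
#' @return A `wave_metrics` object: list with `Im`, `tm`, `t_Rn1` (possibly
#'   `NA`), `R_final`, `validity_max`, `source`.
#' @examples
#' p <- sir_params(N = 1e7, tau = 0.00825, rho = 0.00775, S0 = 9999999)
#' m <- compute_metrics(solve_m2(p, t_end = 60000))
#' c(m$Im, m$tm)
#' @export
compute_metrics <- function(wave, rho = traj_params(wave)$rho) {
  stopifnot(inherits(wave, "wave_trajectory"))
  params <- traj_params(wave)
  extras <- traj_extras(wave)
  funs <- traj_funs(wave)
  M <- if (!is.null(extras$M)) extras$M else 2L

  I_fun <- if (!is.null(funs)) funs$I else NULL
  R_fun <- if (!is.null(funs)) funs$R else NULL

  have_closed_form <- !is.null(extras$tm) && !is.null(extras$Im)
  if (have_closed_form) {
    tm <- extras$tm
    Im <- extras$Im
    # cross-check the closed forms against direct numerical maximization
    if (tm > 0 && !is.null(I_fun)) {
      half <- 10 / (extras$rate %||% (1 / tm))
      lo <- max(0, tm - half); hi <- tm + half
      opt <- stats::optimize(I_fun, c(lo, hi), maximum = TRUE,
                             tol = 1e-9 * (hi - lo))
      if (abs(opt$objective - Im) > 1e-6 * Im)
        warning("closed-form amplitude and numerical maximization disagree ",
                "beyond 1e-6 relative", call. = FALSE)
    }
    t_end_used <- max(max(wave$t), 2 * tm)
  } else {
    ext <- extend_past_peak(wave)
    wave <- ext$wave
    t_end_used <- ext$t_end
    i_max <- which.max(wave$I)
    if (is.null(I_fun)) I_fun <- stats::splinefun(wave$t, wave$I)
    if (i_max == 1L) {
      tm <- 0
      Im <- wave$I[1L]
    } else {
      lo <- wave$t[max(1L, i_max - 1L)]
      hi <- wave$t[min(nrow(wave), i_max + 1L)]
      opt <- stats::optimize(I_fun, c(lo, hi), maximum = TRUE,
                             tol = max(1e-12, 1e-9 * (hi - lo)))
      tm <- opt$maximum
      Im <- opt$objective
      if (Im <= wave$I[1L]) { tm <- 0; Im <- wave$I[1L] }
    }
  }

  # Rn = 1 crossing: the zero of sigma(t), i.e. the interior peak
  t_Rn1 <- NA_real_
  if (tm > 0) {
    if (!is.null(I_fun)) {
      lo <- tm * 0.5; hi <- tm * 1.5
      h <- min(lo / 2, max(1e-8 * tm, 1e-6))
      sigma_fun <- function(t)
        (log(I_fun(t + h)) - log(I_fun(t - h))) / (2 * h)
      if (sigma_fun(lo) > 0 && sigma_fun(hi) < 0) {
        t_Rn1 <- stats::uniroot(sigma_fun, c(lo, hi),
                                tol = max(1e-12, 1e-9 * tm))$root
      } else t_Rn1 <- tm
    } else t_Rn1 <- tm
  }

  R_final <- if (!is.null(extras$R_inf)) extras$R_inf else wave$R[nrow(wave)]
  R_max <- max(max(wave$R), R_final)
  validity_max <- validity_bound(params, R_max, M = M)$bound

  structure(list(Im = Im, tm = tm, t_Rn1 = t_Rn1, R_final = R_final,
                 validity_max = validity_max, source = traj_source(wave)),
            class = "wave_metrics")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.wave_metrics <- function(x, ...) {
  cat("<wave_metrics>\n")
  cat(sprintf("  amplitude Im       = %g persons\n", x$Im))
  cat(sprintf("  time horizon tm    = %g time units\n", x$tm))
  cat(sprintf("  Rn = 1 crossing at = %s\n",
              if (is.na(x$t_Rn1)) "absent (no interior peak)"
              else format(x$t_Rn1)))
  cat(sprintf("  final removed R    = %g persons\n", x$R_final))
  cat(sprintf("  max validity bound = %g\n", x$validity_max))
  invisible(x)
}

# Double the window (re-integrating numeric sources) until I has an interior
# maximum, up to 2^10 doublings.
extend_past_peak <- function(wave) {
  params <- traj_params(wave)
  t_end <- max(wave$t)
  for (k in 0:10) {
    i_max <- which.max(wave$I)
    rising <- i_max == nrow(wave) &&
      wave$I[nrow(wave)] > wave$I[max(1L, nrow(wave) - 1L)]
    if (!rising) return(list(wave = wave, t_end = t_end))
    if (k == 10)
      stop("time horizon not reached after extending the window 2^10 times",
           call. = FALSE)
    t_end <- 2 * t_end
    funs <- traj_funs(wave)
    if (!is.null(funs)) {
      tg <- seq(0, t_end, length.out = nrow(wave))
      wave <- new_trajectory(tg, funs$S(tg), funs$I(tg), funs$R(tg),
                             source = traj_source(wave), params = params,
                             funs = funs, extras = traj_extras(wave))
    } else {
      wave <- switch(traj_source(wave),
        "numeric-SIR" = integrate_sir(params, t_end, n_points = nrow(wave)),
        "numeric-chain" = integrate_chain(
          compute_alphas(params, M = traj_extras(wave)$M %||% 2L),
          t_end, n_points = nrow(wave)),
        stop("cannot extend a trajectory of source ", traj_source(wave),
             call. = FALSE))
    }
  }
}

#' Parameter-sensitivity sweep of wave metrics
#'
#' Recomputes the wave metrics while one parameter varies and the rest stay
#' at their base values, exposing the directional laws of the theory:
#' amplitude grows with the initial spreader count, the population size and
#' the transmission rate, and shrinks with the recovery rate; the time
#' horizon shrinks with the initial spreader count and the transmission rate
#' and grows with the population size.
#'
#' @param base A [sir_params()] base parameter set.
#' @param vary One of `"I0"`, `"N"`, `"tau"`, `"rho"`. Varying `"I0"` adjusts
#'   `S0 = N - I0`; varying `"N"` keeps `I0` fixed and sets `S0 = N - I0`.
#' @param values Positive values of the varied parameter, in the order the
#'   results should be reported.
#' @param model `"m2"` (quadratic closed form, default) or `"m3"` (cubic
#'   closed form; only `vary = "I0"` or `"tau"` make sense there since `rho`
#'   is pinned by the rate constraint).
#' @return A data frame with one row per value: `value`, `Im`, `tm`,
#'   `t_Rn1`, `R_final`, `validity_max`.
#' @export
sensitivity_sweep <- function(base, vary = c("I0", "N", "tau", "rho"),
                              values, model = c("m2", "m3")) {
  stopifnot(inherits(base, "sir_params"))
  vary <- match.arg(vary)
  model <- match.arg(model)
  if (any(values <= 0)) stop("`values` must be positive", call. = FALSE)
  rows <- lapply(values, function(v) {
    if (model == "m3") {
      N <- base$N; tau <- base$tau; S0 <- base$S0
      if (vary == "I0") S0 <- N - v
      else if (vary == "tau") tau <- v
      else if (vary == "N") { N <- v; S0 <- v - base$I0 }
      else stop("`rho` is not free for the cubic solution", call. = FALSE)
      w <- solve_m3(N = N, S0 = S0, tau = tau,
                    t_end = 1, n_points = 2L)  # metrics come from closed forms
    } else {
      p <- switch(vary,
        I0  = sir_params(base$N, base$tau, base$rho, S0 = base$N - v, I0 = v),
        N   = sir_params(v, base$tau, base$rho, S0 = v - base$I0,
                         I0 = base$I0),
        tau = sir_params(base$N, v, base$rho, S0 = base$S0, I0 = base$I0),
        rho = sir_params(base$N, base$tau, v, S0 = base$S0, I0 = base$I0))
      w <- solve_m2(p, t_end = 1, n_points = 2L)
    }
    m <- compute_metrics(w)
    data.frame(value = v, Im = m$Im, tm = m$tm, t_Rn1 = m$t_Rn1,
               R_final = m$R_final, validity_max = m$validity_max)
  })
  do.call(rbind, rows)
}

#' Thresholds for the wave typology
#'
#' The A-E typology partitions the transmission/recovery rate plane into
#' qualitative quadrants ("large" vs "small" rates) plus an intermediate
#' band. The theory gives no numeric cut-offs, so they are configuration;
#' the shipped defaults bracket the canonical scenario rates
#' (`tau = 0.00825`, `rho = 0.00775`).
#'
#' @param tau_lo,tau_hi Transmission-rate cut-offs (`tau_lo < tau_hi`).
#' @param rho_lo,rho_hi Recovery-rate cut-offs (`rho_lo < rho_hi`).
#' @return A `wave_type_thresholds` object.
#' @export
wave_type_thresholds <- function(tau_lo = 0.004, tau_hi = 0.012,
                                 rho_lo = 0.004, rho_hi = 0.012) {
  if (!(tau_lo < tau_hi) || !(rho_lo < rho_hi))
    stop("thresholds must satisfy tau_lo < tau_hi and rho_lo < rho_hi",
         call. = FALSE)
  structure(list(tau_lo = tau_lo, tau_hi = tau_hi,
                 rho_lo = rho_lo, rho_hi = rho_hi),
            class = "wave_type_thresholds")
}

#' Classify a news wave by its transmission and recovery rates
#'
#' The five qualitative types: **A** — large transmission, small recovery
#' (large amplitude, short horizon); **B** — both large (outcome depends on
#' `tau/rho`); **C** — small transmission, large recovery (small amplitude,
#' long horizon); **D** — both small; **E** — intermediate values. The map
#' is total and deterministic: boundary values resolve away from E toward
#' the adjacent corner type, ties broken in the order A, B, C, D.
#'
#' @param tau,rho Positive rates.
#' @param thresholds A [wave_type_thresholds()] object.
#' @return A single character, one of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`.
#' @examples
#' classify_wave_type(0.024, 0.002)   # "A"
#' @export
classify_wave_type <- function(tau, rho,
                               thresholds = wave_type_thresholds()) {
  if (!inherits(thresholds, "wave_type_thresholds"))
    stop("`thresholds` must be a wave_type_thresholds object", call. = FALSE)
  if (tau <= 0 || rho <= 0) stop("rates must be positive", call. = FALSE)
  th <- thresholds
  if (tau >= th$tau_hi && rho <= th$rho_lo) return("A")
  if (tau >= th$tau_hi && rho >= th$rho_hi) return("B")
  if (tau <= th$tau_lo && rho >= th$rho_hi) return("C")
  if (tau <= th$tau_lo && rho <= th$rho_lo) return("D")
  "E"
}
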