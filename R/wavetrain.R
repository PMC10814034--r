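#' Specify a wavetrain of successive news waves
#'
#' A wavetrain is a sequence of news waves in which each new wave (a
#' similar but slightly different piece of news) is seeded at a splice time
#' by the spreaders currently active: segment `n + 1` starts with
#' `I(0) = I_n(t_splice)`, a reset removed pool `R(0) = 0` and a full
#' susceptible pool `S(0) = N - I(0)` — the new piece of news is new to
#' everyone, so nobody has yet lost interest in it. `I` is therefore
#' continuous across splices while `S` and `R` jump.
#'
#' @param N Shared population size.
#' @param I0 Initial active spreaders of the first wave.
#' @param segments A data frame with one row per wave and columns `tau`,
#'   `rho`, and either `duration` (time spent on each wave before splicing;
#'   the last wave's duration is its plotting window) or `peak_fraction`
#'   (splice at that multiple of the segment's own peak time; the quadratic
#'   `D = 0` pulse is symmetric, so a fraction of 2 splices exactly when `I`
#'   returns to its initial value, below 2 while `I` exceeds it, above 2
#'   during decay beneath it).
#' @param model Solution family for every segment; currently the quadratic
#'   `D = 0` closed form.
#' @return A `wavetrain_spec` object.
#' @export
wavetrain_spec <- function(N, I0, segments, model = "analytic-M2-D0") {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1L,
            all(c("tau", "rho") %in% names(segments)))
  if (!any(c("duration", "peak_fraction") %in% names(segments)))
    stop("`segments` needs a `duration` or `peak_fraction` column",
         call. = FALSE)
  if ("duration" %in% names(segments) && any(segments$duration <= 0))
    stop("segment durations must be > 0", call. = FALSE)
  if ("peak_fraction" %in% names(segments) &&
      any(segments$peak_fraction <= 0))
    stop("peak fractions must be > 0", call. = FALSE)
  model <- match.arg(model, "analytic-M2-D0")
  structure(list(N = N, I0 = I0, segments = segments, model = model),
            class = "wavetrain_spec")
}

#' Compose a wavetrain
#'
#' Solves each segment on its own clock with the spliced initial conditions,
#' concatenates the trajectories on the global clock, and classifies the
#' train by the ordering of the segment amplitudes.
#'
#' @param spec A [wavetrain_spec()].
#' @param n_points Grid points per segment.
#' @return A `wavetrain` object: list with `trajectory` (data frame `t`,
#'   `S`, `I`, `R`, `segment`), `splice_times` (global clock),
#'   `segment_metrics` (list of [compute_metrics()] results, each on its
#'   segment's own clock), `peak_times_global`, `amplitudes` and
#'   `train_class`.
#' @examples
#' seg <- data.frame(tau = 0.00825, rho = 0.00775, peak_fraction = 1.5)
#' spec <- wavetrain_spec(N = 1e7, I0 = 1, segments = seg[rep(1, 4), ])
#' train <- compose_wavetrain(spec, n_points = 201)
#' train$train_class
#' @export
compose_wavetrain <- function(spec, n_points = 501L) {
  stopifnot(inherits(spec, "wavetrain_spec"))
  segs <- spec$segments
  n_seg <- nrow(segs)
  I_start <- spec$I0
  offset <- 0
  pieces <- vector("list", n_seg)
  metrics <- vector("list", n_seg)
  splice_times <- numeric(0)
  peaks_global <- numeric(n_seg)

  for (i in seq_len(n_seg)) {
    if (I_start >= spec$N)
      stop("infeasible splice: segment ", i, " would start with I(0) >= N",
           call. = FALSE)
    if (I_start <= 0)
      stop("dead splice: segment ", i, " would start after extinction ",
           "(I = 0)", call. = FALSE)
    p <- sir_params(N = spec$N, tau = segs$tau[i], rho = segs$rho[i],
                    S0 = spec$N - I_start, I0 = I_start)
    probe <- solve_m2(p, t_end = 1, n_points = 2L)
    tm_i <- traj_extras(probe)$tm
    dur <- if ("duration" %in% names(segs) && !is.null(segs$duration) &&
               !is.na(segs$duration[i])) segs$duration[i]
           else {
             if (tm_i <= 0)
               stop("peak-fraction splicing needs a growing segment ",
                    "(segment ", i, " peaks at t = 0)", call. = FALSE)
             segs$peak_fraction[i] * tm_i
           }
    wave <- solve_m2(p, t_end = dur, n_points = n_points)
    m <- compute_metrics(wave)
    metrics[[i]] <- m
    peaks_global[i] <- offset + m$tm
    df <- as.data.frame(wave)[, c("t", "S", "I", "R")]
    df$t <- df$t + offset
    df$segment <- i
    if (i > 1L) df <- df[-1L, , drop = FALSE]  # avoid duplicate global time
    pieces[[i]] <- df
    if (i < n_seg) splice_times <- c(splice_times, offset + dur)
    I_start <- traj_funs(wave)$I(dur)
    offset <- offset + dur
  }

  amplitudes <- vapply(metrics, function(m) m$Im, numeric(1))
  structure(list(trajectory = do.call(rbind, pieces),
                 splice_times = splice_times,
                 segment_metrics = metrics,
                 peak_times_global = peaks_global,
                 amplitudes = amplitudes,
                 train_class = classify_train(amplitudes)),
            class = "wavetrain")
}

#' @export
print.wavetrain <- function(x, ...) {
  cat(sprintf("<wavetrain: %d waves, class '%s'>\n",
              length(x$amplitudes), x$train_class))
  cat("  amplitudes:", format(x$amplitudes, digits = 6), "\n")
  if (length(x$splice_times))
    cat("  splices at:", format(x$splice_times, digits = 6), "\n")
  invisible(x)
}

#' Classify a wavetrain by its segment amplitudes
#'
#' @param amplitudes Peak amplitudes of the successive waves (or a list of
#'   `wave_metrics`). Strictly increasing amplitudes give an increasing
#'   train, strictly decreasing a decreasing one, anything else is mixed.
#'   A single wave is reported as `"increasing"` by convention, with a
#'   warning.
#' @return `"increasing"`, `"decreasing"` or `"mixed"`.
#' @export
classify_train <- function(amplitudes) {
  if (is.list(amplitudes))
    amplitudes <- vapply(amplitudes, function(m) m$Im, numeric(1))
  if (length(amplitudes) < 2L) {
    warning("a single wave is classified 'increasing' by convention",
            call. = FALSE)
    return("increasing")
  }
  d <- diff(amplitudes)
  if (all(d > 0)) "increasing" else if (all(d < 0)) "decreasing" else "mixed"
}
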