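# Respiratory signal and amplitude gating.
#
# The breathing surrogate is a three-component sinusoidal model evaluated at
# the normalized phase x = 2*pi*t / T_R:
#
#   Sig(x) = [sin(x) + sin(2x + 0.7*pi) + sin(2x + pi) - 5.4] / 2
#
# The gate is amplitude-based: the beam is permitted while the signal is at
# or below a threshold (end-exhale gating, the clinical norm for liver).
# The threshold is usually chosen indirectly, as the amplitude whose
# below-threshold dwell fraction over one period equals a requested duty
# cycle. Gating logic only compares the signal to the threshold, so the
# absolute offset of the signal is irrelevant and the signal function is
# injectable.

#' Three-component sinusoidal breathing signal (internal default)
#' @noRd
default_breathing_signal <- function(x) {
  (sin(x) + sin(2 * x + 0.7 * pi) + sin(2 * x + pi) - 5.4) / 2
}

#' Construct a respiratory model
#'
#' @param period respiratory period T_R in s (> 0).
#' @param signal amplitude as a function of normalized phase
#'   `x = 2*pi*t/period`; must be 2*pi-periodic. Default: the package's
#'   three-component sinusoidal model (see Details).
#' @details The default signal is
#'   `Sig(x) = (sin(x) + sin(2x + 0.7*pi) + sin(2x + pi) - 5.4) / 2`.
#'   The additive constant and the global halving follow the published form of
#'   this model; since gating is threshold-based, neither affects the gate
#'   schedule for a given duty cycle.
#' @return Object of class `respiratory_model`.
#' @examples
#' m <- respiratory_model(period = 4)
#' breathing_signal(0, m)  # -2.2955 at start of cycle
#' @export
respiratory_model <- function(period = 4, signal = NULL) {
  stopifnot(is.numeric(period), length(period) == 1L, period > 0)
  if (is.null(signal)) signal <- default_breathing_signal
  stopifnot(is.function(signal))
  structure(list(period = as.numeric(period), signal = signal),
            class = "respiratory_model")
}

#' Evaluate the breathing signal at time t
#'
#' @param t time(s) in s (vectorized).
#' @param model a [respiratory_model()].
#' @return Signal amplitude(s); periodic with period `model$period`.
#' @export
breathing_signal <- function(t, model) {
  stopifnot(inherits(model, "respiratory_model"))
  model$signal(2 * pi * t / model$period)
}

#' Gating configuration
#'
#' @param duty gate-open fraction of the respiratory period, in (0, 1]. Used
#'   when `threshold` is `NULL`: the amplitude threshold is calibrated with
#'   [threshold_for_duty()].
#' @param threshold explicit amplitude threshold; overrides `duty`.
#' @param sense `"below"` (beam on while signal <= threshold; end-exhale
#'   gating, the default) or `"above"`.
#' @return Object of class `gate_config`.
#' @export
gate_config <- function(duty = 0.3, threshold = NULL,
                        sense = c("below", "above")) {
  sense <- match.arg(sense)
  if (is.null(threshold)) {
    stopifnot(is.numeric(duty), length(duty) == 1L)
    if (is.na(duty) || duty <= 0 || duty > 1)
      stop("duty must be in (0, 1]")
  }
  structure(list(duty = if (is.null(threshold)) duty else NULL,
                 threshold = threshold, sense = sense),
            class = "gate_config")
}

#' Amplitude threshold achieving a requested duty cycle
#'
#' Finds the amplitude tau such that the fraction of one respiratory period
#' with `signal <= tau` equals `duty`, by bisection on tau against a dense
#' midpoint grid of the signal (`n_grid` samples per period, default 40000).
#'
#' @param model a [respiratory_model()].
#' @param duty requested gate-open fraction in (0, 1].
#' @param n_grid samples per period used to measure the dwell fraction.
#' @return Threshold amplitude tau.
#' @export
threshold_for_duty <- function(model, duty, n_grid = 40000L) {
  stopifnot(inherits(model, "respiratory_model"))
  if (!is.numeric(duty) || length(duty) != 1L || is.na(duty) ||
      duty <= 0 || duty > 1)
    stop("duty must be in (0, 1]")
  tt <- (seq_len(n_grid) - 0.5) / n_grid * model$period
  s <- breathing_signal(tt, model)
  # duty 1: always open; pad the grid maximum to cover between-sample peaks
  if (duty >= 1) return(max(s) + 1e-6 * diff(range(s)))
  lo <- min(s); hi <- max(s)
  for (i in seq_len(80L)) {
    mid <- (lo + hi) / 2
    if (mean(s <= mid) < duty) lo <- mid else hi <- mid
  }
  hi
}

# -- gate schedules ----------------------------------------------------------

new_gate_schedule <- function(base, period, horizon, always_on = FALSE) {
  intervals <- tile_intervals(base, period, horizon, always_on)
  structure(list(intervals = intervals, base = base, period = period,
                 horizon = horizon,
                 duty_achieved = if (always_on) 1
                                 else sum(intervals$end - intervals$start) /
                                      horizon,
                 always_on = always_on),
            class = "gate_schedule")
}

# Tile the base on-intervals (within [0, period]) across [0, horizon],
# merging intervals that touch across period boundaries, then clip.
tile_intervals <- function(base, period, horizon, always_on = FALSE) {
  if (always_on) return(data.frame(start = 0, end = horizon))
  k_max <- ceiling(horizon / period)
  starts <- as.vector(outer(base$start, (0:k_max) * period, `+`))
  ends <- as.vector(outer(base$end, (0:k_max) * period, `+`))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1L]; me <- ends[1L]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= me + 1e-12) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  keep <- out_s < horizon
  out_s <- out_s[keep]; out_e <- pmin(out_e[keep], horizon)
  data.frame(start = out_s, end = out_e)
}

#' Beam-permitted intervals from a respiratory model and gate config
#'
#' Computes the maximal sub-intervals of `[0, horizon]` where the gate is
#' open (signal at or below the threshold, for the default sense). Interval
#' boundaries are located by bisection to 1e-6 s. The schedule is exactly
#' periodic with the respiratory period; simulators extend it on demand
#' beyond `horizon`.
#'
#' @param model a [respiratory_model()].
#' @param config a [gate_config()].
#' @param horizon schedule horizon in s (> 0).
#' @return Object of class `gate_schedule` with elements `intervals`
#'   (data frame `start`, `end`, half-open `[start, end)`), `period`,
#'   `duty_achieved`, plus the per-period `base` intervals.
#' @examples
#' sched <- gate_intervals(respiratory_model(4), gate_config(duty = 0.3), 40)
#' sum(sched$intervals$end - sched$intervals$start)  # ~12 s on over 40 s
#' @export
gate_intervals <- function(model, config, horizon) {
  stopifnot(inherits(model, "respiratory_model"),
            inherits(config, "gate_config"),
            is.numeric(horizon), horizon > 0)
  tau <- if (!is.null(config$threshold)) config$threshold
         else threshold_for_duty(model, config$duty)
  if (!is.null(config$duty) && config$duty >= 1)
    return(new_gate_schedule(data.frame(start = 0, end = model$period),
                             model$period, horizon, always_on = TRUE))
  sgn <- if (config$sense == "below") 1 else -1
  on_fun <- function(t) sgn * (breathing_signal(t, model) - tau) <= 0
  base <- period_on_intervals(on_fun, model$period)
  if (nrow(base) == 0L) stop("gate never opens: threshold below signal range")
  covers_all <- nrow(base) == 1L && base$start[1L] <= 1e-9 &&
    base$end[1L] >= model$period - 1e-9
  new_gate_schedule(base, model$period, horizon, always_on = covers_all)
}

# Maximal on-intervals of an indicator over one period, boundaries bisected
# to 1e-6 s from a 1e4-point scan. Intervals touching 0 or the period end
# are represented split; periodic tiling re-merges them across boundaries.
period_on_intervals <- function(on_fun, period, n_scan = 10000L,
                                tol = 1e-6) {
  tt <- (0:(n_scan - 1L)) / n_scan * period
  on <- on_fun(tt)
  if (!any(on)) return(data.frame(start = numeric(0), end = numeric(0)))
  if (all(on)) return(data.frame(start = 0, end = period))
  bisect_edge <- function(t_lo, t_hi, want_on_hi) {
    # state changes between t_lo and t_hi; refine the change point
    while (t_hi - t_lo > tol) {
      mid <- (t_lo + t_hi) / 2
      if (on_fun(mid) == want_on_hi) t_hi <- mid else t_lo <- mid
    }
    t_hi
  }
  # scan transitions, closing the cycle with a virtual sample at t = period
  # whose state equals on[1] (periodicity)
  on_ext <- c(on, on[1L])
  t_ext <- c(tt, period)
  starts <- ends <- numeric(0)
  for (i in seq_len(n_scan)) {
    if (on_ext[i] == on_ext[i + 1L]) next
    edge <- bisect_edge(t_ext[i], t_ext[i + 1L], on_ext[i + 1L])
    # snap edges within bisection tolerance of the period boundary
    if (edge < 2 * tol) edge <- 0
    if (edge > period - 2 * tol) edge <- period
    if (on_ext[i + 1L]) starts <- c(starts, edge) else ends <- c(ends, edge)
  }
  if (on[1L]) starts <- c(0, starts)
  if (on_ext[n_scan + 1L]) ends <- c(ends, period)
  keep <- ends - starts > tol
  data.frame(start = starts[keep], end = ends[keep])
}

#' Exact square-wave gate schedule
#'
#' Deterministic test/reference gate: open on `[k*period, k*period +
#' duty*period)` for every cycle `k`. Useful for hand-traceable delivery
#' timelines; the amplitude-gating path produces the same schedule for a
#' square signal.
#'
#' @param period gate period in s.
#' @param duty open fraction in (0, 1].
#' @param horizon schedule horizon in s.
#' @return A `gate_schedule`.
#' @export
square_gate_schedule <- function(period, duty, horizon) {
  stopifnot(period > 0, duty > 0, duty <= 1, horizon > 0)
  if (duty >= 1)
    return(new_gate_schedule(data.frame(start = 0, end = period),
                             period, horizon, always_on = TRUE))
  new_gate_schedule(data.frame(start = 0, end = duty * period),
                    period, horizon)
}

#' Always-open gate schedule
#'
#' @param horizon schedule horizon in s.
#' @return A `gate_schedule` that never closes.
#' @export
always_on_schedule <- function(horizon = Inf) {
  structure(list(intervals = data.frame(start = 0, end = horizon),
                 base = data.frame(start = 0, end = 1), period = 1,
                 horizon = horizon, duty_achieved = 1, always_on = TRUE),
            class = "gate_schedule")
}

# First gate-open interval (start, end) with end > t, in absolute time.
# Periodic extension of the base intervals; merges across period boundaries.
next_on_interval <- function(sched, t) {
  if (sched$always_on) return(c(start = 0, end = Inf))
  P <- sched$period
  k <- floor(t / P)
  cand_s <- as.vector(outer(sched$base$start, (k - 1):(k + 2) * P, `+`))
  cand_e <- as.vector(outer(sched$base$end, (k - 1):(k + 2) * P, `+`))
  o <- order(cand_s)
  cand_s <- cand_s[o]; cand_e <- cand_e[o]
  # merge touching intervals (base halves split at period boundaries)
  j <- 1L
  for (i in seq_along(cand_s)[-1L]) {
    if (cand_s[i] <= cand_e[j] + 1e-12) {
      cand_e[j] <- max(cand_e[j], cand_e[i])
    } else {
      j <- j + 1L
      cand_s[j] <- cand_s[i]; cand_e[j] <- cand_e[i]
    }
  }
  cand_s <- cand_s[seq_len(j)]; cand_e <- cand_e[seq_len(j)]
  # a sliver below 1e-12 s counts as the boundary itself (half-open edges)
  i <- which(cand_e > t + 1e-12)[1L]
  c(start = cand_s[i], end = cand_e[i])
}

# Point query: is the gate open at time t (half-open [start, end))?
gate_is_on <- function(sched, t) {
  if (sched$always_on) return(rep(TRUE, length(t)))
  tm <- t %% sched$period
  vapply(tm, function(x)
    any(sched$base$start <= x & x < sched$base$end), logical(1))
}

#' @export
print.gate_schedule <- function(x, ...) {
  if (x$always_on) {
    cat("Gate schedule: always open\n")
  } else {
    cat(sprintf(
      "Gate schedule: period %g s, %d interval(s)/period, duty %.3f over %g s horizon\n",
      x$period, nrow(x$base), x$duty_achieved, x$horizon))
  }
  invisible(x)
}
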