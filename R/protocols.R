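#' Voltage protocol
#'
#' A protocol is an ordered list of segments (`hold`, `step`, `ramp`), each
#' with a start/end voltage (mV) and duration (s), plus sweep structure.
#' A `step` segment may have `v_start = NA`, in which case the voltage is
#' taken per sweep from `step_levels` (one value per sweep) — this is how
#' step families (I-V protocols, sub/suprathreshold series) are described.
#'
#' @param segments data.frame with columns `kind`, `v_start`, `v_end`,
#'   `duration`.
#' @param step_levels optional numeric vector of per-sweep voltages for
#'   segments with `v_start = NA`; its length sets `n_sweeps`.
#' @param n_sweeps number of sweeps (defaults to `length(step_levels)` or 1).
#' @param sweep_interval time between sweep starts, s; defaults to the sweep
#'   duration (continuous recording).
#' @param sample_interval sampling interval, s (default 2e-4, i.e. 5 kHz).
#' @return a `voltage_protocol` object.
#' @export
voltage_protocol <- function(segments, step_levels = NULL, n_sweeps = NULL,
                             sweep_interval = NULL, sample_interval = 2e-4) {
  stopifnot(is.data.frame(segments),
            all(c("kind", "v_start", "v_end", "duration") %in% names(segments)))
  if (!all(segments$kind %in% c("hold", "step", "ramp")))
    stop("segment kind must be hold, step or ramp")
  if (any(segments$duration <= 0)) stop("segment durations must be positive")
  ramps <- segments$kind == "ramp"
  if (any(ramps & (segments$v_start == segments$v_end)))
    stop("ramp segments must have v_start != v_end")
  # sample_interval must tile each segment (within rounding)
  nsamp <- segments$duration / sample_interval
  if (any(abs(nsamp - round(nsamp)) > 1e-6))
    stop("sample_interval must divide each segment duration")
  if (is.null(n_sweeps))
    n_sweeps <- if (is.null(step_levels)) 1L else length(step_levels)
  if (!is.null(step_levels) && length(step_levels) != n_sweeps)
    stop("length(step_levels) must equal n_sweeps")
  dur <- sum(segments$duration)
  if (is.null(sweep_interval)) sweep_interval <- dur
  structure(list(segments = segments, step_levels = step_levels,
                 n_sweeps = as.integer(n_sweeps), sweep_interval = sweep_interval,
                 sample_interval = sample_interval),
            class = "voltage_protocol")
}

#' Total duration of one sweep
#' @param protocol a [voltage_protocol()].
#' @return duration in s.
#' @export
protocol_duration <- function(protocol) sum(protocol$segments$duration)

#' Number of samples per sweep
#' @param protocol a [voltage_protocol()].
#' @return integer sample count.
#' @export
protocol_n_samples <- function(protocol)
  as.integer(round(protocol_duration(protocol) / protocol$sample_interval))

#' Sample times within a sweep (left edges, starting at 0)
#' @param protocol a [voltage_protocol()].
#' @return numeric vector of times in s.
#' @export
protocol_times <- function(protocol)
  (seq_len(protocol_n_samples(protocol)) - 1L) * protocol$sample_interval

# Resolve per-sweep segment voltages: returns segments with NA steps filled
resolve_segments <- function(protocol, sweep = 1L) {
  seg <- protocol$segments
  idx <- which(seg$kind == "step" & is.na(seg$v_start))
  if (length(idx)) {
    if (is.null(protocol$step_levels))
      stop("protocol has variable step segments but no step_levels")
    v <- protocol$step_levels[[sweep]]
    seg$v_start[idx] <- v
    seg$v_end[idx] <- v
  }
  seg$v_end[seg$kind %in% c("hold", "step")] <-
    seg$v_start[seg$kind %in% c("hold", "step")]
  seg
}

#' Command voltage at given times
#'
#' @param protocol a [voltage_protocol()].
#' @param t times within the sweep, s.
#' @param sweep sweep index (for step families).
#' @return voltages in mV.
#' @export
protocol_voltage <- function(protocol, t, sweep = 1L) {
  seg <- resolve_segments(protocol, sweep)
  ends <- cumsum(seg$duration)
  starts <- c(0, ends[-length(ends)])
  i <- findInterval(pmin(t, ends[length(ends)] - 1e-12), starts)
  frac <- (t - starts[i]) / seg$duration[i]
  seg$v_start[i] + frac * (seg$v_end[i] - seg$v_start[i])
}

# Piecewise-constant voltage bins aligned to the sample grid.
# Ramps are discretised into bins of ~ramp_dt with the midpoint voltage.
# Returns data.frame(i0, i1, v): sample-index range [i0, i1] and voltage.
protocol_bins <- function(protocol, sweep = 1L, ramp_dt = 0.005) {
  seg <- resolve_segments(protocol, sweep)
  dt <- protocol$sample_interval
  bins <- list()
  s0 <- 0L  # samples before this segment
  for (k in seq_len(nrow(seg))) {
    ns <- as.integer(round(seg$duration[k] / dt))
    if (seg$kind[k] == "ramp") {
      per <- max(1L, as.integer(round(ramp_dt / dt)))
      splits <- seq(0L, ns, by = per)
      if (splits[length(splits)] != ns) splits <- c(splits, ns)
      for (j in seq_len(length(splits) - 1L)) {
        a <- splits[j]; b <- splits[j + 1L]
        tm <- (a + b) / 2 * dt
        v <- seg$v_start[k] + tm / seg$duration[k] * (seg$v_end[k] - seg$v_start[k])
        bins[[length(bins) + 1L]] <- c(s0 + a + 1L, s0 + b, v)
      }
    } else {
      bins[[length(bins) + 1L]] <- c(s0 + 1L, s0 + ns, seg$v_start[k])
    }
    s0 <- s0 + ns
  }
  out <- as.data.frame(do.call(rbind, bins))
  names(out) <- c("i0", "i1", "v")
  out
}

#' Named voltage-protocol presets
#'
#' * `"tail"`: 0 mV holding, +100 mV prepulse (200 ms), then a family of
#'   hyperpolarizing tail steps (default -100 to +60 mV in 20 mV increments).
#' * `"ramp-0.5hz"`: 2 s sweeps at 0.5 Hz — hold -60 mV, 1 s ramp from
#'   -100 to +100 mV, return to -60 mV (tail window).
#' * `"step-series-0.2hz"`: 5 s sweeps at 0.2 Hz — hold -60 mV, a 1 s step
#'   whose level is set per sweep (sub- then suprathreshold relative to
#'   E_Ca), then -60 mV repolarization (tail).
#' * `"iv-steps"`: 300 ms steps, +5 mV increments from -100 to +100 mV,
#'   holding -60 mV.
#'
#' @param preset protocol name.
#' @param tail_levels tail-step family voltages, mV (`"tail"`).
#' @param n_sweeps number of sweeps (`"ramp-0.5hz"`).
#' @param v_sub,v_supra,n_sub,n_supra step levels/counts for
#'   `"step-series-0.2hz"`.
#' @param step_duration suprathreshold step length, s (`"step-series-0.2hz"`).
#' @param sample_interval sampling interval, s.
#' @return a [voltage_protocol()].
#' @export
make_protocol <- function(preset = c("tail", "ramp-0.5hz", "step-series-0.2hz", "iv-steps"),
                          tail_levels = seq(-100, 60, by = 20),
                          n_sweeps = 240,
                          v_sub = 90, v_supra = 155, n_sub = 4, n_supra = 8,
                          step_duration = 1,
                          sample_interval = 2e-4) {
  preset <- match.arg(preset)
  seg <- function(...) {
    m <- rbind(...)
    data.frame(kind = m[, 1], v_start = as.numeric(m[, 2]),
               v_end = as.numeric(m[, 3]), duration = as.numeric(m[, 4]),
               stringsAsFactors = FALSE)
  }
  switch(preset,
    "tail" = voltage_protocol(
      seg(c("hold", 0, 0, 0.05), c("step", 100, 100, 0.2), c("step", NA, NA, 0.3)),
      step_levels = tail_levels, sample_interval = sample_interval),
    "ramp-0.5hz" = voltage_protocol(
      seg(c("hold", -60, -60, 0.3), c("ramp", -100, 100, 1.0), c("hold", -60, -60, 0.7)),
      n_sweeps = n_sweeps, sample_interval = sample_interval),
    "step-series-0.2hz" = voltage_protocol(
      seg(c("hold", -60, -60, 1.0), c("step", NA, NA, step_duration),
          c("hold", -60, -60, 4 - step_duration)),
      step_levels = c(rep(v_sub, n_sub), rep(v_supra, n_supra)),
      sample_interval = sample_interval),
    "iv-steps" = voltage_protocol(
      seg(c("hold", -60, -60, 0.05), c("step", NA, NA, 0.3), c("hold", -60, -60, 0.15)),
      step_levels = seq(-100, 100, by = 5), sample_interval = sample_interval)
  )
}

#' Sampled current trace
#'
#' @param sweeps list of numeric current vectors, pA, one per sweep; all the
#'   same length.
#' @param sample_interval sampling interval, s.
#' @param protocol optional [voltage_protocol()]; sweep lengths are checked
#'   against it.
#' @param metadata named list (cell_capacitance pF, seal_resistance GOhm,
#'   leak_at_minus60 pA, solutions, seed, ...).
#' @return a `current_trace` object.
#' @export
current_trace <- function(sweeps, sample_interval, protocol = NULL, metadata = list()) {
  if (!is.list(sweeps)) sweeps <- list(sweeps)
  len <- unique(vapply(sweeps, length, 1L))
  if (length(len) != 1L) stop("all sweeps must have the same length")
  if (!all(vapply(sweeps, function(s) all(is.finite(s)), TRUE)))
    stop("all samples must be finite")
  if (!is.null(protocol) && len != protocol_n_samples(protocol))
    stop("sweep length does not match protocol duration")
  structure(list(sample_interval = sample_interval, sweeps = sweeps,
                 protocol = protocol, metadata = metadata),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("current_trace: %d sweep(s) x %d samples @ %.4g kHz\n",
              length(x$sweeps), length(x$sweeps[[1]]),
              1e-3 / x$sample_interval))
  invisible(x)
}
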