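#' Quality-control thresholds
#'
#' Printed analysis-exclusion rules: whole-cell recordings with a seal
#' resistance below 1 GOhm or more than 90 pA of leak at -60 mV are
#' rejected; on-cell (cell-attached) records with a seal below 8 GOhm are
#' rejected. Inequalities are strict, exactly as printed.
#'
#' @param min_seal_whole_cell GOhm.
#' @param max_leak_at_minus60 pA.
#' @param min_seal_on_cell GOhm.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_seal_whole_cell = 1, max_leak_at_minus60 = 90,
                          min_seal_on_cell = 8) {
  stopifnot(min_seal_whole_cell > 0, max_leak_at_minus60 > 0, min_seal_on_cell > 0)
  structure(list(min_seal_whole_cell = min_seal_whole_cell,
                 max_leak_at_minus60 = max_leak_at_minus60,
                 min_seal_on_cell = min_seal_on_cell),
            class = "qc_thresholds")
}

#' Partition traces by recording quality
#'
#' @param traces list of [current_trace()] objects whose metadata carry
#'   `seal_resistance` (GOhm) and, for whole-cell, `leak_at_minus60` (pA).
#' @param thresholds a [qc_thresholds()] list.
#' @param mode `"whole-cell"` or `"on-cell"`.
#' @return list with `kept`, `rejected` (lists of traces) and `reasons`
#'   (character per input trace; `"ok"` for kept).
#' @export
qc_filter <- function(traces, thresholds = qc_thresholds(),
                      mode = c("whole-cell", "on-cell")) {
  mode <- match.arg(mode)
  reason <- vapply(traces, function(tr) {
    md <- tr$metadata
    if (mode == "whole-cell") {
      if (is.null(md$seal_resistance) || is.null(md$leak_at_minus60))
        return("missing-metadata")
      if (md$seal_resistance < thresholds$min_seal_whole_cell)
        return("seal-below-1GOhm")
      if (md$leak_at_minus60 > thresholds$max_leak_at_minus60)
        return("leak-above-90pA")
    } else {
      if (is.null(md$seal_resistance)) return("missing-metadata")
      if (md$seal_resistance < thresholds$min_seal_on_cell)
        return("seal-below-8GOhm")
    }
    "ok"
  }, "")
  list(kept = traces[reason == "ok"], rejected = traces[reason != "ok"],
       reasons = reason)
}

fit_result <- function(model, params, residual_rms, converged, n_points) {
  structure(list(model = model, params = params, residual_rms = residual_rms,
                 converged = converged, n_points = n_points),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result (%s): %s; rms %.4g; converged: %s; n = %d\n",
              x$model,
              paste(sprintf("%s = %.6g", names(x$params), unlist(x$params)),
                    collapse = ", "),
              x$residual_rms, x$converged, x$n_points))
  invisible(x)
}

#' Single-exponential fit
#'
#' Least-squares fit of the decaying form f(t) = B + A exp(-t/tau), the
#' form used for tail-current deactivation, peak-current activation and the
#' tail-amplitude inactivation time course. Recovers noiseless exponential
#' input to ~1e-6 relative. A constant input (A unidentifiable) is flagged
#' `converged = FALSE` rather than erroring.
#'
#' @param time time points, s.
#' @param current observed values (pA, or normalized amplitudes).
#' @param min_points minimum number of samples (default 10 for sampled
#'   traces; sweep-level fits may lower it).
#' @return a `fit_result` with params A, B, tau (s).
#' @export
fit_exponential <- function(time, current, min_points = 10L) {
  if (length(time) != length(current)) stop("time and current lengths differ")
  n <- length(time)
  if (n < min_points) stop(sprintf("at least %d samples are required", min_points))
  t0 <- time - time[1]
  rng <- diff(range(current))
  if (rng <= .Machine$double.eps * (abs(mean(current)) + 1) * 100) {
    return(fit_result("exponential",
                      list(A = 0, B = mean(current), tau = NA_real_),
                      0, FALSE, n))
  }
  ntail <- max(3L, round(n * 0.1))
  B0 <- mean(current[(n - ntail + 1L):n])
  A0 <- current[1] - B0
  # log-linear initial tau over the early decay
  dev <- (current - B0) / A0
  ok <- which(dev > 0.05)
  tau0 <- if (length(ok) > 2) {
    sl <- unname(stats::coef(stats::lm(log(dev[ok]) ~ t0[ok]))[2])
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(t0)) / 5
  } else diff(range(t0)) / 5
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(A = A0, B = B0, tau = tau0),
                       fn = function(p) current - (p[2] + p[1] * exp(-t0 / p[3])),
                       lower = c(-Inf, -Inf, .Machine$double.eps),
                       control = minpack.lm::nls.lm.control(maxiter = 500,
                                                            ftol = 1e-15,
                                                            ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) {
    return(fit_result("exponential", list(A = A0, B = B0, tau = tau0),
                      NA_real_, FALSE, n))
  }
  cf <- as.list(fit$par)
  rms <- sqrt(mean(fit$fvec^2))
  conv <- is.finite(cf$tau) && cf$tau > 0
  fit_result("exponential", list(A = cf$A, B = cf$B, tau = cf$tau), rms, conv, n)
}

#' Hill (dose-response) fit
#'
#' Fits response = floor + (ceiling - floor) / (1 + (half_max/c)^hill_n)
#' to a concentration-response table; `half_max` is the IC50 (block data)
#' or EC50 (potentiation data). The Hill coefficient is free within
#' [0.3, 4] unless fixed.
#'
#' @param concentrations concentrations, uM (> 0).
#' @param response responses (percent block or fold potentiation).
#' @param hill_n optional fixed Hill coefficient.
#' @param floor,ceiling optional fixed asymptotes.
#' @return a `fit_result` with params half_max (uM), hill_n, floor, ceiling.
#' @export
fit_hill <- function(concentrations, response, hill_n = NULL,
                     floor = NULL, ceiling = NULL) {
  if (length(concentrations) != length(response)) stop("length mismatch")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  n <- length(concentrations)
  if (n < 4L) stop("at least 4 concentrations are required")
  rng <- diff(range(response))
  if (rng <= 1e-12 * (abs(mean(response)) + 1)) {
    return(fit_result("hill", list(half_max = NA_real_, hill_n = NA_real_,
                                   floor = response[1], ceiling = response[1]),
                      0, FALSE, n))
  }
  o <- order(concentrations)
  conc <- concentrations[o]; resp <- response[o]
  f0 <- if (is.null(floor)) min(resp) else floor
  c0 <- if (is.null(ceiling)) max(resp) else ceiling
  mid <- (f0 + c0) / 2
  half0 <- exp(stats::approx(resp, log(conc), xout = mid, ties = mean)$y)
  if (!is.finite(half0)) half0 <- exp(mean(log(conc)))
  start <- list(half_max = half0)
  lower <- c(half_max = min(conc) / 1e3)
  upper <- c(half_max = max(conc) * 1e3)
  if (is.null(hill_n)) {
    start$hill_n <- 1
    lower <- c(lower, hill_n = 0.3); upper <- c(upper, hill_n = 4)
  }
  if (is.null(floor)) {
    start$floor <- f0
    lower <- c(lower, floor = -Inf); upper <- c(upper, floor = Inf)
  }
  if (is.null(ceiling)) {
    start$ceiling <- c0
    lower <- c(lower, ceiling = -Inf); upper <- c(upper, ceiling = Inf)
  }
  hillfun <- function(half_max, hill_n, floor, ceiling)
    floor + (ceiling - floor) / (1 + (half_max / conc)^hill_n)
  fixed <- list(hill_n = hill_n, floor = floor, ceiling = ceiling)
  wrap <- function(p) {
    a <- utils::modifyList(fixed[!vapply(fixed, is.null, TRUE)], as.list(p))
    do.call(hillfun, a[c("half_max", "hill_n", "floor", "ceiling")])
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = unlist(start),
                       fn = function(p) resp - wrap(p),
                       lower = lower[names(start)], upper = upper[names(start)],
                       control = minpack.lm::nls.lm.control(maxiter = 500,
                                                            ftol = 1e-15,
                                                            ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) {
    return(fit_result("hill", list(half_max = NA_real_,
                                   hill_n = if (is.null(hill_n)) NA_real_ else hill_n,
                                   floor = f0, ceiling = c0), NA_real_, FALSE, n))
  }
  p <- as.list(fit$par)
  a <- utils::modifyList(fixed[!vapply(fixed, is.null, TRUE)], p)
  rms <- sqrt(mean(fit$fvec^2))
  conv <- is.finite(a$half_max) && a$half_max > 0 &&
    a$half_max > min(conc) / 100 && a$half_max < max(conc) * 100
  fit_result("hill", a[c("half_max", "hill_n", "floor", "ceiling")], rms, conv, n)
}

#' Multi-level half-amplitude idealization
#'
#' Assigns each sample an integer open-channel level by rounding the
#' baseline-subtracted current to multiples of the unitary amplitude
#' (half-amplitude threshold crossing), clipped at zero. The baseline is by
#' default estimated as the median of the samples in the modal level of the
#' rounded histogram, with ties broken toward level 0.
#'
#' @param trace a [current_trace()] (sweeps are concatenated) or numeric
#'   current vector, pA.
#' @param unitary_amplitude single-channel current amplitude, pA. Signed:
#'   negative for inward openings (e.g. -12.1 pA).
#' @param baseline closed-level current, pA; `NULL` to estimate.
#' @param sample_interval required for a bare numeric trace.
#' @param n_max_advisory warn if more than this many simultaneous openings
#'   are assigned (default 11, the largest stack observed in the records
#'   this mimics).
#' @return an `idealized_record`: list with `level_per_sample`,
#'   `unitary_amplitude`, `baseline`, `n_max`, `dwell_table` (level,
#'   duration), `total_time`, `sample_interval`, `noise_sd_est`,
#'   `low_snr` flag.
#' @export
idealize <- function(trace, unitary_amplitude, baseline = NULL,
                     sample_interval = NULL, n_max_advisory = 11L) {
  if (inherits(trace, "current_trace")) {
    i <- unlist(trace$sweeps, use.names = FALSE)
    dt <- trace$sample_interval
  } else {
    i <- trace
    dt <- sample_interval
    if (is.null(dt)) stop("sample_interval required for a bare numeric trace")
  }
  if (unitary_amplitude == 0) stop("unitary_amplitude must be non-zero")
  if (is.null(baseline)) {
    lev0 <- round(i / unitary_amplitude)
    tab <- table(lev0)
    cnt <- as.integer(tab)
    lv <- as.numeric(names(tab))
    best <- lv[cnt == max(cnt)]
    modal <- best[which.min(abs(best))]  # tie-break toward level 0
    baseline <- stats::median(i[lev0 == modal]) - modal * unitary_amplitude
  }
  level <- pmax(0, round((i - baseline) / unitary_amplitude))
  # robust noise estimate from the differenced signal (level jumps are
  # sparse, so they barely move the median absolute difference)
  noise_sd <- stats::mad(diff(i)) / sqrt(2)
  low_snr <- abs(unitary_amplitude) <= 2 * noise_sd
  if (low_snr)
    warning("unitary amplitude is within 2x the noise SD; idealization unreliable")
  n_max <- max(level)
  if (n_max > n_max_advisory)
    warning(sprintf("%d simultaneous openings assigned (advisory maximum %d)",
                    n_max, n_max_advisory))
  r <- rle(level)
  dwell <- data.frame(level = r$values, duration = r$lengths * dt)
  structure(list(level_per_sample = level, unitary_amplitude = unitary_amplitude,
                 baseline = baseline, n_max = n_max, dwell_table = dwell,
                 total_time = length(level) * dt, sample_interval = dt,
                 noise_sd_est = noise_sd, low_snr = low_snr),
            class = "idealized_record")
}

#' Open probability from an idealized record
#'
#' P_o = sum(level_k * dwell_k) / (n_channels * total_time). When the
#' channel count is unknown (or smaller than the largest observed stack)
#' the maximum observed simultaneous level is used and the result is
#' reported under the NP_o convention.
#'
#' @param rec an [idealize()] record.
#' @param n_channels known channel count, or `NULL`.
#' @return list with `p_o`, `n` (channel count used), `convention`
#'   (`"Po"` or `"NPo"`), `open_time` (channel-seconds) and `total_time`.
#' @export
open_probability <- function(rec, n_channels = NULL) {
  stopifnot(inherits(rec, "idealized_record"))
  if (rec$total_time <= 0) stop("record has zero duration")
  open_time <- sum(rec$dwell_table$level * rec$dwell_table$duration)
  if (is.null(n_channels) || n_channels < rec$n_max) {
    n <- max(rec$n_max, 1L)
    convention <- "NPo"
  } else {
    n <- n_channels
    convention <- "Po"
  }
  list(p_o = open_time / (n * rec$total_time), n = n, convention = convention,
       open_time = open_time, total_time = rec$total_time)
}

#' Pointwise ensemble average of sweeps
#'
#' @param sweeps list of equal-length numeric current vectors, or a
#'   [current_trace()].
#' @return numeric mean trace.
#' @export
ensemble_average <- function(sweeps) {
  if (inherits(sweeps, "current_trace")) sweeps <- sweeps$sweeps
  len <- vapply(sweeps, length, 1L)
  if (length(unique(len)) != 1L) stop("sweeps have unequal lengths")
  colMeans(do.call(rbind, sweeps))
}

#' I-V extraction and reversal potential
#'
#' Reduces each sweep of a step-family recording to one scalar (steady-state
#' mean over the last fraction of the step, signed peak, or tail extremum in
#' the post-step segment) and interpolates the reversal potential linearly
#' between the bracketing points of the steady-state I-V.
#'
#' @param trace a [current_trace()].
#' @param protocol the step-family [voltage_protocol()] (taken from the
#'   trace if `NULL`); the variable-level `step` segment is used.
#' @param measure `"steady"`, `"peak"` or `"tail-max"`.
#' @param steady_fraction fraction of the step used for the steady measure.
#' @return list with `iv` (data.frame v, i), `erev` (mV, `NA` if the I-V
#'   does not cross zero) and `erev_defined`.
#' @export
iv_extract <- function(trace, protocol = NULL,
                       measure = c("steady", "peak", "tail-max"),
                       steady_fraction = 0.1) {
  measure <- match.arg(measure)
  if (is.null(protocol)) protocol <- trace$protocol
  if (is.null(protocol)) stop("a protocol is required")
  seg <- protocol$segments
  kstep <- which(seg$kind == "step" & is.na(seg$v_start))
  if (length(kstep) != 1L) stop("protocol must have exactly one variable step segment")
  dt <- protocol$sample_interval
  ends <- cumsum(round(seg$duration / dt))
  starts <- c(0L, ends[-length(ends)]) + 1L
  idx_step <- starts[kstep]:ends[kstep]
  vs <- protocol$step_levels
  ivals <- vapply(seq_along(trace$sweeps), function(s) {
    cur <- trace$sweeps[[s]]
    if (measure == "steady") {
      k <- max(2L, round(length(idx_step) * steady_fraction))
      mean(cur[idx_step[(length(idx_step) - k + 1L):length(idx_step)]])
    } else if (measure == "peak") {
      seg_cur <- cur[idx_step]
      seg_cur[which.max(abs(seg_cur))]
    } else {
      if (kstep == nrow(seg)) stop("no post-step segment for tail-max")
      idx_tail <- starts[kstep + 1L]:ends[kstep + 1L]
      seg_cur <- cur[idx_tail]
      seg_cur[which.max(abs(seg_cur))]
    }
  }, 1)
  o <- order(vs)
  iv <- data.frame(v = vs[o], i = ivals[o])
  sgn <- sign(iv$i)
  cross <- which(sgn[-1] * sgn[-nrow(iv)] < 0)
  if (any(iv$i == 0)) {
    erev <- iv$v[which(iv$i == 0)[1]]
    defined <- TRUE
  } else if (length(cross)) {
    k <- cross[1]
    erev <- iv$v[k] - iv$i[k] * (iv$v[k + 1] - iv$v[k]) / (iv$i[k + 1] - iv$i[k])
    defined <- TRUE
  } else {
    erev <- NA_real_
    defined <- FALSE
  }
  list(iv = iv, erev = erev, erev_defined = defined)
}

#' Current density
#'
#' @param i current, pA.
#' @param capacitance cell capacitance, pF (> 0).
#' @return pA/pF.
#' @export
current_density <- function(i, capacitance) {
  if (is.null(capacitance) || !is.finite(capacitance) || capacitance <= 0)
    stop("capacitance (pF) must be a positive number")
  i / capacitance
}

#' Inactivation rate from tail amplitudes vs suprathreshold time
#'
#' Fits the per-sweep tail-current amplitude against the cumulative time
#' spent positive to E_Ca with the single-exponential form, reporting the
#' inactivation time constant tau (s). tau is invariant to amplitude
#' rescaling.
#'
#' @param tail_amplitudes tail amplitude per sweep (any consistent sign or
#'   normalization).
#' @param suprathreshold_time time spent above E_Ca in each sweep, s.
#' @return a `fit_result` (model `"exponential"`, tau in s).
#' @export
inactivation_rate <- function(tail_amplitudes, suprathreshold_time) {
  if (length(tail_amplitudes) != length(suprathreshold_time))
    stop("length mismatch")
  t_cum <- cumsum(suprathreshold_time)
  if (sum(suprathreshold_time > 0) < 4L) {
    return(fit_result("exponential",
                      list(A = NA_real_, B = NA_real_, tau = NA_real_),
                      NA_real_, FALSE, length(tail_amplitudes)))
  }
  amp <- abs(tail_amplitudes)
  fit_exponential(t_cum, amp, min_points = 4L)
}
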