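#' Four-state gating parameters
#'
#' Rate constants and conductances for the kinetic scheme
#' C <-> O -> O_block -> I. Opening (k1) grows with depolarization
#' (`fold_open_per_100mV` per +100 mV); closure (k_minus1) grows with
#' hyperpolarization (`fold_close_per_100mV` per -100 mV). Block of the open
#' state by outward-moving Ca2+ applies whenever the membrane potential
#' exceeds E_Ca; recovery from the blocked to the open state applies when it
#' does not. Long-term inactivation (`k2`) proceeds only from O_block while
#' the outward driving force persists. Recovery from inactivation is off by
#' default (irreversible on the experimental timescale).
#'
#' @param k1_0 opening rate at 0 mV, /s.
#' @param k_minus1_0 closing rate at 0 mV, /s.
#' @param fold_open_per_100mV fold increase of k1 per +100 mV (default 1.5).
#' @param fold_close_per_100mV fold increase of k_minus1 per -100 mV
#'   (default 2.2).
#' @param k_block O -> O_block rate when v > E_Ca, /s.
#' @param k_unblock O_block -> O rate when v <= E_Ca, /s.
#' @param k2 O_block -> I rate while v > E_Ca, /s (default 1/2.1).
#' @param k_recover I -> C rate, /s (default 0, absorbing).
#' @param g_in inward unitary conductance, pS (default 121).
#' @param g_out outward unitary conductance, pS (default 198).
#' @param n_channels number of channels.
#' @param potentiation optional list(g_max, K_pot_nM, hill) describing a
#'   phenomenological Hill multiplier on k1 as a function of internal free
#'   Ca2+ (see [k1_potentiation()]); `NULL` disables it.
#' @return a `gating_parameters` object.
#' @export
gating_parameters <- function(k1_0, k_minus1_0,
                              fold_open_per_100mV = 1.5,
                              fold_close_per_100mV = 2.2,
                              k_block = 5000, k_unblock = 5000,
                              k2 = 1 / 2.1, k_recover = 0,
                              g_in = 121, g_out = 198,
                              n_channels = 1L,
                              potentiation = NULL) {
  rates <- c(k1_0, k_minus1_0, k_block, k_unblock, k2, k_recover)
  if (any(rates < 0)) stop("all rates must be non-negative")
  if (g_in <= 0 || g_out <= 0) stop("conductances must be positive")
  if (fold_open_per_100mV <= 0 || fold_close_per_100mV <= 0)
    stop("fold factors must be positive")
  structure(list(k1_0 = k1_0, k_minus1_0 = k_minus1_0,
                 fold_open_per_100mV = fold_open_per_100mV,
                 fold_close_per_100mV = fold_close_per_100mV,
                 k_block = k_block, k_unblock = k_unblock,
                 k2 = k2, k_recover = k_recover,
                 g_in = g_in, g_out = g_out,
                 n_channels = as.integer(n_channels),
                 potentiation = potentiation),
            class = "gating_parameters")
}

#' Calibrate two-state rates from a deactivation time constant and open
#' probability
#'
#' For the reversible C <-> O core, the deactivation time constant at a
#' voltage V is 1/(k1(V) + k_minus1(V)) and the equilibrium open probability
#' is k1(V)/(k1(V) + k_minus1(V)). Given both at one voltage, the 0 mV rates
#' follow from the voltage-dependence folds.
#'
#' @param tau_s deactivation time constant at `v`, s.
#' @param p_open equilibrium open probability at `v`.
#' @param v calibration voltage, mV.
#' @param fold_open,fold_close per-100 mV fold factors.
#' @return list with `k1_0` and `k_minus1_0` (/s).
#' @export
calibrate_two_state <- function(tau_s, p_open, v = -100,
                                fold_open = 1.5, fold_close = 2.2) {
  stopifnot(tau_s > 0, p_open > 0, p_open < 1)
  ksum <- 1 / tau_s
  k1_v <- p_open * ksum
  km1_v <- ksum - k1_v
  list(k1_0 = k1_v / fold_open^(v / 100),
       k_minus1_0 = km1_v / fold_close^(-v / 100))
}

#' Named gating parameter sets
#'
#' * `"wt"` — wild-type PKD2-L1: rates calibrated so that the deactivation
#'   time constant at -100 mV is 43 ms and the constitutive open probability
#'   at -100 mV is 0.007; Ca2+ block and inactivation (k2 = 1/2.1 s) enabled.
#' * `"d523n"` — the selectivity-filter mutant that is not blocked by
#'   outward Ca2+: tau_tail(-100 mV) = 2.3 ms, k_block = 0 (hence no
#'   inactivation).
#' * `"d525n"` — outer-site mutant: tau_tail(-100 mV) = 37 ms, block and
#'   inactivation retained.
#' * `"fast-open"` — a fixture set with fast activation (k1_0 = 50/s,
#'   k_minus1_0 = 125/s) used for inactivation-rate studies, where block
#'   capture of the open channel must not be rate-limited by slow opening;
#'   k2 = 1/2.1 s.
#'
#' @param name parameter-set name.
#' @param n_channels number of channels.
#' @param ... overrides passed to [gating_parameters()].
#' @return a `gating_parameters` object.
#' @export
gating_preset <- function(name = c("wt", "d523n", "d525n", "fast-open"),
                          n_channels = 1L, ...) {
  name <- match.arg(name)
  base <- switch(name,
    "wt" = c(calibrate_two_state(0.043, 0.007), list()),
    "d523n" = c(calibrate_two_state(0.0023, 0.007), list(k_block = 0, k_unblock = 0)),
    "d525n" = c(calibrate_two_state(0.037, 0.007), list()),
    "fast-open" = list(k1_0 = 50, k_minus1_0 = 125)
  )
  args <- utils::modifyList(c(base, list(n_channels = n_channels)), list(...))
  do.call(gating_parameters, args)
}

#' Potentiation multiplier on the opening rate
#'
#' Phenomenological Hill function of internal free Ca2+:
#' 1 + (g_max - 1) * c^h / (c^h + K^h), rising from 1 at zero Ca2+ to
#' `g_max` at saturation. Defaults g_max = 3, K = 300 nM, h = 2. This is a
#' qualitative device for reproducing the potentiation phase of
#' whole-cell recordings and is not constrained by measured rate data.
#'
#' @param free_ca_nM internal free Ca2+, nM.
#' @param potentiation list(g_max, K_pot_nM, hill) or NULL (returns 1).
#' @return dimensionless multiplier on k1.
#' @export
k1_potentiation <- function(free_ca_nM, potentiation = list(g_max = 3, K_pot_nM = 300, hill = 2)) {
  if (is.null(potentiation) || !is.finite(free_ca_nM)) return(1)
  h <- potentiation$hill
  1 + (potentiation$g_max - 1) * free_ca_nM^h /
    (free_ca_nM^h + potentiation$K_pot_nM^h)
}

#' Voltage-dependent opening and closing rates
#'
#' k1(V) = k1_0 * fold_open^(V/100); k_minus1(V) = k_minus1_0 *
#' fold_close^(-V/100). If the parameter set carries a potentiation rule and
#' `free_ca_nM` is supplied, k1 is multiplied by [k1_potentiation()].
#'
#' @param v membrane potential, mV.
#' @param params a [gating_parameters()] object.
#' @param free_ca_nM internal free Ca2+ for potentiation, nM (NA = ignore).
#' @return named vector c(k1, k_minus1) in /s.
#' @export
rate_constants <- function(v, params, free_ca_nM = NA_real_) {
  k1 <- params$k1_0 * params$fold_open_per_100mV^(v / 100) *
    k1_potentiation(free_ca_nM, params$potentiation)
  km1 <- params$k_minus1_0 * params$fold_close_per_100mV^(-v / 100)
  c(k1 = k1, k_minus1 = km1)
}

#' Outward Ca2+ driving force test
#'
#' TRUE iff the membrane potential is positive to the Ca2+ equilibrium
#' potential, i.e. Ca2+ moves outward through an open channel. Governs
#' whether the block or the unblock rate applies.
#'
#' @param v membrane potential, mV.
#' @param e_ca Ca2+ equilibrium potential, mV.
#' @return logical.
#' @export
block_condition <- function(v, e_ca) v > e_ca

#' Generator (transition-rate) matrix of the four-state scheme
#'
#' States in order C, O, O_block, I. Rows sum to zero; off-diagonal entries
#' are non-negative. The O -> O_block entry is k_block when v > E_Ca and 0
#' otherwise; O_block -> O is k_unblock when v <= E_Ca; O_block -> I is k2
#' when v > E_Ca; I -> C is k_recover.
#'
#' @param v membrane potential, mV.
#' @param e_ca Ca2+ equilibrium potential, mV.
#' @param params a [gating_parameters()] object.
#' @param free_ca_nM internal free Ca2+ for potentiation, nM.
#' @return 4x4 numeric matrix with dimnames C, O, Oblock, I.
#' @export
generator_matrix <- function(v, e_ca, params, free_ca_nM = NA_real_) {
  k <- rate_constants(v, params, free_ca_nM)
  above <- block_condition(v, e_ca)
  Q <- matrix(0, 4, 4, dimnames = rep(list(c("C", "O", "Oblock", "I")), 2))
  Q["C", "O"] <- k[["k1"]]
  Q["O", "C"] <- k[["k_minus1"]]
  Q["O", "Oblock"] <- if (above) params$k_block else 0
  Q["Oblock", "O"] <- if (!above) params$k_unblock else 0
  Q["Oblock", "I"] <- if (above) params$k2 else 0
  Q["I", "C"] <- params$k_recover
  diag(Q) <- -rowSums(Q)
  Q
}

# Matrix exponential for the small generator matrices: scaling-and-squaring
# with a [6/6] Pade approximant. Adequate for 4x4 rate matrices; checked
# against Matrix::expm in the test suite.
expm_small <- function(A) {
  c6 <- c(1, 1/2, 5/44, 1/66, 1/792, 1/15840, 1/665280)
  n <- nrow(A)
  nrmA <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrmA, 1e-300) / 0.5)))
  A <- A / 2^s
  I <- diag(n)
  P <- I
  N <- c6[1] * I
  D <- c6[1] * I
  sign <- 1
  for (k in 1:6) {
    P <- P %*% A
    N <- N + c6[k + 1] * P
    sign <- -sign
    D <- D + sign * c6[k + 1] * P
  }
  Fm <- solve(D, N)
  if (s > 0) for (i in seq_len(s)) Fm <- Fm %*% Fm
  Fm
}

#' Deterministic state-occupancy simulation
#'
#' Solves dp/dt = p Q(V(t)) over the protocol by exact matrix-exponential
#' propagation on piecewise-constant voltage bins (ramps are discretised
#' into `ramp_dt` bins). Occupancies sum to one to machine precision at
#' every sample. Sweeps are chained: the final occupancy of sweep s is the
#' initial occupancy of sweep s+1.
#'
#' @param protocol a [voltage_protocol()].
#' @param params a [gating_parameters()] object.
#' @param e_ca Ca2+ equilibrium potential, mV: a single number or a
#'   function(sweep) returning one (fixed within a sweep; couple to the
#'   calcium-accounting module via [coupled_whole_cell()] for feedback).
#' @param p0 initial occupancy c(C, O, Oblock, I); default all closed.
#' @param sweeps sweep indices to simulate (default all).
#' @param free_ca_nM internal free Ca2+ for potentiation, nM.
#' @param ramp_dt ramp discretisation, s.
#' @return data.frame with columns `sweep`, `time` (s, within sweep), `p_C`,
#'   `p_O`, `p_Oblock`, `p_I`; attribute `"final"` holds the final occupancy.
#' @export
simulate_occupancy <- function(protocol, params, e_ca = Inf,
                               p0 = c(1, 0, 0, 0), sweeps = NULL,
                               free_ca_nM = NA_real_, ramp_dt = 0.005) {
  stopifnot(inherits(protocol, "voltage_protocol"),
            inherits(params, "gating_parameters"))
  if (abs(sum(p0) - 1) > 1e-9 || any(p0 < 0))
    stop("p0 must be a probability vector over (C, O, Oblock, I)")
  if (is.null(sweeps)) sweeps <- seq_len(protocol$n_sweeps)
  e_ca_fun <- if (is.function(e_ca)) e_ca else function(sweep) e_ca
  dt <- protocol$sample_interval
  n <- protocol_n_samples(protocol)
  tms <- protocol_times(protocol)
  p <- as.numeric(p0)
  out <- vector("list", length(sweeps))
  for (si in seq_along(sweeps)) {
    sw <- sweeps[si]
    eca <- e_ca_fun(sw)
    bins <- protocol_bins(protocol, sweep = sw, ramp_dt = ramp_dt)
    occ <- matrix(NA_real_, n, 4)
    for (b in seq_len(nrow(bins))) {
      Q <- generator_matrix(bins$v[b], eca, params, free_ca_nM)
      Pstep <- expm_small(Q * dt)
      for (i in bins$i0[b]:bins$i1[b]) {
        occ[i, ] <- p        # occupancy at the left edge of sample i
        p <- as.numeric(p %*% Pstep)
      }
    }
    out[[si]] <- data.frame(sweep = sw, time = tms,
                            p_C = occ[, 1], p_O = occ[, 2],
                            p_Oblock = occ[, 3], p_I = occ[, 4])
  }
  res <- do.call(rbind, out)
  attr(res, "final") <- p
  res
}

#' Convert state occupancancies to a macroscopic current trace
#'
#' I(t) = n_channels * p_O(t) * g(V) * (V(t) - E_rev) with the piecewise
#' ohmic unitary conductance g = g_in for V < E_rev and g_out otherwise
#' (pS * mV / 1000 = pA). O_block and I carry no current.
#'
#' @param occ occupancy data.frame from [simulate_occupancy()].
#' @param protocol the [voltage_protocol()] used.
#' @param params a [gating_parameters()] object.
#' @param erev mixed-ion reversal potential, mV.
#' @return a [current_trace()] with one sweep per simulated sweep.
#' @export
occupancy_to_current <- function(occ, protocol, params, erev = 0) {
  sweeps <- split(occ, occ$sweep)
  cur <- lapply(sweeps, function(d) {
    v <- protocol_voltage(protocol, d$time, sweep = d$sweep[1])
    g <- ifelse(v < erev, params$g_in, params$g_out)
    params$n_channels * d$p_O * g * (v - erev) / 1000
  })
  current_trace(unname(cur), protocol$sample_interval, protocol)
}

# Gillespie path of one channel over piecewise-constant bins.
# Returns integer state per sample (1 = C, 2 = O, 3 = Oblock, 4 = I).
channel_path <- function(bins, dt, n, Qs, state) {
  lev <- integer(n)
  for (b in seq_len(nrow(bins))) {
    Q <- Qs[[b]]
    t_cur <- (bins$i0[b] - 1L) * dt
    t_end <- bins$i1[b] * dt
    i_next <- bins$i0[b]
    while (TRUE) {
      r <- -Q[state, state]
      t_jump <- if (r > 0) t_cur + stats::rexp(1, r) else Inf
      t_stop <- min(t_jump, t_end)
      if (i_next <= bins$i1[b]) {
        i_hi <- min(bins$i1[b], as.integer(floor(t_stop / dt - 1e-9)) + 1L)
        if (i_hi >= i_next) {
          lev[i_next:i_hi] <- state
          i_next <- i_hi + 1L
        }
      }
      if (t_jump >= t_end) break
      rates <- Q[state, ]
      rates[state] <- 0
      state <- sample.int(4L, 1L, prob = rates)
      t_cur <- t_jump
    }
  }
  list(lev = lev, state = state)
}

#' Stochastic single-channel simulation
#'
#' Exact event-driven (Gillespie) simulation of `n_channels` independent
#' four-state chains over the protocol, summed to an ohmic current with
#' optional additive Gaussian noise. Reproducible under a fixed seed.
#'
#' @param protocol a [voltage_protocol()].
#' @param params a [gating_parameters()] object (`n_channels` used).
#' @param e_ca Ca2+ equilibrium potential, mV (fixed).
#' @param seed RNG seed.
#' @param erev reversal potential for the ohmic current, mV.
#' @param noise_sd additive Gaussian noise, pA (0 = none).
#' @param initial `"equilibrium"` (two-state C/O equilibrium at the first
#'   bin voltage) or `"closed"`.
#' @param free_ca_nM internal free Ca2+ for potentiation, nM.
#' @param ramp_dt ramp discretisation, s.
#' @return list with `trace` (a [current_trace()]), `levels` (list per sweep
#'   of the integer number of open channels at each sample — the ground
#'   truth for idealization) and `states` (list per sweep of n_samples x
#'   n_channels integer state matrices).
#' @export
simulate_single_channels <- function(protocol, params, e_ca = Inf, seed = 1L,
                                     erev = 0, noise_sd = 0,
                                     initial = c("equilibrium", "closed"),
                                     free_ca_nM = NA_real_, ramp_dt = 0.005) {
  initial <- match.arg(initial)
  set.seed(seed)
  dt <- protocol$sample_interval
  n <- protocol_n_samples(protocol)
  nc <- params$n_channels
  sweeps <- seq_len(protocol$n_sweeps)
  lev_out <- vector("list", length(sweeps))
  st_out <- vector("list", length(sweeps))
  cur_out <- vector("list", length(sweeps))
  # initial states per channel
  states <- if (nc == 0L) integer(0) else if (initial == "closed") {
    rep(1L, nc)
  } else {
    b1 <- protocol_bins(protocol, 1L, ramp_dt)
    k <- rate_constants(b1$v[1], params, free_ca_nM)
    po <- k[["k1"]] / (k[["k1"]] + k[["k_minus1"]])
    ifelse(stats::runif(nc) < po, 2L, 1L)
  }
  for (si in sweeps) {
    bins <- protocol_bins(protocol, sweep = si, ramp_dt = ramp_dt)
    Qs <- lapply(seq_len(nrow(bins)), function(b)
      generator_matrix(bins$v[b], e_ca, params, free_ca_nM))
    stm <- matrix(1L, n, max(nc, 1L))
    for (ch in seq_len(nc)) {
      cp <- channel_path(bins, dt, n, Qs, states[ch])
      stm[, ch] <- cp$lev
      states[ch] <- cp$state
    }
    open_count <- if (nc == 0L) integer(n) else as.integer(rowSums(stm == 2L))
    v <- protocol_voltage(protocol, protocol_times(protocol), sweep = si)
    g <- ifelse(v < erev, params$g_in, params$g_out)
    cur <- open_count * g * (v - erev) / 1000
    if (noise_sd > 0) cur <- cur + stats::rnorm(n, sd = noise_sd)
    lev_out[[si]] <- open_count
    st_out[[si]] <- if (nc > 0L) stm else stm[, 0, drop = FALSE]
    cur_out[[si]] <- cur
  }
  list(trace = current_trace(cur_out, dt, protocol,
                             metadata = list(seed = seed, erev = erev,
                                             noise_sd = noise_sd)),
       levels = lev_out, states = st_out)
}
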