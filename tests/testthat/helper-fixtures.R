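# shared fixtures for the suite; everything is generated in code

const <- physical_constants()
RTF <- 1000 * const$R * const$T / const$F  # ~25.69 mV

# simple two-segment deactivation protocol: prepulse then test potential
deactivation_protocol <- function(v_test = -100, t_test = 0.4,
                                  sample_interval = 2e-4) {
  voltage_protocol(
    data.frame(kind = c("hold", "step", "step"),
               v_start = c(0, 100, v_test), v_end = c(0, 100, v_test),
               duration = c(0.05, 0.6, t_test)),
    sample_interval = sample_interval)
}

# fit the deactivation tail of a simulated trace; returns tau in s
fitted_tail_tau <- function(params, v_test = -100, t_test = 0.4,
                            sample_interval = 2e-4) {
  prot <- deactivation_protocol(v_test, t_test, sample_interval)
  occ <- simulate_occupancy(prot, params, e_ca = Inf)
  tr <- occupancy_to_current(occ, prot, params, erev = 0)
  sel <- occ$time >= 0.65
  fit_exponential(occ$time[sel] - 0.65, tr$sweeps[[1]][sel])$params$tau
}

# brute-force bisection oracle for the chelator equilibrium (uM units)
bisect_free_ca <- function(total_ca, buffers, tol = 1e-15) {
  f <- function(x) {
    x + sum(vapply(buffers, function(b) 1000 * b$total * x / (x + b$kd), 1)) -
      total_ca
  }
  lo <- 0; hi <- total_ca
  for (i in 1:300) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) < tol * max(lo, 1e-300)) break
  }
  (lo + hi) / 2
}
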