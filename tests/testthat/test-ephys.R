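test_that("QC filter applies the printed strict thresholds", {
  mk <- function(seal, leak = 0) current_trace(list(rep(0, 10)), 1e-3,
    metadata = list(seal_resistance = seal, leak_at_minus60 = leak))
  wc <- qc_filter(list(mk(0.9), mk(1.0), mk(10, 95), mk(10, 90), mk(10, 0)),
                  mode = "whole-cell")
  expect_equal(wc$reasons,
               c("seal-below-1GOhm", "ok", "leak-above-90pA", "ok", "ok"))
  oc <- qc_filter(list(mk(7.9), mk(8.1)), mode = "on-cell")
  expect_equal(oc$reasons, c("seal-below-8GOhm", "ok"))
  nometa <- current_trace(list(rep(0, 10)), 1e-3)
  expect_equal(qc_filter(list(nometa), mode = "whole-cell")$reasons,
               "missing-metadata")
})

test_that("exponential fit: exact noiseless recovery, degenerate, noisy MC", {
  tt <- seq(0, 0.2, by = 2e-4)
  f <- fit_exponential(tt, -12.1 * exp(-tt / 0.043))
  expect_true(f$converged)
  expect_equal(f$params$tau, 0.043, tolerance = 1e-6)
  expect_equal(f$params$A, -12.1, tolerance = 1e-6)
  expect_equal(f$params$B, 0, tolerance = 1e-6)
  # with offset
  f2 <- fit_exponential(tt, 3 + 5 * exp(-tt / 0.02))
  expect_equal(unlist(f2$params[c("A", "B", "tau")]), c(5, 3, 0.02),
               tolerance = 1e-6, ignore_attr = TRUE)
  # constant input is flagged, not fit
  expect_false(fit_exponential(tt, rep(2, length(tt)))$converged)
  # Gaussian noise sd 0.5 pA at 5 kHz over 200 ms: tau unbiased, ~few % error
  set.seed(77)
  errs <- replicate(100, {
    y <- -12.1 * exp(-tt / 0.043) + stats::rnorm(length(tt), sd = 0.5)
    fit_exponential(tt, y)$params$tau / 0.043 - 1
  })
  expect_lt(mean(abs(errs)), 0.05)
  expect_lt(abs(mean(errs)), 0.02)  # unbiased within MC error
})

test_that("Hill fit: round trips at the studied potencies, degeneracies", {
  for (ic50 in c(31, 9, 25, 156, 3)) {
    conc <- 10^seq(log10(ic50) - 2, log10(ic50) + 2, length.out = 7)
    dr <- generate_dose_response(ic50, 1, conc, noise_sd = 0)
    f <- fit_hill(dr$concentration, dr$response)
    expect_true(f$converged)
    expect_equal(f$params$half_max, ic50, tolerance = 1e-3)
  }
  # Hill coefficient recovered when generated at n = 2
  dr2 <- generate_dose_response(31, 2, c(3, 10, 30, 100, 300), noise_sd = 0)
  f2 <- fit_hill(dr2$concentration, dr2$response)
  expect_equal(f2$params$hill_n, 2, tolerance = 1e-3)
  # response at c = half_max is the midpoint by definition
  dr3 <- generate_dose_response(31, 1, c(31), noise_sd = 0)
  expect_equal(dr3$response, 50)
  # constant response cannot be fit
  expect_false(fit_hill(c(1, 3, 10, 30), rep(0, 4))$converged)
})

test_that("idealization: staircase recovery, baseline estimate, SNR warning", {
  dt <- 2e-4
  # flat zero trace idealizes to level 0 throughout
  flat <- idealize(rep(0, 500), -12.1, sample_interval = dt)
  expect_equal(max(flat$level_per_sample), 0)
  # constructed two-channel staircase 0-1-2-1-0 at -12.1 pA steps
  lv_true <- rep(c(0, 1, 2, 1, 0), each = 200)
  stair <- lv_true * -12.1
  set.seed(5)
  rec <- idealize(stair + stats::rnorm(length(stair), sd = 0.5), -12.1,
                  sample_interval = dt)
  expect_equal(rec$level_per_sample, lv_true)
  expect_equal(rec$n_max, 2)
  expect_equal(sum(rec$dwell_table$duration), rec$total_time)
  expect_equal(rec$baseline, 0, tolerance = 0.1)
  # amplitude within 2x the noise flags low SNR
  set.seed(6)
  expect_warning(idealize(stats::rnorm(2000, sd = 1), 1.5,
                          sample_interval = dt), "noise")
})

test_that("idealization agrees with the simulator's true levels at SNR ~24", {
  par <- gating_parameters(10, 10, n_channels = 3, g_in = 121)
  prot <- voltage_protocol(data.frame(kind = "hold", v_start = -100,
                                      v_end = -100, duration = 10),
                           sample_interval = 2e-4)
  sc <- simulate_single_channels(prot, par, seed = 21, noise_sd = 0.5, erev = 0)
  rec <- idealize(sc$trace, unitary_amplitude = -12.1)
  expect_gt(mean(rec$level_per_sample == sc$levels[[1]]), 0.99)
})

test_that("open probability: conventions, scaling and recovery", {
  dt <- 1e-3
  half_open <- idealize(c(rep(-12.1, 500), rep(0, 500)), -12.1,
                        sample_interval = dt)
  expect_equal(open_probability(half_open, 1)$p_o, 0.5)
  expect_equal(open_probability(half_open, 2)$p_o, 0.25)
  expect_equal(open_probability(half_open, 2)$convention, "Po")
  # unknown channel count falls back to NPo with n = n_max
  npo <- open_probability(half_open)
  expect_equal(npo$convention, "NPo")
  expect_equal(npo$n, 1)
  allc <- idealize(rep(0, 100), -12.1, sample_interval = dt)
  expect_equal(open_probability(allc, 1)$p_o, 0)
  # recovery across generator open probabilities (3 SE envelope)
  for (po_true in c(0.01, 0.1, 0.5)) {
    km1 <- 50
    k1 <- po_true / (1 - po_true) * km1
    par <- gating_parameters(k1, km1, fold_open_per_100mV = 1,
                             fold_close_per_100mV = 1, n_channels = 1)
    prot <- voltage_protocol(data.frame(kind = "hold", v_start = -100,
                                        v_end = -100, duration = 60),
                             sample_interval = 2e-4)
    sc <- simulate_single_channels(prot, par, seed = 31, noise_sd = 0.5)
    rec <- idealize(sc$trace, unitary_amplitude = -12.1)
    est <- open_probability(rec, 1)$p_o
    n_open <- sum(rec$dwell_table$level > 0)
    se <- po_true / sqrt(max(n_open, 1))
    expect_lt(abs(est - po_true), 3 * se + 2e-3)
  }
})

test_that("ensemble average: identities and macroscopic tau recovery", {
  s <- sin(seq(0, 1, length.out = 100))
  expect_equal(ensemble_average(list(s, s, s)), s)
  expect_equal(max(abs(ensemble_average(list(s, -s)))), 0)
  expect_error(ensemble_average(list(s, s[-1])), "unequal")
  # 20 stochastic tail sweeps: fitted tau within 25% of the deterministic one
  par <- gating_parameters(10, 25, n_channels = 40)
  prot <- voltage_protocol(
    data.frame(kind = c("hold", "step"), v_start = c(0, -100),
               v_end = c(0, -100), duration = c(0.5, 0.2)),
    sample_interval = 2e-4)
  sc <- simulate_single_channels(prot, par, seed = 8, erev = 0, noise_sd = 0.5)
  avg <- ensemble_average(sc$trace)
  tms <- protocol_times(prot)
  sel <- tms >= 0.5
  tau_fit <- fit_exponential(tms[sel] - 0.5, avg[sel])$params$tau
  tau_true <- 1 / sum(rate_constants(-100, par))
  expect_equal(tau_fit, tau_true, tolerance = 0.25)
})

test_that("I-V extraction interpolates the generator's reversal potential", {
  prot <- make_protocol("iv-steps", sample_interval = 1e-3)
  n <- protocol_n_samples(prot)
  tms <- protocol_times(prot)
  mk_ohmic <- function(erev, g = 100) {
    sweeps <- lapply(seq_len(prot$n_sweeps), function(s) {
      v <- protocol_voltage(prot, tms, s)
      g * (v - erev) / 1000
    })
    current_trace(sweeps, 1e-3, prot)
  }
  iv0 <- iv_extract(mk_ohmic(0), prot, "steady")
  expect_true(iv0$erev_defined)
  expect_equal(iv0$erev, 0, tolerance = 1e-9)
  iv8 <- iv_extract(mk_ohmic(8), prot, "steady")
  expect_equal(iv8$erev, 8, tolerance = 0.5)
  # simulated channel family with a conductance kink: within half a grid step
  par <- gating_parameters(50, 10, n_channels = 100)
  occ <- simulate_occupancy(prot, par, e_ca = Inf)
  tr <- occupancy_to_current(occ, prot, par, erev = 8)
  expect_equal(iv_extract(tr, prot, "steady")$erev, 8, tolerance = 2.5)
  # all-positive currents leave E_rev undefined
  allpos <- current_trace(lapply(seq_len(prot$n_sweeps), function(s) rep(5, n)),
                          1e-3, prot)
  expect_false(iv_extract(allpos, prot, "steady")$erev_defined)
})

test_that("current density divides by capacitance and keeps sign", {
  expect_equal(current_density(0, 10), 0)
  expect_equal(current_density(100, 10), 10)
  expect_equal(current_density(-100, 10), -10)
  expect_error(current_density(100, NULL), "capacitance")
})

test_that("inactivation rate: round trip at tau = 2.1 s and invariances", {
  supra <- rep(1.2, 8)
  amps <- exp(-cumsum(supra) / 2.1)
  f <- inactivation_rate(amps, supra)
  expect_true(f$converged)
  expect_equal(f$params$tau, 2.1, tolerance = 0.01)
  # invariant to amplitude rescaling
  f2 <- inactivation_rate(100 * amps, supra)
  expect_equal(f2$params$tau, f$params$tau, tolerance = 1e-6)
  # no suprathreshold time: unidentifiable
  expect_false(inactivation_rate(rep(1, 6), rep(0, 6))$converged)
})
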