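test_that("voltage-dependent rates: reference, +100 and -100 mV folds", {
  par <- gating_parameters(k1_0 = 10, k_minus1_0 = 25)
  expect_equal(rate_constants(0, par), c(k1 = 10, k_minus1 = 25))
  expect_equal(rate_constants(100, par)[["k1"]], 1.5 * 10)
  expect_equal(rate_constants(-100, par)[["k_minus1"]], 2.2 * 25)
  # opening speeds with depolarization, closing with hyperpolarization
  expect_lt(rate_constants(-100, par)[["k1"]], 10)
  expect_lt(rate_constants(100, par)[["k_minus1"]], 25)
})

test_that("preset calibrations reproduce their defining tau and P_o", {
  for (nm in c("wt", "d523n", "d525n")) {
    par <- gating_preset(nm)
    k <- rate_constants(-100, par)
    tau <- 1 / sum(k)
    po <- k[["k1"]] / sum(k)
    expect_equal(tau, switch(nm, wt = 0.043, d523n = 0.0023, d525n = 0.037),
                 tolerance = 1e-12)
    expect_equal(po, 0.007, tolerance = 1e-12)
  }
  expect_equal(gating_preset("d523n")$k_block, 0)
})

test_that("block condition is the sign of the outward Ca2+ driving force", {
  expect_false(block_condition(88, 88))
  expect_true(block_condition(118, 88))
  # high internal Ca2+ lowers E_Ca so +80 mV becomes blocking
  eca_low_ca <- nernst_potential(0.29 * 2e-3, 0.29 * 100e-9, 2)
  eca_high_ca <- nernst_potential(0.29 * 2e-3, 0.29 * 10e-6, 2)
  expect_false(block_condition(80, eca_low_ca))
  expect_true(block_condition(80, eca_high_ca))
})

test_that("generator matrix: conservation, gating of entries, equilibrium", {
  par <- gating_parameters(k1_0 = 10, k_minus1_0 = 25)
  Q <- generator_matrix(0, Inf, par)
  expect_equal(max(abs(rowSums(Q))), 0)
  expect_true(all(Q[row(Q) != col(Q)] >= 0))
  # below E_Ca only C<->O (and unblock) are open
  expect_equal(Q["O", "Oblock"], 0)
  expect_equal(Q["Oblock", "O"], par$k_unblock)
  expect_equal(Q["Oblock", "I"], 0)
  Qa <- generator_matrix(150, 88, par)
  expect_equal(Qa["O", "Oblock"], par$k_block)
  expect_equal(Qa["Oblock", "O"], 0)
  expect_equal(Qa["Oblock", "I"], par$k2)
  # all-zero rates give the zero matrix
  z <- gating_parameters(0, 0, k_block = 0, k_unblock = 0, k2 = 0)
  expect_equal(generator_matrix(0, Inf, z), generator_matrix(0, Inf, z) * 0)
  # two-state equilibrium 10/(10+25)
  prot <- voltage_protocol(data.frame(kind = "hold", v_start = 0, v_end = 0,
                                      duration = 2), sample_interval = 1e-3)
  occ <- simulate_occupancy(prot, par, e_ca = Inf)
  expect_equal(occ$p_O[nrow(occ)], 10 / 35, tolerance = 1e-6)
})

test_that("matrix-exponential propagator matches the Matrix-package oracle", {
  skip_if_not_installed("Matrix")
  par <- gating_parameters(k1_0 = 10, k_minus1_0 = 25, k_block = 5000,
                           k_unblock = 5000)
  for (v in c(-100, 0, 150)) {
    Q <- generator_matrix(v, 88, par) * 2e-4
    expect_equal(pkdclamp:::expm_small(Q),
                 unname(as.matrix(Matrix::expm(Q))),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("occupancy solver conserves probability and matches closed forms", {
  par <- gating_parameters(k1_0 = 10, k_minus1_0 = 25)
  prot <- voltage_protocol(
    data.frame(kind = c("hold", "step"), v_start = c(0, -100),
               v_end = c(0, -100), duration = c(0.5, 0.5)),
    sample_interval = 2e-4)
  occ <- simulate_occupancy(prot, par, e_ca = Inf)
  expect_lt(max(abs(occ$p_C + occ$p_O + occ$p_Oblock + occ$p_I - 1)), 1e-9)
  # two-state analytic solution during the hold: relaxation from C
  k <- rate_constants(0, par)
  ks <- sum(k)
  sel <- occ$time <= 0.5
  expect_equal(occ$p_O[sel],
               k[["k1"]] / ks * (1 - exp(-ks * occ$time[sel])),
               tolerance = 1e-6)
  # k2 = 0 keeps p_I at zero under block conditions
  par_nok2 <- gating_parameters(10, 25, k2 = 0)
  occ2 <- simulate_occupancy(
    voltage_protocol(data.frame(kind = "hold", v_start = 150, v_end = 150,
                                duration = 0.5), sample_interval = 1e-3),
    par_nok2, e_ca = 88)
  expect_equal(max(occ2$p_I), 0)
  # p_I is non-decreasing when recovery is off
  par_k2 <- gating_parameters(10, 25)
  occ3 <- simulate_occupancy(
    voltage_protocol(data.frame(kind = c("hold", "step", "step"),
                                v_start = c(0, 150, -60), v_end = c(0, 150, -60),
                                duration = c(0.2, 0.5, 0.3)),
                     sample_interval = 1e-3),
    par_k2, e_ca = 88)
  expect_true(all(diff(occ3$p_I) > -1e-12))
})

test_that("suprathreshold occupancy inactivates as exp(-t/2.1) when capture is fast", {
  par <- gating_preset("fast-open")
  prot <- voltage_protocol(data.frame(kind = "hold", v_start = 155, v_end = 155,
                                      duration = 4), sample_interval = 1e-3)
  occ <- simulate_occupancy(prot, par, e_ca = 120, p0 = c(0, 1, 0, 0))
  sel <- occ$time >= 0.2  # past the brief capture transient
  expect_equal(1 - occ$p_I[sel],
               (1 - occ$p_I[which(sel)[1]]) *
                 exp(-(occ$time[sel] - occ$time[which(sel)[1]]) / 2.1),
               tolerance = 0.02)
})

test_that("occupancy converts to piecewise-ohmic current", {
  par <- gating_parameters(1e9, 1e-9)  # pinned open
  prot <- voltage_protocol(
    data.frame(kind = c("step", "step"), v_start = c(-100, 100),
               v_end = c(-100, 100), duration = c(0.1, 0.1)),
    sample_interval = 1e-3)
  occ <- simulate_occupancy(prot, par, e_ca = Inf, p0 = c(0, 1, 0, 0))
  tr <- occupancy_to_current(occ, prot, par, erev = 0)
  i <- tr$sweeps[[1]]
  expect_equal(i[50], -12.1, tolerance = 1e-6)   # 121 pS * -100 mV
  expect_equal(i[150], 19.8, tolerance = 1e-6)   # 198 pS * +100 mV
  # p_O = 0 everywhere gives the zero trace
  occ0 <- occ; occ0$p_O <- 0
  expect_equal(max(abs(occupancy_to_current(occ0, prot, par)$sweeps[[1]])), 0)
})

test_that("stochastic simulation is seed-reproducible and matches the ODE", {
  par <- gating_parameters(10, 25, n_channels = 1500)
  prot <- voltage_protocol(
    data.frame(kind = c("hold", "step"), v_start = c(0, -100),
               v_end = c(0, -100), duration = c(0.3, 0.3)),
    sample_interval = 1e-3)
  a <- simulate_single_channels(prot, par, seed = 11, initial = "closed")
  b <- simulate_single_channels(prot, par, seed = 11, initial = "closed")
  expect_identical(a$trace$sweeps, b$trace$sweeps)
  c2 <- simulate_single_channels(prot, par, seed = 12, initial = "closed")
  expect_false(identical(a$trace$sweeps, c2$trace$sweeps))
  # n_channels = 0 gives a zero trace
  z <- simulate_single_channels(prot, gating_parameters(10, 25, n_channels = 0),
                                seed = 1)
  expect_equal(max(abs(z$trace$sweeps[[1]])), 0)
  # ensemble occupancy within 3 SE of the deterministic solution
  occ <- simulate_occupancy(prot, par, e_ca = Inf)
  frac <- a$levels[[1]] / par$n_channels
  idx <- c(60, 150, 295, 330, 420, 590)
  se <- sqrt(pmax(occ$p_O[idx] * (1 - occ$p_O[idx]), 1e-6) / par$n_channels)
  expect_true(all(abs(frac[idx] - occ$p_O[idx]) < 3 * se))
})

test_that("deactivation tau of the two-state core is recovered by fitting", {
  for (nm in c("wt", "d523n")) {
    par <- gating_preset(nm, n_channels = 100)
    tau_true <- 1 / sum(rate_constants(-100, par))
    tau_fit <- fitted_tail_tau(par, sample_interval = if (nm == "d523n") 2e-5 else 2e-4,
                               t_test = if (nm == "d523n") 0.05 else 0.4)
    expect_equal(tau_fit, tau_true, tolerance = 0.02)
  }
})

test_that("steady-state outward I-V collapses above E_Ca only with block", {
  e_ca <- 88
  prot <- make_protocol("iv-steps", sample_interval = 1e-3)
  run_iv <- function(par) {
    occ <- simulate_occupancy(prot, par, e_ca = e_ca)
    tr <- occupancy_to_current(occ, prot, par, erev = 0)
    iv_extract(tr, prot, "steady")$iv
  }
  wt <- gating_preset("wt", n_channels = 500)
  d523n <- gating_preset("d523n", n_channels = 500)
  iv_wt <- run_iv(wt)
  iv_mut <- run_iv(d523n)
  below <- iv_wt$v >= 40 & iv_wt$v <= 85
  above <- iv_wt$v >= 90
  # Wt: rising below E_Ca, collapsed above (negative slope across E_Ca)
  expect_true(all(diff(iv_wt$i[below]) > 0))
  expect_lt(max(iv_wt$i[above]), 0.05 * max(iv_wt$i[below]))
  # D523N (k_block = 0): keeps rising above E_Ca
  expect_true(all(diff(iv_mut$i[iv_mut$v >= 40]) > 0))
})
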