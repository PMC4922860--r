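test_that("activity coefficients: fixed table, Debye-Hueckel and limits", {
  m <- activity_model()
  expect_equal(activity_coefficient(ion_species("Na", 1, 150), m), 0.74)
  expect_equal(activity_coefficient(ion_species("K", 1, 150), m), 0.72)
  expect_equal(activity_coefficient(ion_species("Cs", 1, 100), m), 0.69)
  expect_equal(activity_coefficient(ion_species("Ca", 2, 20), m), 0.29)
  expect_error(activity_coefficient(ion_species("Li", 1, 10), m), "tabulated")

  # infinite-dilution limit
  dh0 <- activity_model("debye-huckel", ionic_strength = 0)
  expect_equal(activity_coefficient(ion_species("Na", 1, 1), dh0), 1)

  # extended Debye-Hueckel, hand-evaluated oracle:
  # log10 g = -0.509*1*sqrt(.156)/(1+0.328*4*sqrt(.156)) = -0.132409 -> 0.73719
  dh <- activity_model("debye-huckel", ionic_strength = 0.156)
  expect_equal(activity_coefficient(ion_species("Na", 1, 150), dh),
               10^(-0.509 * sqrt(0.156) / (1 + 0.328 * 4 * sqrt(0.156))),
               tolerance = 1e-12)

  # strictly decreasing in ionic strength and in z^2
  Is <- c(0.01, 0.05, 0.1, 0.2, 0.5)
  g_na <- vapply(Is, function(I)
    activity_coefficient(ion_species("Na", 1, 1),
                         activity_model("debye-huckel", ionic_strength = I)), 1)
  expect_true(all(diff(g_na) < 0))
  g_ca <- activity_coefficient(ion_species("Ca", 2, 1),
    activity_model("debye-huckel", ion_size = c(Ca = 4), ionic_strength = 0.1))
  g_na1 <- activity_coefficient(ion_species("Na", 1, 1),
    activity_model("debye-huckel", ion_size = c(Na = 4), ionic_strength = 0.1))
  expect_lt(g_ca, g_na1)
})

test_that("effective activity is gamma times concentration in M", {
  expect_equal(effective_activity(ion_species("Ca", 2, 0), 0.29), 0)
  expect_equal(effective_activity(ion_species("Ca", 2, 20), 0.29), 0.0058)
  expect_equal(effective_activity(ion_species("Cs", 1, 100), 0.69), 0.069)
  expect_error(ion_species("Na", 1, -1), "non-negative")
  expect_error(effective_activity(ion_species("Na", 1, 10), 1.2), "0, 1")
})

test_that("Nernst potential: closed forms and domain errors", {
  expect_equal(nernst_potential(0.05, 0.05, 1), 0)
  expect_equal(nernst_potential(0.1, 0.01, 2), RTF / 2 * log(10), tolerance = 1e-12)
  expect_equal(nernst_potential(0.1, 0.01, 1), RTF * log(10), tolerance = 1e-12)
  expect_error(nernst_potential(0, 0.01, 2), "positive")
})

test_that("monovalent bi-ionic ratio: symmetry, RT/F shift, activity scaling", {
  expect_equal(monovalent_permeability_ratio(0, 0.069, 0.069), 1)
  expect_equal(monovalent_permeability_ratio(RTF, 0.05, 0.05), exp(1),
               tolerance = 1e-12)
  expect_equal(monovalent_permeability_ratio(0, 0.1, 0.05), 2)
  # strictly increasing in the shift
  de <- seq(-50, 50, by = 10)
  r <- vapply(de, monovalent_permeability_ratio, 1,
              activity_cs_ext = 0.069, activity_x_ext = 0.1)
  expect_true(all(diff(r) > 0))
})

test_that("divalent bi-ionic ratio: quadratic oracle and limits", {
  # u^2 + u = 4 * a_x * ratio / a_cs = 2.3536 -> u = 1.11394, E = RTF ln(u)
  u <- (-1 + sqrt(1 + 4 * 2.3536232)) / 2
  e7 <- RTF * log(u)
  expect_equal(divalent_permeability_ratio(e7, 0.069, 0.0058), 7, tolerance = 1e-6)
  expect_equal(e7, 2.77, tolerance = 0.01)
  # E -> -Inf gives 0; u = 1 identity
  expect_lt(divalent_permeability_ratio(-500, 0.069, 0.0058), 1e-6)
  expect_equal(divalent_permeability_ratio(0, 0.069, 0.0058),
               0.069 / (2 * 0.0058), tolerance = 1e-12)
  # strictly increasing in E_rev
  ee <- seq(-150, 150, by = 25)
  r <- vapply(ee, divalent_permeability_ratio, 1, 0.069, 0.0058)
  expect_true(all(diff(r) > 0))
})

test_that("forward/inverse reversal-potential round trip", {
  expect_equal(erev_from_permeability(1, 0.05, 0.05, 1), 0, tolerance = 1e-8)
  expect_equal(erev_from_permeability(7, 0.069, 0.0058, 2),
               RTF * log((-1 + sqrt(1 + 4 * 2.3536232)) / 2), tolerance = 1e-6)
  for (E in seq(-150, 150, by = 30)) {
    r_di <- divalent_permeability_ratio(E, 0.069, 0.0058)
    expect_equal(erev_from_permeability(r_di, 0.069, 0.0058, 2), E,
                 tolerance = 1e-8)
    r_mono <- monovalent_permeability_ratio(E, 0.069, 0.104)
    expect_equal(erev_from_permeability(r_mono, 0.069, 0.104, 1), E,
                 tolerance = 1e-8)
  }
})

test_that("calcium current fraction: worked value and linearity", {
  expect_equal(fraction_ca_current(2, 150, 14.9), 0.199, tolerance = 5e-3)
  expect_equal(fraction_ca_current(0, 150, 14.9), 0)
  expect_equal(fraction_ca_current(1, 150, 14.9), 0.0993, tolerance = 5e-3)
  expect_equal(fraction_ca_current(4, 150, 14.9),
               2 * fraction_ca_current(2, 150, 14.9))
  expect_equal(fraction_ca_current(2, 150, 29.8),
               2 * fraction_ca_current(2, 150, 14.9))
})

test_that("junction-potential correction subtracts once, never idempotent", {
  expect_equal(junction_correct(10, 0), 10)
  expect_equal(junction_correct(10, 3.4), 6.6)
  expect_equal(junction_correct(0, -4.4), 4.4)
  expect_false(junction_correct(junction_correct(10, 3), 3) ==
               junction_correct(10, 3))
  expect_warning(junction_correct(0, 10), "advisory")
})

test_that("permeability_result dispatches on valence and applies corrections", {
  mono <- permeability_result(ion_species("Na", 1, 150), erev = -10,
                              cs_activity = 0.069, junction_potential = 0)
  expect_equal(mono$method, "monovalent-delta")
  expect_equal(mono$ratio,
               monovalent_permeability_ratio(-10, 0.069, 0.74 * 0.150))
  di <- permeability_result(ion_species("Ca", 2, 20), erev = 2.77,
                            cs_activity = 0.069)
  expect_equal(di$method, "divalent-absolute")
  expect_equal(di$ratio, 7, tolerance = 1e-3)
})
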