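#' Recording-solution description
#'
#' @param name label.
#' @param composition named numeric vector of salt concentrations, mM.
#' @param free_ca_nM buffered free Ca2+, nM (NA if unbuffered).
#' @param buffers list of [buffer_spec()] objects present in the solution.
#' @param temperature_K temperature, K.
#' @return a `recording_solution` object.
#' @export
recording_solution <- function(name, composition, free_ca_nM = NA_real_,
                               buffers = list(), temperature_K = 298.15) {
  stopifnot(is.numeric(composition), !is.null(names(composition)),
            all(composition >= 0))
  structure(list(name = name, composition = composition,
                 free_ca_nM = free_ca_nM, buffers = buffers,
                 temperature_K = temperature_K),
            class = "recording_solution")
}

#' Named solution presets
#'
#' Pipette/bath pairs matching the recording conditions the package
#' emulates:
#' * `"standard"` — pipette CsMES 80, NaCl 20, HEPES 10, MgCl2 2,
#'   Cs4-BAPTA 5 (90 nM free Ca2+); bath NaCl 150, HEPES 10, CaCl2 2.
#' * `"dvf-symmetric-na"` — symmetric 144 mM Na+, free divalents < 1 nM.
#' * `"high-k-bath"` — bath KCl 125, NaCl 20, HEPES 10, CaCl2 2 (zeroes the
#'   resting potential for on-cell work); standard pipette.
#' * `"nmdg-ca"` — bath NMDG 100, CaCl2 20, HEPES 10 (divalent bi-ionic
#'   condition); standard pipette.
#' * `"high-buffer"` — standard pipette with BAPTA 15 mM + EGTA 5 mM.
#'
#' @param preset solution-pair name.
#' @return list with `pipette` and `bath` [recording_solution()] objects.
#' @export
make_solutions <- function(preset = c("standard", "dvf-symmetric-na",
                                      "high-k-bath", "nmdg-ca", "high-buffer")) {
  preset <- match.arg(preset)
  std_pip <- recording_solution(
    "standard-pipette",
    c(CsMES = 80, NaCl = 20, HEPES = 10, MgCl2 = 2, Cs4BAPTA = 5),
    free_ca_nM = 90, buffers = list(buffer_spec("BAPTA", 5, 0.22)))
  switch(preset,
    "standard" = list(
      pipette = std_pip,
      bath = recording_solution("standard-bath",
                                c(NaCl = 150, HEPES = 10, CaCl2 = 2))),
    "dvf-symmetric-na" = {
      dvf <- recording_solution("dvf-na",
                                c(NaCl = 144, HEPES = 10),
                                free_ca_nM = 1e-3)  # <1 nM free divalents
      list(pipette = dvf, bath = dvf, divalent_free = TRUE)
    },
    "high-k-bath" = list(
      pipette = std_pip,
      bath = recording_solution("high-k-bath",
                                c(KCl = 125, NaCl = 20, HEPES = 10, CaCl2 = 2))),
    "nmdg-ca" = list(
      pipette = std_pip,
      bath = recording_solution("nmdg-ca-bath",
                                c(NMDG = 100, CaCl2 = 20, HEPES = 10))),
    "high-buffer" = list(
      pipette = recording_solution(
        "high-buffer-pipette",
        c(CsMES = 80, NaCl = 20, HEPES = 10, BAPTA = 15, EGTA = 5),
        free_ca_nM = 15,
        buffers = list(buffer_spec("BAPTA", 15, 0.22),
                       buffer_spec("EGTA", 5, 0.15))),
      bath = recording_solution("standard-bath",
                                c(NaCl = 150, HEPES = 10, CaCl2 = 2)))
  )
}

#' Additive recording-noise model
#'
#' @param gaussian_sd baseline Gaussian noise SD, pA.
#' @param line_frequency_amplitude optional mains-interference amplitude, pA.
#' @param line_frequency_hz mains frequency, Hz.
#' @param seed RNG seed.
#' @return a `noise_model` list.
#' @export
noise_model <- function(gaussian_sd = 0.5, line_frequency_amplitude = 0,
                        line_frequency_hz = 60, seed = 1L) {
  if (gaussian_sd < 0) stop("gaussian_sd must be non-negative")
  structure(list(gaussian_sd = gaussian_sd,
                 line_frequency_amplitude = line_frequency_amplitude,
                 line_frequency_hz = line_frequency_hz, seed = seed),
            class = "noise_model")
}

apply_noise <- function(sweeps, dt, noise) {
  if (is.null(noise)) return(sweeps)
  set.seed(noise$seed)
  lapply(sweeps, function(s) {
    out <- s
    if (noise$gaussian_sd > 0)
      out <- out + stats::rnorm(length(s), sd = noise$gaussian_sd)
    if (noise$line_frequency_amplitude > 0) {
      tt <- (seq_along(s) - 1L) * dt
      out <- out + noise$line_frequency_amplitude *
        sin(2 * pi * noise$line_frequency_hz * tt)
    }
    out
  })
}

#' Fixture description for synthetic traces
#'
#' Bundles a protocol, gating parameter set, noise model and generation
#' mode; `generate_trace()` returns the trace plus a ground-truth sidecar
#' holding every generator parameter, closing the recovery loop for the
#' analysis operations.
#'
#' @param name fixture label.
#' @param protocol a [voltage_protocol()].
#' @param gating a [gating_parameters()] object.
#' @param noise a [noise_model()] or NULL.
#' @param mode `"deterministic"` (occupancy ODE) or `"single-channel"`
#'   (stochastic).
#' @param e_ca Ca2+ equilibrium potential for the block rule, mV.
#' @param erev ohmic reversal potential, mV.
#' @param solutions optional [make_solutions()] result.
#' @return a `fixture_set` list.
#' @export
fixture_set <- function(name, protocol, gating, noise = NULL,
                        mode = c("deterministic", "single-channel"),
                        e_ca = Inf, erev = 0, solutions = NULL) {
  mode <- match.arg(mode)
  structure(list(name = name, protocol = protocol, gating = gating,
                 noise = noise, mode = mode, e_ca = e_ca, erev = erev,
                 solutions = solutions),
            class = "fixture_set")
}

#' Generate a synthetic current trace with its ground-truth sidecar
#'
#' @param fixture a [fixture_set()].
#' @param seed RNG seed (overrides the noise model's).
#' @return list with `trace` (a [current_trace()]), `truth` (named list of
#'   generator parameters: rates, conductances, expected tau and open
#'   probability at the protocol voltages, erev, seed) and, for
#'   single-channel fixtures, `levels` (true open-channel count per sample).
#' @export
generate_trace <- function(fixture, seed = NULL) {
  stopifnot(inherits(fixture, "fixture_set"))
  noise <- fixture$noise
  if (!is.null(seed)) {
    if (is.null(noise)) noise <- noise_model(gaussian_sd = 0, seed = seed)
    else noise$seed <- seed
  }
  par <- fixture$gating
  prot <- fixture$protocol
  truth <- list(name = fixture$name, k1_0 = par$k1_0,
                k_minus1_0 = par$k_minus1_0,
                g_in = par$g_in, g_out = par$g_out,
                n_channels = par$n_channels, erev = fixture$erev,
                e_ca = fixture$e_ca,
                seed = if (is.null(noise)) NA_integer_ else noise$seed)
  # expected two-state deactivation constants / open probabilities at the
  # distinct protocol voltages (below E_Ca)
  vset <- unique(unlist(lapply(seq_len(prot$n_sweeps), function(s)
    resolve_segments(prot, s)$v_start)))
  ks <- vapply(vset, function(v) rate_constants(v, par), c(k1 = 1, k_minus1 = 1))
  truth$voltages <- vset
  truth$tau_s <- 1 / colSums(ks)
  truth$p_open <- ks[1, ] / colSums(ks)
  levels <- NULL
  if (fixture$mode == "deterministic") {
    occ <- simulate_occupancy(prot, par, e_ca = fixture$e_ca)
    tr <- occupancy_to_current(occ, prot, par, erev = fixture$erev)
    tr$sweeps <- apply_noise(tr$sweeps, prot$sample_interval, noise)
    tr <- current_trace(tr$sweeps, prot$sample_interval, prot,
                        metadata = list(fixture = fixture$name,
                                        seed = truth$seed))
  } else {
    sc <- simulate_single_channels(
      prot, par, e_ca = fixture$e_ca,
      seed = if (is.null(noise)) 1L else noise$seed,
      erev = fixture$erev,
      noise_sd = if (is.null(noise)) 0 else noise$gaussian_sd)
    tr <- sc$trace
    tr$metadata$fixture <- fixture$name
    levels <- sc$levels
  }
  out <- list(trace = tr, truth = truth)
  if (!is.null(levels)) out$levels <- levels
  out
}

#' Synthetic Hill-equation dose-response table
#'
#' response = floor + (ceiling - floor) / (1 + (half_max/c)^hill_n) plus
#' optional Gaussian noise; monotone in expectation.
#'
#' @param half_max IC50/EC50, uM.
#' @param hill_n Hill coefficient.
#' @param concentrations concentrations, uM (> 0).
#' @param noise_sd additive noise SD in response units (percent).
#' @param floor,ceiling asymptotes (default 0 and 100 percent block).
#' @param seed RNG seed.
#' @return data.frame with `concentration` (uM) and `response`.
#' @export
generate_dose_response <- function(half_max, hill_n = 1,
                                   concentrations = c(1, 3, 10, 30, 100, 300, 1000),
                                   noise_sd = 0, floor = 0, ceiling = 100,
                                   seed = 1L) {
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  resp <- floor + (ceiling - floor) / (1 + (half_max / concentrations)^hill_n)
  if (noise_sd > 0) {
    set.seed(seed)
    resp <- resp + stats::rnorm(length(resp), sd = noise_sd)
  }
  data.frame(concentration = concentrations, response = resp)
}

#' Emulated Ca2+ uncaging step
#'
#' Flash photolysis of caged Ca2+ is represented as an instantaneous step of
#' internal free Ca2+ at `t_uncage`, which moves E_Ca (Nernst) and thereby
#' the block rule. Returns a per-sweep E_Ca function usable with
#' [simulate_occupancy()] / [simulate_single_channels()].
#'
#' @param free_before_nM,free_after_nM internal free Ca2+ before/after, nM.
#' @param ca_ext_mM external Ca2+, mM.
#' @param t_uncage uncaging time, s (absolute, across chained sweeps).
#' @param sweep_duration duration of one sweep, s.
#' @param gamma_ca Ca2+ activity coefficient.
#' @param constants a [physical_constants()] list.
#' @return function(sweep) returning E_Ca (mV) for that sweep.
#' @export
uncaging_eca <- function(free_before_nM = 100, free_after_nM = 10000,
                         ca_ext_mM = 2, t_uncage, sweep_duration,
                         gamma_ca = 0.29, constants = physical_constants()) {
  a_out <- gamma_ca * ca_ext_mM / 1000
  eca <- function(free_nM)
    nernst_potential(a_out, gamma_ca * free_nM * 1e-9, 2L, constants)
  e_before <- eca(free_before_nM)
  e_after <- eca(free_after_nM)
  function(sweep) {
    t_start <- (sweep - 1) * sweep_duration
    if (t_start >= t_uncage) e_after else e_before
  }
}
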