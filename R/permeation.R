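#' Ion species description
#'
#' @param name ion label, e.g. `"Na"`, `"Cs"`, `"Ca"`.
#' @param valence integer charge; one of +1, +2, +3, -1.
#' @param concentration concentration in mM, non-negative.
#' @param side `"internal"` or `"external"`.
#' @return an `ion_species` list.
#' @export
ion_species <- function(name, valence, concentration, side = c("external", "internal")) {
  side <- match.arg(side)
  if (!is.numeric(concentration) || length(concentration) != 1L || concentration < 0)
    stop("concentration must be a single non-negative number (mM)")
  if (!valence %in% c(1L, 2L, 3L, -1L))
    stop("valence must be one of +1, +2, +3, -1")
  structure(list(name = name, valence = as.integer(valence),
                 concentration = concentration, side = side),
            class = "ion_species")
}

#' Activity-coefficient model
#'
#' Two modes are supported. `"fixed-table"` (the default elsewhere in the
#' package) returns tabulated single-ion activity coefficients; the default
#' table holds the values used for the PKD2-L1 permeability calculations
#' (Na 0.74, K 0.72, Cs 0.69, Ca 0.29). `"debye-huckel"` evaluates the
#' extended Debye-Hueckel law
#' \deqn{\log_{10}\gamma = -A z^2 \sqrt{I} / (1 + B a \sqrt{I})}
#' with ionic strength `I` (M), Debye constants `A` and `B`, and an
#' ion-size parameter `a` (angstrom) per ion.
#'
#' @param mode `"fixed-table"` or `"debye-huckel"`.
#' @param table named numeric vector of gamma values (fixed-table mode).
#' @param dh_A,dh_B Debye-Hueckel constants (25 C water: 0.509, 0.328).
#' @param ion_size named numeric vector of ion-size parameters in angstrom.
#' @param ionic_strength ionic strength in M (debye-huckel mode).
#' @return an `activity_model` list.
#' @export
activity_model <- function(mode = c("fixed-table", "debye-huckel"),
                           table = c(Na = 0.74, K = 0.72, Cs = 0.69, Ca = 0.29),
                           dh_A = 0.509, dh_B = 0.328,
                           ion_size = c(Na = 4, K = 3, Cs = 2.5, Ca = 6),
                           ionic_strength = NA_real_) {
  mode <- match.arg(mode)
  if (any(table <= 0) || any(table > 1))
    stop("activity coefficients must lie in (0, 1]")
  if (mode == "debye-huckel") {
    if (!is.finite(ionic_strength) || ionic_strength < 0)
      stop("ionic_strength (M) must be set and non-negative in debye-huckel mode")
  }
  structure(list(mode = mode, table = table, dh_A = dh_A, dh_B = dh_B,
                 ion_size = ion_size, ionic_strength = ionic_strength),
            class = "activity_model")
}

#' Single-ion activity coefficient
#'
#' @param ion an [ion_species()].
#' @param model an [activity_model()].
#' @return dimensionless gamma in (0, 1].
#' @examples
#' activity_coefficient(ion_species("Ca", 2, 20), activity_model())  # 0.29
#' @export
activity_coefficient <- function(ion, model = activity_model()) {
  stopifnot(inherits(ion, "ion_species"), inherits(model, "activity_model"))
  if (model$mode == "fixed-table") {
    if (!ion$name %in% names(model$table))
      stop(sprintf("no tabulated activity coefficient for ion '%s'", ion$name))
    return(unname(model$table[[ion$name]]))
  }
  I <- model$ionic_strength
  if (I == 0) return(1)
  a <- model$ion_size[[ion$name]]
  if (is.null(a)) stop(sprintf("no ion-size parameter for ion '%s'", ion$name))
  log10g <- -model$dh_A * ion$valence^2 * sqrt(I) / (1 + model$dh_B * a * sqrt(I))
  10^log10g
}

#' Effective activity of an ion
#'
#' alpha = gamma * concentration, returned in M.
#'
#' @param ion an [ion_species()] (concentration in mM).
#' @param gamma activity coefficient in (0, 1].
#' @return effective activity in M.
#' @export
effective_activity <- function(ion, gamma) {
  stopifnot(inherits(ion, "ion_species"))
  if (!is.numeric(gamma) || gamma <= 0 || gamma > 1)
    stop("gamma must lie in (0, 1]")
  gamma * ion$concentration / 1000
}

#' Nernst equilibrium potential
#'
#' (RT/zF) ln(alpha_out / alpha_in), in mV.
#'
#' @param activity_out,activity_in effective activities in M, strictly positive.
#' @param valence ion valence.
#' @param constants a [physical_constants()] list.
#' @return potential in mV.
#' @examples
#' nernst_potential(0.1, 0.01, 2)  # ~ +29.6 mV
#' @export
nernst_potential <- function(activity_out, activity_in, valence,
                             constants = physical_constants()) {
  if (activity_out <= 0 || activity_in <= 0)
    stop("activities must be strictly positive")
  rtf_mv(constants) / valence * log(activity_out / activity_in)
}

#' Monovalent relative permeability from a reversal-potential shift
#'
#' Bi-ionic (paired-bath) form: P_X/P_Cs =
#' (alpha_Cs,e / alpha_X,e) * exp(dErev * F / RT), where `delta_erev` is
#' the junction-corrected shift E_rev(X bath) - E_rev(Cs bath). An
#' absolute bi-ionic variant using internal Cs activity is available via
#' `absolute = TRUE`, in which case `delta_erev` is the absolute E_rev in
#' the X bath and `activity_cs` should be the internal Cs activity.
#'
#' @param delta_erev reversal-potential shift (or absolute E_rev), mV.
#' @param activity_cs_ext external Cs activity, M (internal if `absolute`).
#' @param activity_x_ext external test-ion activity, M.
#' @param constants a [physical_constants()] list.
#' @param absolute use the absolute bi-ionic form.
#' @return dimensionless P_X/P_Cs.
#' @export
monovalent_permeability_ratio <- function(delta_erev, activity_cs_ext, activity_x_ext,
                                          constants = physical_constants(),
                                          absolute = FALSE) {
  if (activity_cs_ext <= 0 || activity_x_ext <= 0)
    stop("activities must be strictly positive")
  (activity_cs_ext / activity_x_ext) * exp(delta_erev / rtf_mv(constants))
}

#' Divalent relative permeability from an absolute reversal potential
#'
#' P_X/P_Cs = alpha_Cs,i * u * (u + 1) / (4 * alpha_X,e) with
#' u = exp(E_rev F / RT).
#'
#' @param erev measured, junction-corrected reversal potential, mV.
#' @param activity_cs_int internal Cs activity, M.
#' @param activity_x_ext external divalent activity, M.
#' @param constants a [physical_constants()] list.
#' @return dimensionless P_X/P_Cs.
#' @export
divalent_permeability_ratio <- function(erev, activity_cs_int, activity_x_ext,
                                        constants = physical_constants()) {
  if (activity_cs_int <= 0 || activity_x_ext <= 0)
    stop("activities must be strictly positive")
  u <- exp(erev / rtf_mv(constants))
  activity_cs_int * u * (u + 1) / (4 * activity_x_ext)
}

#' Reversal potential implied by a permeability ratio
#'
#' Numerical inverse of [monovalent_permeability_ratio()] /
#' [divalent_permeability_ratio()]: root-finds the E_rev at which the
#' forward equation reproduces `ratio`.
#'
#' @param ratio target permeability ratio, > 0.
#' @param activity_cs Cs activity, M (external for monovalent, internal for
#'   divalent).
#' @param activity_x external test-ion activity, M.
#' @param valence 1 (monovalent shift form) or 2 (divalent absolute form).
#' @param constants a [physical_constants()] list.
#' @param interval search bracket in mV.
#' @return E_rev (monovalent: the shift dE_rev) in mV.
#' @export
erev_from_permeability <- function(ratio, activity_cs, activity_x, valence,
                                   constants = physical_constants(),
                                   interval = c(-500, 500)) {
  if (ratio <= 0) stop("ratio must be strictly positive")
  fwd <- if (valence == 1) {
    function(E) monovalent_permeability_ratio(E, activity_cs, activity_x, constants)
  } else if (valence == 2) {
    function(E) divalent_permeability_ratio(E, activity_cs, activity_x, constants)
  } else stop("valence must be 1 or 2")
  f <- function(E) fwd(E) - ratio
  if (f(interval[1]) * f(interval[2]) > 0)
    stop("root not bracketed by the search interval; widen `interval`")
  stats::uniroot(f, interval, tol = 1e-12)$root
}

#' Fraction of current carried by calcium
#'
#' r = ([Ca]_ex / [Na]_ex) * (P_Ca / P_Na). With the 2 mM / 150 mM
#' physiological solutions and P_Ca/P_Na = 14.9 this gives r = 0.199, the
#' factor used in the charge-to-calcium bookkeeping.
#'
#' @param ca_ext external Ca2+ concentration, mM.
#' @param na_ext external Na+ concentration, mM (> 0).
#' @param p_ca_over_p_na relative permeability of Ca2+ to Na+.
#' @return dimensionless r.
#' @export
fraction_ca_current <- function(ca_ext, na_ext, p_ca_over_p_na = 14.9) {
  if (na_ext <= 0) stop("na_ext must be strictly positive")
  (ca_ext / na_ext) * p_ca_over_p_na
}

#' Liquid-junction-potential correction
#'
#' Convention: corrected = measured - junction potential. The correction is
#' not idempotent; apply exactly once to each measured reversal potential.
#' Junction potentials outside the advisory -4.4 to 3.4 mV range trigger a
#' warning only.
#'
#' @param erev_measured measured reversal potential, mV.
#' @param junction_potential measured liquid junction potential, mV.
#' @return corrected reversal potential, mV.
#' @export
junction_correct <- function(erev_measured, junction_potential) {
  if (junction_potential < -4.4 || junction_potential > 3.4)
    warning("junction potential outside the advisory -4.4 to 3.4 mV range")
  erev_measured - junction_potential
}

#' Bi-ionic permeability result table
#'
#' Convenience wrapper combining activity lookup and the appropriate
#' bi-ionic equation for one test ion against the Cs+ reference.
#'
#' @param test_ion an [ion_species()] on the external side.
#' @param erev measured reversal potential (divalent) or shift (monovalent), mV.
#' @param cs_activity Cs+ activity in M: external for monovalents, internal
#'   for divalents. Default internal Cs 100 mM at gamma 0.69.
#' @param model an [activity_model()].
#' @param junction_potential liquid junction potential to subtract, mV.
#' @param constants a [physical_constants()] list.
#' @return a `permeability_result` data.frame row with the ratio, the E_rev
#'   used, the method and the activities.
#' @export
permeability_result <- function(test_ion, erev,
                                cs_activity = 0.69 * 0.100,
                                model = activity_model(),
                                junction_potential = 0,
                                constants = physical_constants()) {
  stopifnot(inherits(test_ion, "ion_species"))
  e_used <- junction_correct(erev, junction_potential)
  gam <- activity_coefficient(test_ion, model)
  a_x <- effective_activity(test_ion, gam)
  if (test_ion$valence == 1) {
    method <- "monovalent-delta"
    ratio <- monovalent_permeability_ratio(e_used, cs_activity, a_x, constants)
  } else if (test_ion$valence == 2) {
    method <- "divalent-absolute"
    ratio <- divalent_permeability_ratio(e_used, cs_activity, a_x, constants)
  } else stop("only monovalent and divalent test ions are supported")
  data.frame(test_ion = test_ion$name, reference_ion = "Cs", ratio = ratio,
             erev_used = e_used, method = method,
             activity_x = a_x, activity_cs = cs_activity,
             stringsAsFactors = FALSE)
}
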