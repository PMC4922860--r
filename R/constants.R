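#' Physical constants
#'
#' Constants used throughout the permeation and calcium-accounting
#' calculations. The defaults are the rounded values used in the original
#' charge-to-calcium bookkeeping (elementary charge 1.6e-19 C, Avogadro
#' 6.02e23 /mol) so that printed worked numbers are reproduced exactly;
#' set `codata = TRUE` for the CODATA 2018 values.
#'
#' @param T_K absolute temperature in kelvin.
#' @param codata logical; use CODATA 2018 values for `e` and `N_A`.
#' @return a list with fields `F` (C/mol), `R` (J/(mol K)), `T` (K),
#'   `N_A` (/mol) and `e` (C).
#' @examples
#' const <- physical_constants()
#' const$R * const$T / const$F * 1000  # RT/F in mV, ~25.7 at 25 C
#' @export
physical_constants <- function(T_K = 298.15, codata = FALSE) {
  stopifnot(is.numeric(T_K), T_K > 0)
  out <- list(
    F   = 96485,
    R   = 8.314,
    T   = T_K,
    N_A = if (codata) 6.02214076e23 else 6.02e23,
    e   = if (codata) 1.602176634e-19 else 1.6e-19
  )
  class(out) <- "physical_constants"
  out
}

# RT/F in mV for a constants list
rtf_mv <- function(constants) 1000 * constants$R * constants$T / constants$F
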