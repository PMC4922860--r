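---
title: "The PKD2-L1 calcium-clamp model: gating, permeation and calcium accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The PKD2-L1 calcium-clamp model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkdclamp)
```

## The phenomenon

PKD2-L1 is a constitutively active, weakly Ca²⁺-selective TRP-family
channel enriched in small cellular compartments — the primary cilium
(~0.5 fL) and the dendritic knob of cerebrospinal-fluid-contacting neurons
(~113 fL). Whole-cell recordings show a characteristic sequence under
physiological external Ca²⁺: the current first potentiates over minutes,
then inactivates completely and irreversibly. Single-channel records show
the complementary event: outward openings disappear the moment internal
free Ca²⁺ is raised. The organizing idea is a *calcium clamp*: Ca²⁺
entering through the channel accumulates until the cytoplasmic side can
drive Ca²⁺ outward through the pore; the outward-moving ion then lodges at
the innermost acidic filter site, blocking conduction and triggering a
long-lived inactivated state. Ca²⁺ can enter a compartment through
PKD2-L1 but cannot leave through it.

This package implements that mechanism as a small set of coupled,
individually testable pieces: a four-state gating model, bi-ionic
permeability bookkeeping, a chelator/accumulation module, the standard
patch-clamp measurement operations, and seeded synthetic-data generators
that close every recovery loop.

## The gating model

States are closed (C), open (O), open-but-blocked (O_block) and
long-term inactivated (I):

* `C -> O` at `k1(V) = k1_0 * 1.5^(V/100)`, `O -> C` at
  `k_minus1(V) = k_minus1_0 * 2.2^(-V/100)` (V in mV). The folds per
  100 mV are measured quantities; their *directions* are a design choice:
  opening must grow with depolarization to give the observed steady-state
  outward rectification, and closure must grow with hyperpolarization to
  make tails decay faster at more negative potentials, as observed.
* `O -> O_block` at `k_block` whenever `V > E_Ca` (outward Ca²⁺ driving
  force), `O_block -> O` at `k_unblock` when `V <= E_Ca`. Block in the
  recordings is effectively instantaneous; the defaults (5000 s⁻¹) are
  fast relative to every other process, and the coupled whole-cell solver
  uses the exact instantaneous-switch limit in closed form.
* `O_block -> I` at `k2 = 1/2.1` s⁻¹, only while the driving force
  persists — inactivation accrues with *cumulative suprathreshold time*.
* `I` is absorbing by default (`k_recover = 0`): recovery is not seen
  within the <20 min timescale of the experiments the model describes.

Unitary current is piecewise ohmic, 121 pS inward and 198 pS outward with
the kink at the reversal potential; tails are observed to be linear, so no
GHK flux rectification is imposed. One open channel at −100 mV therefore
carries −12.1 pA, the level spacing used to idealize stacked openings
(up to 11 simultaneous levels are handled).

**Calibration.** The wild-type `k1_0, k_minus1_0` pair is fixed by two
measurements at −100 mV: deactivation τ = 43 ms (τ = 1/(k1 + k₋1) for the
two-state core) and constitutive open probability 0.007
(p = k1/(k1 + k₋1)). The D523N filter-mutant set uses τ = 2.3 ms,
p = 0.007 and `k_block = 0` — the mutant is not blocked by outward Ca²⁺
and consequently never inactivates; D525N uses τ = 37 ms with block
intact.

A consequence of this calibration is worth stating plainly: with 1.5× per
100 mV on a 0.24 s⁻¹ basal opening rate, opening at strongly depolarized
potentials is still slow (k1(+150 mV) ≈ 0.4 s⁻¹). During a suprathreshold
step, surviving wild-type channels therefore sit mostly in C rather than
O_block, and the tail-amplitude decay against cumulative suprathreshold
time overestimates 1/k2 roughly three-fold. The inactivation-rate
analysis in this package (`analysis/04`, and the τ_inact acceptance
check) therefore uses a *fast-opening* fixture set
(`gating_preset("fast-open")`: k1_0 = 50 s⁻¹, k_minus1_0 = 125 s⁻¹, in
the range of the generic example rates used elsewhere) so that block
capture is not rate-limited by opening, as in the recordings where the
outward current is blocked immediately. With that set the survivor
fraction decays as `exp(-t_supra/2.1 s)` and the fitted τ is within 1% of
1/k2; the residual bias is the ~9 ms each surviving channel spends
reaching O after each step onset.

**Potentiation** is a phenomenological Hill multiplier on k1 —
`1 + (g_max-1)·c^h/(c^h + K^h)` with g_max = 3, K = 300 nM, h = 2 — used
only to reproduce the qualitative potentiation-then-inactivation shape of
the whole-cell time courses. It is not constrained by rate measurements
and nothing quantitative is asserted about it.

**Solvers.** Occupancy follows `dp/dt = p Q(V(t))` by exact
matrix-exponential propagation on piecewise-constant voltage bins (ramps
discretised at 5–10 ms); probabilities are conserved to machine precision
and the propagator is checked against an independent matrix-exponential
implementation in the test suite. The stochastic path is an exact
event-driven (Gillespie) simulation of independent channels; ensemble
occupancy agrees with the deterministic solution within Monte-Carlo error,
which the suite asserts at 3 standard errors.

## Permeation

Relative permeabilities come from reversal potentials under bi-ionic
conditions, using effective activities `α = γ[X]`. The default activity
table (Na⁺ 0.74, K⁺ 0.72, Cs⁺ 0.69, Ca²⁺ 0.29) is the one used for the
measurements this package mirrors; an extended Debye-Hückel evaluator
(`log₁₀γ = -A z²√I/(1 + B å √I)`) is provided but opt-in, because no
single standard parameterization reproduces all four tabulated values
simultaneously. Two printed-formula issues are resolved in favor of
dimensional consistency: the monovalent exponent is implemented as
`exp(ΔE_rev·F/RT)` (the printed form has RT/F inverted), and the
exponential fit is implemented in the decaying form `B + A·exp(-t/τ)`.
The monovalent equation is used in its paired-bath (ΔE_rev) form by
default since Cs⁺ and NMDG⁺ reference baths are interchangeable for this
channel; the divalent equation is absolute and needs the internal Cs⁺
activity, taken as 100 mM (80 CsMES + 20 from Cs₄-BAPTA) — configurable,
since the exact value behind the published ratios is not stated.
`erev_from_permeability()` inverts either equation by bracketed
root-finding; forward∘inverse round trips hold to 1e-8 mV across
±150 mV. Junction correction is `corrected = measured - JP`, applied
exactly once.

## Calcium accounting

Charge-to-calcium bookkeeping follows the printed chain: cumulative
integrated tail charge Q → ion count `|Q|·r/(2e)` → concentration
increment `ions/(N_A·V)`, with r = (2/150)·14.9 = 0.199 under
physiological solutions. The constants default to the rounded values used
in that arithmetic (e = 1.6×10⁻¹⁹ C, N_A = 6.02×10²³, V = 2.14 pL) so
worked numbers reproduce exactly; CODATA values are selectable. Free
Ca²⁺ follows mass-action chelator equilibrium — single buffers in closed
form (cancellation-free quadratic), mixtures by Brent root-finding with a
Newton polish; the suite checks agreement with a brute-force bisection
oracle to 1e-12 relative with exact mass conservation. Apparent Kd values
are inputs (defaults BAPTA 0.22 μM, EGTA 0.15 μM at pH 7.4); the
pH/Mg²⁺/ionic-strength machinery of full chelator calculators is out of
scope. The quoted "good buffering" range (0.68–683 μM) is reproduced as
the 1000-fold log-symmetric interval around a Kd of 21.6 μM; the
literature also quotes 216 μM and sub-μM values for BAPTA — all are
selectable and none is asserted as truth.

The coupled whole-cell solver advances one sweep at a time: gating under
the current E_Ca → tail-transient charge (baseline-subtracted, as the
experimental tail integration) → buffer equilibrium → new free Ca²⁺ →
new E_Ca and potentiation for the next sweep. Buffer updates are
per-sweep, matching the sweep-integrated experimental procedure. One
modeling gate is added here: the binary driving-force block rule is
applied only once internal free Ca²⁺ exceeds ~0.7 μM (the level above
which inactivation dominates potentiation in the compartments this
mechanism serves). Without it, the sign-only rule would let a vanishing
outward Ca²⁺ flux at resting 100 nM block the channel, which the
recordings rule out; with it, zero-external-Ca²⁺ runs show neither
accumulation nor block, as observed.

## Measurement operations

Exponential and Hill fits use Levenberg-Marquardt least squares with
log-linear / interpolated starting values; both are exact (≤1e-6
relative) on noiseless model-generated data and unbiased under additive
Gaussian noise within Monte-Carlo error. The Hill coefficient floats
within [0.3, 4] unless fixed, as no coefficients are reported for the
block data this emulates. Degenerate inputs (constant traces, flat
dose-response tables) return `converged = FALSE` rather than numbers.
Idealization is half-amplitude multi-level rounding with a baseline taken
from the modal closed level (ties toward level 0) and a robust noise
estimate from the differenced trace; records whose unitary amplitude is
within twice the noise SD are flagged. Open probability is
`Σ level·dwell / (n·T)`; when the channel count is unknown the maximum
observed stack is used and the result is reported under the NP_o
convention, kept distinct from true P_o. Reversal potentials come from
linear interpolation between the bracketing points of the steady-state
I-V — deliberately not a spline, so monotone data cannot produce spurious
crossings; with the conductance kink at E_rev the interpolated value is
good to half a voltage step. QC mirrors the printed exclusion rules with
strict inequalities: whole-cell seals <1 GΩ or leak >90 pA at −60 mV, and
on-cell seals <8 GΩ, are rejected with reasons.

## Synthetic data and what passing tests show

Fixtures are generated, never stored: solution presets with the printed
compositions, the four named protocols (tail family; 0.5 Hz ramps;
0.2 Hz sub/suprathreshold step series; 300 ms, +5 mV I-V steps from −100
to +100 mV), deterministic or stochastic traces with seeded Gaussian
noise, and Hill dose-response tables. Sampling defaults to 5 kHz and
single-channel noise to 0.5 pA (SNR ≈ 24 for 12.1 pA events — idealization
is non-trivial but reliable); acquisition settings of the original
recordings are not stated, so these are declared choices, not inferences.
Uncaging is emulated as an instantaneous step of internal free Ca²⁺
feeding E_Ca. Every generator writes a ground-truth sidecar, and the
suite's recovery matrix asserts that each analysis operation returns the
generator's parameter within its stated tolerance.

Problem sizes are chosen to make sampling error small relative to the
asserted tolerances while keeping runs to seconds: 240-sweep (8 min) and
300-sweep (10 min) coupled whole-cell runs at 1 kHz with 2000 channels
(≈0.24 μS maximal inward conductance, matching multi-nA whole-cell
currents); a 240 s single-channel record at 5 kHz for the P_o = 0.0057
estimate (~130 openings, so 2 SE ≈ 17% of the value); 1500-channel
ensembles for the stochastic/deterministic comparison; 1000 random buffer
configurations for the chelator oracle.

What passing does *not* show: the synthetic traces have stationary
Gaussian noise, no capacitance transients, series-resistance error,
drift, or flicker/subconductance behavior, and the generator and analyzer
share the four-state model family. Recovery therefore validates the
estimators and the internal consistency of the mechanism, not the model's
adequacy against raw recordings, which are not publicly deposited.

## Known limitations

* Block is a sign test on the driving force; no rate-versus-[Ca²⁺] law is
  imposed because none is measured across the 10 μM–20 mM range where
  block is seen.
* The wild-type calibration cannot simultaneously produce the large,
  rapidly activating depolarized currents and the 0.007 constitutive
  P_o with single-exponential voltage factors — the reason the
  inactivation-rate analysis uses the fast-opening fixture set (above).
* The compartment model is well-mixed: no diffusion, extrusion pumps or
  exchangers (unknown for these compartments), so per-opening increments
  are order-of-magnitude statements.
* Hidden-Markov rate estimation from single-channel records, hooked-tail
  (hERG-like) inactivation and surface-charge corrections are out of
  scope.
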