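---
title: "Models and methods: from kinetic schemes to binding thermodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: from kinetic schemes to binding thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracekin)
```

# The measurement this package models

A single-molecule field-effect biosensor reports the conformational state of
one tethered molecule as a current level: charge rearrangements near the
nanowire gate its conductance, so a disordered peptide, its partially folded
encounter intermediate, and a fully folded binding complex appear as distinct,
decreasing current levels. A recording is therefore a piecewise-constant
signal — levels connected by effectively instantaneous jumps — buried in
white amplifier noise and the device's intrinsic 1/f noise, band-limited by
the acquisition filter (10 kHz) and sampled at 57.6 or 28.8 kHz.

`tracekin` implements this generative picture end to end and inverts it:

1. **Generate**: a continuous-time Markov chain over conformational/binding
   states (`kinetic_scheme()`, `simulate_path()`), rendered into a realistic
   trace (`render_trace()`).
2. **Idealize**: recover the hidden state sequence with a Gaussian-emission
   hidden Markov model (`fit_hmm()`, `viterbi()`), with a half-amplitude
   threshold baseline (`threshold_idealize()`) as an independent
   cross-check.
3. **Extract kinetics**: dwell tables (`segment_dwells()`), left-truncated
   exponential-mixture maximum likelihood (`fit_exponential_mixture()`),
   rate constants and their bootstrap intervals (`rate_constants()`).
4. **Estimate binding thermodynamics**: Hill dissociation constants
   (`fit_hill()`), Arrhenius activation energies (`fit_arrhenius()`),
   van't Hoff enthalpy/entropy (`fit_vant_hoff()`), observed binding rates
   and the two-step induced-fit model (`compute_kobs()`,
   `fit_induced_fit()`), dynamic disorder (`dynamic_disorder()`), and
   apparent affinities under competition (`apparent_kd()`).

# The generative model

## Kinetic schemes

A scheme is a rate matrix $Q$ over states carrying relative conductance
levels (baseline 1.0). Off-diagonal entries are first-order rate constants
(1/s); transitions marked pseudo-first-order store second-order constants
(1/(M·s)) and are multiplied by the ligand concentration at evaluation time.
Transitions may carry Arrhenius parameters, $k(T) = A e^{-E_a/RT}$, with $Q$
interpreted at a reference temperature of 310.15 K (37 °C) — binding studies
of this kind are run at pseudo-physiological conditions, and rates quoted
without further qualification refer to that temperature.

Built-in constructors cover the study designs this package targets:

* `binding_scheme()` — the bistate equilibrium between an encounter
  intermediate and the bound complex; association is pseudo-first-order with
  $k_{on} = k_{diss}/K_D$, so the stationary bound fraction is the textbook
  $C/(C+K_D)$.
* `apo_scheme()` — clustered self-folding pulses: a linear chain over three
  current levels (0 ↔ 1 ↔ 2) plus a parallel branch 0 ↔ 1\* whose state
  shares the medium level but dwells longer. The exact interconnection
  topology of such intermediates is generally under-determined by level
  data alone; we adopt the simplest arrangement in which each medium-level
  visit is a single exponential dwell, so the medium-level dwell
  distribution is a clean two-component mixture. Alternative wirings (for
  example 1 ↔ 1\* exchange) would produce phase-type medium dwells; users
  can build those with `kinetic_scheme()` directly.
* `competition_scheme()` — mutually exclusive partner-bound and
  inhibitor-bound complexes. The default `"distinct"` topology gives each
  ligand its own encounter intermediate, reflecting the observation that
  different ligands imprint different intermediate ensembles; the
  `"shared"` topology is the textbook purely competitive mechanism, for
  which the apparent dissociation constant obeys the Cheng–Prusoff relation
  $K_D^{app} = K_D (1 + [I]/K_I)$ exactly. The shared variant exists
  primarily as an analytic oracle: measured competition data need not obey
  Cheng–Prusoff when intermediates are ligand-specific, which is why the
  distinct topology is the default and the apparent constants it produces
  are reported as empirical quantities rather than predictions.

`stationary_distribution()` solves $\pi Q = 0$ on the closed communicating
class; states rendered unreachable (e.g. an inhibitor branch at zero
inhibitor) correctly receive zero mass, and genuinely ambiguous chains
(several closed classes) are an error.

## Trace synthesis

`simulate_path()` is an exact Gillespie sampler: dwell times are exponential
in the total exit rate and successors are chosen proportionally to outgoing
rates. Dynamic disorder — slow fluctuation of rates over seconds, far beyond
single dwells — is modelled by a piecewise-constant multiplicative factor on
all rates (`rate_modulation()`): a two-regime alternation or a log-normal
redraw per regime. Dwells crossing a regime boundary are resampled at the
boundary, which is exact by memorylessness.

`render_trace()` evaluates the level function on an internal grid 4× the
output rate, by exact time-weighted averaging within each grid cell — cells
interior to a dwell get the level exactly; only cells straddling a
transition average, which is what an integrating ADC records. Dwells
shorter than one grid cell are flagged with a warning. White noise of
standard deviation `white_sd` and a 1/f component (`pink_noise()`, spectral
shaping of white noise in the frequency domain, normalised to its target
SD) are added on the fine grid; the chain is low-pass filtered and
decimated.

Numerical choices worth stating:

* The anti-alias filter is a zero-phase Butterworth (`signal::filtfilt`),
  not a causal Bessel: zero-phase filtering avoids the group delay that
  would systematically shift dwell edges, which is the property that
  matters for dwell-time estimation. The filter is applied about the trace
  mean because a real acquisition filter runs in steady state — filtering
  the raw offset signal from zero initial conditions would inject a large
  start-up transient.
* Default noise calibration: the paper-scale recordings resolve their
  levels clearly but no signal-to-noise ratio is printed anywhere we could
  adopt, so the package default (`noise_for_scheme()`) sets the smallest
  level separation to 5 white-noise SDs — resolvable-but-noisy — with the
  1/f amplitude at half the white SD. Level drops default to 3% per folding
  step and 6% for the fully bound state, preserving the observed ordering
  (bound < intermediate < free).
* Reproducibility is byte-exact: every stochastic function takes a seed,
  restores the caller's RNG state, and `make_dataset()` spawns per-trace
  child seeds deterministically from the top-level seed.

# Idealization

The hidden Markov model has Gaussian emissions per state. Baum–Welch EM
uses scaled forward–backward recursions (per-sample normalisation with
log-accumulated normalisers — algebraically equivalent to log-space in
stability, far cheaper on megasample traces); the core loops are compiled.
Initialisation is deterministic: emission means at evenly spaced sample
quantiles, SDs at pooled SD/√K, transitions at 0.99 self-probability.
Convergence is declared when the per-sample log-likelihood gain falls below
`tol` (default 1e-6 nats); emission-variance collapse triggers up to three
seed-jittered restarts. States are relabelled by descending mean so state 0
is always the highest-current (least folded) state, giving stable identity
across traces.

Viterbi decoding breaks ties toward the lower state index, and the
half-amplitude threshold idealizer assigns midpoint samples to the
higher-current state; both rules are documented contracts, tested
explicitly. Model size is chosen by BIC with
$p = K^2 - K + 2K + (K-1)$ free parameters.

`segment_dwells()` converts label runs to dwells, merging runs at or below
the dead time (default 2 samples ≈ 35 μs at 57.6 kHz — below the
hundred-microsecond folding pulses, so genuine events survive) into the
neighbour with the nearer mean. First and last dwells are flagged censored
and excluded from fitting by default.

# Dwell kinetics

Dwell-time fitting is unbinned maximum likelihood under a left-truncated
exponential mixture: dwells at or below the dead time are unobservable, and
by memorylessness the surviving dwells minus the dead time are again an
exponential mixture with the same time constants — so EM on the shifted
data is the truncated MLE, and the observed weights map back through each
component's survival probability $e^{-d/\tau_k}$. This truncation
correction is accurate for $\tau \gtrsim 3 \times$ dead time; it is not a
full missed-event (exact hidden-Markov likelihood) correction, a documented
limitation. Component counts are selected by BIC; confidence intervals are
percentile bootstrap (500 resamples, seeded).

`dynamic_disorder()` computes arithmetic mean dwells in consecutive 1-s
windows — second-by-second, the natural scale separating dwell statistics
(ms) from conformational drift (tens of seconds) — and summarises their
spread. For a homogeneous exponential process with $m$ dwells per window
the CV of window means is $1/\sqrt{m}$; excess CV indicates dynamic
disorder.

`compute_kobs()` counts entries into the bound state per second of
observation. For the induced-fit mechanism — bind loosely first, then fold
— the observed rate rises hyperbolically with ligand:
$k_{obs}(C) = k_r + k_f C / (K_1 + C)$. The literature the study leans on
states the two-step model without printing its rate equation; we adopt this
standard increasing-hyperbola form because its concentration dependence is
the diagnostic that separates induced fit from conformational selection
(whose observed rate decreases with ligand), and we document it as an
interpretation rather than a quotation. The fit is weighted least squares
(event counts as weights), with concentrations rescaled internally so all
parameters are O(1); a flat curve drives $k_f$ to its boundary, where
$K_1$ drops out of the model — that degenerate fit is returned explicitly
with `identifiable = FALSE`.

# Binding thermodynamics

* **Bound population.** `bound_fraction()` is the time fraction of samples
  assigned to the bound state — computed from idealized labels, not from
  histogram areas, because labels are deterministic and testable. Its
  binomial-style interval uses the number of dwells, not samples, as the
  effective count, since samples within a dwell are perfectly correlated.
* **Hill fits.** $\alpha(C) = C^n/(K_D^n + C^n)$, least squares with
  $K_D$ parameterised on the log scale (positivity and a symmetric Wald CI
  in log space) and $n$ bounded to [0.2, 4]. The exponent is fitted, not
  fixed: reports flag when the CI for $n$ excludes 1. Inverse-variance
  weighting applies when per-point uncertainties exist.
* **Arrhenius / van't Hoff.** Ordinary least squares of $\ln k$ (or
  $\ln K$) on $1/T$; $E_a = -\mathrm{slope} \cdot R$,
  $\Delta H = -\mathrm{slope} \cdot R$, $\Delta S = \mathrm{intercept}
  \cdot R$. Equilibrium constants are oriented for dissociation,
  $K_{diss} = \tau_{unbound}/\tau_{bound}$, so a positive $\Delta H_{diss}$
  means dissociation is endothermic; the identity
  $\Delta H - T\Delta S = -RT \ln K_{pred}(T)$ holds exactly on the fitted
  line and is asserted in the tests. Temperatures are Kelvin internally;
  `celsius_to_kelvin()` converts at the interface.
* **Competition.** `apparent_kd()` is the same Hill estimator applied at a
  fixed inhibitor concentration and labelled apparent. On the shared-
  intermediate scheme it reproduces Cheng–Prusoff analytically; on the
  distinct-intermediate scheme the shift is larger than the Cheng–Prusoff
  prediction would suggest — which is precisely why the topology is
  configurable rather than assumed.

# What the synthetic data does and does not emulate

The generator reproduces the features that drive the estimators: multi-level
piecewise-constant currents from 2–5-state schemes, dwell scales from
~100 μs (folding pulses) to milliseconds (binding), concentration series
(nM–μM), temperature series (25–45 °C) with Arrhenius-controlled rates,
competition, white + 1/f noise, the 10 kHz filter, and both standard
sampling rates. It does not emulate baseline drift, discrete interferers
(e.g. charged debris), flicker between sub-levels, or the detailed
electrostatics of the sensor (Debye screening, absolute current scale —
traces are in relative conductance because no absolute current-change
values are available to calibrate against). Passing tests therefore
demonstrate correctness of the inference chain under the stated signal
model, not robustness to every artifact of real recordings; the
half-amplitude baseline and the dwell-table CSV interface exist so real,
externally idealized data can enter the pipeline downstream of the HMM.

# Problem sizes used in the shipped analyses

The test-suite and acceptance analyses run at the study's acquisition
settings where the signal chain is under test (60 s at 57.6 kHz for
end-to-end rate recovery; 10–20 s per dose point at 28.8 kHz for dose
series) and at path level where only dwell statistics matter (temperature
series, $k_{obs}$ flux checks, disorder replicates). These sizes give
thousands of events per estimate — enough that Monte-Carlo error sits well
inside each stated tolerance.

# Known limitations

* No missed-event correction beyond dead-time truncation (no exact
  HJC-style likelihood).
* The HMM assumes white emission noise; the rendered 1/f component and
  filter-induced correlation violate this mildly. At the default SNR the
  idealization error this causes is within the tested tolerances, but
  heavily correlated noise would call for pre-whitening, which is out of
  scope.
* Hill-fit confidence intervals are Wald-type in log $K_D$; coverage is
  verified by simulation at the shipped settings but profile intervals
  would be preferable for very short dose series.
* The purely competitive apparent-$K_D$ algebra applies to the shared
  topology only; no closed form is claimed for the distinct topology.
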