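---
title: "Methods: patch-clamp feature extraction and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-clamp feature extraction and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptoprobe)
```

## The problem

Whole-cell patch-clamp studies of cultured human neurons — for example
iPSC-derived dopaminergic neurons from Parkinson's disease patients and
healthy controls — characterize each neuron by a standard battery:
spontaneous excitatory postsynaptic currents (EPSCs) recorded gap-free
in voltage clamp; evoked action potentials over a family of small
current steps; sodium and potassium current–voltage families in voltage
clamp; and passive membrane properties. The scientific comparisons
(e.g. a depressed EPSC rate in patient-derived neurons) are then made
between groups of neurons. synaptoprobe implements this battery as a
reusable, tested pipeline, and pairs every analysis stage with a
synthetic-trace generator that knows the ground truth, so the
correctness of each stage is a measurable quantity rather than an
assumption.

## Operational definitions

The extraction stages follow the operational definitions customary in
this literature; each constant is a configuration key
(see `default_config()`).

**Evoked excitability.** Current-clamp families deliver 35 steps of
3 pA, 400 ms long, starting 12 pA below the steady holding current; the
excitability measure is the total number of action potentials over the
first 17 steps. Spikes are detected on the lightly smoothed voltage
(Savitzky–Golay, 0.5 ms window) as one detection per suprathreshold
excursion: the excursion must peak above −20 mV and be preceded within
2 ms by a dV/dt crossing of 10 mV/ms; a 5 mV hysteresis prevents noise
around the peak criterion from splitting one spike into several
excursions, and a 2 ms refractory merge suppresses residual double
counts. The detection criterion itself (threshold values, refractory)
is a modeling choice — acquisition software conventions differ — which
is why all three constants are exposed.

**Spike shape.** Measured on the first evoked action potential (the
lowest-current spiking sweep). Threshold is the voltage at the first
maximum of the second time-derivative before the peak; because raw
second differences at 20 kHz are noise-dominated, the derivative is
taken by central differences after Savitzky–Golay smoothing (window
0.5 ms, order 3), and "first maximum" means the earliest local maximum
above 10% of the largest value in the 10 ms pre-peak search window
(ties go to the earliest). Amplitude is peak minus threshold; width is
the full width at half maximum with sub-sample linear interpolation at
the half-amplitude crossings; the fast afterhyperpolarization is the
voltage 5 ms after the falling phase re-crosses threshold, minus
threshold.

**Quality control.** Neurons needing more than 50 pA of steady holding
current are excluded from group statistics ("more than" read strictly,
so exactly 50 pA passes); excluded neurons remain in the provenance
log. An indeterminate holding current excludes by default.

**Passive properties.** Input conductance is the difference of
steady-state currents at −70 and −50 mV divided by the 20 mV span
(pA/mV = nS). Capacitance comes from the membrane test. The membrane
test's vendor algorithm is proprietary, so the package defines its own,
and charge integration was chosen as the primary estimator because it
is robust to series-resistance distortion of the transient's time
course: after baseline subtraction the post-step plateau is estimated
over the final 25% of the step, the transient above the plateau is
integrated (trapezoidal) over five fitted decay constants with the
analytic tail added from a mono-exponential fit, and `C = Q/ΔV`.
Integrating much past the transient would only accumulate noise, which
is why the window is tied to the fitted τ. The exponential fit also
yields a consistency estimate `C = τ/R` and the two estimates are
reported with their relative discrepancy.

**Ionic currents.** Voltage-clamp families step from a −60 mV hold
across −90 to +80 mV (the published range fixes only the endpoints;
the 10 mV increment is a default, and the step voltages are read from
the command channel when present). Per step, after subtracting the
pre-step baseline: fast potassium is the maximum current in an early
window (0.5–10 ms after the step, the first 0.5 ms blanked as a
capacitive artifact); slow potassium is the mean over the final 50 ms;
sodium is the minimum over the early window measured *relative to the
sustained (late-window) level*, clamped to ≤ 0. The relative-to-
sustained definition was adopted so that a purely Ohmic cell reports
zero sodium current at every step, including hyperpolarizing ones —
plain baseline subtraction would report the leak offset itself as an
inward current there. Where the inward transient overlaps the
potassium rise the sodium measurement is a net extremum: this matches
the operational character of the published definitions rather than an
ionic decomposition. All three are divided by the capacitance to give
densities in pA/pF.

**Spontaneous EPSCs.** The published analyses name only the acquisition
software, so the detector is the package's own, fully parameterized:
a median-filter baseline tracker (200 ms window, computed on a
decimated trace and interpolated back) removes the holding level and
slow drift; a zero-phase Butterworth low-pass at 1 kHz suppresses
sampling noise; inward deflections beyond `max(5 pA, 4 × robust noise
SD)` (MAD-based) are events. Overlapping events are split at a genuine
intervening trough — both peaks must rise above the valley by at least
the detection threshold and the valley must fall below half the
smaller peak — and a smaller secondary detection within 4 ms of a peak
is treated as a noise excursion on its decay tail and merged (a larger
one, i.e. a genuinely stacked event, is kept). Amplitude is the raw
baseline-subtracted extremum near the filtered peak; onset is the
preceding 10%-of-peak crossing. Decay constants come from
least-squares mono-exponential fits (variable projection over τ) from
the peak over at most 20 ms, truncated at the next event's onset;
fits are refused when a larger event begins inside the window or when
R² < 0.5. A neuron *has synaptic activity* if it shows more than 20
events per 60 s; with other durations the rule is applied to the
60-s-normalized count and a provenance note is attached. A normalized
count of exactly 20 is classified inactive — the published rule
defines ">20" as active and "<20" as inactive, leaving 20 itself to
convention, and the conservative reading was chosen.

**Group statistics.** Two-sample comparisons use the Welch
(unequal-variance) two-tailed t-test — the published "two-sample
t-test" does not specify the variance assumption, and Welch is the
safer default; pooled-variance Student's t is available behind a flag.
The active-fraction comparison uses Fisher's exact test on the 2×2
active/inactive table (chi-squared behind a flag). Current-density
families are compared by one-way ANOVA on each neuron's extreme
density (sodium: most negative across steps; potassium: largest); a
per-voltage two-way layout is available because the published ANOVA's
structure is ambiguous. Amplitude distributions are compared by
two-sample Kolmogorov–Smirnov on the pooled event amplitudes. No
multiple-testing correction is applied; the statistics manifest
records the number of tests performed.

## The synthetic generator

The generator emulates the study design so the pipeline can be
validated end to end:

* **EPSC recordings** (`gen_epsc_trace`): homogeneous-Poisson event
  trains on Gaussian noise, each event an instantaneous-rise,
  mono-exponential-decay inward deflection; amplitudes are lognormal,
  parameterized by mean and CV. The real amplitude distribution family
  is not published; lognormal is a modeling choice (amplitudes are
  positive and right-skewed) and is flagged as such. Overlaps sum
  linearly; the inventory lists every inserted event. Defaults follow
  the study conditions: 20 kHz sampling, 60 s recordings, ~20 pA mean
  amplitude, 2.3 ms decay (1.5 ms for the disease-like contrast),
  ~2 pA noise, control rate 1 event/s with a 0.2× disease scale —
  matching the reported control rates near 1 Hz and patient rates near
  0.2 Hz.
* **Current-clamp families** (`gen_current_clamp`): piecewise-linear
  spike templates (shallow 1 mV/ms approach to threshold, linear rise
  and fall, a flat AHP plateau spanning the +5 ms sample) riding on
  passive step responses, with a deterministic thresholded-linear F–I
  rule; every shape metric has a closed form (FWHM = (rise+fall)/2).
  Conductance-based spiking is deliberately out of scope — templates
  suffice for testing feature recovery, which is what the generator is
  for.
* **Voltage-clamp families** (`gen_voltage_clamp_iv`): linear leak
  reversing at the hold, a Boltzmann-activated inward transient
  (alpha-function time course peaking ~1 ms), an early-peaking outward
  component (~3 ms) and a sustained outward component (τ = 20 ms).
  Ground truth stores, per step, exactly the quantities the extraction
  windows measure on the noiseless model.
* **Membrane tests** (`gen_membrane_test`): ideal RC response — an
  instantaneous jump ΔV/R above the Ohmic plateau relaxing with
  τ = RC, so the transient charge is exactly CΔV.
* **Cohorts** (`gen_cohort` / `draw_cohort_params`): named groups with
  across-neuron distributions (lognormal rates with CV 0.8, normal
  conductance scales truncated at zero, lognormal capacitance) and
  multiplicative group effects. One root seed is split
  deterministically per neuron and per sweep, so any cohort is exactly
  reproducible and distribution-level properties (test power, type-I
  error) can be studied at the parameter-drawing stage without
  synthesizing hundreds of full-length traces.

What the generator does *not* emulate — and what passing tests
therefore cannot certify on real data: seal/access-resistance
artifacts and their drift, multiphasic or finite-rise synaptic
kinetics, bursty (non-Poisson) event timing, electrode offset steps,
line interference, and biological heterogeneity beyond the modeled
distributions. Detector constants tuned here are sensible defaults,
not guarantees, for recordings whose noise deviates strongly from
white Gaussian.

## Numerical choices and degenerate inputs

Mono-exponential fits profile τ by golden-section search on log τ with
the amplitude solved linearly (variable projection), bounded to
[0.05, 100] ms. Half-maximum crossings interpolate linearly between
samples. Second-derivative ties take the earliest maximum. Empty event
lists summarize to rate 0/inactive with missing amplitude statistics.
A membrane test without a voltage step, a voltage-clamp family without
a resolvable baseline, or a capacitance of zero are errors, not
silent zeros; a missing capacitance flags the I-V result rather than
normalizing by a guess. Feature tables write missing metrics as empty
fields, never 0.

## Problem sizes used in validation

The shipped validation suite runs at desk scale, chosen to exercise
every stage with comfortable statistical resolution: 100 synthetic
60-s EPSC recordings for detector scoring; ≥200 fitted events per
decay-constant condition plus a 30-vs-30 neuron cohort for the decay
contrast; 130 current-clamp families for spike-count accuracy; 500
replicate parameter-stage cohorts for type-I error; and a two-group
demo cohort (15+15 neurons, 60 s recordings) for the end-to-end group
comparison. The full Fisher-exact cross-check enumerates every 2×2
table with total n up to 30.

## Interchange format and junction potential

Recordings move through an HDF5 interchange (one group per sweep,
float64 samples, JSON metadata; units always mV/pA/ms). ABF/NWB
parsing is not built in; convert upstream. Command potentials are
reported as commanded (−60 mV hold); the ~10 mV liquid-junction
correction is carried as metadata and applied only when a
configuration flag asks for it, because figures in this literature
conventionally report uncorrected values.

## Known limitations

* The EPSC detector is threshold-based; template-matching or
  deconvolution detectors would resolve heavily overlapping events
  better and could be added behind the same interface.
* Series-resistance compensation is not modeled; capacitance by charge
  integration is robust to it, but the τ/R cross-check is not.
* The activity rule's 60-s normalization assumes stationarity within
  the recording.
* Group statistics treat neurons as independent; cells from the same
  line or batch are pooled, as is conventional in this literature, and
  mixed-effects modeling is out of scope.
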