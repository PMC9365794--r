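# synaptoprobe

Feature extraction and group statistics for whole-cell patch-clamp
recordings of cultured neurons — the analysis battery used to compare
patient-derived neuron cohorts (for example iPSC-derived dopaminergic
neurons from Parkinson's disease patients against healthy controls),
where the headline readout is the rate of spontaneous synaptic currents
per neuron.

The package covers, per neuron:

* **Spontaneous EPSCs** — detection of inward synaptic currents on
  gap-free voltage-clamp traces (median-filter baseline tracking,
  zero-phase 1 kHz low-pass, threshold at `max(5 pA, 4×MAD)`), event
  rate and amplitude, mono-exponential decay constants (τ), and the
  activity classification (*active* ⇔ more than 20 events per 60 s).
* **Evoked excitability** — total action potentials over the first 17
  of 35 current steps (3 pA increments, 400 ms, from 12 pA below the
  holding current), with spikes counted once per suprathreshold
  excursion (dV/dt ≥ 10 mV/ms, peak ≥ −20 mV).
* **Spike shape** — threshold from the first maximum of the smoothed
  second derivative before the peak, amplitude, full width at half
  maximum (sub-sample interpolation), and the fast
  afterhyperpolarization 5 ms after threshold re-crossing.
* **Passive properties** — input conductance `G = ΔI/20 mV` from the
  −70/−50 mV steady-state currents; capacitance from the membrane test
  by charge integration (`C = Q/ΔV`) with a τ/R exponential-fit
  cross-check.
* **Ionic currents** — capacitance-normalized I–V curves (pA/pF) from
  −90…+80 mV step families: sodium peak (early-window inward transient
  relative to the sustained level), fast potassium (early-window
  maximum), slow potassium (late-window mean).
* **Group comparisons** — Welch two-tailed t-tests with mean ± SEM per
  group, Fisher's exact test on active fractions, one-way ANOVA on
  current densities, and Kolmogorov–Smirnov comparison of EPSC
  amplitude distributions. Quality control excludes neurons needing
  more than 50 pA of holding current.

Every stage is validated against a built-in synthetic-recording
generator with complete ground truth: Poisson EPSC trains with
lognormal amplitudes, piecewise-linear spike templates with closed-form
shape metrics, Boltzmann-gated current families, ideal-RC membrane
tests, and multi-group cohorts with configurable group effects.

## Worked example

Detect and summarize spontaneous EPSCs on a synthetic 60 s recording
whose ground truth is known:

```r
library(synaptoprobe)

g  <- gen_epsc_trace(rate_hz = 1, amp_mean_pa = 20, amp_cv = 0.3,
                     tau_ms = 2.3, noise_sd_pa = 2, duration_s = 60, seed = 42)
tr <- g$recording$sweeps[[1]]$response
ev <- fit_events_tau(tr, detect_epscs(tr))
summarize_events(ev, 60)
#> <event_summary> 70 events / 60 s = 1.167 Hz; mean amp 21.6 pA; mean tau 2.25 ms; active
g$truth$n_events
#> [1] 70
```

All 70 inserted events are recovered; the mean fitted decay constant
(2.25 ms) sits within a few percent of the generative 2.3 ms, and the
neuron is classified as synaptically active (70 > 20 events/60 s).

A two-group cohort end to end — a control group and a disease-like
group whose EPSC rate is scaled to 0.2× (the depression reported for
patient-derived neurons):

```r
cfg <- cohort_config(groups = list(
         control = group_spec(n = 8),
         pd      = group_spec(n = 8, rate_scale = 0.2, epsc_tau_ms = 1.5)),
       epsc_duration_s = 30)
run_pipeline(synthetic = cfg, out_dir = "demo_out", seed = 42)
f <- read_features_table("demo_out/features.csv")

compare_feature(f, "epsc_rate_hz", "control", "pd")
#> <welch_t> epsc_rate_hz: control (n=8, 0.8542 +- 0.153) vs pd (n=8, 0.3375 +- 0.145), stat=2.446, p=0.0283

compare_active_fraction(f, "control", "pd")
#> <fisher_exact> active_fraction: control (n=8, 0.75 +- NA) vs pd (n=8, 0.25 +- NA), stat=NA, p=0.1319
```

The rate depression is recovered (0.34 vs 0.85 events/s, Welch
p = 0.028 at n = 8 + 8); the active-fraction contrast (6/8 vs 2/8) is
directionally right but, as expected at this sample size, not
significant by Fisher's exact test. `demo_out/` also contains the
per-event table, per-group summary table, a JSON statistics manifest,
the generator's ground truth, and a run manifest with the MD5 of every
output (reruns with the same seed are byte-identical).

A thin command-line wrapper with `simulate` / `extract` / `all`
subcommands is installed at `inst/cli/synaptoprobe`; recordings are
exchanged in an HDF5 interchange format (ABF/NWB must be converted
upstream — no parser for those is bundled).

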