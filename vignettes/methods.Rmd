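---
title: "Measuring and evaluating EEG predictors of nociceptive response during sedation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and evaluating EEG predictors of nociceptive response during sedation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noceeg)
```

## The problem

During procedural sedation (propofol + remifentanil, spontaneously
breathing patients) the clinically hard question is not the depth of
hypnosis but whether the patient will *respond to a painful stimulus* —
a nail-bed compression scored on the Ramsay sedation scale (RSS 2–6,
6 = no response) or the gag reflex at endoscope insertion (GAG 0/1).
Classical depth-of-hypnosis monitors analyse the EEG below 30–47 Hz and
are blind to the frontal-muscle EMG that rides on a forehead
biopotential above 60 Hz, yet that EMG component carries exactly the
arousal information that predicts imminent response.

`noceeg` implements a measurement-and-evaluation pipeline for this
question: linear (spectral) and non-linear (auto-mutual-information)
measures computed on EEG filtered both in the traditional bands
(δ 0.1–4, θ 4–8, α 8–12, β 12–30 Hz) and in two high-frequency bands
where scalp/facial EMG dominates (HF 60–95 Hz, VHF 105–145 Hz), plus
the evaluation machinery — prediction probability (Pk), leave-one-out
discriminant classification with sensitivity/specificity, and a
randomized constrained feature-subset search — and a synthetic
recording generator so the whole pipeline is testable without clinical
data.

## Preprocessing

Two processing streams are prepared from the native recording
(≥ 300 Hz): a *traditional* stream conditioned to 0.1–45 Hz and
resampled to 128 Hz, and a *high-frequency* stream conditioned to
0.1–145 Hz and resampled to 300 Hz. Resampling is FFT-based rational
resampling: the spectrum is truncated at the smaller Nyquist frequency
(an ideal anti-alias filter) and inverse-transformed on the new grid.
Stream-level conditioning reuses the same spectral brick wall; the
order-50 FIR filters described next are reserved for the seven
analysis bands. The FFT route was chosen for passband fidelity: the
test-suite pins the reconstruction of a 10 Hz sinusoid across the
900→128 Hz conversion to better than 2 %.

Analysis windows are taken 30–90 s *before* each response annotation,
so the stimulation itself never contaminates the analysed signal. A
window is only attributed to its annotation if the effect-site
concentrations were stable across it (|ΔCe| < 0.1 μg/ml propofol and
< 0.1 ng/ml remifentanil between the first and last second); while the
condition fails, the window start advances one second at a time,
keeping the pre-event-proximal end (the 30 s guard before stimulation
is sacrosanct; the far end is expendable). Windows shorter than 50 s
(6400 samples at 128 Hz) are discarded.

Artifact handling has two stages, in order:

1. **Analytic-envelope peak suppression (ASEF).** The instantaneous
   envelope is the magnitude of the analytic signal (FFT construction).
   Samples whose envelope exceeds `k` times the median envelope
   (default `k = 5`) are rescaled onto that threshold. Because one
   rescaling pass perturbs the global envelope, the pass is iterated
   against the threshold fixed by the first-pass median until
   convergence — this makes the operation idempotent to numerical
   tolerance. Peak artifacts are amplitude events; rescaling preserves
   the frequency content of the window.
2. **Jump rejection.** A forward scan maintains the running mean of
   absolute first differences; at the first difference exceeding
   `factor` times that mean (default 10) the window is truncated just
   before the jump and the rest dropped — an abrupt discontinuity
   marks an electrode/contact event whose aftermath is untrustworthy.
   The running mean is only trusted after 50 accumulated differences
   (`min_history`): with one or two observations the rule would fire
   on ordinary signal. We read the exceedance criterion as a
   multiplier (×10) rather than a fraction (10 %): a literal 10 %-of-
   mean rule rejects essentially every physiological sample, so the
   multiplier reading is the only self-consistent one. Both knobs are
   config-exposed.

Band filtering uses order-50 FIR filters (Hamming windowed-sinc,
scaled to unity gain at the passband centre) applied forward–backward
(zero-phase), so no measure is lag-shifted; the effective magnitude
response is the squared design response, which only sharpens the
≤ 5 % stop-band intent. No 50/100 Hz notch is needed anywhere: every
analysis band excludes the mains and device-self-test lines by
construction.

## Spectral measures

The PSD is estimated by Welch's method: one-second Hamming-tapered
segments, 25 % overlap, density scaling with taper power correction —
so the integral of the density equals the signal power up to
discretisation, which the test-suite checks Parseval-style against the
sample variance. From the PSD of each stream we take, per band:
normalized band power (trapezoidal in-band area over the total area of
the *stream* support — 0–64 Hz for the 128 Hz path, 0–150 Hz for the
300 Hz path), the weighted mean (centroid) frequency `mF`, and the
spectral edge frequencies SEF50/75/90 with linear interpolation of the
cumulative area between 1 Hz grid points (the interpolation removes
staircase bias at the grid resolution). The band-filtered window
additionally yields its standard deviation and its autocorrelation
(biased estimator, lag-0 normalised). TB-band (0.1–145 Hz) measures
are computed on the 300 Hz stream, the only one whose support covers
the band.

## Auto-mutual information

The AMIF quantifies how much information a signal shares with its
τ-lagged copy. Each band-filtered window is quantized into 32
equidistant amplitude bins spanning the window's own range (recomputed
per window — this makes every AMIF measure invariant to affine
amplitude transforms, which limits inter-individual amplitude
variability). For each lag τ the joint distribution of
(xᵢ, xᵢ₊τ) is tabulated; the Shannon AMIF is the mutual information of
that table (0·log 0 = 0), bounded by log₂ 32 = 5 bits at τ = 0, and
the Rényi-q generalisation is

> AMIF_Re_q(τ) = 1/(q−1) · log₂ Σ P(xᵢ, xᵢ₊τ)^q / [P(xᵢ)^(q−1) P(xᵢ₊τ)^(q−1)]

summed over occupied cells. Orders q < 1 emphasise rare symbol pairs,
q > 1 common ones; q → 1 recovers Shannon, which the tests verify at
q = 1 ± 10⁻³. The default battery is Shannon plus
q ∈ {0.1, 0.2, 0.5, 2, 3, 5, 10, 30, 50, 100}. The cell sums are
evaluated in log-sum-exp form in compiled code: at q = 50–100 with
rare symbols the terms span hundreds of orders of magnitude and
overflow double precision otherwise. The lag horizon is 1 s — 300
samples on the 300 Hz stream and 128 samples on the 128 Hz stream —
and curves are normalised by their τ = 0 value.

Four scalars summarise each (normalised) curve, and the same four are
applied to the autocorrelation: the mean `m` over τ ≥ 1, the value
`maxL` at the first relative maximum (we return the *value*, not the
lag — the measure is grouped with `m` and `min` as a magnitude), the
signed absolute minimum `min` over τ ≥ 1, and the first decay
`FD = 1 − v(1)`. Higher `m`, `maxL`, `min` mean more regularity;
higher `FD` means faster information loss, i.e. more complexity.
τ = 0 is excluded from `m` and `min` because it is the normalisation
point and carries no predictability information. Measures are named
`measure(family_q)_band`, e.g. `FD(Re_05)_VHF`, `m(Re_50)_theta`,
`min(Ac)_delta`.

## Evaluation

Measures are screened per trial with the Mann–Whitney U test,
Bonferroni-corrected with an explicit family size (the number of
measures per trial; for per-lag curve screening, the number of lags).
Six two-class trials are defined: RSS 5 vs 6, RSS < 6 vs 6,
RSS < 5 vs 5, RSS < 5 vs 6, RSS < 5 vs ≥ 5, and GAG 1 vs 0.

Classification uses a linear discriminant with pooled within-class
covariance, equal priors, and the decision threshold at the midpoint
of the projected class means, validated by leave-one-out;
sensitivity/specificity are the percentages of response/no-response
windows classified correctly, recomputable from the returned
prediction log. The discriminant is deliberately a compact in-package
implementation — the randomized search multiplies into ~2·10⁵
leave-one-out fits — and the test-suite pins its decision boundary to
`MASS::lda` on a probe grid.

Pk, the prediction probability, is the chance that the indicator
correctly orders a random between-class pair (ties count half):
implemented via midranks, proven equal to brute-force pair counting in
the tests, with a delete-one jackknife standard error. Two Pk values
are compared by a normal-theory test on their difference. Orientation
is explicit: `pk(scores) + pk(−scores) = 1`; no automatic folding
around 0.5 is applied.

The subset search draws, per iteration, up to four candidate measures
whose pairwise absolute Spearman correlations stay below 0.7 ("not
correlated", made operational), evaluates them by leave-one-out, keeps
subsets with Sen > 60 % and Spe > 60 % (strict inequalities), and
ranks by Pk with deterministic tie-breaking (higher Sen + Spe, then
lexicographic subset name). 1000 iterations, no early stopping; the
whole search is reproducible from its seed. The candidate pool is the
screened set — measures significant in at least one trial — which is
what makes planted-subset recovery well-posed: pure-noise measures
rarely survive Bonferroni screening.

## The synthetic generator

The generator emulates the *statistical structure the measures read*,
not biophysics (no neural-mass or PK/PD model). One epoch of 130 s per
event: effect-site concentrations ramp linearly for 30 s at each epoch
start and stay flat, the event is annotated 5 s before the epoch end,
so the nominal pre-event span falls entirely in the stable plateau;
RSS = 6 is annotated only in latent-unresponsive epochs. The EEG is a
sum of band-limited Gaussian components with state-dependent gains, an
alpha component whose centre frequency shifts with state, a weak
broadband floor, optional 50/100 Hz mains lines, and Poisson-placed
20×-amplitude Gaussian peak artifacts (default 0.5/min — occasional,
as in clinically usable recordings).

Complexity contrasts are driven by *bandwidth*, not by additive
deterministic tones: a narrowband component has a long correlation
time (high AMIF mean over the 1 s horizon), and noise concentrated in
the upper VHF range has high lag-1 predictability (low first decay) —
the surrogate of motor-unit firing-rate synchronisation under deep
sedation. In the unresponsive state the β and EMG gains drop, the α
peak shifts from 10.5 to 9.5 Hz (at effect size 1), the EMG component
narrows towards 125–145 Hz, and the θ component broadens; δ/θ gains
rise mildly, consistent with slow-wave dominance. Every between-state
gap scales linearly with a single `effect_size` knob and vanishes at
0, giving an exact null generator. We initially tried sinusoid-tone
"regularity" fractions for the AMIF contrasts and measured them to be
nearly inert; the bandwidth parameterisation replaced them before the
defaults were frozen.

What the generator does *not* emulate: non-stationarity within a
window, real EMG burst dynamics, electrode pops (the jump-rejection
target), drug pharmacokinetics, or inter-subject variability. Passing
tests therefore demonstrate that the pipeline recovers planted
statistical structure under controlled conditions — not clinical
performance. The clinical performance tables of the motivating study
require its 378-patient database and are explicitly out of scope.

## Numerical choices and problem sizes

* 32 quantisation bins (fixed; no adaptive or equiprobable binning,
  no kernel/k-NN estimators).
* Zero-probability cells contribute nothing to either entropy family.
* SEF/`mF` integration is piecewise-linear with exact fractional band
  edges.
* Degenerate inputs are flagged, not silently numeric: constant
  windows give NaN AMIF curves with a warning, zero-power bands give
  NaN spectral measures with a warning, and these propagate as
  missing values excluded pairwise downstream.
* The direction-recovery checks assert the low-frequency complexity
  direction on `m(Sh)_theta`: Shannon weights all symbol pairs and
  responds monotonically to the bandwidth knob, whereas extreme-q
  Rényi orders (q = 50) track only the joint-histogram mode cells and
  respond non-monotonically on this generator (verified by a
  dedicated isolation experiment during design).
* Calibration and direction suites run at 100 events per class
  (~200 analysed windows, ~7.8 M samples per record); the oracle
  suites run at ≤ 50-sample toys where literal nested-sum evaluation
  is feasible. These sizes give medians and Pk estimates whose Monte
  Carlo noise is an order of magnitude below the asserted margins.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(n_per_class = 20, effect_size = 1, seed = 42)
rec <- generate_record(cfg)
tab <- compute_measures(rec, bands = c("theta", "beta", "VHF"),
                        specs = list(entropy_spec("Re", 0.5),
                                     entropy_spec("Re", 50)))
ds <- apply_trial(tab, "trial2")
loo_evaluate(ds, c("m(Re_50)_theta", "P_beta", "P_VHF", "FD(Re_05)_VHF"))
```

## Known limitations

* The ASEF reference algorithm is not publicly specified; the
  envelope-rescaling contract implemented here is this package's
  normative definition.
* `maxL` is undefined (NaN) on monotone non-increasing curves, which
  happens routinely for broadband windows; downstream code excludes
  missing values pairwise.
* The EDF writer emits plain 16-bit EDF with 1 s records and requires
  whole-second signals; annotations travel in CSV sidecars, not EDF+
  streams.
* Leave-one-out refits the discriminant per window without downdating
  shortcuts; for the problem sizes here (≤ a few hundred windows,
  ≤ 4 measures) this is well inside interactive budgets.
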