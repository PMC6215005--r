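---
title: "Decoding response-inhibition performance from Go/Nogo EEG: models, choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding response-inhibition performance from Go/Nogo EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In a Go/Nogo task, frequent Go stimuli demand a speeded button press and
rare Nogo stimuli demand withholding it. People differ stably in how well
they inhibit: some trade speed for accuracy, some commit many false alarms.
`nogodecode` implements a data-driven pipeline that asks which features of
the single-trial EEG — any channel, any post-stimulus time point, any
frequency between 1 and 18 Hz — best predict whether an individual is a
"good" or a "bad" performer, instead of restricting attention to the
classical inhibition ERPs (Nogo-N2, Nogo-P3).

The pipeline is: behavioral grouping → epoch cleaning → current source
density (CSD) → ERP averaging and Morlet total power → subject × feature
banks → hybrid t-test + SFFS feature selection with an RBF-SVM wrapper →
train/validation, permutation, and feature-omission verification. A
synthetic cohort generator with plantable ground truth makes every stage
testable without access to recorded data.

## Behavioral grouping

Per subject the speed–accuracy performance ratio is

$$r = \frac{100\,(1 - \mathrm{FA})}{\overline{RT}_{Go}} \quad
  [\%/\mathrm{ms}],$$

where FA is the Nogo false-alarm rate and the denominator is the mean
correct-Go reaction time. Larger is better: fewer false alarms and/or
faster responses. Typical values sit near 0.25 %/ms (e.g. 12% false alarms
at 348 ms gives 0.2525). Subjects are excluded when their mean Go RT
exceeds the cohort mean by more than 3 cohort SDs (computed before any
exclusion), or when false alarms or misses reach 50%. The remaining
subjects are split at the median ratio into equally sized "low" and "high"
performance groups; ties at the median are broken by stable subject-ID
order so that even cohorts always split exactly in half.

## Preprocessing

The pipeline consumes cleaned, band-limited (0.5–18 Hz), epoched data
(−2000 … +2000 ms around stimulus onset). Its fixed stage order is:

1. **Artifact rejection** (in µV, before CSD): a trial is dropped if any
   channel shows a peak-to-peak range above 200 µV within any 100 ms
   window, or below 0.5 µV within any 200 ms window. Windows slide at
   1-sample steps — only the window lengths are part of the convention,
   and the densest scan is the conservative reading. "Activity" is read
   as peak-to-peak
   range, the standard usage in commercial analyzers. Rejection is
   idempotent by construction.
2. **CSD transform**: a spherical-spline surface Laplacian (spline order
   m = 4, Legendre series truncated at n = 10 by default), yielding
   reference-free values in µV/m². The analyzer's undocumented
   "precision" setting has no standard equivalent; we expose a ridge
   term `lambda` (default 1e-5) on the spline system instead, plus the
   head radius. On a dense montage the implementation reproduces the
   analytic spherical-harmonic eigenvalues $\ell(\ell+1)$ to better than
   1% for $\ell \le 4$ (an acceptance test).
3. **Baseline correction** over −200…0 ms per trial and channel. CSD and
   baseline are both linear, so their order is immaterial (tested); the
   conventional order is kept.
4. **Averaging** of correct trials per condition into per-subject ERPs.

Classical quantification is provided for completeness: local-extremum peak
detection within component windows (P1 90–110 ms and N1 170–190 ms at
PO9/PO10; falls back to the window extremum with a flag when the window
contains no interior extremum, so flat subjects do not crash an analysis),
mean amplitudes (N2: 250–280 ms at Cz; P3: 370–410 ms at FC1/P1), and the
electrode-validation procedure: each electrode's mean |amplitude| in a
component window is compared against the average of all others with a
paired one-sided t-test, selecting electrodes significant at α = 0.0007
(the conventional Bonferroni-corrected threshold, taken as given rather
than recomputed from the montage size).

## Time–frequency decomposition

The Morlet wavelet is implemented verbatim in the printed form

$$W(t, f_0) = A\, e^{-t^2/\sigma_t^2}\, e^{2 i \pi f_0 t}, \qquad
A = (\sigma_t \sqrt{\pi})^{-1/2}, \qquad
\sigma_t = \frac{1}{2\pi \sigma_f}, \qquad
\sigma_f = \frac{f_0}{5.5},$$

including the $\sigma_t^2$ (not $2\sigma_t^2$) denominator, because the
conventional worked resolution values check out against exactly these
forms: $2\sigma_f = 0.36$ Hz at 1 Hz, $1.09$ Hz at 3 Hz, and
$2\sigma_t = 350$ ms, $2\sigma_f = 1.82$ Hz at 5 Hz. (The sometimes-quoted
$2\sigma_t = 1770$ ms at 1 Hz does not follow from these closed forms,
which give 1750.7 ms; the closed form is used.) Kernels are truncated at
$\pm 5\sigma_t$, where the Gaussian tail is below $10^{-5}$ of the peak.

**Total power** is computed per single trial and then averaged, which
retains non-phase-locked activity — this is why the synthetic generator
gives its oscillatory bursts a random phase per trial: they cancel out of
the ERP average but survive in total power. Convolution uses zero padding;
samples closer than one wavelet duration ($2\sigma_t$) to an epoch edge
are flagged invalid and never enter feature banks. (Requiring full
$\pm5\sigma_t$ kernel support instead would leave *no* valid sample at
1–2 Hz inside a ±2 s epoch, emptying those rows; the $2\sigma_t$ margin is
the operative rule, which is also why the epochs are 4 s long.)

## Feature banks and selection

Candidate features are all (channel, time) points from 0 to 1.5 s at
sample resolution — 64 × 385 = 24,640 at 256 Hz — and, for total power,
the same grid per frequency 1…18 Hz. All features are z-scored across
subjects (population SD by default; the divisor does not affect the
t-filter or the SVM after standardization, and zero-variance columns are
dropped with a log message).

Selection is hybrid: a two-sample t-test per column keeps candidates with
p strictly below 0.01 (Welch by default; the variant is configurable and
immaterial for balanced groups), then sequential floating forward
selection (SFFS) with a 10-fold cross-validated RBF-SVM as the wrapper
criterion. The kernel is $K(x, y) = \exp(-\lVert x-y\rVert^2 / 2\sigma^2)$
with σ = 5 — "sigma" is read as the Gaussian width, the conventional
parameterization — and soft-margin cost C = 1 (unstated in the protocol;
exposed in the configuration). The SVM is a from-scratch SMO C-SVC
(maximal-violating-pair working-set selection), cross-checked in
development against libsvm decision values to ~1e-7.

Folds are stratified by group and drawn once per run from the seed, which
keeps the per-fold accuracy granularity stable (1/24 ≈ 4.17% at N = 240)
and makes the whole selection deterministic. Ties between candidates are
broken by lower filter p-value, then column order. Per cumulative feature
count the report carries the k fold accuracies, their mean, classwise
accuracies, and Student-t 99% confidence bounds
$\bar a \pm t_{0.995, k-1}\, s/\sqrt{k}$; two accuracies differ
significantly iff their closed intervals are disjoint (touching endpoints
overlap).

SFFS is a greedy heuristic with conditional backtracking, not an exact
search: it provably matches exhaustive search over singletons at step 1
and never falls below plain SFS on the recorded best-of-size, but it can
miss the exhaustive optimum for larger subsets (one of twenty small test
instances exhibits this). The acceptance suite states this outcome rather
than papering over it.

## Verification

Because the reproduction protocol selects features on the full analysis
set, its training-criterion accuracies are optimistic. The verification
stage quantifies generalization: a stratified 70/30 subject split (168/72
at N = 240), selection on the training set only, a single evaluation per
cumulative feature count on the validation set, a 1000-iteration
label-permutation test (labels reshuffled over all subjects with group
sizes preserved; the reported percentage counts permutations whose
accuracy the real-label accuracy *strictly* exceeds — ties are
not-better), and feature-omission ablation (remove the selected columns,
re-run the full filter + SFFS protocol on the remainder, report the
validation accuracy — at chance if the removed features carried all the
signal). Permutations reuse the already-selected features, matching the
verification protocol; a stricter per-permutation re-selection mode
exists but is not the default. A fully nested mode
(`nested_cv_accuracy`) additionally re-runs normalization, filter and
SFFS inside every training fold, demonstrating on null data that
selection bias lives in the training criterion, not in held-out
estimates.

## The synthetic cohort generator

The generator emulates the study design the pipeline targets: 240
subjects, 64-channel extended 10/20 montage (idealized spherical
positions), 256 Hz, 450 trials at 70:30 Go:Nogo, mean Go RT 348 ms
(SD 30), mean FA rate 12% (SD 5%), ~1.25% misses. Background activity is
1/f-plus-white Gaussian noise (RMS 10 and 2 µV), synthesized in the
frequency domain band-limited to 0.5–18 Hz, matching the offline filter
of the emulated recordings. Planted components are Gaussian-windowed
transients and Hann-windowed sinusoidal bursts — simple, analytically
checkable shapes: visual P1/N1 at PO9/PO10, a Nogo-N2 at Cz, a Nogo-P3 at
FC1, a Go-P3 at P1, and three group-modulated plants on Nogo trials — a
broadband transient at C3/322 ms, a 4 Hz theta burst at C3/324 ms and a
9 Hz alpha burst at T7/207 ms.

Per subject, a latent performance score $s \sim N(0,1)$ drives behavior:
$\mathrm{FA} = \mathrm{logit}^{-1}(\mathrm{logit}(0.12) - 0.47\,s +
\varepsilon_f)$ and $RT = 348 - 29\,s + \varepsilon_r$, with residual SDs
derived so the marginal FA/RT dispersions match their configured values.
These coupling defaults make behavior a strongly trait-driven readout —
the coherent stated world for a study that groups stable performers by a
behavioral trait; the residual noise then mostly reflects the binomial
sampling of the realized FA rate over the subject's Nogo trials. All
randomness flows from one master seed through per-subject substreams, so
any subject can be regenerated in isolation (the streaming pipeline in
`run_pipeline()` relies on this) and equal seeds give bit-identical
cohorts.

**Effect-size semantics.** `effect_size` is the Cohen's d of a planted
feature between the two *behavioral* performance groups — the contrast
the downstream filter and classifier actually see. The calibration
propagates three attenuations analytically: trial-averaged background
noise at the feature ($\sigma_m = \sigma_{bg}/\sqrt{m}$ over the expected
retained correct-Nogo trials), the grid-sampling loss of a transient
peaking between samples, and the score-to-ratio correlation ρ (delta
method, including binomial FA-rate noise). Because groups come from a
median split of a noisy readout, no planted slope can exceed
$d_{\max} = 1.596\,\rho/\sqrt{1 - 0.637\rho^2}$; configurations beyond
this ceiling are rejected with the ceiling printed. At full-scale trial
counts ρ ≈ 0.96 and $d_{\max}$ ≈ 2.4; at the demo scale (60 trials)
ρ ≈ 0.84 and $d_{\max}$ ≈ 1.6. Setting `effect_size = 0` plants no
group-discriminative component at all, giving an exact null world.

**What the generator does not emulate** — and what a green test therefore
does not establish: spatial correlation of background noise across
channels (noise is independent per channel, so CSD denoising looks more
favorable than in vivo), ocular/muscle artifacts beyond what the
rejection thresholds see, trial-to-trial latency jitter of components,
volume-conducted source mixing (components live on single electrodes),
and non-stationarities across the session. Recovery results on this world
validate the pipeline's statistics and bookkeeping, not its robustness to
those realities.

## Scales, budgets and defaults

The `demo_config()` preset scales the world to 16 channels, 64 Hz and 60
trials (42 Go / 18 Nogo expected) — every axis about four times smaller
than full scale — while keeping the cohort size, behavioral parameters
and planted effects. This is the configuration the CPU-bounded acceptance
checks run at; a full-scale cohort does not fit in memory all at once,
which is why `run_pipeline()` streams subjects and why `generate_cohort()`
is documented for reduced configurations.

Key defaults, in one place: filter α = 0.01 (strict), k = 10 folds,
max 20 features, SVM σ = 5 / C = 1, CI level 0.99, train fraction 0.7,
1000 permutations, CSD m = 4 / n = 10 / λ = 1e-5, wavelet ratio 5.5,
frequencies 1–18 Hz, feature window 0–1.5 s, baseline −200–0 ms.

## Known limitations

The SMO solver recomputes the kernel matrix per fit, which is fine at
n ≤ a few hundred subjects but not for much larger cohorts. The idealized
montage is a constructive spherical 10/20 layout, not a digitized cap.
The HDF5-style cohort container is implemented as plain text (JSON + CSV)
— interoperable and diffable, but not the right choice for very large
cohorts. Confidence bounds treat fold accuracies as i.i.d., the usual but
optimistic assumption under cross-validation.
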