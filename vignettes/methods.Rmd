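---
title: "Recognizing flight behaviors from fused physiological signals: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing flight behaviors from fused physiological signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A pilot performing different maneuvers (takeoff, level flight, turn-and-hover,
roll, somersault, stall) exhibits systematic autonomic responses: heart rate
rises and heart-rate variability falls with task difficulty, breathing
quickens, tonic skin conductance climbs, and sustained forearm muscle tension
changes. `physiofuse` implements the full chain that turns five wearable
channels — ECG (512 Hz), galvanic skin response (64 Hz), surface EMG
(1024 Hz), respiration (64 Hz) and skin temperature (32 Hz) — into a
per-window behavior label, by feature-level fusion of 28 channel statistics
followed by decision-level fusion of four tree classifiers under
confidence-weighted voting.

Because the cohort that motivated this pipeline is private, the package ships
a synthetic cohort generator whose parameters encode exactly the monotone
difficulty trends the pipeline is supposed to detect. Every stage is therefore
testable against known ground truth; what a green test establishes, and what
it does not, is discussed at the end.

## Preprocessing

Per subject and channel the chain is: artifact detection → 30-s tile
rejection → neighborhood imputation → z-scoring → filter bank. Two points
deserve explanation.

**Where the percentage rule runs.** The artifact detector flags any sample
whose relative change from the previous *accepted* sample exceeds 20%
(strict inequality; the accepted-reference form prevents one spike from
cascading flags). A relative-change rule is only meaningful on a positive,
slowly varying native scale: applied after z-scoring, a zero-mean channel
produces unbounded ratios near zero crossings, and on an oscillatory channel
(ECG, EMG) every QRS upstroke or noise burst trips it — in our experiments the
rule then flags well over 20% of samples and rejects *every* tile. We
therefore run detection, rejection and imputation on the native sensor scale
and only then normalize (z-scoring is linear, so the later filters are
unaffected by the swap), and apply the percentage rule by default only to the
slowly-varying channels (GSR, RESP, SKT). Beat-to-beat artifacts on the ECG
side are handled where they are well-defined: RR intervals outside a
300–2000 ms physiologic gate are excluded from all HRV statistics.

**The filter bank.** Each channel gets (in order) a denoising stage, a
high-pass, a 50 Hz band-stop and a low-pass, with the published cutoffs; any
stage whose cutoff reaches the channel's Nyquist frequency is skipped and
logged (e.g. the 50 Hz notch on 64 Hz channels, and the 200 Hz low-pass on the
32 Hz skin-temperature channel). The published 5 Hz high-pass for skin
temperature is *below* Nyquist but would delete a quasi-DC thermistor signal
entirely; we treat it as a transcription error and skip it, logging the
decision. Filters are second-order IIR biquads (Butterworth Q for high/low
pass, Q = 30 for the notch) run forward-backward for zero phase; the notch
attenuates a 50 Hz tone by far more than the 20 dB the test demands.
Denoising is a hand-rolled periodized db4 wavelet transform (depth
`floor(log2(rate/8))`). For ECG and respiration — signals that are sparse in
the wavelet domain — details are soft-thresholded at the universal threshold
with the noise scale taken from the finest band (MAD/0.6745). Surface EMG is
itself broadband: universal-threshold shrinkage would remove ~99% of its
energy, so the EMG wavelet stage instead subtracts the level-J approximation
(baseline wander) and leaves the detail bands intact, which matches the
stated purpose of the stage (baseline noise and drift removal).

**Beat detection** is a Pan–Tompkins-family detector (derivative, squaring,
150 ms moving-window integration, adaptive threshold at 20% of the 99th
percentile, 250 ms refractory, refinement to the ECG maximum within 100 ms).
On noise-free synthetic ECG it recovers ≥ 99% of ground-truth beats; that is a
statement about clean quasi-periodic signals, not about pathological rhythms.

## Features

Windows are 30 s long with a 10 s step; a window takes the label covering the
majority of its span and is dropped if it overlaps a rejected tile or a label
gap. The 28 features, in canonical order, are: 13 ECG/HRV features
(instantaneous value, HR, NN, SDNN, SDSD, RMSSD, pNN50, pNN20, ULF, VLF, LF,
HF, LF/HF), 3 skin-conductance features (value, mean, SD), 7 EMG features
(value, mean, SD, RMS, iEMG, median frequency, mean power frequency), 4
respiration features (value, mean, SD, dominant frequency) and the skin
temperature value. All statistics use the population (1/N) standard
deviation, matching the defining formulas. "Value" features are read from the
common 2 Hz downsampled stream at the window end.

Three definitional choices were genuinely open:

* **EMG mean and SD are computed on the rectified waveform** (mean absolute
  value and its SD). The mean of a high-passed, zero-mean EMG trace is
  identically ~0; only the rectified reading makes the reported
  high correlation between EMG mean and integrated EMG, and the reported
  downward difficulty trend of EMG mean, possible. RMS is unaffected
  (RMS(|x|) = RMS(x)); iEMG is `sum(|x|)·dt`.
* **Spectral HRV uses a rolling tachogram buffer** (RR intervals resampled to
  a uniform 4 Hz grid), up to 5 min long, ending at the window and truncated
  at the start of the window's behavior segment. A 30-s window cannot resolve
  ULF (≤ 0.003 Hz) at all, and letting the buffer cross a maneuver boundary
  injects the between-behavior mean-RR step into the slow bands, swamping the
  real slow variability. Windows whose buffer is shorter than 2 min report
  ULF/VLF as missing; LF, HF and LF/HF need 1 min. Bands are the standard
  ULF ≤ 0.003, VLF 0.003–0.04, LF 0.04–0.15, HF 0.15–0.4 Hz, integrated from
  a Hann/50%-overlap Welch estimate (segment ≤ 120 s, 4096-point FFT so the
  slow bands contain bins). Rows with missing values are kept and flagged,
  never silently dropped; model fitting uses complete rows.
* **pNN50/pNN20 use strict inequalities** (a successive difference of exactly
  20 ms does not count), so pNN50 ≤ pNN20 always holds.

## The synthetic cohort: a stated world

Each behavior is generated from a profile holding the physiological causes of
the trends the screening stage is meant to find. Difficulty `d` (a 1–10
subjective rating) maps to parameters linearly (or log-linearly):

| parameter | curve | direction |
|---|---|---|
| mean RR interval | 1000 − 40·d ms | ↓ |
| slow RR modulation (two tones < 0.003 Hz) | 40·e^(−0.25·d) ms | ↓ |
| 0.095 Hz RR modulation | 22 − 1.4·d ms | ↓ |
| respiration-coupled RR modulation | 6 + 0.9·d ms | ↑ |
| respiration rate | 0.15 + 0.022·d Hz | ↑ |
| tonic skin conductance | 2 + 0.8·d µS | ↑ |
| phasic response rate | 2 + 0.5·d per min | ↑ |
| EMG activation | 0.85 − 0.06·d | ↓ |

The magnitudes are design choices — the source experiments report trend
directions, not effect sizes — chosen once to be physiologically plausible
(62–100 bpm heart rates, 10–22 breaths/min) and detectable; they were not
revisited after seeing test outcomes. ECG is a Gaussian-bump PQRST template
driven by an RR process with exactly the band structure above, so spectral
HRV features have known ground truth; GSR is a tonic level plus
Poisson-arriving phasic responses (≈0.7 s rise, 3 s decay), with the tonic
level ramping over 10 s at behavior boundaries (real skin conductance drifts;
an instantaneous step would also be indistinguishable from an artifact to the
percentage rule); EMG is zero-mean white noise with RMS
`noise floor + 0.5·activation`; respiration is a slowly amplitude-jittered
sinusoid; skin temperature is a bounded random walk slower than 0.1 °C/s.

Two cohort-level mechanisms matter for interpretation:

* **Personalization.** When a difficulty table is supplied (the packaged
  14-subject table by default), each subject's per-behavior parameters are
  driven by *that subject's own rating*. Trend recovery is evaluated per
  subject against the subject's own ratings, so this is required for the
  check to be attainable: a subject who rated stall a 3 genuinely should look
  like other subjects' easy maneuvers. A side effect is that cross-subject
  generalization (leave-one-subject-out CV) is intrinsically hard in this
  world — the label→physiology mapping differs across subjects — so LOO
  accuracies here sit well below the within-subject k-fold figures and below
  what the original study reports on real data.
* **Inter-subject jitter.** One multiplicative log-normal factor per subject
  and parameter (SD 0.08 by default) scales each parameter curve. Because the
  factor is constant within subject, within-subject monotonicity — and hence
  trend recovery — is preserved exactly, while between-subject variation
  makes LOO CV strictly harder than k-fold CV; the controlled experiment in
  the acceptance suite (jitter 0.02 vs 0.5 on rating-free cohorts) shows the
  k-fold/LOO gap widening with jitter.

What the generator does *not* emulate: realistic ECG morphology beyond
identifiable R-peaks, motion artifacts (beyond an optional spike-injection
knob), ectopic beats, the stall occurring at a random time (segments are
scheduled blocks, for reproducibility), and any coupling between channels
beyond the shared respiration frequency. A green trend-recovery or
classification test therefore establishes that the pipeline's machinery is
correct and sensitive, not that the original study's effect sizes or
accuracies are reproduced.

## Screening

Inter-feature redundancy uses the Pearson coefficient in its covariance form;
feature–difficulty association uses Kendall's tau-b (ties are heavy when the
grouping variable is a 1–10 rating, so the tie-corrected variant is the only
defensible choice; the source does not specify one). Associations are banded
none/moderate/high at |tau| = 0.1/0.3 — the published figure communicates the
grouping by color only, so the thresholds are configurable. Each window is
assigned its subject's own rating; using the per-behavior mean rating instead
is a switch. The retained 19-feature set is reproduced verbatim in selection
mode `"paper"` (reading its bare "RESP" and "SC" entries as the respective
instantaneous values); mode `"threshold"` implements the generic
drop-the-redundant-member rule with an importance-based tie-break.

## Ensemble and evaluation

The four base classifiers — a single CART decision tree, 100 extremely
randomized trees (random split thresholds, √p feature subsampling, no
bootstrap, probability averaging), multinomial gradient boosting (100 rounds,
depth 3, shrinkage 0.1) and a second-order Newton-boosting variant (100
rounds, depth 6, shrinkage 0.3, L2 λ = 1, hessian-weighted trees) — are
implemented natively on a shared Rcpp tree kernel, because no tree-model
package is available in the target environment. Hyperparameters mirror the
common library defaults and are pinned in the specification objects.

The combiner is per-window confidence-weighted voting: member *i* votes for
its argmax class with weight ω_i = max_j p_i(j); the class score g(L) is the
sum of the weights of the members voting L, and the ensemble returns
argmax g. With all confidences equal this reduces exactly to majority voting.
Ties are broken toward the lowest label code and logged — the scheme itself
is silent on ties. A full soft-voting variant (argmax of summed probability
vectors) is available for comparison but is not the default, since the
combiner's weight is defined as the probability of the *predicted* class
only. No temporal smoothing across windows is applied.

Evaluation offers class-stratified k-fold CV (note: windows of one subject
can land in both train and test folds — that leakage is part of the protocol
being reproduced and is why k-fold accuracy exceeds LOO accuracy) and
leave-one-subject-out CV. The multi-class "MSE" statistic is the mean squared
difference of integer label codes in the fixed behavior order; since such a
statistic is representation-dependent, the codebook is explicit and
swappable, and no attempt is made to tune it toward any published value.

## Numerical choices and degenerate inputs

* Population SD everywhere a defining formula is involved; `stats::sd()`'s
  1/(N−1) is never used for features.
* Constant signals: z-scoring errors; Pearson/Kendall return `NA` (not 0);
  respiration frequency returns `NA` when no peak clears 5× the in-band
  median PSD.
* Imputation shrinks its 11-point neighborhood at boundaries and falls back
  to the nearest unflagged value when the whole neighborhood is flagged.
* Fewer than 2 R-peaks in a window makes all time-domain HRV features of the
  window missing; fewer than 8 RR intervals in the buffer makes the spectral
  set missing.
* Welch PSD: Hann window, 50% overlap, per-segment mean removal (no linear
  detrend — a detrend would also remove the genuine slow HRV component the
  ULF band measures), one-sided density scaling.
* Median frequency interpolates linearly inside the crossing bin; a
  zero-power spectrum yields `NA`.

## Known limitations

The LOO accuracies on the default synthetic cohort are far below the source
study's (by design of the personalization model, see above). The percentage
artifact rule is not applied to ECG/EMG raw samples; a pipeline facing real
electrode-motion artifacts would need a dedicated ECG artifact stage. The
tree kernel is exact but minimal: no missing-value handling inside trees
(complete rows are required), no monotonic constraints, no column-wise
histogram acceleration. The stall segment is scheduled, not random.
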