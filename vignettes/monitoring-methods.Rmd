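---
title: "Methods: speech and physiology biomarkers for daily COPD monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speech and physiology biomarkers for daily COPD monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models, its tunable
parameters, and the design decisions taken where the protocol left choices
open. It states no empirical result beyond what the test suite and the
`analysis/` scripts themselves compute.

## The monitoring problem

A smartwatch worn in daily life records audio (44.1 kHz, on a
2-min-on/8-min-off duty cycle, i.e. 20% of wall-clock time), 1-Hz heart
rate derived by the vendor from the optical sensor, and daily step counts.
Each morning the wearer answers an eight-item questionnaire: three major
symptoms (sputum-colour change, increased breathlessness, increased sputum
amount) score 5 points each, five minor symptoms (cold, fever, increased
wheezing, sore throat, worsening cough) score 1 point each. A daily score
of 6 or more therefore requires at least one major plus one minor symptom,
and an *exacerbation* is two or more consecutive days at or above 6. The
analysis asks whether daily speech features are associated with the daily
score and the per-day exacerbation state, and whether heart-rate
variability (HRV) and activity *moderate* those associations.

## Audio segmentation cascade

Raw audio passes four stages, each with its threshold exposed in
`run_config()`:

1. **Silence gate.** Non-overlapping 50-ms frames; a frame survives when
   its RMS intensity is at least −20 dB. The intensity reference is full
   scale (amplitude 1.0, so dB = 20·log10(RMS)): the protocol does not
   state a reference, and dBFS is deterministic and device-independent.
2. **Windowing.** Non-silent intervals are tiled with 2-s windows stepped
   by 1 s (50% overlap); a trailing remainder shorter than 2 s is dropped.
   All frame and window intervals are half-open `[start, end)`.
3. **Voice activity detection.** A pluggable scorer maps each 20-ms frame
   to a speech probability; probabilities are binarised at 0.7, consecutive
   speech frames merge into utterances, and utterances shorter than 250 ms
   are discarded. The bundled scorer (`energy_periodicity_vad`) combines a
   logistic intensity term with the normalised autocorrelation peak in the
   100–400 Hz lag range — deterministic and dependency-free, which is what
   the tests need; a pretrained neural detector can be plugged in through
   the same `(frame, rate) -> probability` contract. The bundled scorer is
   an energy-periodicity heuristic: it will pass loud periodic non-speech
   (a siren) and is not meant to approximate a neural detector's
   selectivity on real-world audio.
4. **Window classification.** A window counts as speech when its combined
   utterance time strictly exceeds 1.5 s (75% coverage); exactly 1.5 s is
   non-speech.

Overlapping retained windows are unioned on the recording timeline, both
for the daily speech-duration statistic and to form merged utterance
segments. The protocol does not say how the 50%-overlap duplication was
resolved before feature extraction; union semantics (each instant counted
once, features computed per merged segment) is this package's choice and
is recorded in the outputs.

## Speech features

Features are computed per merged segment and averaged (unweighted,
missing values excluded pairwise) to one row per participant-day.

**Perturbation.** On consecutive glottal periods `T_i` and cycle peak
amplitudes `A_i`: local jitter = mean|ΔT|/mean T, absolute jitter =
mean|ΔT| (ms), rap/ppq5 compare each period to its 3-/5-point local mean,
ddp = mean|Δ²T|/mean T; shimmer analogously on amplitudes with apq3/5/11
and dda. The identities ddp = 3·rap and dda = 3·apq3 hold exactly and are
asserted for all inputs. The protocol names these features without
formulas; the definitions above are the standard voice-analysis ones and
are frozen here as the single canonical set. Periods are tracked by
seeding cycle-by-cycle peak picking (on the rectified waveform, with
parabolic sub-sample refinement) from a frame-level autocorrelation F0.

**Pitch.** Frame-level F0 by normalised autocorrelation over a 60–400 Hz
search range (an adult clinical cohort; configurable); a frame is voiced
when the peak reaches 0.45. Two numerical guards matter: the finite
analysis frame biases the autocorrelation ramp towards longer lags, so the
peak position is refined on locally bias-corrected values
(`r * N/(N - lag)`); and a subharmonic at twice the period can beat the
true peak by a hair under high jitter, so the shortest-lag local maximum
within 0.07 of the global maximum wins (an octave guard). Without these
two corrections, planted-F0 recovery fails at 2% jitter (octave outliers
drag the daily mean several Hz low).

**HNR.** 10·log10(r/(1−r)) with `r` the mean bias-corrected
autocorrelation peak over voiced frames, capped at 60 dB: as periodicity
becomes perfect `r → 1` and the ratio diverges, so a ceiling keeps
near-perfect synthetic signals finite. By construction this estimator
returns approximately the additive-noise SNR on synthetic voices, which is
what the generator-oracle test asserts.

**Formants.** The segment is decimated to ~11 kHz (8th-order Butterworth
anti-alias filter at 0.85 of the target Nyquist, then downsampling) before
autocorrelation-method LPC via the Levinson-Durbin recursion, order 14,
on the whole segment's autocovariance. Roots of the prediction polynomial
with bandwidth < 700 Hz and frequency in (90 Hz, Nyquist − 200 Hz) are
formant candidates; the four lowest are reported. Decimation is essential,
not cosmetic: at the full 44.1 kHz band the formant region occupies a
fifth of the bandwidth and even a −40 dB white-noise floor dominates the
fit; order 14 (rather than the textbook 2 + 2·formants) gives the model
spare pole pairs to absorb the residual noise floor.

**Derived vocal-tract measures.** With formants `F_1..F_4` and speed of
sound c = 35,000 cm/s (configurable): mean formant (arithmetic mean),
formant dispersion (F4−F1)/3, Δf as the least-squares quarter-wave spacing
(regression of `F_i` on the odd half-multiples (2i−1)/2 through the
origin), geometric-mean formant, VTL by Fitch's weighted quarter-wave
average, VTL = c/(2Δf), and formant position pF as the mean standardised
deviation from reference means/SDs. The pF reference defaults to the
processed cohort's own formant distribution (the normalisation population
is not stated in the protocol) and is configurable to external norms.

**Syllabic nuclei.** Intensity peaks above the segment's median intensity
(offset configurable), separated by dips of ≥ 2 dB and coincident with
voiced frames, count as syllable nuclei; runs of unvoiced/low-intensity
frames ≥ 0.3 s count as pauses. Speech rate and pause rate divide by the
segment duration; phonation time is the active (voiced, above-threshold)
fraction. The median threshold implies that roughly half the frames of a
continuously voiced segment are "active" — phonation time is a relative,
threshold-dependent quantity, which is why tests bound it rather than pin
it.

## Physiology

Heart-rate runs are split wherever the inter-sample gap exceeds the 1-s
period plus a 0.5-s tolerance; a run of k 1-Hz samples spans k seconds,
and runs under 45 s are dropped (shorter segments cannot carry the
0.04–0.15 Hz low-frequency HRV component). Heart rate converts to RR by
HR×RR = 60,000; each converted 1-Hz sample is treated as one NN interval
(the protocol does not state whether beat-to-beat intervals were
reconstructed). The range filter keeps 350–1200 ms inclusive ("below 350"
and "above 1200" are removed, so the bounds themselves survive), and a
removed sample breaks the successive-difference chain, so pNN20 never
compares across an excised beat (a `bridge_removals` flag restores the
naive behaviour). SDNN uses the sample (n−1) standard deviation. Daily
values are unweighted means over segments — the protocol says only
"averaged across a day", and unweighted matches that wording most simply.

## Statistical models

All features and physiological covariates are z-scored with cohort-pooled
mean and sample SD (per-participant scaling is a configurable
alternative). The univariate screen fits, per feature,
`outcome ~ feature + age + sex + smoking + (1 | participant)` — random
intercept only, the simplest structure consistent with per-term reporting.
The daily score uses a linear mixed model with Satterthwaite
denominator-degrees-of-freedom p-values (lmerTest); the per-day
exacerbation state uses a logistic mixed model with Wald z p-values and
odds-ratio reporting. Confidence intervals are Wald at 95% on the link
scale, exponentiated for odds ratios. Non-convergence is flagged in the
result row, never silently dropped, and a confounder that is constant in
the analysed rows (possible in small synthetic cohorts) is dropped from
that fit. No multiple-testing correction is applied by default, matching
raw-star reporting; `render_reports(adjust = "BH")` is available.

The interaction design contains feature and covariate main effects, all
feature×covariate two-way products, HRV×steps covariate two-way products,
and feature×HRV×steps three-way products. Variance inflation factors are
computed per term as 1/(1−R²) of its column regressed on all other
columns (product columns included as plain columns); pruning removes the
highest-VIF term at or above 20 and recomputes until all survive, with
ties broken by removing the lexicographically last term — deterministic
and logged. The cutoff 20 is unusually permissive but is retained as the
protocol's value.

Moderation stratifies the moderator into `< M−SD`, `[M−SD, M)`,
`[M, M+SD)`, `> M+SD` (boundaries from the observed mean and SD, half-open
exactly as printed; a value exactly at M+SD belongs to no stratum, a
measure-zero event) and refits the univariate model per stratum. Strata
with fewer than 10 complete rows or 2 participants are reported as empty
rows — data, not errors.

## The synthetic-data generators

**Voices** are impulse trains filtered through a cascade of four
second-order resonators, so planted periods, amplitudes and formant
frequencies are exactly known. Cycle periods are T0·(1 + jitter/100·z)
and amplitudes 1 + shimmer/100·w with z, w standard normal clipped at ±3
(guaranteeing positive periods for perturbations < 33%); white noise is
added at a configurable SNR (default 25 dB, a realistic close-talk
sustained-phonation level); pauses carry a −60 dB noise floor. Resonator
bandwidths default to 150/200/250/300 Hz — wide enough that each cycle
rings down before the next begins, keeping per-cycle peak amplitudes
separable for the shimmer oracle. The generator records its realized
period and amplitude sequences; they are the oracle for all perturbation
features.

**Heart rate** comes from a stationary AR(1) RR process (mean 800 ms, SD
40 ms, autocorrelation 0.9 by default) with a configurable fraction of
steps forced beyond 20 ms (controlling pNN20), converted hyperbolically
and emitted at 1 Hz in full double precision (device quantisation is not
modelled, so the RR→HR→RR round trip is exact); dropout removes contiguous
gaps. The generator records its retained RR values per contiguous run —
the oracle for the HRV chain. The default wear time is one hour per day:
enough 45-s segments to exercise every code path at desk scale.

**Cohorts** draw features directly on the z-scale (i.i.d. standard
normal), build a latent daily severity from planted fixed effects,
feature×moderator interactions, a per-participant random intercept,
confounder terms and unit Gaussian noise, and generate each symptom by a
logistic link on severity — majors rarer at baseline (intercept −3) but
steeper (slope 1.3) than minors (−1.5 to −2.5, slope 0.8), so score ≥ 6
days concentrate at high severity and the exacerbation rule is exercised.
Demographics follow the cohort the protocol describes: ages uniform on
55–93, one third female, smoking never/ex/active at 11.1/66.7/22.2
percent. Per-stream missingness (speech 25%, HRV 30%, steps 10%, diary 5%
by default) is independent day by day — the protocol reports differing
per-stream availability but not a mechanism, so independence is the
neutral choice. The default planted structure (jitter fixed effect −0.3,
jitter×pNN20 interaction −0.5) reproduces the moderation phenomenon the
analysis is designed to detect: a positive jitter-score slope at low
pNN20 reversing to negative at high pNN20.

What the generators deliberately do **not** model: conversational speech
content, ambient acoustic scenes, PPG waveforms or motion artifacts,
correlated feature dynamics, or informative missingness. Passing tests
therefore demonstrate that the pipeline recovers what it claims from data
satisfying its own assumptions — not that those assumptions hold in any
clinical cohort, whose headline coefficients are not reproducible without
the original (undeposited) data.

## Problem sizes and determinism

The validation suite uses the study-scale cohort (20 participants × 100
days) for effect-recovery and type-I calibration (50 and 200 replicates),
20 seeded voices of 1.5 s for perturbation/formant recovery, and 1000-case
fuzzing for oracle equivalence — sizes chosen so the whole suite runs on a
single CPU in a few minutes while keeping the binomial bands meaningful.
All randomness flows from explicit integer seeds through `withr`; a rerun
with the same configuration and seed reproduces every table byte for byte
(asserted by hashing).
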