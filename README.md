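# copdvoice

Speech, heart-rate-variability (HRV) and activity biomarkers for free-living
monitoring of chronic obstructive pulmonary disease (COPD).

People with COPD carry smartwatches through their daily lives; the watch
records snippets of audio, 1-Hz heart rate from the optical sensor, and
daily step counts, while a morning questionnaire captures which of eight
respiratory symptoms were worse than usual. `copdvoice` implements, as a
tested and reusable R pipeline, the full analysis that links those streams
to daily COPD severity:

* **Audio segmentation** — silence gating (50-ms frames below −20 dBFS are
  discarded), 2-s analysis windows with a 1-s step, a pluggable frame-level
  voice activity detector binarised at 0.7, a 250-ms minimum utterance, and
  retention of windows whose combined utterance time exceeds 1.5 s (75% of
  the window). Daily usable speech is the union of retained windows.
* **Speech features** — 27 per participant-day: HNR, the jitter family
  (local, absolute, rap, ppq5, ddp), the shimmer family (local, apq3, apq5,
  apq11, dda), F0 statistics, formants F1–F4 by linear-prediction root
  finding, derived vocal-tract measures (Δf, formant dispersion, two VTL
  estimates, geometric-mean formant, formant position), and syllabic-nuclei
  rates (pause rate, phonation time, speech rate).
* **Physiology** — 1-Hz heart rate is segmented (runs ≥ 45 s), converted to
  RR intervals through HR × RR = 60,000, range-filtered to 350–1200 ms, and
  summarised daily as HRV(mean NN), HRV(SDNN) and HRV(pNN20); activity is
  the daily step count.
* **Outcomes** — the daily symptom score (three major symptoms at 5 points,
  five minor at 1 point) and the exacerbation rule: two or more consecutive
  days with score ≥ 6.
* **Statistics** — for each feature a univariate mixed-effects model
  `outcome ~ feature + age + sex + smoking + (1 | participant)` (linear for
  the score; logistic with odds-ratio reporting for the per-day
  exacerbation state), iterative variance-inflation-factor pruning
  (cutoff 20), multivariate models with feature×covariate two-way and
  feature×HRV×steps three-way interactions, and a moderation analysis that
  refits the univariate model within four moderator strata
  (< M−SD, [M−SD, M), [M, M+SD), > M+SD).

Because no clinical recordings ship with the package, a first-class
synthetic-data module generates every input with known ground truth:
impulse-train/resonator voices with planted jitter, shimmer, F0 and
formants; AR(1) RR processes emitted as 1-Hz heart rate with gaps; and
longitudinal cohorts whose symptom diaries arise from a latent severity
with planted fixed, random-intercept and interaction (moderation) effects.
Every stage is validated against that ground truth.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data and write their tables under `results/`. The core of it in a session:

```r
library(copdvoice)

spec <- cohort_spec(seed = 20260921L)   # 20 participants x 100 days,
                                        # planted jitter effect -0.3 and
                                        # jitter-by-pNN20 interaction -0.5
res <- run_pipeline(run_config(seed = 20260921L), spec)

render_reports(res$screen$score)[, c("variable", "report")]
#>         variable                  report
#>  absolute jitter -0.71 [-0.92, -0.49]***
#>     apq3 shimmer      0.09 [-0.13, 0.31]
#>          mean F0      0.00 [-0.21, 0.22]
#>          mean F2      0.06 [-0.16, 0.27]
```

Only the feature with a planted effect survives the screen: one more SD of
absolute jitter predicts a 0.71-point lower daily symptom score. The
moderation analysis then stratifies that slope by HRV(pNN20):

```r
render_reports(res$moderation[[1]])[, c("stratum", "report")]
#>            stratum                  report
#>        < Mean - SD      0.89 [0.18, 1.60]*
#>  [Mean - SD, Mean)      0.02 [-0.40, 0.44]
#>  [Mean, Mean + SD) -1.45 [-1.85, -1.04]***
#>        > Mean + SD -2.01 [-2.69, -1.34]***
```

The jitter–score association reverses sign across pNN20 strata — positive
when parasympathetic tone is low, negative when it is high — which is
exactly the planted moderation structure, recovered end to end.

On the signal side, `analysis/02_signal_features.R` extracts features from
synthetic WAV recordings with planted perturbations 0.5/1/2% jitter and
2/5/10% shimmer and recovers 0.63/1.24/2.16% and 2.54/5.54/10.88%.

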