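test_that("voice generation is deterministic and validates its spec", {
  v1 <- gen_voice(voice_spec(duration_s = 0.5, seed = 7))
  v2 <- gen_voice(voice_spec(duration_s = 0.5, seed = 7))
  expect_identical(v1$samples, v2$samples)
  v3 <- gen_voice(voice_spec(duration_s = 0.5, seed = 8))
  expect_false(identical(v1$samples, v3$samples))

  expect_error(voice_spec(duration_s = 0))
  expect_error(voice_spec(jitter_pct = 25))
  expect_error(voice_spec(formants_hz = c(500, 400, 2500, 3500)))
  expect_error(voice_spec(f0_hz = 600))  # above F1
})

test_that("zero-perturbation noiseless voice yields zero jitter and shimmer", {
  v <- gen_voice(voice_spec(duration_s = 1.5, jitter_pct = 0,
                            shimmer_pct = 0, noise_snr_db = Inf, seed = 1))
  tr <- track_periods(v$samples, v$sample_rate_hz)
  expect_gt(length(tr$periods_ms), 100)
  jit <- jitter_features(tr)
  shi <- shimmer_features(tr)
  expect_lt(jit$jitter, 0.05)
  expect_lt(shi$shimmer, 0.5)
})

test_that("constant-pitch voice recovers its F0 with near-zero spread", {
  v <- gen_voice(voice_spec(duration_s = 3, f0_hz = 150, jitter_pct = 0,
                            shimmer_pct = 0, noise_snr_db = Inf, seed = 2))
  ctr <- f0_contour(v$samples, v$sample_rate_hz)
  st <- f0_stats(ctr$f0_hz)
  expect_equal(st$mean_f0, 150, tolerance = 0.01)
  expect_lt(st$std_f0, 1)
})

test_that("extracted jitter matches the generator's own period list", {
  v <- gen_voice(voice_spec(duration_s = 2, jitter_pct = 1.0,
                            shimmer_pct = 0, seed = 1))
  truth <- jitter_features(
    list(periods_ms = v$ground_truth$runs[[1]]$periods_ms))
  est <- jitter_features(track_periods(v$samples, v$sample_rate_hz))
  expect_lt(abs(est$jitter - truth$jitter), 0.3)
})

test_that("heart-rate stream honours its trivial limits", {
  hr <- gen_hr_stream(mean_rr_ms = 800, sdnn_ms = 0, prob_large_delta = 0,
                      dropout_rate = 0, seed = 1, seconds_per_day = 300)
  expect_true(all(abs(hr$samples$hr_bpm - 60000 / 800) < 1e-9))
  d <- daily_hrv(hr$samples$t_s, hr$samples$hr_bpm)
  expect_equal(d$sdnn_ms, 0)
  expect_equal(d$pnn20_pct, 0)

  hr2 <- gen_hr_stream(mean_rr_ms = 1000, sdnn_ms = 20, dropout_rate = 0,
                       seed = 2, seconds_per_day = 300)
  expect_equal(mean(hr2$samples$hr_bpm), 60, tolerance = 0.05)
})

test_that("pipeline HRV equals HRV on the generator's retained RR lists", {
  hr <- gen_hr_stream(n_days = 1, sdnn_ms = 40, dropout_rate = 0.15,
                      seed = 7, seconds_per_day = 1800)
  truth_segs <- lapply(hr$ground_truth$runs_by_day[[1]], function(r) {
    if (length(r$rr_ms) >= 45) r$rr_ms else NULL
  })
  truth_segs <- truth_segs[!vapply(truth_segs, is.null, logical(1))]
  truth <- oracle_hrv(truth_segs)
  est <- daily_hrv(hr$samples$t_s, hr$samples$hr_bpm)
  expect_equal(est$mean_nn_ms, truth$mean_nn_ms, tolerance = 1e-6)
  expect_equal(est$sdnn_ms, truth$sdnn_ms, tolerance = 1e-6)
  expect_equal(est$pnn20_pct, truth$pnn20_pct, tolerance = 1e-6)
  expect_equal(est$n_segments, truth$n_segments)
})

test_that("cohort generation is deterministic and feature-score null holds", {
  c1 <- gen_cohort(smoke_cohort_spec(3))
  c2 <- gen_cohort(smoke_cohort_spec(3))
  expect_identical(c1, c2)

  null_spec <- cohort_spec(n_participants = 50, n_days = 100,
                           fixed_effects = numeric(0),
                           interaction_effects = numeric(0),
                           random_intercept_sd = 0,
                           confounder_effects = c(age = 0, sex_female = 0,
                                                  smoking_ex = 0,
                                                  smoking_active = 0),
                           missingness_rates = c(speech = 0, hrv = 0,
                                                 steps = 0, diary = 0),
                           seed = 11)
  co <- gen_cohort(null_spec)
  r <- stats::cor(co$abs_jitter, co$daily_score)
  expect_lt(abs(r), 0.1)
})

test_that("cohort generator rejects bad specs and degenerate scores", {
  expect_error(cohort_spec(n_participants = 1))
  expect_error(cohort_spec(missingness_rates = c(speech = 1.5, hrv = 0,
                                                 steps = 0, diary = 0)))
  expect_error(cohort_spec(fixed_effects = c(not_a_feature = 1)))
  # a huge positive smoking effect on a cohort where everyone smokes pushes
  # every diary day to the maximal score -> rejected as degenerate
  sat <- cohort_spec(n_participants = 5, n_days = 10,
                     fixed_effects = numeric(0),
                     interaction_effects = numeric(0),
                     confounder_effects = c(age = 0, sex_female = 0,
                                            smoking_ex = 100,
                                            smoking_active = 100),
                     missingness_rates = c(speech = 0, hrv = 0, steps = 0,
                                           diary = 0),
                     noise_sd = 0, random_intercept_sd = 0, seed = 1)
  expect_error(gen_cohort(sat), "degenerate")
  expect_s3_class(gen_cohort(smoke_cohort_spec(2)), "data.frame")
})

test_that("voice ground truth stores planted parameters for the sidecar", {
  v <- gen_voice(voice_spec(duration_s = 0.5, seed = 4,
                            syllable_pattern = list(c(0.3, 0.2))))
  gt <- v$ground_truth
  expect_s3_class(gt$spec, "voice_spec")
  expect_length(gt$runs, 1)
  expect_true(all(gt$runs[[1]]$periods_ms > 0))
  # pause is near-silent: at least 40 dB below the voiced RMS
  sr <- v$sample_rate_hz
  voiced_rms <- sqrt(mean(v$samples[1:(0.3 * sr)]^2))
  pause_rms <- sqrt(mean(v$samples[(0.35 * sr):(0.5 * sr)]^2))
  expect_gt(20 * log10(voiced_rms / pause_rms), 40)
})
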