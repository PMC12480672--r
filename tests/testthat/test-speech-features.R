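test_that("period tracking recovers a pulse train and rejects noise", {
  sr <- 44100
  x <- numeric(sr)
  x[seq(1, sr, by = round(sr / 150))] <- 1
  # smooth the pulses slightly so peak picking has structure
  x <- as.numeric(stats::filter(x, filter = c(1.6, -0.72),
                                method = "recursive"))
  tr <- track_periods(x, sr)
  expect_gt(length(tr$periods_ms), 100)
  expect_equal(stats::median(tr$periods_ms), 1000 / 150, tolerance = 0.01)

  withr::with_seed(1, {
    noise <- stats::rnorm(sr) * 0.3
  })
  trn <- track_periods(noise, sr)
  expect_length(trn$periods_ms, 0)
})

test_that("jitter formulas match hand-computed alternating-period values", {
  tr <- list(periods_ms = rep(c(10, 10.1), 10))
  jit <- jitter_features(tr)
  expect_equal(jit$absolute_jitter, 0.1)
  expect_equal(jit$jitter, 100 * 0.1 / 10.05, tolerance = 1e-9)
  expect_equal(jit$ddp_jitter, 3 * jit$rap_jitter)
  expect_true(all(is.na(unlist(jitter_features(list(periods_ms = c(1, 2)))))))
  # constant periods: all zero
  expect_true(all(unlist(jitter_features(list(periods_ms = rep(5, 20)))) == 0))
})

test_that("shimmer formulas match hand-computed alternating-amplitude values", {
  tr <- list(amplitudes = rep(c(1, 1.1), 10))
  shi <- shimmer_features(tr)
  expect_equal(shi$shimmer, 100 * 0.1 / 1.05, tolerance = 1e-9)
  expect_equal(shi$dda_shimmer, 3 * shi$apq3_shimmer)
  expect_true(all(unlist(shimmer_features(list(amplitudes = rep(2, 20)))) == 0))
})

test_that("perturbation features equal the direct-formula oracle on fuzzed tracks", {
  withr::with_seed(42, {
    for (k in 1:50) {
      tr <- random_track()
      jit <- jitter_features(tr)
      shi <- shimmer_features(tr)
      oj <- oracle_jitter(tr$periods_ms)
      os <- oracle_shimmer(tr$amplitudes)
      for (nm in names(oj)) {
        expect_equal(jit[[nm]], oj[[nm]], tolerance = 1e-9, label = nm)
      }
      for (nm in names(os)) {
        expect_equal(shi[[nm]], os[[nm]], tolerance = 1e-9, label = nm)
      }
    }
  })
})

test_that("perturbation identities and scale invariances hold", {
  withr::with_seed(3, {
    for (k in 1:10) {
      tr <- random_track()
      jit <- jitter_features(tr)
      shi <- shimmer_features(tr)
      expect_equal(jit$ddp_jitter, 3 * jit$rap_jitter, tolerance = 1e-12)
      expect_equal(shi$dda_shimmer, 3 * shi$apq3_shimmer, tolerance = 1e-12)
      # amplitude scaling leaves the jitter family and relative shimmer alone
      tr2 <- tr; tr2$amplitudes <- tr$amplitudes * 7
      expect_equal(unlist(shimmer_features(tr2)), unlist(shi),
                   tolerance = 1e-12)
      expect_equal(unlist(jitter_features(tr2)), unlist(jit),
                   tolerance = 1e-12)
    }
  })
})

test_that("HNR tracks the planted signal-to-noise ratio", {
  v10 <- gen_voice(voice_spec(duration_s = 1.5, jitter_pct = 0,
                              shimmer_pct = 0, noise_snr_db = 10, seed = 3))
  expect_equal(hnr(v10$samples, v10$sample_rate_hz), 10, tolerance = 2)

  t <- seq(0, 1, by = 1 / 44100)
  expect_equal(hnr(sin(2 * pi * 150 * t), 44100), 60)  # capped

  withr::with_seed(2, noise <- stats::rnorm(44100) * 0.2)
  expect_true(is.na(hnr(noise, 44100)))
})

test_that("daily F0 statistics pool voiced frames", {
  expect_equal(f0_stats(c(150, 150, NA, 150)),
               list(mean_f0 = 150, std_f0 = 0))
  expect_equal(f0_stats(c(rep(100, 5), rep(200, 5)))$mean_f0, 150)
  expect_true(is.na(f0_stats(c(NA, NA))$mean_f0))
})

test_that("formant estimation recovers planted resonators within 50 Hz", {
  v <- gen_voice(voice_spec(duration_s = 2, seed = 6))
  fm <- estimate_formants(v$samples, v$sample_rate_hz)
  planted <- c(500, 1500, 2500, 3500)
  est <- unlist(fm)
  expect_true(all(abs(est - planted) < 50))
  expect_true(all(diff(est) > 0))

  withr::with_seed(4, noise <- stats::rnorm(44100) * 0.2)
  expect_true(is.na(estimate_formants(noise, 44100)$f1_hz))
})

test_that("formant-derived measures match their closed forms", {
  fd <- formant_derived(list(f1_hz = 500, f2_hz = 1500, f3_hz = 2500,
                             f4_hz = 3500))
  expect_equal(fd$fdisp, 1000)
  expect_equal(fd$delta_f, 1000)
  expect_equal(fd$fitch_vtl, 17.5)
  expect_equal(fd$vtl_delta_f, 17.5)
  expect_equal(fd$mff, (500 * 1500 * 2500 * 3500)^0.25)
  expect_equal(fd$mean_formant, 2000)

  # homogeneity: scaling formants by k scales spacings by k, lengths by 1/k
  k <- 1.15
  fd2 <- formant_derived(list(f1_hz = 500 * k, f2_hz = 1500 * k,
                              f3_hz = 2500 * k, f4_hz = 3500 * k))
  expect_equal(fd2$delta_f, k * fd$delta_f)
  expect_equal(fd2$fdisp, k * fd$fdisp)
  expect_equal(fd2$mff, k * fd$mff)
  expect_equal(fd2$fitch_vtl, fd$fitch_vtl / k)
  expect_equal(fd2$vtl_delta_f, fd$vtl_delta_f / k)

  # pF of the reference set itself is zero
  ref <- list(mean = c(500, 1500, 2500, 3500), sd = c(50, 100, 150, 200))
  fd3 <- formant_derived(list(f1_hz = 500, f2_hz = 1500, f3_hz = 2500,
                              f4_hz = 3500), pf_ref = ref)
  expect_equal(fd3$pf, 0)
})

test_that("syllabic-nuclei features count constructed bursts and pauses", {
  # 4 voiced bursts with 3 internal ~0.35-s pauses over a 4-s segment
  v <- gen_voice(voice_spec(duration_s = 4, sample_rate_hz = 16000,
                            noise_snr_db = Inf,
                            syllable_pattern = list(c(0.73, 0.36),
                                                    c(0.73, 0.36),
                                                    c(0.73, 0.36),
                                                    c(0.73, 0)),
                            seed = 8))
  syl <- syllable_nuclei_features(v$samples, 16000)
  expect_equal(syl$speech_rate * 4, 4, tolerance = 0.01)   # 4 nuclei
  expect_equal(syl$pause_rate * 4, 3, tolerance = 0.01)    # 3 pauses
  # with the median-intensity threshold roughly half the frames are active
  expect_gt(syl$phonation_time, 0.35)
  expect_lt(syl$phonation_time, 0.75)

  # continuous single vowel: one nucleus over the whole duration
  v1 <- gen_voice(voice_spec(duration_s = 2, sample_rate_hz = 16000,
                             noise_snr_db = Inf, seed = 9))
  s1 <- syllable_nuclei_features(v1$samples, 16000)
  expect_equal(s1$speech_rate, 1 / 2, tolerance = 0.01)

  sil <- syllable_nuclei_features(rep(1e-6, 16000), 16000)
  expect_equal(sil$speech_rate, 0)
  expect_true(is.na(sil$phonation_time))
  expect_error(syllable_nuclei_features(numeric(0), 16000), "empty")
})

test_that("daily aggregation averages segments with pairwise deletion", {
  seg <- data.frame(jitter = c(1, 3), hnr = c(20, NA))
  d <- daily_aggregate(seg, participant = "P01", date = "d1")
  expect_equal(d$jitter, 2)
  expect_equal(d$hnr, 20)
  expect_equal(d$n_segments, 2)
  expect_null(daily_aggregate(seg[0, ]))
  one <- daily_aggregate(seg[1, , drop = FALSE])
  expect_equal(one$jitter, 1)
})

test_that("parameter recovery holds across planted perturbation levels", {
  grid <- expand.grid(jit = c(0.5, 1, 2), shi = c(2, 5, 10))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    v <- gen_voice(voice_spec(duration_s = 1.5, jitter_pct = grid$jit[i],
                              shimmer_pct = grid$shi[i], seed = 100 + i))
    tr <- track_periods(v$samples, v$sample_rate_hz)
    truth <- v$ground_truth$runs[[1]]
    c(jit_true = oracle_jitter(truth$periods_ms)$jitter,
      jit_est = jitter_features(tr)$jitter,
      shi_true = oracle_shimmer(truth$amplitudes)$shimmer,
      shi_est = shimmer_features(tr)$shimmer)
  })
  res <- do.call(rbind, res)
  expect_true(all(abs(res[, "jit_est"] - res[, "jit_true"]) <= 0.3))
  expect_true(all(abs(res[, "shi_est"] - res[, "shi_true"]) <= 1.5))
  expect_gt(stats::cor(res[, "jit_est"], res[, "jit_true"]), 0.95)
  expect_gt(stats::cor(res[, "shi_est"], res[, "shi_true"]), 0.95)
})
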