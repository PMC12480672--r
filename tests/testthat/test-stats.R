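test_that("z-scoring standardises with the sample SD and flags constants", {
  df <- data.frame(x = c(1, 2, 3), y = c(5, 5, 5), z = c(1, NA, 3))
  out <- zscore(df, "x")
  expect_equal(out$x, c(-1, 0, 1))
  expect_error(zscore(df, "y"), "y")
  outz <- zscore(df, "z")
  expect_true(is.na(outz$z[2]))
  # idempotent up to re-estimation
  expect_equal(zscore(out, "x")$x, out$x)
})

test_that("VIF values and pruning behave on canonical designs", {
  withr::with_seed(10, {
    ortho <- as.data.frame(qr.Q(qr(matrix(stats::rnorm(400), 100))))
    names(ortho) <- c("a", "b", "c", "d")
  })
  v <- vif_values(ortho, names(ortho))
  expect_true(all(abs(v - 1) < 0.2))
  pr <- vif_prune(ortho, names(ortho))
  expect_equal(sort(pr$retained), c("a", "b", "c", "d"))
  expect_equal(nrow(pr$removed), 0)

  dup <- data.frame(a = stats::rnorm(50))
  dup$b <- dup$a
  dup$c <- stats::rnorm(50)
  pr2 <- vif_prune(dup, c("a", "b", "c"))
  expect_equal(nrow(pr2$removed), 1)
  expect_equal(pr2$removed$term, "b")   # lexicographically last of the tie
  expect_true(all(vif_values(dup, pr2$retained) < 20))
})

test_that("VIF pruning matches the brute-force greedy oracle", {
  withr::with_seed(77, {
    for (k in 1:12) {
      p <- sample(4:8, 1)
      n <- 60
      X <- matrix(stats::rnorm(n * p), n)
      # manufacture collinearity: one or two near-sums of other columns
      X[, p] <- X[, 1] + X[, 2] + stats::rnorm(n, sd = 0.05)
      if (p >= 6) X[, p - 1] <- X[, 3] - X[, 4] + stats::rnorm(n, sd = 0.05)
      df <- as.data.frame(X)
      names(df) <- sprintf("t%02d", seq_len(p))
      got <- vif_prune(df, names(df))$retained
      want <- oracle_vif_prune(df, names(df))
      expect_equal(sort(got), sort(want))
    }
  })
})

test_that("the interaction design reproduces the published term structure", {
  d <- build_interaction_design("abs_jitter")
  expect_true(all(c("abs_jitter", "hrv_pnn20", "pa_steps",
                    "abs_jitter:hrv_pnn20", "abs_jitter:pa_steps",
                    "hrv_pnn20:pa_steps",
                    "abs_jitter:hrv_pnn20:pa_steps") %in% d))
  # 5 mains + 3 covariate two-ways + 4 feature two-ways + 3 three-ways
  expect_length(d, 15)
  # without the covariate-by-steps terms: the plain enumeration
  d0 <- build_interaction_design("abs_jitter",
                                 include_covariate_interactions = FALSE)
  expect_length(d0, 12)
  # degenerate: no features
  dn <- build_interaction_design(character(0))
  expect_length(dn, 7)
  expect_true(all(grepl("^[a-z_0-9]+(:[a-z_0-9]+){0,2}$", d)))
})

test_that("significance stars and report formatting follow the tiers", {
  expect_equal(significance_stars(c(0.049, 0.0009, 0.02, 0.2, 0.005)),
               c("*", "***", "*", "", "**"))
  res <- rbind(
    data.frame(term = "abs_jitter", estimate = 0.5, ci_low = 0.2,
               ci_high = 0.8, p_value = 0.049, stars = "*", scale = "beta",
               converged = TRUE, n_obs = 10L, stratum = NA),
    data.frame(term = "abs_jitter:hrv_pnn20", estimate = 1.5, ci_low = 1.1,
               ci_high = 2.0, p_value = 0.0009, stars = "***", scale = "or",
               converged = TRUE, n_obs = 10L, stratum = NA))
  rep <- render_reports(res)
  expect_match(rep$report[1], "0.50 \\[0.20, 0.80\\]\\*$")
  expect_match(rep$report[2], "\\*\\*\\*$")
  expect_equal(rep$variable[2], "absolute jitter:HRV(pNN20)")
  # odds-ratio rows keep positive CI bounds on the reporting scale
  expect_gt(res$ci_low[2], 0)
})

test_that("the univariate screen recovers a planted effect and its sign", {
  spec <- cohort_spec(fixed_effects = c(abs_jitter = -0.4),
                      interaction_effects = numeric(0), seed = 31)
  tab <- zscore(gen_cohort(spec), c("abs_jitter"))
  r <- fit_univariate(tab, "abs_jitter", "score")
  expect_lt(r$estimate, 0)
  expect_lt(r$ci_high, 0)
  expect_equal(r$stars, "***")

  # estimates are invariant to row order
  perm <- tab[withr::with_seed(1, sample(nrow(tab))), ]
  r2 <- fit_univariate(perm, "abs_jitter", "score")
  expect_equal(r2$estimate, r$estimate, tolerance = 1e-6)
})

test_that("the logistic screen reports odds ratios with valid intervals", {
  spec <- cohort_spec(fixed_effects = c(abs_jitter = 0.5),
                      interaction_effects = numeric(0), seed = 32)
  tab <- zscore(gen_cohort(spec), "abs_jitter")
  r <- fit_univariate(tab, "abs_jitter", "exacerbation")
  expect_equal(r$scale, "or")
  expect_gt(r$estimate, 1)          # positive effect raises the odds
  expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
  expect_gt(r$ci_low, 0)
})

test_that("a planted interaction is recovered by the multivariate model", {
  hits <- 0L
  for (s in 1:8) {
    spec <- cohort_spec(fixed_effects = c(abs_jitter = -0.3),
                        interaction_effects = c("abs_jitter:hrv_pnn20" = 0.5),
                        missingness_rates = c(speech = 0, hrv = 0, steps = 0,
                                              diary = 0),
                        seed = 400 + s)
    tab <- zscore(gen_cohort(spec), c("abs_jitter", "hrv_pnn20", "hrv_sdnn",
                                      "hrv_mean_nn", "pa_steps"))
    terms <- c("abs_jitter", "hrv_pnn20", "abs_jitter:hrv_pnn20")
    res <- fit_multivariate(tab, terms, "score")
    row <- res[res$term == "abs_jitter:hrv_pnn20", ]
    if (row$ci_low > 0) hits <- hits + 1L
  }
  expect_gte(hits, 7L)
})

test_that("permuting participant-day structure destroys planted recovery", {
  spec <- cohort_spec(fixed_effects = c(abs_jitter = -0.4),
                      interaction_effects = numeric(0),
                      missingness_rates = c(speech = 0, hrv = 0, steps = 0,
                                            diary = 0), seed = 55)
  tab <- zscore(gen_cohort(spec), "abs_jitter")
  tab$abs_jitter <- withr::with_seed(2, sample(tab$abs_jitter))
  r <- fit_univariate(tab, "abs_jitter", "score")
  expect_gt(r$p_value, 0.01)
})

test_that("an independent confounder barely moves the feature estimate", {
  spec <- cohort_spec(fixed_effects = c(abs_jitter = -0.4),
                      interaction_effects = numeric(0),
                      confounder_effects = c(age = 0, sex_female = 0,
                                             smoking_ex = 0,
                                             smoking_active = 0),
                      missingness_rates = c(speech = 0, hrv = 0, steps = 0,
                                            diary = 0), seed = 66)
  tab <- zscore(gen_cohort(spec), "abs_jitter")
  with_conf <- fit_univariate(tab, "abs_jitter", "score")
  bare <- copdvoice:::fit_mixed(tab, "abs_jitter", "score",
                                confounders = FALSE)
  se <- (with_conf$ci_high - with_conf$ci_low) / (2 * stats::qnorm(0.975))
  expect_lt(abs(with_conf$estimate - bare$estimate), 2 * se)
})

test_that("moderation strata occupy the normal-quantile proportions", {
  withr::with_seed(8, m <- stats::rnorm(100000))
  mu <- mean(m); s <- stats::sd(m)
  occ <- c(mean(m < mu - s), mean(m >= mu - s & m < mu),
           mean(m >= mu & m < mu + s), mean(m > mu + s))
  expect_equal(occ, c(0.159, 0.341, 0.341, 0.159), tolerance = 0.02)
})

test_that("stratified slopes flip sign under a planted moderation", {
  spec <- cohort_spec(n_participants = 30, n_days = 120,
                      fixed_effects = c(abs_jitter = -0.3),
                      interaction_effects = c("abs_jitter:hrv_pnn20" = 0.5),
                      missingness_rates = c(speech = 0, hrv = 0, steps = 0,
                                            diary = 0), seed = 77)
  tab <- zscore(gen_cohort(spec), c("abs_jitter", "hrv_pnn20"))
  md <- moderation_stratify(tab, "abs_jitter", "hrv_pnn20", "score")
  occupied <- md[!is.na(md$estimate), ]
  expect_gte(nrow(occupied), 2)
  lo <- occupied$estimate[1]
  hi <- occupied$estimate[nrow(occupied)]
  # positive interaction: negative slope at low pNN20, positive at high
  expect_lt(lo, 0)
  expect_gt(hi, 0)
})

test_that("empty strata are reported as data, not errors", {
  spec <- smoke_cohort_spec(12)
  tab <- zscore(gen_cohort(spec), c("abs_jitter", "hrv_pnn20"))
  # a moderator whose extreme stratum has almost no rows
  tab$sparse_mod <- pmin(tab$hrv_pnn20, 1)
  md <- moderation_stratify(tab, "abs_jitter", "sparse_mod", "score",
                            min_rows = 1e6)
  expect_true(all(is.na(md$estimate)))
  expect_equal(md$stratum, c("< Mean - SD", "[Mean - SD, Mean)",
                             "[Mean, Mean + SD)", "> Mean + SD"))
})
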