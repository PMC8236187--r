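test_that("two-sample t-test matches the pooled-variance closed form", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- two_sample_t(a, b, labels = c("iPSC", "neuron"), var_equal = TRUE)
  oracle <- pooled_t_oracle(a, b)
  expect_equal(res$statistic, oracle$t, tolerance = 1e-12)
  expect_equal(res$df, oracle$df)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
  expect_identical(res$delta_mean, 3)
  expect_identical(res$contrast, "neuron-iPSC")
})

test_that("t-test conventions: identical groups, degenerate variance, scale invariance", {
  g <- c(70, 75, 80)
  same <- two_sample_t(g, g)
  expect_identical(same$delta_mean, 0)
  expect_equal(same$p_value, 1)

  const <- two_sample_t(c(5, 5), c(5, 5))
  expect_true(const$degenerate)
  expect_identical(const$p_value, 1)

  set.seed(50)
  a <- rnorm(8, 70, 5); b <- rnorm(10, 80, 5)
  p1 <- two_sample_t(a, b)$p_value
  p2 <- two_sample_t(3 * a, 3 * b)$p_value
  expect_equal(p1, p2, tolerance = 1e-12)

  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
})

test_that("Tukey HSD adjusted p-values match the studentized-range oracle", {
  # balanced 3 x 5 fixture
  withr::with_seed(51, {
    stage <- rep(c("iPSC", "NPC", "neuron"), each = 5)
    y <- c(rnorm(5, 75, 5), rnorm(5, 80, 5), rnorm(5, 85, 5))
  })
  res <- anova_tukey(y, stage)
  oracle <- tukey_oracle(y, stage)
  expect_equal(nrow(res), 3)
  for (k in seq_len(nrow(res))) {
    expect_equal(res$p_value[k], unname(oracle[res$contrast[k]]),
                 tolerance = 1e-9)
  }

  # unbalanced groups exercise the Tukey-Kramer standard errors
  withr::with_seed(52, {
    stage2 <- rep(c("iPSC", "NPC", "neuron"), c(8, 3, 6))
    y2 <- rnorm(17, rep(c(74, 79, 84), c(8, 3, 6)), 6)
  })
  res2 <- anova_tukey(y2, stage2)
  oracle2 <- tukey_oracle(y2, stage2)
  for (k in seq_len(nrow(res2))) {
    expect_equal(res2$p_value[k], unname(oracle2[res2$contrast[k]]),
                 tolerance = 1e-9)
  }
})

test_that("Tukey adjustment is conservative relative to unadjusted pairwise t-tests", {
  for (seed in 1:5) {
    withr::with_seed(60 + seed, {
      stage <- rep(c("a", "b", "c"), each = 6)
      y <- rnorm(18, rep(c(70, 76, 82), each = 6), 8)
    })
    res <- anova_tukey(y, stage)
    # unadjusted comparison on the same pooled error (Fisher LSD)
    mse <- sum(tapply(y, stage, function(v) sum((v - mean(v))^2))) / 15
    for (k in seq_len(nrow(res))) {
      gs <- strsplit(res$contrast[k], "-")[[1]]
      tstat <- abs(mean(y[stage == gs[1]]) - mean(y[stage == gs[2]])) /
        sqrt(mse * (1 / 6 + 1 / 6))
      praw <- 2 * pt(-tstat, 15)
      expect_gte(res$p_value[k] + 1e-12, praw)
    }
  }
})

test_that("anova_tukey identity case and input validation", {
  stage <- rep(c("a", "b", "c"), each = 4)
  y <- rep(c(1, 2, 3, 4), 3)   # identical distribution in each group
  res <- anova_tukey(y, stage)
  expect_equal(attr(res, "anova_F"), 0, tolerance = 1e-12)
  expect_true(all(res$p_value > 0.999))
  expect_error(anova_tukey(y[1:8], stage[1:8]), "exactly 3")
  expect_error(anova_tukey(c(y, 1), c(stage[1:11], "c", "d")), "exactly 3")
})

test_that("mixed-model meta-analysis reduces to OLS when dataset variance is zero", {
  # identical replicate datasets: between-dataset variance is estimated
  # exactly at the zero boundary, so GLS collapses to OLS
  one <- simulate_cellstage_datasets(
    cellstage_sim_spec(n_datasets = 1, dataset_sd = 0, residual_sd = 7,
                       design = list(d = c(iPSC = 6, NPC = 2, neuron = 10)),
                       seed = 5))
  tab <- do.call(rbind, lapply(1:4, function(i) {
    b <- one
    b$dataset_id <- paste0("ds", i)
    b$sample_id <- paste0(b$sample_id, "_", i)
    b
  }))
  fit <- stage_meta_analysis(tab)
  expect_equal(fit$random_intercept_sd, 0, tolerance = 1e-8)
  ols <- lm(predicted_age_dpc ~ factor(group, levels = c("iPSC", "NPC", "neuron")),
            data = tab)
  expect_equal(fit$fixed_effects$estimate, unname(coef(ols)), tolerance = 1e-6)
  expect_equal(fit$method, "reml_mixed")
})

test_that("mixed-model estimates are invariant to dataset relabeling", {
  tab <- simulate_cellstage_datasets(cellstage_sim_spec(seed = 6))
  fit1 <- stage_meta_analysis(tab)
  tab2 <- tab
  tab2$dataset_id <- chartr("12345", "54321", tab2$dataset_id)
  fit2 <- stage_meta_analysis(tab2)
  expect_equal(fit1$fixed_effects$estimate, fit2$fixed_effects$estimate,
               tolerance = 1e-8)
  expect_equal(fit1$random_intercept_sd, fit2$random_intercept_sd,
               tolerance = 1e-8)
})

test_that("permuting stage labels within datasets nulls the stage effects", {
  ests <- vapply(1:40, function(i) {
    tab <- simulate_cellstage_datasets(cellstage_sim_spec(seed = 100 + i))
    withr::with_seed(i, {
      for (ds in unique(tab$dataset_id)) {
        idx <- tab$dataset_id == ds
        tab$group[idx] <- sample(tab$group[idx])
      }
    })
    fit <- stage_meta_analysis(tab)
    fit$fixed_effects$estimate[fit$fixed_effects$term == "stageneuron"]
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests)), 3 * se + 0.5)
})

test_that("single-dataset input falls back to OLS with a warning", {
  tab <- simulate_cellstage_datasets(
    cellstage_sim_spec(n_datasets = 1,
                       design = list(ds1 = c(iPSC = 10, NPC = 5, neuron = 10)),
                       seed = 9))
  expect_warning(fit <- stage_meta_analysis(tab), "single dataset")
  expect_equal(fit$method, "ols_fallback")
  expect_true(is.na(fit$random_intercept_sd))
})
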