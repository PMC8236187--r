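test_that("linear predictor arithmetic and unit conversion are exact", {
  clk <- clock_model("toy", intercept = 100, coefficients = c(cgA = 50))
  b <- tiny_betas(matrix(0.5, 1, 1), probes = "cgA", samples = "s1")
  pred <- predict_age(b, clk)
  expect_identical(pred$raw_score, 125)
  expect_identical(pred$predicted_age_dpc, 125)
  expect_identical(pred$probe_coverage, 1)

  # age-transformed clock: raw score 0 -> adult_age years -> dpc
  mtc <- clock_model("mtc_like", intercept = -0.25, coefficients = c(cgA = 0.5),
                     output_unit = "years", transform = "horvath_log_linear")
  pred2 <- predict_age(b, mtc)
  expect_identical(pred2$raw_score, 0)
  expect_identical(pred2$predicted_age_native, 20)
  expect_identical(pred2$predicted_age_dpc, 20 * 365 + 280)

  # gestational-week clocks convert as weeks * 7
  gac <- clock_model("gac_like", intercept = 10, coefficients = c(cgA = 8),
                     output_unit = "weeks_ga")
  expect_identical(predict_age(b, gac)$predicted_age_dpc, 14 * 7)
})

test_that("prediction is linear in betas for identity-transform clocks", {
  set.seed(12)
  clk <- clock_model("lin", 90, setNames(rnorm(5, 0, 30), paste0("cg", 1:5)))
  b1 <- tiny_betas(matrix(runif(5), 5, 1), probes = paste0("cg", 1:5), samples = "a")
  b2 <- tiny_betas(matrix(runif(5), 5, 1), probes = paste0("cg", 1:5), samples = "b")
  avg <- tiny_betas((b1 + b2) / 2, probes = paste0("cg", 1:5), samples = "m")
  p1 <- predict_age(b1, clk)$predicted_age_dpc
  p2 <- predict_age(b2, clk)$predicted_age_dpc
  pm <- predict_age(avg, clk)$predicted_age_dpc
  expect_equal(pm, (p1 + p2) / 2, tolerance = 1e-12)
})

test_that("missing-probe policies behave as documented", {
  clk <- clock_model("c", 100, c(cgA = 50, cgB = -20))
  full <- tiny_betas(matrix(c(0.5, 0.25), 2, 1), probes = c("cgA", "cgB"),
                     samples = "s1")
  partial <- full["cgA", , drop = FALSE]

  # with nothing missing, drop equals fail exactly
  expect_identical(predict_age(full, clk, "drop")$predicted_age_dpc,
                   predict_age(full, clk, "fail")$predicted_age_dpc)

  expect_error(predict_age(partial, clk, "fail"), "absent")
  expect_warning(pd <- predict_age(partial, clk, "drop"), "coverage")
  expect_identical(pd$predicted_age_dpc, 100 + 50 * 0.5)
  expect_identical(pd$probe_coverage, 0.5)
  expect_true(pd$low_coverage)

  expect_warning(pm <- predict_age(partial, clk, "mean_impute"), "coverage")
  expect_identical(pm$predicted_age_dpc, 100 + 50 * 0.5 - 20 * 0.5)
  expect_warning(
    pr <- predict_age(partial, clk, "mean_impute",
                      reference_means = c(cgB = 0.25)),
    "coverage")
  expect_identical(pr$predicted_age_dpc, 100 + 50 * 0.5 - 20 * 0.25)

  none <- tiny_betas(matrix(0.5, 1, 1), probes = "cgZ", samples = "s1")
  expect_error(predict_age(none, clk, "drop"), "none of the clock's probes")
})

test_that("a near-unpenalized clock on noiseless data reproduces the OLS fit", {
  withr::with_seed(30, {
    n <- 60; p <- 5
    X <- matrix(runif(n * p, 0.2, 0.8), p, n,
                dimnames = list(paste0("cg", 1:p), paste0("S", 1:n)))
    coefs <- c(40, -25, 60, 10, -15)
    y <- 100 + drop(t(X) %*% coefs)   # exact linear signal, no noise
  })
  path <- elastic_net_path(X, y, alpha = 0.5, lambda = c(1, 0.1, 1e-6),
                           standardize = FALSE)
  clk <- clock_model("ols_limit", path$intercepts[3],
                     path$coefficients[, 3][path$coefficients[, 3] != 0])
  pred <- predict_age(X, clk)
  ols <- lm(y ~ t(X))
  expect_equal(pred$predicted_age_dpc, unname(fitted(ols)), tolerance = 1e-3)
  expect_equal(pred$predicted_age_dpc, unname(y), tolerance = 1e-3)
})

test_that("out-of-training-range predictions are flagged, not clipped", {
  clk <- clock_model("rng", 100, c(cgA = 200),
                     training = list(age_range_dpc = c(37, 185)))
  b <- tiny_betas(matrix(c(0.1, 0.9), 1, 2), probes = "cgA",
                  samples = c("young", "old"))
  pred <- predict_age(b, clk)
  expect_identical(pred$predicted_age_dpc, c(120, 280))
  expect_identical(pred$out_of_training_range, c(FALSE, TRUE))
})

test_that("batch prediction produces all dataset x clock blocks and isolates failures", {
  set.seed(31)
  mk <- function(ids, probes) {
    b <- tiny_betas(matrix(runif(length(probes) * length(ids)),
                           length(probes), length(ids)),
                    probes = probes, samples = ids)
    sheet <- sample_sheet(ids, runif(length(ids), 50, 150), "dpc",
                          dataset_id = ids[1], group = "iPSC")
    list(betas = b, sheet = sheet)
  }
  ds <- list(d1 = mk(paste0("a", 1:3), c("cgA", "cgB")),
             d2 = mk(paste0("b", 1:4), c("cgA", "cgB")))
  clocks <- list(clock_model("c1", 100, c(cgA = 10)),
                 clock_model("c2", 80, c(cgA = 5, cgB = 5)))
  tab <- batch_predict(ds, clocks)
  expect_equal(nrow(tab), (3 + 4) * 2)
  expect_setequal(unique(tab$clock_name), c("c1", "c2"))

  # a clock whose probes are absent fails on both datasets but the other
  # clock's blocks survive
  clocks2 <- c(clocks, list(clock_model("broken", 0, c(cgZ = 1))))
  w <- capture_warnings(tab2 <- batch_predict(ds, clocks2))
  expect_match(w, "failed on dataset", all = TRUE)
  expect_length(w, 2)
  expect_equal(nrow(tab2), (3 + 4) * 2)

  # round trip through the table writer
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(tab, path)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$predicted_age_dpc, tab$predicted_age_dpc)
})
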