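test_that("pfilter applies the strict >1% rules sample-first and is idempotent", {
  # 100 probes x 4 samples: S1 has 2 failing probes (2% > 1% -> excluded),
  # S2 exactly 1 (1%, not > 1% -> retained)
  detp <- detp_fixture(100, 4)
  detp[1:2, 1] <- 0.2
  detp[1, 2] <- 0.2
  res <- pfilter(detp)
  expect_identical(res$samples, c("S2", "S3", "S4"))
  # probe stats computed on retained samples: cg0001 fails in 1/3 of
  # retained samples (> 1%) -> excluded
  expect_false("cg0001" %in% res$probes)
  expect_true("cg0002" %in% res$probes)
  expect_equal(res$report$counts_after, c(probes = 99, samples = 3))

  # idempotence: re-running on the filtered matrix removes nothing
  res2 <- pfilter(detp[res$probes, res$samples])
  expect_identical(res2$samples, res$samples)
  expect_identical(res2$probes, res$probes)
})

test_that("pfilter identity case and failure modes", {
  clean <- detp_fixture(50, 200)
  res <- pfilter(clean)
  expect_equal(nrow(res$report$samples_excluded), 0)
  expect_equal(nrow(res$report$probes_excluded), 0)
  expect_error(pfilter(matrix(numeric(0), 0, 0)), "non-empty")
  allbad <- detp_fixture(10, 3, failures = cbind(rep(1:10, 3), rep(1:3, each = 10)))
  err <- tryCatch(pfilter(allbad), error = function(e) e)
  expect_match(conditionMessage(err), "all samples removed")
  expect_s3_class(err$report, "qc_report")
})

test_that("blacklist exclusion removes flagged probes and warns on unannotated", {
  annot <- probe_annotation(paste0("cg", 1:5), rep("II", 5),
                            snp_affected = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                            cross_hybridizing = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  res <- exclude_blacklisted(paste0("cg", 1:5), annot)
  expect_identical(res$probes, paste0("cg", 3:5))
  expect_setequal(res$report$probes_excluded$reason, c("snp", "cross_hybridizing"))

  res2 <- exclude_blacklisted(paste0("cg", 3:5), annot)
  expect_identical(res2$probes, paste0("cg", 3:5))

  expect_warning(res3 <- exclude_blacklisted(c("cg3", "cgX"), annot),
                 "absent from annotation")
  expect_identical(res3$probes, c("cg3", "cgX"))
  expect_equal(res3$report$n_unannotated_retained, 1)
})

test_that("beta quantile normalization matches the mean-order-statistic definition", {
  b <- tiny_betas(cbind(c(0.1, 0.5, 0.9), c(0.2, 0.6, 0.8)))
  annot <- all_type2_annot(rownames(b))
  out <- beta_quantile_normalize(b, annot)
  expect_equal(unname(out[, 1]), c(0.15, 0.55, 0.85), tolerance = 1e-12)
  expect_equal(unname(out[, 2]), c(0.15, 0.55, 0.85), tolerance = 1e-12)

  # identical columns are a fixed point
  b2 <- tiny_betas(cbind(c(0.2, 0.4, 0.7), c(0.2, 0.4, 0.7)))
  expect_equal(beta_quantile_normalize(b2, all_type2_annot(rownames(b2))), b2,
               tolerance = 1e-12)

  expect_warning(one <- beta_quantile_normalize(b[, 1, drop = FALSE], annot),
                 "single sample")
  expect_equal(one, b[, 1, drop = FALSE])
})

test_that("within-probe-type value multisets agree across samples after QN", {
  set.seed(21)
  b <- tiny_betas(matrix(runif(400), 100, 4))
  annot <- probe_annotation(rownames(b),
                            design_type = rep(c("I", "II"), 50))
  out <- beta_quantile_normalize(b, annot)
  for (tp in c("I", "II")) {
    sel <- annot$design_type == tp
    sorted <- apply(out[sel, ], 2, sort)
    for (j in 2:4) expect_equal(sorted[, j], sorted[, 1], tolerance = 1e-12)
  }
})

test_that("dasen normalization: fixed points, degenerate type, beta arithmetic", {
  probes <- sprintf("cg%02d", 1:20)
  annot <- probe_annotation(probes, rep(c("I", "II"), each = 10))
  set.seed(5)
  M1 <- matrix(rexp(20, 1 / 3000), 20, 1)
  U1 <- matrix(rexp(20, 1 / 3000), 20, 1)
  M <- cbind(M1, M1); U <- cbind(U1, U1)
  dimnames(M) <- dimnames(U) <- list(probes, c("S1", "S2"))
  detp <- detp_fixture(20, 2); dimnames(detp) <- dimnames(M)
  iset <- intensity_set(M, U, detp)
  out <- dasen_normalize(iset, annot)
  # identical samples stay identical, and QN makes sorted values equal by type
  expect_equal(out[, 1], out[, 2], tolerance = 1e-12)
  expect_true(all(out >= 0 & out <= 1))

  # all Type II, two identical samples: betas reduce to M/(M+U+100) directly
  annot2 <- all_type2_annot(probes)
  M900 <- matrix(900, 20, 2, dimnames = dimnames(M))
  U0 <- matrix(0, 20, 2, dimnames = dimnames(M))
  out2 <- dasen_normalize(intensity_set(M900, U0, detp), annot2)
  expect_equal(unname(out2[1, 1]), 900 / (900 + 0 + 100), tolerance = 1e-12)

  # unknown design type is an error
  annot3 <- probe_annotation(probes[-1], rep("II", 19))
  expect_error(dasen_normalize(iset, annot3), "design type unknown")
})

test_that("dasen with a single probe type equals plain per-type quantile normalization", {
  probes <- sprintf("cg%02d", 1:30)
  annot <- all_type2_annot(probes)
  set.seed(6)
  M <- matrix(rexp(90, 1 / 2000), 30, 3, dimnames = list(probes, paste0("S", 1:3)))
  U <- matrix(rexp(90, 1 / 2000), 30, 3, dimnames = dimnames(M))
  detp <- detp_fixture(30, 3); dimnames(detp) <- dimnames(M)
  out <- dasen_normalize(intensity_set(M, U, detp), annot)
  Mq <- limma::normalizeQuantiles(M, ties = TRUE)
  Uq <- limma::normalizeQuantiles(U, ties = TRUE)
  expect_equal(unname(out), unname(Mq / (Mq + Uq + 100)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("intersect_probes keeps fully observed shared probes in first-matrix order", {
  a <- tiny_betas(matrix(0.5, 3, 2), probes = c("A", "B", "C"))
  b <- tiny_betas(matrix(0.5, 3, 2), probes = c("B", "C", "D"))
  res <- intersect_probes(list(a, b))
  expect_identical(res$probes, c("B", "C"))
  expect_identical(rownames(res$matrices[[2]]), c("B", "C"))

  # probes with any missing value are not "available in all samples"
  a2 <- a; a2["B", 1] <- NA
  expect_identical(intersect_probes(list(a2, b))$probes, "C")

  # invariant to input order up to row ordering
  res_rev <- intersect_probes(list(b, a))
  expect_setequal(res_rev$probes, res$probes)

  expect_identical(intersect_probes(list(a))$probes, c("A", "B", "C"))
  d <- tiny_betas(matrix(0.5, 2, 2), probes = c("X", "Y"))
  expect_error(intersect_probes(list(a, d)), "no probes shared")
})

test_that("stratified split honours round-half-up counts per dataset and seed determinism", {
  sheet <- sample_sheet(sprintf("s%03d", 1:100), 100, "dpc",
                        dataset_id = rep(c("d1", "d2"), c(60, 40)))
  sp <- stratified_split(sheet, 0.75, seed = 42)
  tab <- table(sp$dataset_id, sp$assignment)
  expect_equal(unname(tab["d1", "train"]), 45)
  expect_equal(unname(tab["d2", "train"]), 30)
  expect_equal(unname(tab["d1", "test"]), 15)
  expect_equal(unname(tab["d2", "test"]), 10)

  sp2 <- stratified_split(sheet, 0.75, seed = 42)
  expect_identical(sp$assignment, sp2$assignment)

  sheet4 <- sample_sheet(paste0("s", 1:4), 100, "dpc")
  tab4 <- table(stratified_split(sheet4, 0.75, seed = 1)$assignment)
  expect_equal(unname(tab4["train"]), 3)

  sheet1 <- sample_sheet(paste0("s", 1:5), 100, "dpc",
                         dataset_id = c("d1", rep("d2", 4)))
  expect_warning(sp1 <- stratified_split(sheet1, 0.75, seed = 1),
                 "size 1")
  expect_identical(sp1$assignment[sp1$dataset_id == "d1"], "train")
})
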