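#' Detection p-value filtering of samples and probes
#'
#' Two-pass filter on a detection p-value matrix: first a sample is
#' removed iff strictly more than `sample_frac_thresh` of its probes have
#' p > `p_thresh`; then, among the retained samples, a probe is removed
#' iff strictly more than `probe_frac_thresh` of samples have
#' p > `p_thresh`. The defaults implement the usual "> 1% of probes /
#' samples failing at p > 0.05" rule. The filter is idempotent.
#'
#' @param det_p probes x samples matrix of detection p-values.
#' @param sample_frac_thresh fraction of failing probes above which a
#'   sample is excluded (strict inequality).
#' @param probe_frac_thresh fraction of failing samples above which a
#'   probe is excluded (strict inequality).
#' @param p_thresh detection p-value above which a call fails.
#' @return list with `samples` (retained sample ids), `probes` (retained
#'   probe ids) and `report` (a `qc_report`).
#' @export
pfilter <- function(det_p, sample_frac_thresh = 0.01,
                    probe_frac_thresh = 0.01, p_thresh = 0.05) {
  if (!is.matrix(det_p) || nrow(det_p) == 0 || ncol(det_p) == 0) {
    stop("det_p must be a non-empty probes x samples matrix")
  }
  if (any(det_p < 0 | det_p > 1, na.rm = TRUE)) stop("detection p-values must lie in [0,1]")
  fail <- det_p > p_thresh
  fail[is.na(fail)] <- TRUE

  sample_fail_frac <- colMeans(fail)
  bad_samples <- sample_fail_frac > sample_frac_thresh
  kept_samples <- colnames(det_p)[!bad_samples]

  report <- list(
    thresholds = list(sample_frac_thresh = sample_frac_thresh,
                      probe_frac_thresh = probe_frac_thresh,
                      p_thresh = p_thresh),
    counts_before = c(probes = nrow(det_p), samples = ncol(det_p)),
    samples_excluded = data.frame(
      sample_id = colnames(det_p)[bad_samples],
      reason = rep("detection_p", sum(bad_samples)),
      fail_fraction = unname(sample_fail_frac[bad_samples]),
      stringsAsFactors = FALSE, row.names = NULL))
  class(report) <- "qc_report"

  if (length(kept_samples) == 0) {
    err <- simpleError("all samples removed by detection p-value filter")
    err$report <- report
    stop(err)
  }

  probe_fail_frac <- rowMeans(fail[, !bad_samples, drop = FALSE])
  bad_probes <- probe_fail_frac > probe_frac_thresh
  kept_probes <- rownames(det_p)[!bad_probes]

  report$probes_excluded <- data.frame(
    probe_id = rownames(det_p)[bad_probes],
    reason = rep("detection_p", sum(bad_probes)),
    fail_fraction = unname(probe_fail_frac[bad_probes]),
    stringsAsFactors = FALSE, row.names = NULL)
  report$counts_after <- c(probes = length(kept_probes),
                           samples = length(kept_samples))
  list(samples = kept_samples, probes = kept_probes, report = report)
}

#' Remove blacklisted probes
#'
#' Drops probes flagged as SNP-affected or cross-hybridizing in the
#' annotation. Probes missing from the annotation are retained with a
#' warning (and counted in the report).
#'
#' @param probes character vector of probe ids.
#' @param annot a [probe_annotation()].
#' @return list with `probes` (retained ids) and `report` (exclusions with
#'   per-probe reasons and the count of unannotated probes).
#' @export
exclude_blacklisted <- function(probes, annot) {
  stopifnot(inherits(annot, "probe_annotation"))
  idx <- match(probes, annot$probe_id)
  unknown <- is.na(idx)
  if (any(unknown)) {
    warning(sum(unknown), " probes absent from annotation were retained")
  }
  snp <- !unknown & annot$snp_affected[idx]
  xhyb <- !unknown & annot$cross_hybridizing[idx]
  drop <- snp | xhyb
  reason <- ifelse(snp & xhyb, "snp;cross_hybridizing",
            ifelse(snp, "snp", "cross_hybridizing"))
  report <- list(
    probes_excluded = data.frame(probe_id = probes[drop],
                                 reason = reason[drop],
                                 stringsAsFactors = FALSE, row.names = NULL),
    n_unannotated_retained = sum(unknown),
    counts_before = c(probes = length(probes)),
    counts_after = c(probes = sum(!drop)))
  class(report) <- "qc_report"
  list(probes = probes[!drop], report = report)
}

# between-sample quantile normalization: every column's sorted values are
# replaced by the across-sample mean of order statistics, ties averaged.
quantile_normalize_columns <- function(m) {
  if (ncol(m) < 2) return(m)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Probe-type-aware quantile normalization of intensities (dasen-style)
#'
#' Normalizes methylated/unmethylated intensities in three steps and
#' returns beta values:
#' \enumerate{
#'   \item background equalization: for each sample, Type II methylated
#'     and unmethylated intensities are shifted so a low-intensity
#'     background quantile (default the 5th percentile) of Type II matches
#'     that of Type I, with the per-sample offsets smoothed by a linear
#'     fit against sample index;
#'   \item between-sample quantile normalization of the methylated and of
#'     the unmethylated intensities, separately within Type I and within
#'     Type II probes (four independent normalizations);
#'   \item `beta = M / (M + U + beta_offset)`.
#' }
#' Intensities driven negative by the background shift are clamped to 0;
#' the count is attached as attribute `n_clamped`.
#'
#' @param intens an [intensity_set()].
#' @param annot a [probe_annotation()] covering every probe (design type
#'   is required).
#' @param beta_offset stabilizing offset in the beta denominator
#'   (default 100, the array-standard alpha).
#' @param background_quantile quantile used to estimate background level.
#' @param smooth `"linear"` (fit offsets against sample index) or
#'   `"none"` (use raw per-sample offsets).
#' @return a probes x samples beta matrix.
#' @export
dasen_normalize <- function(intens, annot, beta_offset = 100,
                            background_quantile = 0.05,
                            smooth = c("linear", "none")) {
  stopifnot(inherits(intens, "intensity_set"))
  smooth <- match.arg(smooth)
  if (length(intens$sample_ids) < 2) stop("dasen_normalize needs >= 2 samples")
  idx <- match(intens$probe_ids, annot$probe_id)
  if (anyNA(idx)) {
    stop("design type unknown for probes: ",
         paste(utils::head(intens$probe_ids[is.na(idx)], 5), collapse = ", "))
  }
  design <- annot$design_type[idx]
  is1 <- design == "I"
  is2 <- design == "II"

  shift_type2 <- function(X) {
    if (!any(is1) || !any(is2)) return(X)  # single chemistry: nothing to equalize
    q1 <- apply(X[is1, , drop = FALSE], 2, stats::quantile,
                probs = background_quantile, na.rm = TRUE)
    q2 <- apply(X[is2, , drop = FALSE], 2, stats::quantile,
                probs = background_quantile, na.rm = TRUE)
    off <- q1 - q2
    if (smooth == "linear" && length(off) > 2) {
      off <- stats::fitted(stats::lm(off ~ seq_along(off)))
    }
    X[is2, ] <- sweep(X[is2, , drop = FALSE], 2, off, "+")
    X
  }

  M <- shift_type2(intens$methylated)
  U <- shift_type2(intens$unmethylated)
  n_clamped <- sum(M < 0, na.rm = TRUE) + sum(U < 0, na.rm = TRUE)
  M[M < 0] <- 0
  U[U < 0] <- 0

  for (sel in list(is1, is2)) {
    if (sum(sel) > 0) {
      M[sel, ] <- quantile_normalize_columns(M[sel, , drop = FALSE])
      U[sel, ] <- quantile_normalize_columns(U[sel, , drop = FALSE])
    }
  }

  betas <- M / (M + U + beta_offset)
  out <- beta_matrix(betas, intens$probe_ids, intens$sample_ids)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Quantile-normalize beta values within probe design type
#'
#' Fallback normalization when only beta values are available (as for
#' public datasets distributed without raw intensities): between-sample
#' quantile normalization performed separately within Type I and Type II
#' probes.
#'
#' @param betas beta matrix.
#' @param annot a [probe_annotation()] giving design types.
#' @return normalized beta matrix.
#' @export
beta_quantile_normalize <- function(betas, annot) {
  if (ncol(betas) < 2) {
    warning("single sample: quantile normalization is the identity")
    return(betas)
  }
  idx <- match(rownames(betas), annot$probe_id)
  if (anyNA(idx)) stop("design type unknown for some probes")
  design <- annot$design_type[idx]
  out <- betas
  for (tp in unique(design)) {
    sel <- design == tp
    out[sel, ] <- quantile_normalize_columns(betas[sel, , drop = FALSE])
  }
  beta_matrix(out)
}

#' Intersect probes across beta matrices
#'
#' Returns the probes present, and fully observed (no missing values), in
#' every matrix, in the row order of the first matrix, together with the
#' matrices subsetted and row-aligned to that common set.
#'
#' @param matrices list of beta matrices.
#' @return list with `probes` and `matrices`.
#' @export
intersect_probes <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  observed <- lapply(matrices, function(m) rownames(m)[rowSums(is.na(m)) == 0])
  common <- Reduce(intersect, observed)
  common <- rownames(matrices[[1]])[rownames(matrices[[1]]) %in% common]
  if (length(common) == 0) stop("no probes shared by all matrices")
  list(probes = common,
       matrices = lapply(matrices, function(m) m[common, , drop = FALSE]))
}

#' Stratified train/test split
#'
#' Within each dataset, `floor(fraction_train * n)` samples (plus one if
#' the fractional part is >= 0.5, i.e. round half up) are assigned to the
#' training set uniformly at random; deterministic for a fixed seed.
#' A stratum of size 1 goes to the training set with a warning.
#'
#' @param sheet a [sample_sheet()].
#' @param fraction_train target training fraction (default 0.75).
#' @param seed integer RNG seed.
#' @return data frame of class `split_assignment` with columns
#'   `sample_id`, `dataset_id`, `assignment`; the fraction and seed are
#'   kept as attributes.
#' @export
stratified_split <- function(sheet, fraction_train = 0.75, seed) {
  stopifnot(inherits(sheet, "sample_sheet"), !missing(seed))
  if (any(is.na(sheet$dataset_id))) stop("dataset_id required for every sample")
  out <- withr::with_seed(as.integer(seed), {
    pieces <- lapply(split(sheet$sample_id, sheet$dataset_id), function(ids) {
      n <- length(ids)
      n_train <- floor(fraction_train * n + 0.5)  # round half up
      if (n == 1) warning("stratum of size 1 assigned to training set")
      train_ids <- sample(ids, n_train)
      data.frame(sample_id = ids,
                 assignment = ifelse(ids %in% train_ids, "train", "test"),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, pieces)
  })
  out <- out[match(sheet$sample_id, out$sample_id), ]
  out$dataset_id <- sheet$dataset_id
  rownames(out) <- NULL
  out <- out[, c("sample_id", "dataset_id", "assignment")]
  attr(out, "fraction_train") <- fraction_train
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("split_assignment", "data.frame")
  out
}
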