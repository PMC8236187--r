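#' devclock: development-stage epigenetic clocks
#'
#' Build, apply and evaluate DNA methylation age clocks on the prenatal
#' (days post-conception) timescale, and compare predicted epigenetic age
#' between cellular differentiation stages.
#'
#' The central objects are plain matrices and data frames following array
#' conventions: beta matrices are probes x samples with probe IDs as
#' rownames and sample IDs as colnames; sample sheets are data frames with
#' one row per sample.
#'
#' @keywords internal
"_PACKAGE"

VALID_AGE_UNITS <- c("dpc", "weeks_pc", "years")
VALID_SEX <- c("male", "female", "unknown")
VALID_OUTPUT_UNITS <- c("dpc", "years", "weeks_ga")
VALID_TRANSFORMS <- c("identity", "horvath_log_linear")

#' Construct a validated beta matrix
#'
#' A beta matrix is a probes x samples numeric matrix of methylation
#' proportions with unique probe IDs as rownames and unique sample IDs as
#' colnames. Missing values are `NA`. All non-missing values must lie in
#' \[0, 1\] (up to a small numerical slack for values read from text).
#'
#' @param values numeric matrix, probes in rows and samples in columns.
#' @param probe_ids,sample_ids optional character vectors overriding the
#'   dimnames of `values`.
#' @param tol slack allowed outside \[0, 1\] before a value is an error.
#' @return the validated numeric matrix (probes x samples).
#' @export
beta_matrix <- function(values, probe_ids = rownames(values),
                        sample_ids = colnames(values), tol = 1e-9) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probe_ids) || is.null(sample_ids)) {
    stop("beta_matrix requires probe and sample identifiers")
  }
  if (length(probe_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("identifier lengths inconsistent with matrix dimensions")
  }
  if (anyDuplicated(probe_ids)) {
    stop("duplicate probe ids: ", paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ", paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  dimnames(values) <- list(as.character(probe_ids), as.character(sample_ids))
  bad <- which(!is.na(values) & (values < -tol | values > 1 + tol), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s': %g",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
                 values[bad[1, , drop = FALSE]]))
  }
  # snap tiny numerical excursions back onto the boundary
  values[!is.na(values) & values < 0] <- 0
  values[!is.na(values) & values > 1] <- 1
  values
}

#' Bundle methylated/unmethylated intensities with detection p-values
#'
#' @param methylated,unmethylated non-negative probes x samples matrices.
#' @param detection_p probes x samples matrix of detection p-values in \[0,1\].
#' @return an object of class `intensity_set`.
#' @export
intensity_set <- function(methylated, unmethylated, detection_p) {
  mats <- list(methylated = as.matrix(methylated),
               unmethylated = as.matrix(unmethylated),
               detection_p = as.matrix(detection_p))
  dims <- lapply(mats, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("methylated, unmethylated and detection_p must share dimensions")
  }
  pid <- rownames(mats$methylated)
  sid <- colnames(mats$methylated)
  if (is.null(pid) || is.null(sid)) stop("intensity matrices need dimnames")
  for (nm in names(mats)) {
    if (!identical(rownames(mats[[nm]]), pid) || !identical(colnames(mats[[nm]]), sid)) {
      stop("id ordering differs between intensity components")
    }
  }
  if (any(mats$methylated < 0, na.rm = TRUE) || any(mats$unmethylated < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative")
  }
  if (any(mats$detection_p < 0 | mats$detection_p > 1, na.rm = TRUE)) {
    stop("detection p-values must lie in [0,1]")
  }
  structure(c(mats, list(probe_ids = pid, sample_ids = sid)),
            class = "intensity_set")
}

#' Construct a probe annotation table
#'
#' One row per probe: Illumina design type (I or II) plus blacklist flags
#' for SNP-affected and cross-hybridizing probes, and platform membership.
#'
#' @param probe_id character vector of unique probe IDs.
#' @param design_type "I" or "II" per probe.
#' @param snp_affected,cross_hybridizing logical blacklist flags.
#' @param platform_450k,platform_epic logical platform membership flags.
#' @return a data frame of class `probe_annotation`.
#' @export
probe_annotation <- function(probe_id, design_type,
                             snp_affected = FALSE, cross_hybridizing = FALSE,
                             platform_450k = TRUE, platform_epic = TRUE) {
  probe_id <- as.character(probe_id)
  if (anyDuplicated(probe_id)) stop("duplicate probe_id in annotation")
  design_type <- as.character(design_type)
  if (!all(design_type %in% c("I", "II"))) stop("design_type must be 'I' or 'II'")
  out <- data.frame(probe_id = probe_id,
                    design_type = design_type,
                    snp_affected = rep_len(as.logical(snp_affected), length(probe_id)),
                    cross_hybridizing = rep_len(as.logical(cross_hybridizing), length(probe_id)),
                    platform_450k = rep_len(as.logical(platform_450k), length(probe_id)),
                    platform_epic = rep_len(as.logical(platform_epic), length(probe_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("probe_annotation", "data.frame")
  out
}

#' Construct a sample sheet
#'
#' @param sample_id unique sample identifiers.
#' @param age_value numeric ages, interpreted according to `age_unit`.
#' @param age_unit one of `"dpc"`, `"weeks_pc"`, `"years"` per sample.
#' @param sex `"male"`, `"female"` or `"unknown"` per sample.
#' @param dataset_id dataset/batch label per sample.
#' @param group tissue or cell-stage label per sample.
#' @return data frame of class `sample_sheet` with a
#'   `chronological_age_dpc` column filled by [to_dpc()].
#' @export
sample_sheet <- function(sample_id, age_value, age_unit, sex = "unknown",
                         dataset_id = "dataset1", group = "tissue") {
  sample_id <- as.character(sample_id)
  n <- length(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample_id in sample sheet")
  age_unit <- rep_len(as.character(age_unit), n)
  if (!all(age_unit %in% VALID_AGE_UNITS)) {
    stop("age_unit must be one of: ", paste(VALID_AGE_UNITS, collapse = ", "))
  }
  sex <- rep_len(as.character(sex), n)
  if (!all(sex %in% VALID_SEX)) {
    stop("sex must be one of: ", paste(VALID_SEX, collapse = ", "))
  }
  out <- data.frame(sample_id = sample_id,
                    age_value = as.numeric(rep_len(age_value, n)),
                    age_unit = age_unit,
                    sex = sex,
                    dataset_id = rep_len(as.character(dataset_id), n),
                    group = rep_len(as.character(group), n),
                    stringsAsFactors = FALSE)
  out$chronological_age_dpc <- to_dpc(out$age_value, out$age_unit)
  class(out) <- c("sample_sheet", "data.frame")
  out
}

#' Construct a clock model
#'
#' A clock model is an intercept plus a sparse map from probe IDs to
#' weights, together with the unit its linear predictor lives on and any
#' output transform (e.g. the log-linear age transform used by
#' multi-tissue clocks trained on transformed adult/child ages).
#'
#' @param name clock label used in prediction output.
#' @param intercept numeric intercept of the linear predictor.
#' @param coefficients named numeric vector of nonzero probe weights. May be
#'   empty for a degenerate intercept-only fit, but such a model cannot be
#'   serialized with [write_clock()].
#' @param output_unit `"dpc"`, `"years"` or `"weeks_ga"` — the unit of the
#'   (back-transformed) prediction.
#' @param transform `"identity"` or `"horvath_log_linear"`.
#' @param transform_params list; for `horvath_log_linear`, `adult_age`.
#' @param training optional list of training metadata (alpha, lambda,
#'   n_train, age_range_dpc).
#' @return object of class `clock_model`.
#' @export
clock_model <- function(name, intercept, coefficients,
                        output_unit = "dpc", transform = "identity",
                        transform_params = list(), training = list()) {
  output_unit <- match.arg(output_unit, VALID_OUTPUT_UNITS)
  transform <- match.arg(transform, VALID_TRANSFORMS)
  coefficients <- coefficients[coefficients != 0]
  if (length(coefficients) > 0 && is.null(names(coefficients))) {
    stop("coefficients must be named by probe id")
  }
  if (anyDuplicated(names(coefficients))) stop("duplicate probe in coefficients")
  if (transform == "horvath_log_linear") {
    if (output_unit != "years") {
      stop("horvath_log_linear transform is only meaningful with output_unit = 'years'")
    }
    if (is.null(transform_params$adult_age)) transform_params$adult_age <- 20
    if (transform_params$adult_age <= 0) stop("adult_age must be positive")
  }
  structure(list(name = as.character(name),
                 intercept = as.numeric(intercept),
                 coefficients = coefficients,
                 output_unit = output_unit,
                 transform = transform,
                 transform_params = transform_params,
                 training = training),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model '%s'>\n", x$name))
  cat(sprintf("  intercept: %g, %d probe coefficients\n",
              x$intercept, length(x$coefficients)))
  cat(sprintf("  output unit: %s, transform: %s\n", x$output_unit, x$transform))
  if (length(x$training)) {
    cat(sprintf("  trained: alpha=%s lambda=%s n=%s\n",
                format(x$training$alpha), format(x$training$lambda),
                format(x$training$n_train)))
  }
  invisible(x)
}

#' @export
print.intensity_set <- function(x, ...) {
  cat(sprintf("<intensity_set> %d probes x %d samples\n",
              length(x$probe_ids), length(x$sample_ids)))
  invisible(x)
}
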