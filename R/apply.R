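#' Apply a clock to a beta matrix
#'
#' Computes for every sample the raw linear predictor
#' `intercept + sum_j coef_j * beta_j` over the clock's probes, applies
#' the clock's output transform, and converts the native-unit prediction
#' to days post-conception.
#'
#' Probes absent from the data are handled by `missing_policy`:
#' \describe{
#'   \item{fail}{any absent clock probe aborts (default — silently
#'     dropping probes changes the estimand);}
#'   \item{mean_impute}{absent probes contribute a beta of 0.5, or the
#'     value in `reference_means` when supplied;}
#'   \item{drop}{absent probes are omitted from the sum.}
#' }
#' Predictions falling outside the clock's training age range (when that
#' metadata is present) are flagged, not clipped.
#'
#' @param betas beta matrix (probes x samples).
#' @param clock a [clock_model()].
#' @param missing_policy see Details.
#' @param reference_means optional named vector of reference beta means
#'   used by `mean_impute`.
#' @param coverage_floor clock-probe coverage below which a warning flag
#'   is set on the result rows (default 0.8).
#' @return data frame of class `prediction_result` with columns
#'   `sample_id`, `clock_name`, `raw_score`, `predicted_age_native`,
#'   `predicted_age_dpc`, `probe_coverage`, `low_coverage`,
#'   `out_of_training_range`.
#' @export
predict_age <- function(betas, clock,
                        missing_policy = c("fail", "mean_impute", "drop"),
                        reference_means = NULL, coverage_floor = 0.8) {
  stopifnot(inherits(clock, "clock_model"))
  missing_policy <- match.arg(missing_policy)
  probes <- names(clock$coefficients)
  present <- probes %in% rownames(betas)
  coverage <- if (length(probes)) mean(present) else 1
  if (length(probes) && !any(present)) {
    stop("none of the clock's probes are present in the data")
  }
  if (missing_policy == "fail" && any(!present)) {
    stop(sum(!present), " clock probes absent from data (missing_policy = 'fail'): ",
         paste(utils::head(probes[!present], 5), collapse = ", "))
  }

  vals <- matrix(0, nrow = length(probes), ncol = ncol(betas),
                 dimnames = list(probes, colnames(betas)))
  if (any(present)) vals[probes[present], ] <- betas[probes[present], , drop = FALSE]
  if (any(!present) && missing_policy == "mean_impute") {
    fill <- rep(0.5, sum(!present))
    if (!is.null(reference_means)) {
      hit <- probes[!present] %in% names(reference_means)
      fill[hit] <- reference_means[probes[!present][hit]]
    }
    vals[probes[!present], ] <- fill
  }
  # under "drop" absent probes stay at 0 and thus vanish from the sum
  raw <- clock$intercept +
    if (length(probes)) drop(crossprod(vals, clock$coefficients)) else
      rep(0, ncol(betas))
  raw <- stats::setNames(as.numeric(raw), colnames(betas))

  native <- switch(clock$transform,
    identity = raw,
    horvath_log_linear = horvath_anti_transform(
      raw, clock$transform_params$adult_age %||% 20))
  unit <- switch(clock$output_unit, dpc = "dpc", years = "years",
                 weeks_ga = "weeks_pc")
  dpc <- to_dpc(native, unit)

  out_of_range <- rep(NA, length(raw))
  rng <- clock$training$age_range_dpc
  if (!is.null(rng)) out_of_range <- dpc < rng[1] | dpc > rng[2]

  out <- data.frame(sample_id = colnames(betas),
                    clock_name = clock$name,
                    raw_score = raw,
                    predicted_age_native = native,
                    predicted_age_dpc = dpc,
                    probe_coverage = coverage,
                    low_coverage = coverage < coverage_floor,
                    out_of_training_range = out_of_range,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (out$low_coverage[1]) {
    warning(sprintf("clock '%s': probe coverage %.2f below floor %.2f",
                    clock$name, coverage, coverage_floor))
  }
  class(out) <- c("prediction_result", "data.frame")
  out
}

#' Apply several clocks to several datasets
#'
#' Produces the long prediction table used for clock benchmarking and
#' cell-stage comparisons. A clock failing on one dataset (e.g. because of
#' platform-specific probe loss under `missing_policy = "fail"`) is
#' recorded as a warning; the remaining dataset x clock blocks are still
#' produced.
#'
#' @param datasets named list; each element a list with `betas` (beta
#'   matrix) and `sheet` (a [sample_sheet()]).
#' @param clocks list of [clock_model()]s.
#' @param missing_policy,reference_means,coverage_floor passed to
#'   [predict_age()].
#' @return long data frame: `sample_id`, `dataset_id`, `group`,
#'   `clock_name`, `predicted_age_dpc`, `probe_coverage`,
#'   `chronological_age_dpc`.
#' @export
batch_predict <- function(datasets, clocks,
                          missing_policy = c("fail", "mean_impute", "drop"),
                          reference_means = NULL, coverage_floor = 0.8) {
  missing_policy <- match.arg(missing_policy)
  blocks <- list()
  for (ds_name in names(datasets)) {
    ds <- datasets[[ds_name]]
    for (clock in clocks) {
      pred <- tryCatch(
        predict_age(ds$betas, clock, missing_policy = missing_policy,
                    reference_means = reference_means,
                    coverage_floor = coverage_floor),
        error = function(e) {
          warning(sprintf("clock '%s' failed on dataset '%s': %s",
                          clock$name, ds_name, conditionMessage(e)))
          NULL
        })
      if (is.null(pred)) next
      i <- match(pred$sample_id, ds$sheet$sample_id)
      blocks[[length(blocks) + 1]] <- data.frame(
        sample_id = pred$sample_id,
        dataset_id = ds$sheet$dataset_id[i],
        group = ds$sheet$group[i],
        clock_name = pred$clock_name,
        predicted_age_dpc = pred$predicted_age_dpc,
        probe_coverage = pred$probe_coverage,
        chronological_age_dpc = ds$sheet$chronological_age_dpc[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(blocks) == 0) stop("no predictions produced")
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
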