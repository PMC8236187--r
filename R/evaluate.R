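#' Prediction accuracy: Pearson correlation and RMSE
#'
#' The two statistics used to profile clock performance: the sample
#' Pearson correlation between predicted and chronological age, and the
#' root mean squared error `sqrt(mean((pred - true)^2))` (no
#' degrees-of-freedom correction), in the units of the inputs.
#'
#' @param pred_dpc,true_dpc equal-length numeric vectors (n >= 3), no
#'   missing values.
#' @param subset_label optional label recorded in the report.
#' @return list of class `eval_report`: `n`, `pearson_r` (`NA` with a
#'   reason when either vector has zero variance), `rmse`,
#'   `age_range_dpc`, `subset`.
#' @export
accuracy <- function(pred_dpc, true_dpc, subset_label = NULL) {
  if (length(pred_dpc) != length(true_dpc)) stop("length mismatch")
  if (length(pred_dpc) < 3) stop("need at least 3 samples")
  if (anyNA(pred_dpc) || anyNA(true_dpc)) stop("missing values not allowed")
  r <- NA_real_
  r_missing_reason <- NULL
  if (stats::var(pred_dpc) == 0 || stats::var(true_dpc) == 0) {
    r_missing_reason <- "zero variance in predictions or ages"
  } else {
    r <- stats::cor(pred_dpc, true_dpc, method = "pearson")
  }
  structure(list(n = length(pred_dpc),
                 pearson_r = r,
                 r_missing_reason = r_missing_reason,
                 rmse = sqrt(mean((pred_dpc - true_dpc)^2)),
                 age_range_dpc = range(true_dpc),
                 subset = subset_label),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report%s> n=%d r=%s RMSE=%.4g (ages %.4g-%.4g)\n",
              if (is.null(x$subset)) "" else paste0(" ", x$subset),
              x$n, ifelse(is.na(x$pearson_r), "NA", sprintf("%.4f", x$pearson_r)),
              x$rmse, x$age_range_dpc[1], x$age_range_dpc[2]))
  invisible(x)
}

#' Accuracy restricted to the training age range
#'
#' Clock error outside the age range seen in training is dominated by
#' extrapolation; this recomputes [accuracy()] on the samples whose
#' chronological age does not exceed `max_dpc` (e.g. 185 dpc, the top of
#' a fetal training range).
#'
#' @param pred_dpc,true_dpc as in [accuracy()].
#' @param max_dpc inclusive upper cutoff on chronological age.
#' @return an `eval_report` whose `subset` records the cutoff.
#' @export
range_restricted_accuracy <- function(pred_dpc, true_dpc, max_dpc) {
  if (max_dpc <= min(true_dpc)) stop("max_dpc must exceed the youngest sample")
  keep <- true_dpc <= max_dpc
  if (sum(keep) < 3) stop("fewer than 3 samples at or below the cutoff")
  accuracy(pred_dpc[keep], true_dpc[keep],
           subset_label = sprintf("true_age<=%g dpc", max_dpc))
}

#' Test for a sex difference in the age trajectory of predictions
#'
#' Ordinary least squares of predicted age on chronological age, sex and
#' their interaction (`pred ~ age + sex + age:sex`), with sex dummy-coded
#' against a documented reference level (default female). The interaction
#' p-value (Wald t-test) asks whether the clock tracks age with a
#' different slope in males and females. An optional exclusion list
#' supports sensitivity refits (e.g. dropping the samples with the most
#' extreme predicted ages).
#'
#' @param pred_dpc,true_dpc predicted and chronological ages (dpc).
#' @param sex character vector, `"male"`/`"female"` per sample.
#' @param exclude optional sample ids (requires `sample_ids`) or integer
#'   indices to drop before fitting.
#' @param sample_ids optional sample identifiers aligned with the data.
#' @param reference sex reference level (default `"female"`).
#' @return list of class `interaction_model_result`: `coefficients`
#'   (estimate/se/t/p per term), `interaction_p`, `n`, `excluded`,
#'   `reference`.
#' @export
sex_interaction_test <- function(pred_dpc, true_dpc, sex, exclude = NULL,
                                 sample_ids = NULL, reference = "female") {
  n0 <- length(pred_dpc)
  stopifnot(length(true_dpc) == n0, length(sex) == n0)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n0))
  keep <- rep(TRUE, n0)
  if (!is.null(exclude)) {
    keep <- if (is.numeric(exclude)) !(seq_len(n0) %in% exclude)
            else !(sample_ids %in% exclude)
  }
  d <- data.frame(pred = pred_dpc[keep], age = true_dpc[keep],
                  sex = sex[keep], stringsAsFactors = FALSE)
  d <- d[d$sex %in% c("male", "female"), ]
  tab <- table(d$sex)
  if (length(tab) < 2 || any(tab < 3)) {
    stop("both sexes must be present with >= 3 samples each")
  }
  d$sex <- stats::relevel(factor(d$sex, levels = c("female", "male")),
                          ref = reference)
  fit <- stats::lm(pred ~ age * sex, data = d)
  ct <- summary(fit)$coefficients
  inter_row <- grep("age:sex", rownames(ct))
  structure(list(coefficients = ct,
                 interaction_p = unname(ct[inter_row, "Pr(>|t|)"]),
                 n = nrow(d),
                 excluded = sample_ids[!keep],
                 reference = reference),
            class = "interaction_model_result")
}
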