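#' Two-sample t-test between cell stages
#'
#' Compares predicted epigenetic age between two groups (e.g. iPSC vs
#' neuron). Welch's unequal-variance test by default — the convention of
#' standard statistical software when variance equality is not asserted —
#' with the pooled-variance Student test available via `var_equal`.
#' When both groups are constant with equal means the test statistic is
#' undefined; by convention p = 1 is returned with a flag.
#'
#' @param pred_a,pred_b numeric vectors (each n >= 2) of predicted ages
#'   in the reference and comparison group.
#' @param labels length-2 character: names of group a and group b.
#' @param var_equal use the pooled-variance test.
#' @return one-row data frame of class `stage_contrast_result`:
#'   `contrast`, `delta_mean` (mean(b) - mean(a)), `statistic`, `df`,
#'   `p_value`, `n_a`, `n_b`, `method`, `degenerate`.
#' @export
two_sample_t <- function(pred_a, pred_b, labels = c("a", "b"),
                         var_equal = FALSE) {
  if (length(pred_a) < 2 || length(pred_b) < 2) stop("each group needs n >= 2")
  delta <- mean(pred_b) - mean(pred_a)
  degenerate <- stats::var(pred_a) == 0 && stats::var(pred_b) == 0
  if (degenerate && delta == 0) {
    stat <- 0; df <- NA_real_; p <- 1
  } else if (degenerate) {
    stat <- Inf * sign(delta); df <- NA_real_; p <- 0
  } else {
    tt <- stats::t.test(pred_b, pred_a, var.equal = var_equal)
    stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  }
  out <- data.frame(contrast = paste0(labels[2], "-", labels[1]),
                    delta_mean = delta, statistic = stat, df = df,
                    p_value = p, n_a = length(pred_a), n_b = length(pred_b),
                    method = if (var_equal) "t_test_pooled" else "t_test_welch",
                    degenerate = degenerate,
                    stringsAsFactors = FALSE)
  class(out) <- c("stage_contrast_result", "data.frame")
  out
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Used when three cell stages are available: an overall F-test for any
#' stage difference, followed by all pairwise contrasts with familywise
#' adjustment from the studentized range distribution (Tukey–Kramer
#' standard errors for unbalanced groups).
#'
#' @param values numeric response (predicted ages, dpc).
#' @param stage factor (or coercible) with exactly 3 levels, each with
#'   >= 2 observations.
#' @return data frame of class `stage_contrast_result` with one row per
#'   pairwise contrast (`delta_mean`, Tukey-adjusted `p_value`, group
#'   sizes); the ANOVA F statistic and its p-value are attached as
#'   attributes `anova_F` and `anova_p`.
#' @export
anova_tukey <- function(values, stage) {
  stage <- factor(stage)
  if (nlevels(stage) != 3) stop("anova_tukey expects exactly 3 stages")
  if (any(table(stage) < 2)) stop("every stage needs >= 2 observations")
  d <- data.frame(y = as.numeric(values), stage = stage)
  fit <- stats::aov(y ~ stage, data = d)
  av <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$stage
  counts <- table(stage)
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- data.frame(contrast = rownames(tk),
                    delta_mean = tk[, "diff"],
                    statistic = NA_real_,
                    df = stats::df.residual(fit),
                    p_value = tk[, "p adj"],
                    n_a = as.integer(counts[vapply(pairs, `[[`, "", 2)]),
                    n_b = as.integer(counts[vapply(pairs, `[[`, "", 1)]),
                    method = "tukey_hsd",
                    degenerate = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("stage_contrast_result", "data.frame")
  attr(out, "anova_F") <- av[["F value"]][1]
  attr(out, "anova_p") <- av[["Pr(>F)"]][1]
  out
}

#' Cross-dataset mixed-effects comparison of cell stages
#'
#' Pools predicted epigenetic ages across studies with a linear mixed
#' model: fixed effects for cell stage (two dummies contrasting NPC vs
#' iPSC and neuron vs iPSC, iPSC being the reference) and a random
#' intercept per dataset, fitted by REML. Datasets lacking a stage still
#' inform the remaining contrasts. Fixed-effect p-values are Wald z
#' tests; small-sample degrees-of-freedom corrections (e.g. Satterthwaite)
#' would give larger p-values at few datasets.
#'
#' With a single dataset the model is unidentifiable and the function
#' falls back to ordinary least squares with a warning.
#'
#' @param table long data frame with one row per sample.
#' @param response,stage_col,dataset_col column names for the predicted
#'   age, the stage label and the dataset label.
#' @param stages stage levels in order, first = reference.
#' @return list of class `mixed_model_fit`: `fixed_effects` (estimate,
#'   se, z, p per term), `random_intercept_sd`, `residual_sd`, `n`,
#'   `n_datasets`, `converged`, `method` ("reml_mixed" or "ols_fallback").
#' @export
stage_meta_analysis <- function(table, response = "predicted_age_dpc",
                                stage_col = "group",
                                dataset_col = "dataset_id",
                                stages = c("iPSC", "NPC", "neuron")) {
  need <- c(response, stage_col, dataset_col)
  if (!all(need %in% colnames(table))) {
    stop("table lacks columns: ", paste(setdiff(need, colnames(table)), collapse = ", "))
  }
  d <- data.frame(y = table[[response]],
                  stage = factor(table[[stage_col]], levels = stages),
                  dataset = factor(table[[dataset_col]]))
  d <- d[!is.na(d$stage), ]
  if (nrow(d) == 0) stop("no rows with a recognized stage label")
  n_datasets <- nlevels(droplevels(d$dataset))

  if (n_datasets < 2) {
    warning("single dataset: falling back to ordinary least squares")
    fit <- stats::lm(y ~ stage, data = d)
    ct <- summary(fit)$coefficients
    fe <- data.frame(term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
                     z = ct[, 3], p_value = ct[, 4],
                     stringsAsFactors = FALSE, row.names = NULL)
    out <- list(fixed_effects = fe, random_intercept_sd = NA_real_,
                residual_sd = summary(fit)$sigma, n = nrow(d),
                n_datasets = n_datasets, converged = TRUE,
                method = "ols_fallback")
    class(out) <- "mixed_model_fit"
    return(out)
  }

  fit <- lme4::lmer(y ~ stage + (1 | dataset), data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  converged <- length(fit@optinfo$conv$lme4$messages) == 0
  ct <- stats::coef(summary(fit))
  z <- ct[, "Estimate"] / ct[, "Std. Error"]
  fe <- data.frame(term = rownames(ct), estimate = ct[, "Estimate"],
                   se = ct[, "Std. Error"], z = z,
                   p_value = 2 * stats::pnorm(-abs(z)),
                   stringsAsFactors = FALSE, row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- list(fixed_effects = fe,
              random_intercept_sd = vc$sdcor[vc$grp == "dataset"],
              residual_sd = vc$sdcor[vc$grp == "Residual"],
              n = nrow(d), n_datasets = n_datasets,
              converged = converged, method = "reml_mixed")
  class(out) <- "mixed_model_fit"
  out
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("<mixed_model_fit %s> n=%d datasets=%d converged=%s\n",
              x$method, x$n, x$n_datasets, x$converged))
  print(x$fixed_effects, digits = 4)
  cat(sprintf("  random intercept sd=%.4g residual sd=%.4g\n",
              x$random_intercept_sd, x$residual_sd))
  invisible(x)
}
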