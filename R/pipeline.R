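#' Run a configured end-to-end workflow
#'
#' Executes a sequence of steps — `simulate`, `qc`, `split`, `train`,
#' `predict`, `evaluate`, `compare_stages` — against a configuration
#' given as a named list or a YAML file. Each step writes its outputs
#' under `out_dir` and passes its products (beta matrix, sample sheet,
#' split, clock, predictions) to later steps; file inputs named in the
#' config may replace any intermediate. A single top-level `seed` is
#' expanded into recorded per-step seeds, and a parameter log
#' (`run_log.json`) captures every effective setting, so re-running an
#' identical config reproduces every output byte for byte.
#'
#' Config keys: `out_dir`, `seed`, `steps` (character vector), and one
#' optional named list per step with its parameters (e.g.
#' `train: {alpha: 0.5, n_folds: 10}`; `qc: {betas:, detp:, annot:}`;
#' `predict: {clock_files: [...]}`).
#'
#' @param config named list or path to a YAML config file.
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @return invisibly, the output directory path.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("config must name an out_dir")
  steps <- config$steps %||% c("simulate", "split", "train", "predict", "evaluate")
  known <- c("simulate", "qc", "split", "train", "predict", "evaluate",
             "compare_stages")
  bad <- setdiff(steps, known)
  if (length(bad)) {
    stop("unknown step(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  }
  # pre-flight: every file referenced in the config must exist
  paths <- unlist(lapply(steps, function(s) {
    p <- config[[s]]
    if (is.null(p) || is.null(names(p))) return(NULL)
    unlist(p[grepl("(file|files|path|betas|detp|annot|sheet)$", names(p))],
           use.names = FALSE)
  }))
  paths <- as.character(paths[vapply(paths, is.character, logical(1))])
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  master_seed <- as.integer(config$seed %||% 1)
  step_seed <- function(i) (master_seed * 1009L + i * 101L) %% 2147483647L
  logged_config <- config
  logged_config$out_dir <- NULL  # location, not a parameter of the analysis
  log <- list(package_version = as.character(utils::packageVersion("devclock")),
              master_seed = master_seed, steps = steps,
              config = logged_config)

  state <- new.env(parent = emptyenv())
  for (i in seq_along(steps)) {
    s <- steps[i]
    p <- config[[s]] %||% list()
    seed_i <- step_seed(i)
    log[[paste0("seed_", s)]] <- seed_i
    switch(s,
      simulate = {
        spec <- do.call(sim_spec, c(p, list(seed = seed_i)))
        sim <- simulate_age_dataset(spec)
        state$betas <- sim$betas
        state$sheet <- sim$sheet
        state$detp <- sim$intensities$detection_p
        write_matrix(sim$betas, file.path(out_dir, "betas.tsv"))
        write_table(as.data.frame(sim$sheet), file.path(out_dir, "sample_sheet.tsv"))
        write_table(sim$truth, file.path(out_dir, "probe_truth.tsv"))
      },
      qc = {
        if (!is.null(p$betas)) state$betas <- read_matrix(p$betas, "beta")
        if (!is.null(p$detp)) state$detp <- read_matrix(p$detp, "detection_p")
        if (is.null(state$betas)) stop("qc step needs a beta matrix")
        if (!is.null(state$detp)) {
          pf <- pfilter(state$detp,
                        sample_frac_thresh = p$sample_frac_thresh %||% 0.01,
                        probe_frac_thresh = p$probe_frac_thresh %||% 0.01,
                        p_thresh = p$p_thresh %||% 0.05)
          state$betas <- state$betas[pf$probes, pf$samples, drop = FALSE]
          if (!is.null(state$sheet)) {
            state$sheet <- state$sheet[state$sheet$sample_id %in% pf$samples, ]
          }
          jsonlite::write_json(
            list(samples_excluded = pf$report$samples_excluded,
                 probes_excluded = pf$report$probes_excluded,
                 counts_before = as.list(pf$report$counts_before),
                 counts_after = as.list(pf$report$counts_after)),
            file.path(out_dir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
        }
        write_matrix(state$betas, file.path(out_dir, "betas_qc.tsv"))
      },
      split = {
        if (!is.null(p$sheet)) state$sheet <- read_sample_sheet(p$sheet)
        state$split <- stratified_split(state$sheet,
                                        fraction_train = p$fraction_train %||% 0.75,
                                        seed = seed_i)
        write_table(as.data.frame(state$split), file.path(out_dir, "split.tsv"))
      },
      train = {
        train_ids <- if (!is.null(state$split)) {
          state$split$sample_id[state$split$assignment == "train"]
        } else state$sheet$sample_id
        cfg <- train_config(alpha = p$alpha %||% 0.5,
                            n_folds = p$n_folds %||% 10,
                            lambda_rule = p$lambda_rule %||% "min",
                            seed = seed_i)
        keep <- intersect(colnames(state$betas), train_ids)
        ages <- state$sheet$chronological_age_dpc[match(keep, state$sheet$sample_id)]
        fit <- fit_elastic_net_clock(state$betas[, keep, drop = FALSE], ages,
                                     cfg, name = p$name %||% "trained_clock")
        state$clock <- fit$model
        write_clock(fit$model, file.path(out_dir, "clock.tsv"))
        jsonlite::write_json(fit$diagnostics,
                             file.path(out_dir, "train_diagnostics.json"),
                             auto_unbox = TRUE, digits = NA)
      },
      predict = {
        clocks <- if (!is.null(p$clock_files)) {
          lapply(p$clock_files, read_clock)
        } else list(state$clock)
        if (is.null(clocks[[1]])) stop("predict step needs a clock (train first or give clock_files)")
        test_ids <- if (!is.null(state$split)) {
          state$split$sample_id[state$split$assignment == "test"]
        } else colnames(state$betas)
        test_ids <- intersect(colnames(state$betas), test_ids)
        ds <- list(main = list(betas = state$betas[, test_ids, drop = FALSE],
                               sheet = state$sheet[match(test_ids, state$sheet$sample_id), ]))
        state$predictions <- batch_predict(ds, clocks,
                                           missing_policy = p$missing_policy %||% "fail")
        write_table(state$predictions, file.path(out_dir, "predictions.tsv"))
      },
      evaluate = {
        pr <- state$predictions
        if (is.null(pr)) stop("evaluate step needs predictions")
        reports <- lapply(split(pr, pr$clock_name), function(b) {
          rep1 <- accuracy(b$predicted_age_dpc, b$chronological_age_dpc)
          out <- list(n = rep1$n, pearson_r = rep1$pearson_r, rmse = rep1$rmse,
                      age_range_dpc = rep1$age_range_dpc)
          if (!is.null(p$max_dpc)) {
            rep2 <- range_restricted_accuracy(b$predicted_age_dpc,
                                              b$chronological_age_dpc, p$max_dpc)
            out$restricted <- list(n = rep2$n, pearson_r = rep2$pearson_r,
                                   rmse = rep2$rmse, max_dpc = p$max_dpc)
          }
          out
        })
        jsonlite::write_json(reports, file.path(out_dir, "evaluation.json"),
                             auto_unbox = TRUE, digits = NA)
      },
      compare_stages = {
        pr <- state$predictions
        if (is.null(pr)) stop("compare_stages step needs predictions")
        fit <- stage_meta_analysis(pr,
                                   stages = p$stages %||% c("iPSC", "NPC", "neuron"))
        jsonlite::write_json(
          list(fixed_effects = fit$fixed_effects,
               random_intercept_sd = fit$random_intercept_sd,
               residual_sd = fit$residual_sd, n = fit$n,
               n_datasets = fit$n_datasets, method = fit$method),
          file.path(out_dir, "stage_contrasts.json"),
          auto_unbox = TRUE, digits = NA)
      })
  }
  # parameter log is deliberately timestamp-free so reruns are bit-identical
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
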