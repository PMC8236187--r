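#' Specification for a synthetic age-structured methylation dataset
#'
#' Describes a simulated cohort of prenatal samples: ages drawn uniformly
#' on a fetal range, a subset of probes whose methylation tracks age
#' linearly on the logit scale, Gaussian logit-scale noise, matched
#' intensity matrices, and detection p-values with a configurable failure
#' rate. Defaults mirror a fetal training cohort: 200 samples, ages
#' 37–185 dpc, 2000 probes of which 50 are age-associated, logit noise
#' sd 0.02.
#'
#' Probe-level draws (which probes carry signal, their baselines and
#' slopes, design types) use `probe_seed`; sample-level draws (ages, sex,
#' noise, depths, detection failures) use `seed`, so probe truth can be
#' held fixed across replicates by varying only `seed`.
#'
#' @param n_samples,n_probes,n_age_probes cohort and panel sizes.
#' @param age_range_dpc length-2 numeric, uniform age range in dpc.
#' @param effect_scale typical absolute logit slope per dpc of an
#'   age probe; individual slopes are `sign * effect_scale * U(0.5, 1.5)`.
#' @param sd_logit Gaussian noise sd on the logit scale.
#' @param frac_type1 fraction of probes given Type I chemistry (the
#'   remainder Type II), roughly the 450K array share.
#' @param sex_slope_diff relative slope difference for male samples at
#'   age probes (0 = no sex effect).
#' @param detect_fail_rate probability a detection p-value is a failure
#'   (drawn U(0.05, 1) instead of U(0, 0.01)).
#' @param platform_masks optional named list of probe-id subsets
#'   emulating platform-specific panels; per-mask beta matrices are
#'   returned alongside the full data.
#' @param depth_meanlog,depth_sdlog lognormal total-intensity depth.
#' @param beta_offset offset used when deriving intensities from betas.
#' @param seed,probe_seed integer seeds (see Details).
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(n_samples = 200, n_probes = 2000,
                     n_age_probes = max(1L, round(0.025 * n_probes)),
                     age_range_dpc = c(37, 185), effect_scale = 0.01,
                     sd_logit = 0.02, frac_type1 = 0.28,
                     sex_slope_diff = 0, detect_fail_rate = 0.002,
                     platform_masks = NULL,
                     depth_meanlog = log(10000), depth_sdlog = 0.2,
                     beta_offset = 100, seed = 1, probe_seed = seed) {
  stopifnot(n_samples > 0, n_probes > 0, n_age_probes >= 0,
            n_age_probes <= n_probes, sd_logit > 0,
            length(age_range_dpc) == 2, age_range_dpc[1] < age_range_dpc[2])
  structure(as.list(environment()), class = "sim_spec")
}

#' Simulate an age-structured methylation dataset
#'
#' Generates a beta matrix, a matched intensity set, a sample sheet and a
#' ground-truth probe table under a [sim_spec()]. Age probes have
#' `logit(mean beta) = a_j + s_j * age`; observed betas are
#' `plogis(mean + N(0, sd_logit))`, so values always lie in (0, 1).
#' Intensities satisfy `beta = M / (M + U + beta_offset)` exactly:
#' `M = beta * T`, `U = (1 - beta) * T - beta_offset` with a per-cell
#' lognormal depth `T` (raised where needed to keep `U` non-negative).
#' Output is bit-reproducible for fixed seeds.
#'
#' @param spec a [sim_spec()].
#' @return list with `betas`, `intensities` (an [intensity_set()]),
#'   `sheet` (a [sample_sheet()]), `truth` (probe table: `probe_id`,
#'   `is_age_probe`, `baseline_logit`, `slope_logit_per_dpc`,
#'   `design_type`) and, when `platform_masks` is set, `platform_betas`.
#' @export
simulate_age_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  probe_ids <- sprintf("cg%07d", seq_len(spec$n_probes))
  sample_ids <- sprintf("S%03d", seq_len(spec$n_samples))

  # probe-level truth
  truth <- withr::with_seed(spec$probe_seed, {
    age_idx <- sort(sample.int(spec$n_probes, spec$n_age_probes))
    baseline <- stats::runif(spec$n_probes, -1.5, 1.5)
    slope <- numeric(spec$n_probes)
    slope[age_idx] <- sample(c(-1, 1), spec$n_age_probes, replace = TRUE) *
      spec$effect_scale * stats::runif(spec$n_age_probes, 0.5, 1.5)
    design <- sample(c("I", "II"), spec$n_probes, replace = TRUE,
                     prob = c(spec$frac_type1, 1 - spec$frac_type1))
    data.frame(probe_id = probe_ids,
               is_age_probe = seq_len(spec$n_probes) %in% age_idx,
               baseline_logit = baseline,
               slope_logit_per_dpc = slope,
               design_type = design,
               stringsAsFactors = FALSE)
  })

  sim <- withr::with_seed(spec$seed, {
    ages <- stats::runif(spec$n_samples, spec$age_range_dpc[1],
                         spec$age_range_dpc[2])
    sex <- sample(c("female", "male"), spec$n_samples, replace = TRUE)
    slope_mat <- outer(truth$slope_logit_per_dpc, ages)
    if (spec$sex_slope_diff != 0) {
      male <- sex == "male"
      slope_mat[, male] <- outer(
        truth$slope_logit_per_dpc * (1 + spec$sex_slope_diff), ages[male])
    }
    mu <- truth$baseline_logit + slope_mat
    eps <- matrix(stats::rnorm(spec$n_probes * spec$n_samples, 0, spec$sd_logit),
                  spec$n_probes, spec$n_samples)
    betas <- stats::plogis(mu + eps)
    depth <- matrix(stats::rlnorm(spec$n_probes * spec$n_samples,
                                  spec$depth_meanlog, spec$depth_sdlog),
                    spec$n_probes, spec$n_samples)
    # ensure (1-beta)*T >= beta_offset so U stays non-negative
    floor_T <- spec$beta_offset / pmax(1 - betas, 1e-12) + spec$beta_offset
    depth <- pmax(depth, floor_T)
    M <- betas * depth
    U <- (1 - betas) * depth - spec$beta_offset
    detp <- matrix(stats::runif(spec$n_probes * spec$n_samples, 0, 0.01),
                   spec$n_probes, spec$n_samples)
    fail <- matrix(stats::runif(spec$n_probes * spec$n_samples) <
                     spec$detect_fail_rate,
                   spec$n_probes, spec$n_samples)
    detp[fail] <- stats::runif(sum(fail), 0.05, 1)
    list(ages = ages, sex = sex, betas = betas, M = M, U = U, detp = detp)
  })

  dn <- list(probe_ids, sample_ids)
  dimnames(sim$betas) <- dn
  dimnames(sim$M) <- dn
  dimnames(sim$U) <- dn
  dimnames(sim$detp) <- dn

  sheet <- sample_sheet(sample_ids, age_value = sim$ages, age_unit = "dpc",
                        sex = sim$sex, dataset_id = "sim1",
                        group = "fetal_brain")
  out <- list(betas = beta_matrix(sim$betas),
              intensities = intensity_set(sim$M, sim$U, sim$detp),
              sheet = sheet,
              truth = truth)
  if (!is.null(spec$platform_masks)) {
    if (is.null(names(spec$platform_masks))) stop("platform_masks must be named")
    out$platform_betas <- lapply(spec$platform_masks, function(ids) {
      if (!all(ids %in% probe_ids)) stop("platform mask names unknown probes")
      out$betas[ids, , drop = FALSE]
    })
  }
  out
}

#' Specification for synthetic multi-dataset cell-stage predictions
#'
#' Emulates the pooled design of stem-cell differentiation studies:
#' several datasets, each contributing a subset of the iPSC/NPC/neuron
#' stages, with predicted epigenetic age generated as
#' `stage mean + dataset intercept + residual noise`. Default stage means
#' (75.6, 79.1, 83.2 dpc) and pooled group sizes (30 iPSC, 4 NPC, 48
#' neurons over 5 datasets) mirror a typical pooled iPSC-neuron design.
#'
#' @param n_datasets number of datasets (default 5).
#' @param stage_means named numeric, true mean predicted age per stage.
#' @param dataset_sd sd of the dataset random intercept (dpc).
#' @param residual_sd residual sd (dpc).
#' @param design optional list (length `n_datasets`) of named integer
#'   vectors giving per-dataset samples per stage; the default allocates
#'   one dataset with all three stages, one with iPSC+NPC, and the rest
#'   with iPSC+neuron, summing to 30/4/48.
#' @param seed integer seed.
#' @return list of class `cellstage_sim_spec`.
#' @export
cellstage_sim_spec <- function(n_datasets = 5,
                               stage_means = c(iPSC = 75.6, NPC = 79.1,
                                               neuron = 83.2),
                               dataset_sd = 5, residual_sd = 7,
                               design = NULL, seed = 1) {
  stopifnot(all(stage_means > 0), dataset_sd >= 0, residual_sd >= 0,
            n_datasets >= 1)
  if (is.null(design)) {
    design <- default_cellstage_design(n_datasets)
  }
  if (length(design) != n_datasets) stop("design length must equal n_datasets")
  structure(list(n_datasets = n_datasets, stage_means = stage_means,
                 dataset_sd = dataset_sd, residual_sd = residual_sd,
                 design = design, seed = as.integer(seed)),
            class = "cellstage_sim_spec")
}

default_cellstage_design <- function(n_datasets) {
  if (n_datasets == 5) {
    # pooled totals 30 iPSC / 4 NPC / 48 neurons
    list(ds1 = c(iPSC = 6, NPC = 2, neuron = 12),
         ds2 = c(iPSC = 6, NPC = 2),
         ds3 = c(iPSC = 6, neuron = 12),
         ds4 = c(iPSC = 6, neuron = 12),
         ds5 = c(iPSC = 6, neuron = 12))
  } else {
    stats::setNames(
      replicate(n_datasets, c(iPSC = 6, NPC = 2, neuron = 10),
                simplify = FALSE),
      paste0("ds", seq_len(n_datasets)))
  }
}

#' Simulate cell-stage prediction tables across datasets
#'
#' @param spec a [cellstage_sim_spec()].
#' @return data frame with `sample_id`, `dataset_id`, `group`,
#'   `predicted_age_dpc`; the generating parameters (including the drawn
#'   dataset intercepts) are attached as attribute `truth`.
#' @export
simulate_cellstage_datasets <- function(spec) {
  stopifnot(inherits(spec, "cellstage_sim_spec"))
  withr::with_seed(spec$seed, {
    intercepts <- stats::rnorm(spec$n_datasets, 0, spec$dataset_sd)
    rows <- list()
    k <- 0
    for (i in seq_len(spec$n_datasets)) {
      ds <- names(spec$design)[i]
      for (stg in names(spec$design[[i]])) {
        n <- spec$design[[i]][[stg]]
        if (n == 0) next
        y <- spec$stage_means[[stg]] + intercepts[i] +
          stats::rnorm(n, 0, spec$residual_sd)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("%s_%s_%02d", ds, stg, seq_len(n) + k),
          dataset_id = ds, group = stg, predicted_age_dpc = y,
          stringsAsFactors = FALSE)
        k <- k + n
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(stage_means = spec$stage_means,
                               dataset_sd = spec$dataset_sd,
                               residual_sd = spec$residual_sd,
                               dataset_intercepts = stats::setNames(
                                 intercepts, names(spec$design)))
    out
  })
}
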