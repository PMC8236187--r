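#' Training configuration for an elastic-net clock
#'
#' @param alpha elastic-net mixing parameter in \[0,1\]; 0 is ridge, 1 is
#'   lasso. Default 0.5, the usual choice for methylation clocks.
#' @param n_folds number of cross-validation folds (default 10).
#' @param lambda_grid optional descending vector of penalty strengths; if
#'   `NULL`, 100 log-spaced values from the data-derived `lambda_max` down
#'   to `1e-4 * lambda_max`.
#' @param lambda_rule `"min"` (CV-minimum, default) or `"one_se"`.
#' @param seed integer seed controlling fold assignment.
#' @param standardize standardize predictors internally (coefficients are
#'   always returned on the original beta scale).
#' @return list of class `train_config`.
#' @export
train_config <- function(alpha = 0.5, n_folds = 10, lambda_grid = NULL,
                         lambda_rule = c("min", "one_se"), seed = 1,
                         standardize = TRUE) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(alpha >= 0, alpha <= 1, n_folds >= 2)
  if (!is.null(lambda_grid)) {
    stopifnot(all(lambda_grid > 0), !is.unsorted(rev(lambda_grid)))
  }
  structure(list(alpha = alpha, n_folds = as.integer(n_folds),
                 lambda_grid = lambda_grid, lambda_rule = lambda_rule,
                 seed = as.integer(seed), standardize = isTRUE(standardize)),
            class = "train_config")
}

# deterministic fold assignment: shuffle sample indices under the seed,
# then deal round-robin so folds are balanced
make_foldid <- function(n, n_folds, seed) {
  withr::with_seed(seed, {
    perm <- sample.int(n)
    foldid <- integer(n)
    foldid[perm] <- rep_len(seq_len(n_folds), n)
    foldid
  })
}

#' Fit an elastic-net age clock with cross-validated penalty selection
#'
#' Regresses chronological age (dpc) on methylation beta values across all
#' probes, minimizing
#' \deqn{\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i^\top\beta)^2 +
#'   \lambda\left[\alpha\|\beta\|_1 + \frac{1-\alpha}{2}\|\beta\|_2^2\right]}
#' with the penalty strength chosen by k-fold cross-validation. The
#' returned clock carries the intercept and the nonzero coefficients on
#' the original beta scale, with `output_unit = "dpc"` and no transform.
#'
#' @param betas beta matrix (probes x samples) with no missing values;
#'   run [intersect_probes()] or [impute_missing()] first.
#' @param ages_dpc numeric vector of chronological ages in dpc, one per
#'   sample (column).
#' @param cfg a [train_config()].
#' @param name name for the returned clock.
#' @return list with `model` (a [clock_model()]) and `diagnostics`
#'   (lambda grid, per-lambda CV mean squared error and standard error,
#'   selected lambda, nonzero count, fold seed).
#' @export
fit_elastic_net_clock <- function(betas, ages_dpc, cfg = train_config(),
                                  name = "clock") {
  stopifnot(inherits(cfg, "train_config"))
  if (anyNA(betas)) stop("betas contain missing values; impute or intersect first")
  n <- ncol(betas)
  if (length(ages_dpc) != n) stop("ages_dpc length must equal number of samples")
  if (stats::var(ages_dpc) == 0) stop("constant age vector")
  if (n < cfg$n_folds) stop("fewer samples than CV folds")

  X <- t(betas)
  foldid <- make_foldid(n, cfg$n_folds, cfg$seed)
  cv_args <- list(x = X, y = ages_dpc, alpha = cfg$alpha, foldid = foldid,
                  standardize = cfg$standardize, family = "gaussian",
                  thresh = 1e-16, maxit = 10^7)
  if (is.null(cfg$lambda_grid)) {
    cv_args$nlambda <- 100
    cv_args$lambda.min.ratio <- 1e-4
  } else {
    cv_args$lambda <- cfg$lambda_grid
  }
  cvfit <- do.call(glmnet::cv.glmnet, cv_args)

  lambda <- switch(cfg$lambda_rule,
                   min = cvfit$lambda.min,
                   one_se = cvfit$lambda.1se)
  co <- stats::coef(cvfit, s = lambda)
  co <- stats::setNames(as.numeric(co), rownames(co))
  intercept <- unname(co["(Intercept)"])
  beta_co <- co[names(co) != "(Intercept)"]
  beta_co <- beta_co[beta_co != 0]

  model <- clock_model(
    name = name, intercept = intercept, coefficients = beta_co,
    output_unit = "dpc", transform = "identity",
    training = list(alpha = cfg$alpha, lambda = lambda, n_train = n,
                    age_range_dpc = range(ages_dpc)))
  diagnostics <- list(lambda_grid = cvfit$lambda,
                      cv_mse = cvfit$cvm, cv_se = cvfit$cvsd,
                      selected_lambda = lambda,
                      lambda_rule = cfg$lambda_rule,
                      n_nonzero = length(beta_co),
                      nonzero_path = cvfit$nzero,
                      fold_seed = cfg$seed)
  list(model = model, diagnostics = diagnostics)
}

#' Elastic-net coefficient path at fixed penalties (no cross-validation)
#'
#' Thin wrapper around the penalized solver used for diagnostics and
#' closed-form comparisons: fits the same objective as
#' [fit_elastic_net_clock()] along a supplied lambda sequence and returns
#' intercepts and dense coefficients per lambda.
#'
#' @param betas beta matrix (probes x samples), no missing values.
#' @param ages_dpc response vector (dpc).
#' @param alpha elastic-net mixing parameter.
#' @param lambda descending vector of penalty strengths.
#' @param standardize standardize predictors internally.
#' @return list with `lambda`, `intercepts` (one per lambda) and
#'   `coefficients` (probes x lambda matrix on the original scale).
#' @export
elastic_net_path <- function(betas, ages_dpc, alpha, lambda,
                             standardize = TRUE) {
  if (anyNA(betas)) stop("betas contain missing values")
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  X <- t(betas)
  # the solver needs >= 2 columns; pad single-probe input with a constant
  # column, which stays at zero under any positive penalty
  padded <- ncol(X) == 1
  if (padded) X <- cbind(X, `.pad.` = 0)
  fit <- glmnet::glmnet(X, ages_dpc, alpha = alpha, lambda = lambda,
                        standardize = standardize, family = "gaussian",
                        thresh = 1e-16, maxit = 10^7)
  co <- as.matrix(stats::coef(fit))
  co <- co[setdiff(rownames(co), if (padded) ".pad." else character(0)), ,
           drop = FALSE]
  list(lambda = fit$lambda,
       intercepts = unname(co["(Intercept)", ]),
       coefficients = co[rownames(co) != "(Intercept)", , drop = FALSE])
}

#' Maximal violation of the elastic-net stationarity conditions
#'
#' Solver-independent optimality check for a fitted (intercept, beta) at
#' penalty `lambda` and mixing `alpha`: with residual
#' `r = y - b0 - X beta`, a minimizer satisfies, coordinate-wise in the
#' (optionally standardized) predictor scale,
#' `|x_j' r / n| <= alpha * lambda` where `beta_j = 0`, and
#' `x_j' r / n = (1-alpha) * lambda * beta_j / s_y + alpha * lambda * sign(beta_j)`
#' where `beta_j != 0`, plus `mean(r) = 0` for the intercept. Returns the
#' largest absolute violation across all conditions (0 at an exact
#' optimum). When `standardize = TRUE` the conditions are evaluated in
#' standardized coordinates, which is where the penalty is applied.
#'
#' `s_y` is the population standard deviation of the response: gaussian
#' coordinate-descent solvers rescale the response to unit variance
#' before fitting and report `lambda` back on the original response
#' scale, which leaves the L1 conditions unchanged but gives the ridge
#' term an effective weight of `lambda * (1 - alpha) / s_y`. Set
#' `response_sd = 1` to check the textbook objective (exact when the
#' response was pre-standardized).
#'
#' @param betas probes x samples predictor matrix used in the fit.
#' @param ages_dpc response vector.
#' @param intercept,coefficients fitted intercept and named coefficient
#'   vector on the original scale (zero coefficients may be omitted).
#' @param lambda,alpha penalty strength and mixing of the fit.
#' @param standardize whether the fit standardized predictors.
#' @param response_sd scaling of the ridge term (see Details); default
#'   the population sd of `ages_dpc`.
#' @return maximal absolute violation (numeric scalar).
#' @export
en_kkt_violation <- function(betas, ages_dpc, intercept, coefficients,
                             lambda, alpha, standardize = TRUE,
                             response_sd = NULL) {
  X <- t(betas)
  n <- nrow(X)
  b <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (length(coefficients)) b[names(coefficients)] <- coefficients
  r <- ages_dpc - intercept - drop(X %*% b)

  if (standardize) {
    mu <- colMeans(X)
    sdev <- sqrt(colMeans(sweep(X, 2, mu)^2))  # population sd, the solver's scaling
    sdev[sdev == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
    bs <- b * sdev
  } else {
    Xs <- X
    bs <- b
  }
  if (is.null(response_sd)) {
    response_sd <- sqrt(mean((ages_dpc - mean(ages_dpc))^2))
  }
  g <- drop(crossprod(Xs, r)) / n
  active <- bs != 0
  v_zero <- if (any(!active)) max(pmax(abs(g[!active]) - alpha * lambda, 0)) else 0
  v_active <- if (any(active)) {
    max(abs(g[active] - (1 - alpha) * lambda * bs[active] / response_sd -
              alpha * lambda * sign(bs[active])))
  } else 0
  max(v_zero, v_active, abs(mean(r)))
}

#' Impute missing beta values
#'
#' @param betas beta matrix possibly containing `NA`.
#' @param strategy `"probe_mean"` replaces each missing cell with the
#'   probe's across-sample mean; `"fail"` raises on any missing value.
#' @return beta matrix without missing values.
#' @export
impute_missing <- function(betas, strategy = c("probe_mean", "fail")) {
  strategy <- match.arg(strategy)
  if (!anyNA(betas)) return(betas)
  if (strategy == "fail") stop("missing beta values present")
  all_missing <- rowSums(!is.na(betas)) == 0
  if (any(all_missing)) {
    stop("probe(s) entirely missing: ",
         paste(utils::head(rownames(betas)[all_missing], 5), collapse = ", "))
  }
  means <- rowMeans(betas, na.rm = TRUE)
  idx <- which(is.na(betas), arr.ind = TRUE)
  betas[idx] <- means[idx[, 1]]
  betas
}
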