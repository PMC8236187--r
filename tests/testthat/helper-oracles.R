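# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results from first principles (closed
# forms, textbook formulas) rather than calling the code paths they check.

# pooled-variance two-sample t-test, textbook formulas
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Tukey-Kramer adjusted p-values from group summaries and the
# studentized range distribution
tukey_oracle <- function(values, stage) {
  stage <- factor(stage)
  k <- nlevels(stage)
  ns <- tapply(values, stage, length)
  ms <- tapply(values, stage, mean)
  df <- length(values) - k
  mse <- sum(tapply(values, stage, function(v) sum((v - mean(v))^2))) / df
  out <- list()
  lv <- levels(stage)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    se <- sqrt(mse / 2 * (1 / ns[[i]] + 1 / ns[[j]]))
    q <- abs(ms[[j]] - ms[[i]]) / se
    out[[paste0(lv[j], "-", lv[i])]] <- unname(ptukey(q, k, df,
                                                      lower.tail = FALSE))
  }
  unlist(out)
}

# forward log-linear age transform, written out independently
forward_loglinear_oracle <- function(age, adult_age = 20) {
  if (age < adult_age) log(age + 1) - log(adult_age + 1)
  else (age - adult_age) / (adult_age + 1)
}

# small beta matrix with ids
tiny_betas <- function(values, probes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- probes %||% sprintf("cg%04d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("S%d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# annotation where every probe is Type II and unflagged
all_type2_annot <- function(probes) {
  probe_annotation(probes, design_type = rep("II", length(probes)))
}

# deterministic detection-p matrix: all passing except listed failures
detp_fixture <- function(n_probes, n_samples, failures = NULL, p_ok = 0.001,
                         p_bad = 0.2) {
  m <- matrix(p_ok, n_probes, n_samples,
              dimnames = list(sprintf("cg%04d", seq_len(n_probes)),
                              sprintf("S%d", seq_len(n_samples))))
  if (!is.null(failures)) m[failures] <- p_bad
  m
}
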