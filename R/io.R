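#' Read a probes x samples matrix from delimited text
#'
#' First column holds probe IDs, header row holds sample IDs. The delimiter
#' is auto-detected (tab or comma). Empty cells and `"NA"` are read as
#' missing. Row and column order are preserved exactly as in the file.
#'
#' @param path file path.
#' @param kind what the values are: `"beta"` (validated to \[0,1\]),
#'   `"intensity"` (validated non-negative) or `"detection_p"` (\[0,1\]).
#' @return numeric matrix with probe rownames and sample colnames; for
#'   `kind = "beta"` it passes [beta_matrix()] validation.
#' @export
read_matrix <- function(path, kind = c("beta", "intensity", "detection_p")) {
  kind <- match.arg(kind)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), comment.char = "",
                          colClasses = NA)
  if (ncol(df) < 2) stop("matrix file needs a probe id column plus >= 1 sample")
  probe_ids <- as.character(df[[1]])
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(probe_ids)) {
    stop("duplicate probe ids in ", path, ": ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in ", path)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- probe_ids
  colnames(m) <- sample_ids
  switch(kind,
    beta = beta_matrix(m),
    intensity = {
      if (any(m < 0, na.rm = TRUE)) stop("negative intensity in ", path)
      m
    },
    detection_p = {
      if (any(m < 0 | m > 1, na.rm = TRUE)) {
        stop("detection p-value outside [0,1] in ", path)
      }
      m
    })
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty file: ", path)
  n_tab <- lengths(regmatches(first, gregexpr("\t", first)))
  n_comma <- lengths(regmatches(first, gregexpr(",", first)))
  if (n_tab >= n_comma && n_tab > 0) "\t" else if (n_comma > 0) "," else "\t"
}

#' Write a probes x samples matrix as tab-delimited text
#'
#' Values are serialized at full double precision (`%.17g`) so a
#' read/write round trip is exact; missing values are written as `NA`.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param id_col name of the leading identifier column.
#' @export
write_matrix <- function(m, path, id_col = "probe_id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  header <- paste(c(id_col, colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a clock coefficient file
#'
#' The format is a two-column delimited table (term, coefficient) with a
#' reserved `(Intercept)` row, optionally preceded by metadata comment
#' lines `#name=`, `#output_unit=`, `#transform=`, `#adult_age=`.
#' Published supplementary coefficient tables reshape into this layout by
#' keeping the probe-ID and weight columns and adding the intercept row.
#' Zero-coefficient rows are dropped with a warning.
#'
#' @param path file path.
#' @return a [clock_model()].
#' @export
read_clock <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0) stop("clock file has no coefficient rows: ", path)
  sep <- if (grepl("\t", body[1])) "\t" else ","
  parts <- strsplit(body, sep, fixed = TRUE)
  if (any(lengths(parts) < 2)) stop("clock file rows need two columns (term, coefficient)")
  terms <- vapply(parts, `[[`, character(1), 1)
  vals <- vapply(parts, `[[`, character(1), 2)
  # tolerate a header row like "term,coefficient"
  if (is.na(suppressWarnings(as.numeric(vals[1])))) {
    terms <- terms[-1]; vals <- vals[-1]
  }
  coefs <- suppressWarnings(as.numeric(vals))
  if (anyNA(coefs)) stop("non-numeric coefficient in clock file: ", path)
  names(coefs) <- terms
  if (!"(Intercept)" %in% terms) stop("clock file lacks the '(Intercept)' row: ", path)
  intercept <- unname(coefs[["(Intercept)"]])
  coefs <- coefs[terms != "(Intercept)"]
  if (any(coefs == 0)) {
    warning(sum(coefs == 0), " zero-coefficient rows dropped from clock file")
    coefs <- coefs[coefs != 0]
  }
  tp <- list()
  if (!is.null(meta$adult_age)) tp$adult_age <- as.numeric(meta$adult_age)
  clock_model(name = meta$name %||% sub("\\.[^.]*$", "", basename(path)),
              intercept = intercept,
              coefficients = coefs,
              output_unit = meta$output_unit %||% "dpc",
              transform = meta$transform %||% "identity",
              transform_params = tp)
}

#' Write a clock model to a coefficient file
#'
#' Inverse of [read_clock()]: metadata as `#key=value` lines followed by a
#' tab-delimited term/coefficient table at full double precision, so that
#' `read_clock(write_clock(m))` reproduces `m` bit for bit.
#'
#' @param model a [clock_model()] with at least one nonzero coefficient.
#' @param path output path.
#' @export
write_clock <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  if (length(model$coefficients) == 0) {
    stop("refusing to write an intercept-only clock (no coefficients)")
  }
  meta <- c(sprintf("#name=%s", model$name),
            sprintf("#output_unit=%s", model$output_unit),
            sprintf("#transform=%s", model$transform))
  if (model$transform == "horvath_log_linear") {
    meta <- c(meta, sprintf("#adult_age=%.17g", model$transform_params$adult_age))
  }
  rows <- c(sprintf("(Intercept)\t%.17g", model$intercept),
            sprintf("%s\t%.17g", names(model$coefficients), model$coefficients))
  writeLines(c(meta, rows), path)
  invisible(path)
}

#' Read a sample sheet CSV
#'
#' Requires columns `sample_id`, `age_value`, `age_unit`, `sex`,
#' `dataset_id`, `group`; extra columns are preserved.
#'
#' @param path CSV (or TSV) path.
#' @return a validated [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("sample_id", "age_value", "age_unit", "sex", "dataset_id", "group")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols)) {
    stop("sample sheet lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- sample_sheet(df$sample_id, df$age_value, df$age_unit, df$sex,
                      df$dataset_id, df$group)
  extra <- setdiff(colnames(df), c(need, "chronological_age_dpc"))
  for (cl in extra) out[[cl]] <- df[[cl]]
  out
}

#' Write a data frame as delimited text at full numeric precision
#'
#' @param df data frame.
#' @param path output path.
#' @param sep field separator.
#' @export
write_table <- function(df, path, sep = "\t") {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.double(df2[[j]])) {
      df2[[j]] <- ifelse(is.na(df2[[j]]), "NA", sprintf("%.17g", df2[[j]]))
    }
  }
  utils::write.table(df2, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
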