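## Delimited-text I/O for methylation matrices, phenotype tables and results.

.read_delim_chr <- function(path, dialect) {
  if (!file.exists(path))
    spike_error(sprintf("file not found: %s", path), "spike_io_error")
  sep <- if (dialect == "tsv") "\t" else ","
  dt <- tryCatch(
    data.table::fread(path, sep = sep, header = TRUE, colClasses = "character",
                      na.strings = NULL, data.table = FALSE,
                      check.names = FALSE),
    error = function(e) spike_error(sprintf("cannot parse %s: %s",
                                            path, conditionMessage(e)),
                                    "spike_parse_error"))
  if (ncol(dt) < 2L)
    spike_error(sprintf("%s: expected at least an identifier column and one data column",
                        path), "spike_parse_error")
  dt
}

.as_numeric_col <- function(cells, missing_tokens) {
  is_miss <- cells %in% missing_tokens
  num <- suppressWarnings(as.numeric(cells))
  num[is_miss] <- NA_real_
  list(num = num, bad = which(is.na(num) & !is_miss))
}

#' Read a methylation matrix from delimited text
#'
#' Expects the layout of ArrayExpress "processed" files: the first row holds
#' sample identifiers, the first column CpG identifiers, the remaining cells
#' numeric methylation values. Cells equal to a missing token are recorded as
#' `NA` (never as zero).
#'
#' @param path path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param scale value scale of the file, `"m"` or `"beta"`.
#' @param missing_tokens character vector of cell values treated as missing.
#' @return A [methylation_matrix()].
#' @export
read_methylation_matrix <- function(path, dialect = c("tsv", "csv"),
                                    scale = c("m", "beta"),
                                    missing_tokens = c("NA", "")) {
  dialect <- match.arg(dialect)
  scale <- match.arg(scale)
  dt <- .read_delim_chr(path, dialect)
  cpg_ids <- dt[[1L]]
  sample_ids <- colnames(dt)[-1L]
  if (anyDuplicated(cpg_ids))
    spike_error(sprintf("%s: duplicate CpG identifier(s): %s", path,
                        paste(unique(cpg_ids[duplicated(cpg_ids)]),
                              collapse = ", ")),
                "spike_identifier_error")
  if (anyDuplicated(sample_ids))
    spike_error(sprintf("%s: duplicate sample identifier(s): %s", path,
                        paste(unique(sample_ids[duplicated(sample_ids)]),
                              collapse = ", ")),
                "spike_identifier_error")
  vals <- matrix(NA_real_, nrow = length(cpg_ids), ncol = length(sample_ids),
                 dimnames = list(cpg_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- .as_numeric_col(dt[[j + 1L]], missing_tokens)
    if (length(col$bad)) {
      i <- col$bad[1L]
      spike_error(sprintf(
        "%s: non-numeric value '%s' at row %d (CpG '%s'), column '%s'",
        path, dt[[j + 1L]][i], i, cpg_ids[i], sample_ids[j]),
        "spike_parse_error")
    }
    vals[, j] <- col$num
  }
  methylation_matrix(vals, scale = scale)
}

#' Read a covariate from a phenotype table
#'
#' @param path path to a delimited phenotype table with one row per sample.
#' @param sample_col name of the column holding sample identifiers.
#' @param covariate_col name of the column holding the continuous covariate
#'   (for example smoking pack years).
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A [covariate_vector()], rows in file order.
#' @export
read_covariate_table <- function(path, sample_col, covariate_col,
                                 dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  dt <- .read_delim_chr(path, dialect)
  for (col in c(sample_col, covariate_col))
    if (!col %in% colnames(dt))
      spike_error(sprintf("%s: column '%s' not found (columns: %s)", path, col,
                          paste(colnames(dt), collapse = ", ")),
                  "spike_config_error")
  ids <- dt[[sample_col]]
  if (anyDuplicated(ids))
    spike_error(sprintf("%s: duplicate sample identifier(s): %s", path,
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                "spike_identifier_error")
  col <- .as_numeric_col(dt[[covariate_col]], character(0))
  if (length(col$bad)) {
    i <- col$bad[1L]
    spike_error(sprintf("%s: non-numeric covariate '%s' at row %d (sample '%s')",
                        path, dt[[covariate_col]][i], i, ids[i]),
                "spike_parse_error")
  }
  covariate_vector(col$num, ids)
}

#' Align a methylation matrix and a covariate on shared samples
#'
#' Restricts both inputs to the intersection of their sample identifiers, in
#' the matrix's column order, and reports what was dropped on each side.
#' Idempotent: aligning already-aligned inputs changes nothing.
#'
#' @param mat a [methylation_matrix()].
#' @param cov a [covariate_vector()].
#' @return A list with elements `matrix`, `covariate` and
#'   `dropped = list(matrix = ..., covariate = ...)`.
#' @export
align_samples <- function(mat, cov) {
  mat_ids <- colnames(mat)
  cov_ids <- names(cov)
  common <- intersect(mat_ids, cov_ids)
  if (length(common) == 0L)
    spike_error("no shared sample identifiers between matrix and covariate",
                "spike_alignment_error")
  list(
    matrix = methylation_matrix(unclass(mat)[, common, drop = FALSE],
                                scale = value_scale(mat)),
    covariate = covariate_vector(as.numeric(cov)[match(common, cov_ids)],
                                 common),
    dropped = list(matrix = setdiff(mat_ids, common),
                   covariate = setdiff(cov_ids, common))
  )
}

#' Convert beta-values to M-values
#'
#' \eqn{M = \log_2(\beta / (1 - \beta))}, with \eqn{\beta} clamped to
#' `[epsilon, 1 - epsilon]` so the boundary values 0 and 1 map to finite
#' M-values. Strictly increasing on (0, 1) and antisymmetric around 0.5.
#'
#' @param beta numeric vector of beta-values in \[0, 1\] (`NA` passed through).
#' @param epsilon small positive clamp; default `1e-6`.
#' @return M-values, same shape as `beta`.
#' @examples
#' beta_to_m(c(0.5, 0.8))  # 0, 2
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  if (!is.numeric(beta))
    spike_error("'beta' must be numeric", "spike_input_error")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0 ||
      epsilon >= 0.5)
    spike_error("'epsilon' must be a single number in (0, 0.5)",
                "spike_config_error")
  fin <- beta[is.finite(beta)]
  if (length(fin) && (min(fin) < 0 || max(fin) > 1))
    spike_error("beta-values must lie in [0, 1]", "spike_domain_error")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' Ensure a methylation matrix is on the M-value scale
#'
#' @param mat a [methylation_matrix()].
#' @param epsilon clamp passed to [beta_to_m()] for beta-scale input.
#' @return The matrix on the M-value scale (unchanged when already there).
#' @export
as_m_values <- function(mat, epsilon = 1e-6) {
  if (!inherits(mat, "methyl_matrix"))
    spike_error("'mat' must be a methyl_matrix", "spike_input_error")
  if (value_scale(mat) == "m") return(mat)
  v <- unclass(mat)
  out <- matrix(beta_to_m(as.numeric(v), epsilon = epsilon),
                nrow = nrow(v), dimnames = dimnames(v))
  methylation_matrix(out, scale = "m")
}

.results_numeric_cols <- c("slope_nonspike", "slope_pvalue", "q1", "q3",
                           "pred_at_spike", "slope_all", "slope_deviation")

.fmt_num <- function(x, digits) {
  out <- formatC(x, digits = digits, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}

#' Write the per-CpG results table
#'
#' One row per classified CpG with the columns `cpg_id`, `n_spike`,
#' `n_nonspike`, `slope_nonspike`, `slope_pvalue`, `phi`, `q1`, `q3`,
#' `pred_at_spike`, `category`, `slope_all`, `slope_deviation`. Numbers are
#' serialized with `digits` significant digits; [read_results_table()]
#' reproduces them to that precision.
#'
#' @param results a `spike_detection` object from [detect_all()] or its
#'   `results` data frame.
#' @param path output path (TSV).
#' @param digits significant digits used for serialization; default 10.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path, digits = 10L) {
  df <- if (inherits(results, "spike_detection")) results$results else results
  if (!is.data.frame(df) || nrow(df) == 0L)
    spike_error("'results' must contain at least one classified CpG",
                "spike_input_error")
  out <- df
  for (col in intersect(.results_numeric_cols, colnames(out)))
    out[[col]] <- .fmt_num(df[[col]], digits)
  .write_tsv(out, path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path path to the TSV.
#' @return A data frame.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path))
    spike_error(sprintf("file not found: %s", path), "spike_io_error")
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                    check.names = FALSE)
}

.write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    spike_error(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
                "spike_io_error")
  invisible(path)
}
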