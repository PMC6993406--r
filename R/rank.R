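#' Slope deviation between the with-spike and without-spike fits
#'
#' Fits two regressions of M-values on the covariate — one on all samples,
#' one excluding the spike group — and returns both slopes and the absolute
#' difference between them, the ranking statistic for suspicious CpGs.
#'
#' @param m numeric vector of M-values.
#' @param x numeric covariate vector, same length.
#' @param spike_idx integer indices of the spike samples.
#' @param nonspike_idx integer indices of the non-spike samples.
#' @return A list `slope_all`, `slope_nonspike`, `deviation`.
#' @export
dual_fit_deviation <- function(m, x, spike_idx, nonspike_idx) {
  if (length(m) != length(x))
    spike_error("'m' and 'x' must have the same length", "spike_input_error")
  if (length(spike_idx) == 0L)
    spike_error("spike index set is empty", "spike_insufficient_error")
  fit_ns <- fit_ols(x[nonspike_idx], m[nonspike_idx])
  all_idx <- c(spike_idx, nonspike_idx)
  fit_all <- fit_ols(x[all_idx], m[all_idx])
  list(slope_all = fit_all$beta1, slope_nonspike = fit_ns$beta1,
       deviation = abs(fit_all$beta1 - fit_ns$beta1))
}

#' Rank suspicious CpGs by slope deviation
#'
#' Filters the detection results to the requested categories (by default the
#' suspicious ones, `RNN` and `RPN`), sorts by `slope_deviation` in
#' decreasing order with ties broken by CpG identifier, and returns the top
#' `k` for visual inspection.
#'
#' @param results a `spike_detection` object or its `results` data frame.
#' @param categories category labels to keep; default `c("RNN", "RPN")`.
#' @param k maximum number of CpGs returned; default 6.
#' @return A data frame `rank`, `cpg_id`, `category`, `slope_all`,
#'   `slope_nonspike`, `slope_deviation`, `signed_deviation` (the raw
#'   `slope_all - slope_nonspike`).
#' @export
rank_suspicious <- function(results, categories = c("RNN", "RPN"), k = 6L) {
  df <- if (inherits(results, "spike_detection")) results$results else results
  k <- as.integer(k)
  if (is.na(k) || k < 1L)
    spike_error("'k' must be a positive integer", "spike_config_error")
  bad <- setdiff(categories, spike_categories())
  if (length(bad))
    spike_error(sprintf("unknown category label(s): %s",
                        paste(bad, collapse = ", ")),
                "spike_config_error")
  df <- df[df$category %in% categories, , drop = FALSE]
  df <- df[order(-df$slope_deviation, df$cpg_id), , drop = FALSE]
  df <- utils::head(df, k)
  out <- data.frame(
    rank = seq_len(nrow(df)),
    cpg_id = df$cpg_id,
    category = df$category,
    slope_all = df$slope_all,
    slope_nonspike = df$slope_nonspike,
    slope_deviation = df$slope_deviation,
    signed_deviation = df$slope_all - df$slope_nonspike)
  rownames(out) <- NULL
  out
}

#' Export plot-ready data for ranked CpGs
#'
#' Writes a long-format TSV with everything needed to redraw the inspection
#' panels (scatter of M-values over the covariate with both regression
#' lines): per ranked CpG, one `record = "sample"` row per sample
#' (`sample_id`, `x`, `m`, `is_spike`) and two `record = "line"` rows with
#' the intercept and slope of the all-samples and non-spike fits.
#'
#' @param ranked output of [rank_suspicious()].
#' @param mat the aligned [methylation_matrix()] (M- or beta-scale).
#' @param cov the aligned [covariate_vector()].
#' @param spec the [spike_spec()] used for detection.
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
export_plot_data <- function(ranked, mat, cov, spec, path) {
  if (!is.data.frame(ranked) || nrow(ranked) == 0L)
    spike_error("'ranked' must be a non-empty ranking table",
                "spike_input_error")
  if (!identical(colnames(mat), names(cov)))
    spike_error("matrix and covariate sample identifiers do not match",
                "spike_alignment_error")
  missing <- setdiff(ranked$cpg_id, rownames(mat))
  if (length(missing))
    spike_error(sprintf("CpG identifier(s) not found in matrix: %s",
                        paste(missing, collapse = ", ")),
                "spike_lookup_error")
  mat <- as_m_values(mat)
  vals <- unclass(mat)
  x <- as.numeric(cov)
  idx <- split_spike(cov, spec)
  is_spike <- seq_along(x) %in% idx$spike

  rows <- vector("list", nrow(ranked))
  for (r in seq_len(nrow(ranked))) {
    cg <- ranked$cpg_id[r]
    y <- vals[cg, ]
    ok_ns <- idx$nonspike[is.finite(y[idx$nonspike])]
    ok_sp <- idx$spike[is.finite(y[idx$spike])]
    fit_ns <- fit_ols(x[ok_ns], y[ok_ns])
    fit_all <- fit_ols(x[c(ok_sp, ok_ns)], y[c(ok_sp, ok_ns)])
    samples <- data.frame(
      cpg_id = cg, rank = ranked$rank[r], record = "sample",
      sample_id = names(cov), x = x, m = as.numeric(y),
      is_spike = is_spike, fit = NA_character_,
      intercept = NA_real_, slope = NA_real_)
    lines <- data.frame(
      cpg_id = cg, rank = ranked$rank[r], record = "line",
      sample_id = NA_character_, x = NA_real_, m = NA_real_,
      is_spike = NA, fit = c("all", "nonspike"),
      intercept = c(fit_all$beta0, fit_ns$beta0),
      slope = c(fit_all$beta1, fit_ns$beta1))
    rows[[r]] <- rbind(samples, lines)
  }
  .write_tsv(do.call(rbind, rows), path)
}
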