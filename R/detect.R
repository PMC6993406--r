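#' Split samples into spike and non-spike groups
#'
#' @param cov a [covariate_vector()].
#' @param spec a [spike_spec()].
#' @return A list with integer index vectors `spike` and `nonspike`
#'   (disjoint and exhaustive). Empty groups are allowed here; group-size
#'   requirements are enforced by [detect_all()].
#' @export
split_spike <- function(cov, spec) {
  if (!inherits(spec, "spike_spec"))
    spike_error("'spec' must be a spike_spec", "spike_input_error")
  x <- as.numeric(cov)
  if (length(x) == 0L)
    spike_error("empty covariate", "spike_input_error")
  in_spike <- if (spec$membership == "equal") {
    x == spec$position
  } else if (spec$side == "left") {
    x <= spec$position
  } else {
    x >= spec$position
  }
  list(spike = which(in_spike), nonspike = which(!in_spike))
}

#' Trend decision for the non-spike samples
#'
#' Returns the linear (clinical) effect phi of the covariate: the sign of the
#' fitted slope when the slope is significant at `params$alpha` AND its
#' absolute value reaches `params$clinical_threshold`; 0 otherwise.
#'
#' @param fit an `ols_fit` on the non-spike samples.
#' @param params a [detection_params()].
#' @return Integer, one of -1, 0, +1.
#' @export
determine_phi <- function(fit, params = detection_params()) {
  if (!inherits(fit, "ols_fit"))
    spike_error("'fit' must be an ols_fit", "spike_input_error")
  if (fit$pvalue < params$alpha && abs(fit$beta1) >= params$clinical_threshold)
    as.integer(sign(fit$beta1))
  else
    0L
}

#' Tolerance band of the spike-group methylation values
#'
#' The band the regression's prediction at the spike position is compared
#' against: `q1 = mean - 2 * sd` and `q3 = mean + 2 * sd` of the spike-group
#' M-values (sample standard deviation, n - 1 denominator).
#'
#' @param m_spike numeric vector of spike-group M-values (non-finite values
#'   dropped); at least 2 are required.
#' @return A `spike_band` list: `mean_spike`, `sd_spike`, `q1`, `q3`,
#'   `n_spike`.
#' @export
spike_band <- function(m_spike) {
  m <- as.numeric(m_spike)
  m <- m[is.finite(m)]
  if (length(m) < 2L)
    spike_error(sprintf(
      "need at least 2 spike-group values for the band, got %d", length(m)),
      "spike_insufficient_error")
  mu <- mean(m)
  s <- stats::sd(m)
  structure(list(mean_spike = mu, sd_spike = s,
                 q1 = mu - 2 * s, q3 = mu + 2 * s, n_spike = length(m)),
            class = "spike_band")
}

## The decision table shared by both sides. "Suspicious" means the prediction
## of the non-spike regression at the spike position falls strictly outside
## the band on the side that opposes the trend; ties on the band edge are not
## suspicious.
.classify <- function(phi, pred, band, side) {
  if (phi == 0L) return("NoLinearTrend")
  if (side == "left") {
    if (phi > 0L) {
      if (pred < band$q1) "RNN" else "PLT"
    } else {
      if (pred > band$q3) "RPN" else "NLT"
    }
  } else {
    if (phi > 0L) {
      if (pred > band$q3) "RNN" else "PLT"
    } else {
      if (pred < band$q1) "RPN" else "NLT"
    }
  }
}

#' Classify one CpG against a spike at the left
#'
#' Combines the trend decision phi with the spike band: for phi = +1 the CpG
#' is suspicious (`RNN`) when the regression's prediction at the spike
#' position lies strictly below `q1`, otherwise a plain positive linear
#' trend (`PLT`); for phi = -1 it is suspicious (`RPN`) when the prediction
#' lies strictly above `q3`, otherwise `NLT`; phi = 0 gives
#' `NoLinearTrend`. At the usual left position 0 the prediction is the
#' intercept of the non-spike regression.
#'
#' @param fit_nonspike `ols_fit` on the non-spike samples.
#' @param band a [spike_band()].
#' @param spec a [spike_spec()] with `side == "left"`.
#' @param params a [detection_params()].
#' @return A category label (see [spike_categories()]).
#' @export
classify_left <- function(fit_nonspike, band, spec,
                          params = detection_params()) {
  if (!inherits(spec, "spike_spec") || spec$side != "left")
    spike_error("classify_left() requires a spike_spec with side = \"left\"",
                "spike_config_error")
  phi <- determine_phi(fit_nonspike, params)
  .classify(phi, predict_at(fit_nonspike, spec$position), band, "left")
}

#' Classify one CpG against a spike at the right
#'
#' The decision rules of [classify_left()] with the band comparisons
#' swapped: a rising trend extrapolated above the band (`pred > q3`) means
#' the spike pulls the slope down (`RNN`); a falling trend extrapolated
#' below the band (`pred < q1`) means the spike pulls it up (`RPN`).
#'
#' @inheritParams classify_left
#' @param spec a [spike_spec()] with `side == "right"`.
#' @return A category label (see [spike_categories()]).
#' @export
classify_right <- function(fit_nonspike, band, spec,
                           params = detection_params()) {
  if (!inherits(spec, "spike_spec") || spec$side != "right")
    spike_error("classify_right() requires a spike_spec with side = \"right\"",
                "spike_config_error")
  phi <- determine_phi(fit_nonspike, params)
  .classify(phi, predict_at(fit_nonspike, spec$position), band, "right")
}

#' Run the spike-interaction screen on every CpG
#'
#' For each CpG: fit the non-spike regression, decide the trend phi, build
#' the spike band, classify the CpG, and additionally fit the pooled
#' (spike + non-spike) regression to obtain the slope deviation used for
#' ranking. Missing values are handled per CpG with pairwise-complete
#' samples; CpGs with too little complete data are reported in a skip list
#' with a reason, never silently dropped. Beta-scale input is converted to
#' M-values first.
#'
#' @param mat a [methylation_matrix()], samples aligned with `cov` (see
#'   [align_samples()]).
#' @param cov a [covariate_vector()] in the same sample order.
#' @param spec a [spike_spec()].
#' @param params a [detection_params()].
#' @return A `spike_detection` list:
#'   `results` — data frame with one row per classified CpG (columns
#'   `cpg_id`, `n_spike`, `n_nonspike`, `slope_nonspike`, `slope_pvalue`,
#'   `phi`, `q1`, `q3`, `pred_at_spike`, `category`, `slope_all`,
#'   `slope_deviation`);
#'   `skipped` — data frame `cpg_id`, `reason`;
#'   plus the `spec`, `params` and overall group sizes.
#' @export
detect_all <- function(mat, cov, spec, params = detection_params()) {
  if (!inherits(mat, "methyl_matrix"))
    spike_error("'mat' must be a methyl_matrix", "spike_input_error")
  if (!inherits(cov, "covariate_vector"))
    spike_error("'cov' must be a covariate_vector", "spike_input_error")
  if (!identical(colnames(mat), names(cov)))
    spike_error(paste("matrix and covariate sample identifiers do not match;",
                      "run align_samples() first"),
                "spike_alignment_error")
  if (!inherits(params, "detection_params"))
    spike_error("'params' must be detection_params", "spike_input_error")
  mat <- as_m_values(mat)
  x <- as.numeric(cov)
  idx <- split_spike(cov, spec)
  if (length(idx$spike) < params$min_spike_n)
    spike_error(sprintf("spike group has %d sample(s); need at least %d",
                        length(idx$spike), params$min_spike_n),
                "spike_config_error")
  if (length(idx$nonspike) < params$min_nonspike_n)
    spike_error(sprintf("non-spike group has %d sample(s); need at least %d",
                        length(idx$nonspike), params$min_nonspike_n),
                "spike_config_error")

  vals <- unclass(mat)
  n_cpg <- nrow(vals)
  cpg_ids <- rownames(vals)
  x_sp <- x[idx$spike]
  x_ns <- x[idx$nonspike]

  res <- vector("list", n_cpg)
  skip <- vector("list", n_cpg)
  for (i in seq_len(n_cpg)) {
    y <- vals[i, ]
    y_sp <- y[idx$spike]
    y_ns <- y[idx$nonspike]
    ok_sp <- is.finite(y_sp)
    ok_ns <- is.finite(y_ns)
    if (sum(ok_sp) < params$min_spike_n) {
      skip[[i]] <- data.frame(cpg_id = cpg_ids[i],
                              reason = sprintf(
                                "only %d complete spike value(s), need %d",
                                sum(ok_sp), params$min_spike_n))
      next
    }
    if (sum(ok_ns) < params$min_nonspike_n) {
      skip[[i]] <- data.frame(cpg_id = cpg_ids[i],
                              reason = sprintf(
                                "only %d complete non-spike value(s), need %d",
                                sum(ok_ns), params$min_nonspike_n))
      next
    }
    xn <- x_ns[ok_ns]
    if (max(xn) == min(xn)) {
      skip[[i]] <- data.frame(cpg_id = cpg_ids[i],
                              reason = "constant covariate among complete non-spike samples")
      next
    }
    fit_ns <- fit_ols(xn, y_ns[ok_ns])
    band <- spike_band(y_sp[ok_sp])
    phi <- determine_phi(fit_ns, params)
    pred <- predict_at(fit_ns, spec$position)
    category <- .classify(phi, pred, band, spec$side)
    fit_all <- fit_ols(c(x_sp[ok_sp], xn), c(y_sp[ok_sp], y_ns[ok_ns]))
    res[[i]] <- data.frame(
      cpg_id = cpg_ids[i],
      n_spike = sum(ok_sp),
      n_nonspike = sum(ok_ns),
      slope_nonspike = fit_ns$beta1,
      slope_pvalue = fit_ns$pvalue,
      phi = phi,
      q1 = band$q1,
      q3 = band$q3,
      pred_at_spike = pred,
      category = category,
      slope_all = fit_all$beta1,
      slope_deviation = abs(fit_all$beta1 - fit_ns$beta1))
  }
  results <- do.call(rbind, res[!vapply(res, is.null, logical(1L))])
  skipped <- do.call(rbind, skip[!vapply(skip, is.null, logical(1L))])
  if (is.null(results))
    results <- data.frame(cpg_id = character(0), n_spike = integer(0),
                          n_nonspike = integer(0), slope_nonspike = numeric(0),
                          slope_pvalue = numeric(0), phi = integer(0),
                          q1 = numeric(0), q3 = numeric(0),
                          pred_at_spike = numeric(0), category = character(0),
                          slope_all = numeric(0), slope_deviation = numeric(0))
  if (is.null(skipped))
    skipped <- data.frame(cpg_id = character(0), reason = character(0))
  rownames(results) <- NULL
  rownames(skipped) <- NULL
  structure(list(results = results, skipped = skipped, spec = spec,
                 params = params, n_spike = length(idx$spike),
                 n_nonspike = length(idx$nonspike)),
            class = "spike_detection")
}

#' @export
print.spike_detection <- function(x, ...) {
  cat(sprintf(
    "spike_detection: %d CpG(s) classified, %d skipped (spike %s at %g, %d spike / %d non-spike samples)\n",
    nrow(x$results), nrow(x$skipped), x$spec$side, x$spec$position,
    x$n_spike, x$n_nonspike))
  print(summarize_categories(x))
  invisible(x)
}

#' Count CpGs per category
#'
#' @param results a `spike_detection` object or its `results` data frame.
#' @return A data frame `category`, `count` with the five categories in the
#'   fixed order `NLT`, `NoLinearTrend`, `PLT`, `RNN`, `RPN`; counts sum to
#'   the number of classified CpGs (skipped CpGs are reported separately in
#'   the skip list).
#' @export
summarize_categories <- function(results) {
  df <- if (inherits(results, "spike_detection")) results$results else results
  lev <- spike_categories()
  counts <- table(factor(df$category, levels = lev))
  data.frame(category = lev, count = as.integer(counts))
}
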