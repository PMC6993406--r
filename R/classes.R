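#' Construct a methylation matrix
#'
#' A light wrapper around a numeric matrix with CpG sites in rows and samples
#' in columns. Values are either M-values (unbounded,
#' \eqn{M = \log_2(\beta/(1-\beta))}) or beta-values (methylated fraction in
#' \[0, 1\]); the scale travels with the object so downstream steps can
#' convert automatically.
#'
#' @param values numeric matrix, CpGs in rows, samples in columns; `dimnames`
#'   must hold unique CpG and sample identifiers.
#' @param scale `"m"` or `"beta"`.
#' @return A `methyl_matrix`: the matrix with a `value_scale` attribute.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("cg1", "cg2"), c("s1", "s2", "s3")))
#' methylation_matrix(m, scale = "m")
#' @export
methylation_matrix <- function(values, scale = c("m", "beta")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    spike_error("'values' must be a numeric matrix", "spike_input_error")
  cpg <- rownames(values)
  smp <- colnames(values)
  if (is.null(cpg) || is.null(smp))
    spike_error("matrix must carry CpG rownames and sample colnames",
                "spike_identifier_error")
  if (anyDuplicated(cpg))
    spike_error(sprintf("duplicate CpG identifier(s): %s",
                        paste(unique(cpg[duplicated(cpg)]), collapse = ", ")),
                "spike_identifier_error")
  if (anyDuplicated(smp))
    spike_error(sprintf("duplicate sample identifier(s): %s",
                        paste(unique(smp[duplicated(smp)]), collapse = ", ")),
                "spike_identifier_error")
  if (scale == "beta") {
    v <- values[is.finite(values)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      spike_error("beta-values must lie in [0, 1]", "spike_domain_error")
  }
  structure(values, value_scale = scale, class = c("methyl_matrix", "matrix"))
}

#' @export
print.methyl_matrix <- function(x, ...) {
  cat(sprintf("methyl_matrix: %d CpG site(s) x %d sample(s), %s-values\n",
              nrow(x), ncol(x), attr(x, "value_scale")))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE], 4L))
  invisible(x)
}

#' @rdname methylation_matrix
#' @param x a `methyl_matrix`.
#' @export
value_scale <- function(x) attr(x, "value_scale") %||% "m"

#' Construct a covariate vector
#'
#' The continuous covariate of interest (for example smoking pack years),
#' keyed by sample identifier.
#'
#' @param x numeric vector of finite covariate values.
#' @param sample_ids character vector of unique sample identifiers,
#'   same length as `x`. Taken from `names(x)` when omitted.
#' @return A named numeric vector of class `covariate_vector`.
#' @export
covariate_vector <- function(x, sample_ids = names(x)) {
  if (is.null(sample_ids))
    spike_error("sample identifiers are required", "spike_identifier_error")
  if (length(sample_ids) != length(x))
    spike_error("covariate and sample identifiers differ in length",
                "spike_input_error")
  if (anyDuplicated(sample_ids))
    spike_error(sprintf("duplicate sample identifier(s): %s",
                        paste(unique(sample_ids[duplicated(sample_ids)]),
                              collapse = ", ")),
                "spike_identifier_error")
  x <- as.numeric(x)
  if (any(!is.finite(x)))
    spike_error("covariate values must be finite", "spike_parse_error")
  structure(stats::setNames(x, sample_ids),
            class = c("covariate_vector", "numeric"))
}

#' @export
print.covariate_vector <- function(x, ...) {
  cat(sprintf("covariate_vector: %d sample(s), range [%g, %g]\n",
              length(x), min(x), max(x)))
  print(utils::head(stats::setNames(as.numeric(x), names(x))))
  invisible(x)
}

#' Specify the covariate spike
#'
#' Defines which samples form the spike: the side of the distribution the
#' point mass sits on, its position in covariate units, and the membership
#' rule. With `membership = "equal"` only samples exactly at the position
#' belong to the spike (the usual spike-at-zero case); with `"at_or_beyond"`
#' all samples at or beyond the position belong to it (`x <= position` for a
#' left spike, `x >= position` for a right spike — a clumped boundary
#' category such as "heavy smoker").
#'
#' @param side `"left"` or `"right"`.
#' @param position spike position in covariate units. Defaults to 0 for a
#'   left spike; must be supplied for a right spike.
#' @param membership `"equal"` or `"at_or_beyond"`. Defaults to `"equal"` for
#'   a left spike and `"at_or_beyond"` for a right spike.
#' @return A list of class `spike_spec`.
#' @examples
#' spike_spec("left")                 # never-smokers at SPY = 0
#' spike_spec("right", position = 60) # heavy smokers clumped at >= 60 SPY
#' @export
spike_spec <- function(side = c("left", "right"), position = NULL,
                       membership = NULL) {
  side <- match.arg(side)
  if (is.null(position)) {
    if (side == "right")
      spike_error("the spike position must be given for a spike at the right",
                  "spike_config_error")
    position <- 0
  }
  if (!is.numeric(position) || length(position) != 1L || !is.finite(position))
    spike_error("'position' must be a single finite number",
                "spike_config_error")
  membership <- membership %||% if (side == "left") "equal" else "at_or_beyond"
  if (!membership %in% c("equal", "at_or_beyond"))
    spike_error("'membership' must be \"equal\" or \"at_or_beyond\"",
                "spike_config_error")
  structure(list(side = side, position = as.numeric(position),
                 membership = membership),
            class = "spike_spec")
}

#' @export
print.spike_spec <- function(x, ...) {
  cat(sprintf("spike_spec: side=%s, position=%g, membership=%s\n",
              x$side, x$position, x$membership))
  invisible(x)
}

#' Detection parameters
#'
#' Tuning parameters of the trend decision and the group-size guards.
#' `alpha` is the two-sided significance level of the slope test on the
#' non-spike samples. `clinical_threshold` is the minimum absolute slope
#' (M-value units per covariate unit) a trend must reach to count as a
#' clinical effect — useful for large studies where tiny slopes turn
#' significant; the default 0 reduces the rule to pure significance.
#'
#' @param alpha significance level in (0, 1); default 0.05.
#' @param clinical_threshold non-negative minimum |slope|; default 0.
#' @param min_spike_n minimum spike-group size (>= 2, the spike standard
#'   deviation must exist).
#' @param min_nonspike_n minimum non-spike group size (>= 3, the slope
#'   p-value must exist).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(alpha = 0.05, clinical_threshold = 0,
                             min_spike_n = 2L, min_nonspike_n = 3L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1)
    spike_error("'alpha' must be a single number in (0, 1)",
                "spike_config_error")
  if (!is.numeric(clinical_threshold) || length(clinical_threshold) != 1L ||
      !is.finite(clinical_threshold) || clinical_threshold < 0)
    spike_error("'clinical_threshold' must be a non-negative number",
                "spike_config_error")
  min_spike_n <- as.integer(min_spike_n)
  min_nonspike_n <- as.integer(min_nonspike_n)
  if (is.na(min_spike_n) || min_spike_n < 2L)
    spike_error("'min_spike_n' must be an integer >= 2", "spike_config_error")
  if (is.na(min_nonspike_n) || min_nonspike_n < 3L)
    spike_error("'min_nonspike_n' must be an integer >= 3",
                "spike_config_error")
  structure(list(alpha = alpha, clinical_threshold = clinical_threshold,
                 min_spike_n = min_spike_n, min_nonspike_n = min_nonspike_n),
            class = "detection_params")
}

#' Category labels in the fixed reporting order
#'
#' @return `c("NLT", "NoLinearTrend", "PLT", "RNN", "RPN")`.
#' @export
spike_categories <- function() {
  c("NLT", "NoLinearTrend", "PLT", "RNN", "RPN")
}
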