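## Seeded scenario simulator: the nine spike-by-trend configurations.
##
## Scenarios are lettered A..I. The column (letter group) fixes the sign of
## the non-spike trend: A, B, C positive; D, E, F none; G, H, I negative.
## The row fixes where the spike-group methylation sits relative to the
## non-spike regression line extrapolated to the spike position — the
## quantity the classifier actually tests. For the "suspicious" scenarios
## (A, B with a rising trend; H, I with a falling trend) the spike opposes
## the trend; for the supporting scenarios (C, G) and the no-trend column the
## spike sits on the line or on its consistent side.

.scenario_truth <- c(A = "RNN", B = "RNN", C = "PLT",
                     D = "NoLinearTrend", E = "NoLinearTrend",
                     F = "NoLinearTrend",
                     G = "NLT", H = "RPN", I = "RPN")

.scenario_slope_sign <- c(A = 1, B = 1, C = 1, D = 0, E = 0, F = 0,
                          G = -1, H = -1, I = -1)

## Direction of the default spike offset (relative to the extrapolated line)
## for a spike at the LEFT; mirrored for a spike at the right, where the
## line's value at the spike position sits at the other end of the m-range.
.scenario_offset_dir_left <- c(A = 1, B = 1, C = 0, D = 1, E = 0, F = -1,
                               G = 0, H = -1, I = -1)

.offset_dir <- function(scenario, side) {
  d <- .scenario_offset_dir_left[[scenario]]
  if (side == "right") -d else d
}

.check_offset_sign <- function(scenario, side, offset) {
  d <- .offset_dir(scenario, side)
  if (scenario %in% c("D", "E", "F")) return(TRUE)     # truth is phi-gated
  if (d == 0) {
    # supporting scenarios: the spike must not sit on the opposing side
    opp <- .offset_dir(switch(scenario, C = "A", G = "I"), side)
    sign(offset) * opp <= 0
  } else {
    sign(offset) == d
  }
}

#' Specify one simulation scenario
#'
#' Builds the parameter set for one of the nine spike-by-trend scenarios.
#' Defaults encode a strong, clearly separated configuration: non-spike
#' covariate uniform over a 10-unit range, slope of +/-0.5 M-value units per
#' covariate unit (0 for the no-trend column), Gaussian noise with standard
#' deviation 1, 10 spike and 30 non-spike samples, and — for the scenarios
#' whose spike lies off the extrapolated line — a spike mean offset of
#' 6 noise standard deviations in the scenario's direction.
#'
#' @param scenario one of `"A"` to `"I"`.
#' @param side `"left"` (default) or `"right"`.
#' @param spike_position spike position; default 0 (left) / 20 (right).
#' @param n_spike,n_nonspike group sizes; defaults 10 and 30.
#' @param x_range range of the non-spike covariate; default a 10-unit
#'   interval adjacent to the spike position.
#' @param slope non-spike trend in M-value units per covariate unit; the sign
#'   must match the scenario column. Default `+/-0.5` or 0.
#' @param intercept M-value of the trend line at covariate 0; default 0.
#' @param spike_mean_offset spike-group mean M-value minus the trend line's
#'   value at the spike position; its sign must be compatible with the
#'   scenario. Default `6 * noise_sd` in the scenario's direction (0 for
#'   on-line spikes).
#' @param noise_sd Gaussian noise standard deviation on M-values; default 1.
#' @param seed integer seed making the draw reproducible.
#' @param membership spike membership rule; defaults as in [spike_spec()].
#' @return A list of class `scenario_spec`, including the implied `truth`
#'   category label.
#' @export
scenario_spec <- function(scenario, side = c("left", "right"),
                          spike_position = NULL,
                          n_spike = 10L, n_nonspike = 30L,
                          x_range = NULL, slope = NULL, intercept = 0,
                          spike_mean_offset = NULL, noise_sd = 1,
                          seed = 1L, membership = NULL) {
  side <- match.arg(side)
  if (!is.character(scenario) || length(scenario) != 1L ||
      !scenario %in% names(.scenario_truth))
    spike_error("'scenario' must be a single letter A..I",
                c("spike_spec_error", "spike_config_error"))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0)
    spike_error("'noise_sd' must be a positive number",
                c("spike_spec_error", "spike_config_error"))
  n_spike <- as.integer(n_spike)
  n_nonspike <- as.integer(n_nonspike)
  if (is.na(n_spike) || n_spike < 2L)
    spike_error("'n_spike' must be an integer >= 2",
                c("spike_spec_error", "spike_config_error"))
  if (is.na(n_nonspike) || n_nonspike < 3L)
    spike_error("'n_nonspike' must be an integer >= 3",
                c("spike_spec_error", "spike_config_error"))
  spike_position <- spike_position %||% if (side == "left") 0 else 20
  x_range <- x_range %||% if (side == "left") {
    c(spike_position + 1, spike_position + 11)
  } else {
    c(spike_position - 11, spike_position - 1)
  }
  if (length(x_range) != 2L || x_range[1] >= x_range[2])
    spike_error("'x_range' must be an increasing (lo, hi) pair",
                c("spike_spec_error", "spike_config_error"))
  if (side == "left" && x_range[1] < spike_position ||
      side == "right" && x_range[2] > spike_position)
    spike_error("'x_range' must lie on the non-spike side of the spike position",
                c("spike_spec_error", "spike_config_error"))
  ssign <- .scenario_slope_sign[[scenario]]
  slope <- slope %||% (0.5 * ssign)
  if (sign(slope) != ssign)
    spike_error(sprintf(
      "scenario %s requires a %s slope, got %g", scenario,
      c("negative", "zero", "positive")[ssign + 2], slope),
      c("spike_spec_error", "spike_config_error"))
  spike_mean_offset <- spike_mean_offset %||%
    (.offset_dir(scenario, side) * 6 * noise_sd)
  if (!.check_offset_sign(scenario, side, spike_mean_offset))
    spike_error(sprintf(
      "spike_mean_offset %g is incompatible with scenario %s (side %s)",
      spike_mean_offset, scenario, side),
      c("spike_spec_error", "spike_config_error"))
  spk <- spike_spec(side, position = spike_position, membership = membership)
  structure(list(scenario = scenario, side = side,
                 spike = spk, spike_position = spike_position,
                 n_spike = n_spike, n_nonspike = n_nonspike,
                 x_range = as.numeric(x_range), slope = slope,
                 intercept = intercept,
                 spike_mean_offset = spike_mean_offset,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 truth = .scenario_truth[[scenario]]),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "scenario_spec %s (%s spike at %g): slope=%g, offset=%g, sd=%g, n=%d+%d, truth=%s\n",
    x$scenario, x$side, x$spike_position, x$slope, x$spike_mean_offset,
    x$noise_sd, x$n_spike, x$n_nonspike, x$truth))
  invisible(x)
}

## Draw the covariate design (spike + non-spike x values) from the current
## RNG stream. Spike samples come first.
.draw_covariate <- function(spec) {
  width <- diff(spec$x_range)
  x_sp <- if (spec$spike$membership == "equal") {
    rep(spec$spike_position, spec$n_spike)
  } else if (spec$side == "left") {
    spec$spike_position - stats::runif(spec$n_spike, 0, 0.1 * width)
  } else {
    spec$spike_position + stats::runif(spec$n_spike, 0, 0.1 * width)
  }
  x_ns <- stats::runif(spec$n_nonspike, spec$x_range[1], spec$x_range[2])
  ids <- c(sprintf("sp%03d", seq_len(spec$n_spike)),
           sprintf("ns%03d", seq_len(spec$n_nonspike)))
  covariate_vector(c(x_sp, x_ns), ids)
}

## Draw one CpG's m-values for an existing covariate design, from the
## current RNG stream. Spike means are offset relative to the trend line at
## the NOMINAL spike position.
.draw_row <- function(spec, x) {
  n_sp <- spec$n_spike
  x_ns <- as.numeric(x)[-seq_len(n_sp)]
  line_at_spike <- spec$intercept + spec$slope * spec$spike_position
  m_sp <- line_at_spike + spec$spike_mean_offset +
    stats::rnorm(n_sp, 0, spec$noise_sd)
  m_ns <- spec$intercept + spec$slope * x_ns +
    stats::rnorm(spec$n_nonspike, 0, spec$noise_sd)
  c(m_sp, m_ns)
}

.truth_row <- function(spec, cpg_id) {
  data.frame(cpg_id = cpg_id, category = spec$truth,
             scenario = spec$scenario, slope = spec$slope,
             intercept = spec$intercept,
             spike_mean_offset = spec$spike_mean_offset,
             noise_sd = spec$noise_sd)
}

.new_sim <- function(values, cov, truth, spike) {
  structure(list(matrix = methylation_matrix(values, scale = "m"),
                 covariate = cov, truth = truth, spike = spike),
            class = "spike_sim")
}

#' @export
print.spike_sim <- function(x, ...) {
  cat(sprintf("spike_sim: %d CpG(s) x %d sample(s); truth: %s\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s=%d", names(table(x$truth$category)),
                            table(x$truth$category)), collapse = ", ")))
  print(x$spike)
  invisible(x)
}

#' Generate a single-CpG scenario dataset
#'
#' Draws one CpG under the given scenario: non-spike covariate values
#' uniform over `x_range`, non-spike M-values on the trend line plus
#' Gaussian noise, spike M-values at the line's value at the spike position
#' plus the scenario offset plus noise. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec a [scenario_spec()].
#' @return A `spike_sim` list: `matrix` (1 CpG), `covariate`, `truth`
#'   (data frame with the expected category and generating parameters), and
#'   `spike` (the [spike_spec()] to use for detection).
#' @export
generate_scenario <- function(spec) {
  if (!inherits(spec, "scenario_spec"))
    spike_error("'spec' must be a scenario_spec",
                c("spike_spec_error", "spike_config_error"))
  set.seed(spec$seed)
  cov <- .draw_covariate(spec)
  set.seed(spec$seed + 1L)
  m <- .draw_row(spec, cov)
  values <- matrix(m, nrow = 1L,
                   dimnames = list("cg0000001", names(cov)))
  .new_sim(values, cov, .truth_row(spec, "cg0000001"), spec$spike)
}

#' Generate a multi-CpG scenario matrix
#'
#' Stacks CpGs drawn from one or more scenario specifications over a single
#' shared covariate design. All specifications must agree on the covariate
#' design (side, position, membership, group sizes, `x_range`). The
#' covariate is drawn from the master `seed` and row `i`'s noise from
#' `seed + i`, so a single-spec, count-1 call reproduces
#' [generate_scenario()] at the same seed.
#'
#' @param specs a [scenario_spec()] or a list of them.
#' @param counts integer vector, CpGs per specification.
#' @param seed master integer seed.
#' @return A `spike_sim` with `sum(counts)` CpGs and a complete truth map.
#' @export
generate_matrix <- function(specs, counts, seed = 1L) {
  if (inherits(specs, "scenario_spec")) specs <- list(specs)
  if (!length(specs) || !all(vapply(specs, inherits, logical(1L),
                                    "scenario_spec")))
    spike_error("'specs' must be scenario_spec objects",
                c("spike_spec_error", "spike_config_error"))
  counts <- as.integer(counts)
  if (length(counts) != length(specs) || any(is.na(counts) | counts < 1L))
    spike_error("'counts' must be positive integers, one per spec",
                c("spike_spec_error", "spike_config_error"))
  design <- function(s) s[c("side", "spike_position", "n_spike",
                            "n_nonspike", "x_range")]
  ref <- design(specs[[1L]])
  for (s in specs[-1L])
    if (!identical(design(s), ref) ||
        !identical(s$spike$membership, specs[[1L]]$spike$membership))
      spike_error("all specs must share one covariate design",
                  c("spike_spec_error", "spike_config_error"))
  seed <- as.integer(seed)
  set.seed(seed)
  cov <- .draw_covariate(specs[[1L]])
  total <- sum(counts)
  cpg_ids <- sprintf("cg%07d", seq_len(total))
  values <- matrix(NA_real_, nrow = total, ncol = length(cov),
                   dimnames = list(cpg_ids, names(cov)))
  truth <- vector("list", total)
  row <- 0L
  for (k in seq_along(specs)) {
    for (j in seq_len(counts[k])) {
      row <- row + 1L
      set.seed(seed + row)
      values[row, ] <- .draw_row(specs[[k]], cov)
      truth[[row]] <- .truth_row(specs[[k]], cpg_ids[row])
    }
  }
  .new_sim(values, cov, do.call(rbind, truth), specs[[1L]]$spike)
}

#' Generate a null matrix for type-I-error checks
#'
#' All CpGs have zero trend and a spike mean on the (flat) line, so the
#' expected classification is `NoLinearTrend` throughout; a correctly sized
#' trend decision flags a fraction alpha of them.
#'
#' @param n_cpg number of CpGs.
#' @param n_spike,n_nonspike group sizes.
#' @param noise_sd Gaussian noise standard deviation; default 1.
#' @param seed master integer seed.
#' @param side spike side; default `"left"`.
#' @return A `spike_sim`.
#' @export
null_matrix <- function(n_cpg, n_spike = 10L, n_nonspike = 30L,
                        noise_sd = 1, seed = 1L, side = "left") {
  spec <- scenario_spec("E", side = side, n_spike = n_spike,
                        n_nonspike = n_nonspike, noise_sd = noise_sd,
                        seed = as.integer(seed))
  generate_matrix(spec, n_cpg, seed = seed)
}

#' Inject an outlier sample into a simulated dataset
#'
#' Appends one sample at the given covariate position whose M-value on every
#' CpG is the CpG's generating trend line at that position, shifted by
#' `m_offset`, plus one Gaussian noise draw from the current RNG stream.
#' The truth map is left unchanged: surfacing the outlier's effect is what
#' the detector is for.
#'
#' @param ds a `spike_sim`.
#' @param position covariate value of the outlier; must lie in the non-spike
#'   region.
#' @param m_offset M-value shift applied on every CpG.
#' @param sample_id identifier for the new sample; default `"outlier1"`.
#' @return The modified `spike_sim`.
#' @export
inject_outlier <- function(ds, position, m_offset, sample_id = "outlier1") {
  if (!inherits(ds, "spike_sim"))
    spike_error("'ds' must be a spike_sim", "spike_input_error")
  spk <- ds$spike
  in_spike <- if (spk$membership == "equal") {
    position == spk$position
  } else if (spk$side == "left") {
    position <= spk$position
  } else {
    position >= spk$position
  }
  if (in_spike)
    spike_error("outlier position falls inside the spike region",
                c("spike_spec_error", "spike_config_error"))
  if (sample_id %in% names(ds$covariate))
    spike_error(sprintf("sample identifier '%s' already present", sample_id),
                "spike_identifier_error")
  vals <- unclass(ds$matrix)
  tr <- ds$truth
  m_new <- tr$intercept + tr$slope * position + m_offset +
    stats::rnorm(nrow(vals), 0, tr$noise_sd)
  vals <- cbind(vals, m_new)
  colnames(vals)[ncol(vals)] <- sample_id
  cov <- covariate_vector(c(as.numeric(ds$covariate), position),
                          c(names(ds$covariate), sample_id))
  .new_sim(vals, cov, tr, spk)
}

#' Write a simulated dataset to disk
#'
#' Emits the matrix/phenotype TSV dialect the readers consume, plus the
#' truth map: `<prefix>matrix.tsv` (CpG rows, sample columns),
#' `<prefix>pheno.tsv` (`sample_id`, `x`) and `<prefix>truth.tsv`
#' (`cpg_id`, `expected_category`).
#'
#' @param ds a `spike_sim`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix; default `""`.
#' @param digits significant digits for serialization; default 10.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_dataset <- function(ds, dir, prefix = "", digits = 10L) {
  if (!inherits(ds, "spike_sim"))
    spike_error("'ds' must be a spike_sim", "spike_input_error")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vals <- unclass(ds$matrix)
  chr <- matrix(.fmt_num(as.numeric(vals), digits), nrow = nrow(vals),
                dimnames = dimnames(vals))
  mat_df <- data.frame(cpg_id = rownames(vals), chr, check.names = FALSE)
  paths <- c(matrix = file.path(dir, paste0(prefix, "matrix.tsv")),
             pheno = file.path(dir, paste0(prefix, "pheno.tsv")),
             truth = file.path(dir, paste0(prefix, "truth.tsv")))
  .write_tsv(mat_df, paths[["matrix"]])
  .write_tsv(data.frame(sample_id = names(ds$covariate),
                        x = .fmt_num(as.numeric(ds$covariate), digits)),
             paths[["pheno"]])
  .write_tsv(data.frame(cpg_id = ds$truth$cpg_id,
                        expected_category = ds$truth$category),
             paths[["truth"]])
  invisible(paths)
}
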