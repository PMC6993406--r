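test_that("scenario specs validate slope sign and offset direction", {
  expect_error(scenario_spec("A", slope = -0.5), class = "spike_spec_error")
  expect_error(scenario_spec("E", slope = 0.2), class = "spike_spec_error")
  expect_error(scenario_spec("I", slope = 0.5), class = "spike_spec_error")
  # opposing-spike scenarios need the opposing offset sign
  expect_error(scenario_spec("A", spike_mean_offset = -3),
               class = "spike_spec_error")
  expect_error(scenario_spec("H", spike_mean_offset = 3),
               class = "spike_spec_error")
  # supporting scenarios may sit on the line or its consistent side
  expect_s3_class(scenario_spec("C", spike_mean_offset = -6),
                  "scenario_spec")
  expect_error(scenario_spec("C", spike_mean_offset = 2),
               class = "spike_spec_error")
  # right side mirrors the directions
  expect_s3_class(scenario_spec("A", side = "right",
                                spike_mean_offset = -6), "scenario_spec")
  expect_error(scenario_spec("A", side = "right", spike_mean_offset = 6),
               class = "spike_spec_error")
})

test_that("generation is deterministic in the seed", {
  s <- scenario_spec("C", seed = 123L)
  expect_identical(generate_scenario(s), generate_scenario(s))
  d1 <- generate_matrix(list(scenario_spec("A"), scenario_spec("E")),
                        c(3, 3), seed = 5L)
  d2 <- generate_matrix(list(scenario_spec("A"), scenario_spec("E")),
                        c(3, 3), seed = 5L)
  expect_identical(unclass(d1$matrix), unclass(d2$matrix))
  expect_identical(d1$covariate, d2$covariate)
  d3 <- generate_matrix(list(scenario_spec("A"), scenario_spec("E")),
                        c(3, 3), seed = 6L)
  expect_false(identical(unclass(d1$matrix), unclass(d3$matrix)))
})

test_that("a single-spec count-1 matrix equals generate_scenario", {
  spec <- scenario_spec("G", seed = 17L)
  one <- generate_scenario(spec)
  mat <- generate_matrix(spec, 1L, seed = 17L)
  expect_equal(unname(unclass(mat$matrix)), unname(unclass(one$matrix)))
  expect_equal(as.numeric(mat$covariate), as.numeric(one$covariate))
  expect_identical(mat$truth$category, one$truth$category)
})

test_that("generate_matrix rejects inconsistent covariate designs", {
  a <- scenario_spec("A")
  b <- scenario_spec("B", spike_position = 2, x_range = c(3, 13))
  expect_error(generate_matrix(list(a, b), c(1, 1)),
               class = "spike_spec_error")
})

test_that("detect_all recovers the truth map of a mixed strong-effect matrix", {
  ds <- generate_matrix(list(scenario_spec("C"), scenario_spec("E"),
                             scenario_spec("I")), c(5, 5, 5), seed = 2L)
  det <- detect_all(ds$matrix, ds$covariate, ds$spike)
  hits <- sum(det$results$category ==
                ds$truth$category[match(det$results$cpg_id,
                                        ds$truth$cpg_id)])
  expect_gte(hits, 14L)
  expect_identical(sum(summarize_categories(det)$count),
                   nrow(det$results))
})

test_that("null matrices carry a NoLinearTrend truth and reproduce", {
  nm <- null_matrix(50, seed = 4L)
  expect_identical(unique(nm$truth$category), "NoLinearTrend")
  expect_identical(unclass(null_matrix(50, seed = 4L)$matrix),
                   unclass(nm$matrix))
  expect_identical(unique(nm$truth$slope), 0)
})

test_that("an injected extreme outlier flips null CpGs to suspicious", {
  nm <- null_matrix(60, seed = 8L)
  det0 <- detect_all(nm$matrix, nm$covariate, nm$spike)
  n_susp0 <- sum(det0$results$category %in% c("RNN", "RPN"))

  # high-leverage sample far beyond the non-spike range with very low
  # m-values: the fitted line tilts towards it and turns significant
  set.seed(99)
  out <- inject_outlier(nm, position = 30, m_offset = -25)
  det1 <- detect_all(out$matrix, out$covariate, out$spike)
  n_susp1 <- sum(det1$results$category %in% c("RNN", "RPN"))
  expect_gt(n_susp1, n_susp0)
  expect_identical(out$truth, nm$truth)   # truth map unchanged

  expect_error(inject_outlier(nm, position = 0, m_offset = -25),
               class = "spike_spec_error")
})

test_that("written datasets round-trip through the readers", {
  ds <- generate_matrix(scenario_spec("A", seed = 21L), 4L, seed = 21L)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  mat <- read_methylation_matrix(paths[["matrix"]])
  cov <- read_covariate_table(paths[["pheno"]], "sample_id", "x")
  expect_identical(rownames(mat), rownames(ds$matrix))
  expect_identical(colnames(mat), names(ds$covariate))
  expect_equal(unclass(mat), unclass(ds$matrix), tolerance = 1e-9)
  expect_equal(as.numeric(cov), as.numeric(ds$covariate), tolerance = 1e-9)
  truth <- read_results_table(paths[["truth"]])
  expect_identical(truth$expected_category, ds$truth$category)
})
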