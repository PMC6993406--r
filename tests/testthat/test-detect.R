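test_that("split_spike applies the membership rule", {
  cov <- covariate_vector(c(0, 0, 5, 12), sprintf("s%d", 1:4))
  sp <- split_spike(cov, spike_spec("left"))
  expect_identical(sp$spike, c(1L, 2L))
  expect_identical(sp$nonspike, c(3L, 4L))

  cov2 <- covariate_vector(c(7, 18, 20, 25, 27.7), sprintf("s%d", 1:5))
  sp2 <- split_spike(cov2, spike_spec("right", 20))
  expect_identical(sp2$spike, c(3L, 4L, 5L))
  expect_identical(sp2$nonspike, c(1L, 2L))

  cov3 <- covariate_vector(c(1, 2, 3), sprintf("s%d", 1:3))
  sp3 <- split_spike(cov3, spike_spec("left"))
  expect_length(sp3$spike, 0L)
  expect_identical(sp3$nonspike, 1:3)
})

test_that("determine_phi gates on significance and clinical threshold", {
  p <- detection_params(alpha = 0.05)
  expect_identical(determine_phi(make_fit(0, 1.2, 0.01), p), 1L)
  expect_identical(determine_phi(make_fit(0, 1.2, 0.20), p), 0L)
  expect_identical(determine_phi(make_fit(0, -1.2, 0.01), p), -1L)
  thr <- detection_params(alpha = 0.05, clinical_threshold = 0.5)
  expect_identical(determine_phi(make_fit(0, -0.3, 0.001), thr), 0L)
  expect_identical(determine_phi(make_fit(0, -0.6, 0.001), thr), -1L)
})

test_that("spike_band uses the n-1 standard deviation", {
  b <- spike_band(c(10, 10, 10))
  expect_equal(b$mean_spike, 10)
  expect_equal(b$sd_spike, 0)
  expect_equal(c(b$q1, b$q3), c(10, 10))

  b2 <- spike_band(c(1, 3))
  expect_equal(b2$mean_spike, 2)
  expect_equal(b2$sd_spike, sqrt(2), tolerance = 1e-12)
  expect_equal(b2$q1, 2 - 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(b2$q3, 2 + 2 * sqrt(2), tolerance = 1e-12)

  expect_error(spike_band(5), class = "spike_insufficient_error")
})

test_that("classify_left follows the decision rules with strict inequalities", {
  spec <- spike_spec("left")
  rising <- fit_ols(1:10, 0.5 * (1:10))      # exact line through origin
  expect_identical(classify_left(rising, spike_band(rep(10, 3)), spec), "RNN")
  expect_identical(classify_left(rising, spike_band(rep(0, 3)), spec), "PLT")
  flat <- fit_ols(1:10, rep(2, 10))
  expect_identical(classify_left(flat, spike_band(rep(10, 3)), spec),
                   "NoLinearTrend")
  falling <- fit_ols(1:10, 10 - 0.5 * (1:10))  # beta0 = 10
  expect_identical(classify_left(falling, spike_band(rep(0, 3)), spec), "RPN")
  expect_identical(classify_left(falling, spike_band(rep(10, 3)), spec),
                   "NLT")
  expect_error(classify_left(rising, spike_band(rep(0, 3)),
                             spike_spec("right", 20)),
               class = "spike_config_error")
})

test_that("classify_right swaps the band comparisons", {
  spec <- spike_spec("right", 20)
  rising <- fit_ols(1:10, 0.5 * (1:10))        # predicts 10 at x = 20
  expect_identical(classify_right(rising, spike_band(rep(0, 3)), spec), "RNN")
  falling <- fit_ols(1:10, 10 - 0.5 * (1:10))  # predicts 0 at x = 20
  expect_identical(classify_right(falling, spike_band(rep(5, 3)), spec),
                   "RPN")
  # band edge tie: 10 > 10 is false, not suspicious
  expect_identical(classify_right(rising, spike_band(rep(10, 3)), spec),
                   "PLT")
  expect_error(classify_right(rising, spike_band(rep(0, 3)),
                              spike_spec("left")),
               class = "spike_config_error")
})

test_that("detect_all classifies engineered CpGs and skips incomplete ones", {
  ds <- tiny_dataset(list(
    rnn = c(10, 10, 10, 0.5, 1, 1.5, 2, 2.5),    # rising, spike far above
    plt = c(0.4, 0.5, 0.6, 1, 1.5, 2, 2.5, 3),   # rising, spike on line
    none = c(1, 1.1, 0.9, 2, 2.1, 1.9, 2.05, 2), # flat non-spike part
    gone = c(1, 1, 1, NA, NA, NA, NA, NA)))      # no non-spike data
  det <- detect_all(ds$matrix, ds$covariate, ds$spec)
  expect_identical(det$results$category,
                   c("RNN", "PLT", "NoLinearTrend"))
  expect_identical(det$skipped$cpg_id, "gone")
  expect_match(det$skipped$reason, "non-spike")
  s <- summarize_categories(det)
  expect_identical(s$count[match(c("RNN", "PLT", "NoLinearTrend", "RPN",
                                   "NLT"), s$category)],
                   c(1L, 1L, 1L, 0L, 0L))
  expect_identical(sum(s$count), nrow(det$results))
})

test_that("detect_all enforces alignment and group sizes up front", {
  ds <- tiny_dataset(list(cg = c(1, 1, 1, 1, 2, 3, 4, 5)))
  cov_bad <- covariate_vector(as.numeric(ds$covariate),
                              rev(names(ds$covariate)))
  expect_error(detect_all(ds$matrix, cov_bad, ds$spec),
               class = "spike_alignment_error")

  one_spike <- covariate_vector(c(0, 1, 2, 3, 4, 5, 6, 7),
                                names(ds$covariate))
  expect_error(detect_all(ds$matrix, one_spike, ds$spec),
               class = "spike_config_error")
})

test_that("beta-scale input gives the same results as pre-converted input", {
  set.seed(3)
  beta <- matrix(runif(40, 0.05, 0.95), 5, 8,
                 dimnames = list(sprintf("cg%d", 1:5), sprintf("s%d", 1:8)))
  cov <- covariate_vector(c(0, 0, 0, 1, 2, 3, 4, 5), sprintf("s%d", 1:8))
  spec <- spike_spec("left")
  det_b <- detect_all(methylation_matrix(beta, "beta"), cov, spec)
  mvals <- matrix(beta_to_m(as.numeric(beta)), 5, dimnames = dimnames(beta))
  det_m <- detect_all(methylation_matrix(mvals, "m"), cov, spec)
  expect_equal(det_b$results, det_m$results)
})

test_that("summarize_categories of empty results is all zero", {
  empty <- data.frame(cpg_id = character(0), category = character(0))
  s <- summarize_categories(empty)
  expect_identical(s$category, spike_categories())
  expect_identical(s$count, integer(5))
})
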