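# Independent oracles and fixture builders shared across the suite.

# Direct normal-equations solve, independent of fit_ols()'s closed form.
oracle_ols_coef <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(crossprod(X), crossprod(X, y)))
}

# Reference least-squares p-value for the slope.
oracle_ols_pvalue <- function(x, y) {
  summary(stats::lm(y ~ x))$coefficients[2L, 4L]
}

# Brute-force reimplementation of the five-category decision table, written
# straight from its verbal definition (not from the package internals).
oracle_category <- function(phi, pred, q1, q3, side) {
  if (phi == 0) return("NoLinearTrend")
  suspicious <- if (side == "left") {
    (phi == 1 && pred < q1) || (phi == -1 && pred > q3)
  } else {
    (phi == 1 && pred > q3) || (phi == -1 && pred < q1)
  }
  if (suspicious) {
    if (phi == 1) "RNN" else "RPN"
  } else {
    if (phi == 1) "PLT" else "NLT"
  }
}

make_fit <- function(beta0, beta1, pvalue, se = 0.1, n = 10L) {
  structure(list(beta0 = beta0, beta1 = beta1, se_beta1 = se,
                 pvalue = pvalue, n = n, df = n - 2L),
            class = "ols_fit")
}

# Tiny aligned matrix + covariate with a left spike at 0 (3 spike samples at
# x = 0, 5 non-spike samples at x = 1..5).
tiny_dataset <- function(rows) {
  x <- c(0, 0, 0, 1, 2, 3, 4, 5)
  ids <- sprintf("s%d", seq_along(x))
  vals <- do.call(rbind, rows)
  dimnames(vals) <- list(names(rows), ids)
  list(matrix = methylation_matrix(vals, "m"),
       covariate = covariate_vector(x, ids),
       spec = spike_spec("left"))
}

write_tsv_fixture <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
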