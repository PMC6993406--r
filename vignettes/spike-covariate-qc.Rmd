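---
title: "Screening spike-at-zero covariates in EWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening spike-at-zero covariates in EWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikecheck)
```

## The problem

Epigenome-wide association studies regress the methylation of hundreds of
thousands of CpG sites on a covariate of interest. When that covariate is
continuous but carries a point mass at one edge — all never-smokers at
smoking pack years (SPY) = 0, or a clumped "heavy" category at the upper
boundary — the per-CpG linear regression silently mixes two populations.
If the spike group's methylation is consistent with the trend in the
remaining samples, nothing is lost. If it is not, the pooled slope can be
attenuated, cancelled, or flipped in sign, and every downstream step
(multiple-testing, pathway and enrichment analysis) inherits the wrong
effect direction. `spikecheck` screens for exactly this before the
differential analysis, in the spirit of independent filtering: the screen
uses only the spike structure of the covariate, not the test statistic of
the downstream analysis.

## The model and its decision rules

Methylation enters as M-values, `M = log2(beta / (1 - beta))`, the log odds
of the methylated fraction; they are unbounded and closer to the
homoscedastic Gaussian assumption of least squares than beta-values.
(`beta_to_m()` performs the conversion, clamping beta to
`[epsilon, 1 - epsilon]`, default `epsilon = 1e-6`, so boundary values map
to finite M-values. Some texts describe the transform loosely in terms of a
natural logarithm; the implemented and conventional definition is base-2.)

Given a spike specification (side, position, membership rule) each CpG is
processed independently:

1. **Trend decision.** OLS of the M-values on the covariate over the
   *non-spike* samples only. With slope `b1` and two-sided p-value `p`,

   `phi = sign(b1)` if `p < alpha` and `|b1| >= clinical_threshold`, else 0.

2. **Spike band.** `Q1/Q3 = mean(m_spike) -/+ 2 * sd(m_spike)` (sample
   standard deviation, n−1 denominator) over the spike-group M-values.

3. **Classification.** Let `p0` be the non-spike regression's prediction at
   the spike position (for the usual left spike at 0, the intercept).
   Left spike: `phi = +1` with `p0 < Q1` is `RNN`; `phi = -1` with
   `p0 > Q3` is `RPN`; otherwise `PLT`/`NLT`; `phi = 0` is
   `NoLinearTrend`. Right spike: the band comparisons swap — a rising trend
   extrapolating *above* the band (`p0 > Q3`) means the spike drags the
   pooled slope down (`RNN`); a falling trend extrapolating below it means
   the spike drags it up (`RPN`).

4. **Ranking.** Suspicious CpGs are ordered by
   `|b1(all samples) - b1(non-spike samples)|`, ties broken by CpG
   identifier, and the top `k` (default 6) exported with plot-ready data
   for visual inspection.

The regression is deliberately simplistic — no confounders, no
empirical-Bayes moderation. It is a pretest, not an effect estimate: CpGs
that pass go on to a properly adjusted differential model; CpGs that fail
are inspected by eye.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 0.05 | — | significance level of the slope t-test; no multiple-testing correction, since the screen is an independent filter, not an inference |
| `clinical_threshold` | 0 | M-value per covariate unit | minimum \|slope\| for a trend to count; raise it in large studies where trivial slopes turn significant |
| `min_spike_n` | 2 | samples | the spike standard deviation must exist |
| `min_nonspike_n` | 3 | samples | the slope p-value must exist |
| `epsilon` | 1e-6 | — | beta clamp for the M-value transform |
| `k` | 6 | CpGs | size of the inspection short-list |

Spike membership defaults to `equal` for a left spike (exactly the spike
value, the spike-at-zero case) and `at_or_beyond` for a right spike (a
clumped boundary category); both are selectable.

## Numerical and degenerate-case choices

* **Zero-residual fits.** Exact lines are common in constructed test data
  and give an infinite t statistic; the p-value is defined as 0 when the
  slope is nonzero (residual sum of squares numerically zero, relative
  tolerance 1e-12) and 1 when the slope is zero, so `phi` stays defined.
* **Band ties.** `p0 == Q1` or `p0 == Q3` is *not* suspicious: the rules
  use strict inequalities, so a spike exactly on the band edge stays
  `PLT`/`NLT`.
* **Missing values** are handled per CpG with pairwise-complete samples.
  CpGs whose complete data fall below the group minimums, or whose
  complete non-spike covariate is constant, go to a skip list with a
  reason; they are excluded from category summaries but never silently
  dropped.
* **Left-spike generalisation.** The rule compares the *prediction at the
  spike position*, not the raw intercept, so a nonzero left spike position
  behaves correctly; at position 0 the two coincide.
* The five category counts always partition the classified CpGs, and the
  whole decision is invariant under positive affine transforms of the
  M-values, joint shifts of covariate and spike position, and sample
  permutation; mirroring the covariate and swapping the spike side maps
  `RNN <-> RPN` and `PLT <-> NLT`. These laws are asserted in the test
  suite.

## The scenario simulator

`scenario_spec()`/`generate_scenario()` emulate the nine qualitative
spike-by-trend configurations on a single CpG: the non-spike trend is
positive (scenarios A–C), absent (D–F) or negative (G–I), and the
spike-group mean sits above, on, or below the trend line *extrapolated to
the spike position* — the quantity the classifier actually tests. A and B
(rising trend opposed by a high spike) are truly `RNN`, C truly `PLT`,
D–F `NoLinearTrend`, G `NLT`, and H and I truly `RPN`; for a right spike
the offsets mirror so the scenario semantics (oppose/support the trend)
are preserved. Note that a "mid-range" spike in the qualitative picture is
an *off-line* spike whenever the trend is non-flat, which is why B and H
default to an opposing offset rather than zero.

Defaults define the simulated study conditions: M-value noise is Gaussian
with `noise_sd = 1` (the simulator models normally distributed M-values,
not array chemistry), the non-spike covariate is uniform over a 10-unit
range adjacent to the spike, the trend is ±0.5 M-value units per covariate
unit, off-line spikes are offset by `6 * noise_sd`, and groups have 10
spike and 30 non-spike samples. Under these conditions the per-scenario
recovery probability is essentially 1 for the effect scenarios and exactly
`1 - alpha = 95%` for the no-trend scenarios — a correctly sized trend
test flags 5% of nulls, so the D–F recovery rate is checked against a
binomial envelope around 95% rather than a sharp bound.

`generate_matrix()` stacks CpGs from several scenario specifications over
one shared covariate drawn from the master seed, with row `i`'s noise
drawn from `seed + i`, so matrices are reproducible row-wise.
`null_matrix()` is the all-null special case used for type-I-error
calibration. `inject_outlier()` appends a single high-leverage sample at a
chosen covariate value with shifted M-values on every CpG — the situation
where one extreme exposure value with unusual methylation manufactures
suspicious interactions across the array, which the screen surfaces as a
side effect of its design.

What the simulator does **not** model: beta-value distributions, probe
types, batch effects, and correlation between CpG sites. Passing the
recovery suite therefore shows that the decision rules identify the
geometry they are designed for under Gaussian noise; it does not certify
behaviour on raw, unnormalised, or batch-confounded data, which must be
preprocessed before the screen as in any EWAS pipeline.

```{r simulator}
ds <- generate_matrix(list(scenario_spec("A", seed = 42),
                           scenario_spec("C", seed = 42),
                           scenario_spec("E", seed = 42)),
                      counts = c(4, 4, 4), seed = 42)
det <- detect_all(ds$matrix, ds$covariate, ds$spike)
summarize_categories(det)
rank_suspicious(det, k = 3)
```

## Design decisions taken where the design was open

* **alpha is uncorrected and configurable.** The screen is a pretest; a
  family-wise or FDR correction would change its character from "inspect
  anything suspicious" to "infer interactions", which is not its job.
* **Ranking pools RNN and RPN** by default; the `categories` argument
  restricts ranking to either class, since inspection figures are usually
  drawn per category.
* **The deviation is an absolute difference** of the two slopes; the
  signed difference is carried alongside in every output so the direction
  of the distortion remains visible.
* **Category semantics are fixed by the non-spike trend sign**: `RNN`
  always means a *positive* non-spike trend opposed by the spike, `RPN` a
  *negative* one, on either spike side.
* **No spike modelling.** Fractional polynomials or spike indicator terms
  could fit the data better, but for hundreds of thousands of CpGs they
  spend degrees of freedom on a structure that only a small fraction of
  sites exhibits, and a well-fitted interaction is still biologically
  suspect; flag-and-inspect is the intended behaviour.
* **Spike positions are user-supplied, never inferred** from histograms;
  choosing them is a subject-matter decision.

## Problem sizes

The shipped test suite and the acceptance script are sized for a desk run:
OLS equivalence on 200 random instances (n = 3–30), scenario recovery with
200 replicates per scenario and side, type-I calibration on 1,000 null
CpGs, and the invariance laws on 100 random single-CpG instances. A full
450K/EPIC array (~5e5 CpGs) runs through `detect_all()` in minutes, as the
per-CpG work is a pair of closed-form regressions.

## Known limitations

* The screen assumes preprocessed, normalised M-values; it does not adjust
  for batch or confounders, by design — adjusted modelling belongs to the
  post-hoc analysis of the CpGs that pass.
* With `membership = "equal"`, covariate values intended to be in the
  spike must match the position exactly (after whatever rounding the
  phenotype table carries).
* A spike group of 2–3 samples makes the band extremely sensitive to its
  standard deviation estimate; results from very small spike groups should
  be read as a short-list for inspection, nothing more.
* `phi` uses a plain t-test; heavy-tailed M-value noise inflates the
  no-trend false-positive rate above alpha, which moves borderline CpGs
  between `NoLinearTrend` and the trend categories but cannot create
  suspicious calls on its own (those also require the band violation).
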