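Package: spikecheck
Title: Detection of Suspicious Spike-Covariate Interactions in Methylation Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-control screen for epigenome-wide association studies in
    which a continuous covariate (for example smoking pack years) carries a
    point mass ("spike") at the left or right edge of its distribution. For
    every CpG site a simple linear regression is fitted on the non-spike
    samples, the trend decision is combined with a tolerance band around the
    spike-group methylation values, and each CpG is classified as showing a
    positive or negative linear trend, no linear trend, or a suspicious
    reversal/negation of the trend by the spike. Suspicious CpGs are ranked
    by the deviation between the with-spike and without-spike regression
    slopes for visual inspection before downstream differential analysis.
    Includes a seeded scenario simulator for the nine spike-by-trend
    configurations and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
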