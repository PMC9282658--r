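Package: startlehab
Title: Acoustic Startle Habituation, Sensitivity and Homozygosity Mapping for Larval Zebrafish
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for larval zebrafish acoustic startle assays and
    the genetics that goes with them. Encodes the 50-stimulus habituation
    protocol and the multi-intensity sensitivity assay, classifies
    short-latency C-bend (SLC) responses, computes per-larva habituation
    percentages with non-responder filtering, sensitivity-phase response rates,
    area-under-curve sensitivity indices and SLC kinematic summaries. Includes
    a pooled-sequencing homozygosity-mapping stage (allele-fraction scores,
    running-median smoothing, linkage-interval calling), dCAPS/CAPS
    restriction-digest genotype calling, a normality-gated group-comparison
    report, and a synthetic-data generator (Bernoulli startle cohorts,
    logistic intensity-response curves, Mendelian crosses, binomially sampled
    pooled read counts under Haldane recombination) so every stage is testable
    without live larvae.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
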