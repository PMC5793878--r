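Package: methdrift
Title: Differential DNA Methylation Regions, Regulatory Target Integration,
    and Gene-Set Survival Stratification for Replicated WGBS Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls differentially methylated regions (DMRs) from replicated
    whole-genome bisulfite sequencing count tables using a Rao-Scott
    overdispersion-corrected likelihood-ratio test, merges differentially
    methylated CpGs into regions and re-tests them with Benjamini-Hochberg
    control, integrates DMRs with differential-expression tables through a
    distance-decayed regulatory-potential score with Kolmogorov-Smirnov
    function tests and rank-product target calling, quantifies persistence of
    methylation changes after an intervention (retention index,
    classification, k-means clustering), and stratifies samples by
    single-sample gene-set enrichment scores with Kaplan-Meier/log-rank
    survival comparison.  Ships a beta-binomial synthetic-data generator with
    known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
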