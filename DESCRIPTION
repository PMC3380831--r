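Package: dyadcall
Title: Nucleosome Calling and Differential Occupancy Analysis for MNase-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls nucleosomes from MNase-seq read-center (dyad) density by
    iterative greedy peak detection on a Gaussian-smoothed track, classifies
    each nucleosome's position response (Welch t-test on member read centers)
    and occupancy response (binomial test on windowed read-center counts)
    to histone depletion across replicates with Bonferroni correction,
    builds cross-replicate consensus and depletion-dependent nucleosome
    sets, and measures permutation z-score enrichment of chromatin
    annotations, expression classes, remodeler-style directional shifts,
    and DNA-encoded sequence preference over those sets.  A synthetic-data
    module generates phased nucleosome arrays, perturbations, MNase-like
    fragments, and annotation tracks with known ground truth so the whole
    pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    IRanges,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
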