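Package: ssrpipe
Title: Cultivar Collection Analysis with Nuclear and Chloroplast
    Microsatellites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classification of clonally propagated plant cultivar
    collections from codominant nuclear simple sequence repeat (SSR)
    genotypes and haploid chloroplast SSR haplotypes. Provides synonym
    (duplicate clone) detection with probability-of-identity, chloroplast
    haplotype assignment and group tabulation, Bayesian admixture
    clustering via a Gibbs sampler with the Evanno delta-K criterion and
    replicate-run alignment, exclusion-based parentage analysis with
    seed/pollen role assignment from maternal chloroplast inheritance,
    per-group diversity statistics including rarefaction allelic
    richness, principal coordinate analysis on the Smouse-Peakall
    codominant distance, a fully seeded synthetic-data generator with
    ground truth, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
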