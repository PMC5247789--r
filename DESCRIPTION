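Package: snpdesert
Title: Homozygous-Desert Segment Analysis and Founder-History Simulation
    for Diploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies SNP-free ("homozygous desert") segments in the
    heterozygous SNP calls of a single diploid individual after
    coverage-based filtering of collapsed assembly regions, compares the
    observed segment statistics against a random-placement null, and
    discriminates recent close-relative inbreeding from a small-founder
    population history.  Includes an explicit-meiosis pedigree simulator
    for four close-relative mating designs, a forward-in-time
    Wright-Fisher simulator with recombination, mutation and exponential
    growth from 2-4 founders (sparse ancestry-block arithmetic, compiled
    core), and a synthetic-data generator that emulates a heterozygous
    multi-scaffold genome with embedded identity-by-descent tracts and a
    bimodal read-depth track.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
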