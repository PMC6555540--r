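Package: sgrmap
Title: Suppressor Locus Mapping and Phenotype Quantification for
    Barcode-Based Yeast Genetic Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping extragenic suppressor loci in
    Saccharomyces cerevisiae by barcode-based genetic-linkage screens
    (genetic interaction mapping against the pooled deletion
    collection), and for quantifying suppressor phenotypes: sliding
    window genome scans with a permutation null, growth-curve
    doubling-time estimation, per-gene RNA polymerase I occupancy
    statistics from Miller-spread counts and ChIP tables, and
    internal-control normalized fold changes for pulse-labelling,
    transcriptional run-on and northern signal tables.  A seeded
    synthetic-data generator reproduces the statistical structure of
    every input (linkage-dependent barcode depletion after a meiotic
    cross, exponential growth with multiplicative noise, overdispersed
    polymerase counts, replicate signal intensities with loading
    controls, and colony counts for mutation-frequency estimation), so
    the whole pipeline is testable without microarray or imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
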