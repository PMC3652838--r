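Package: barcodegap
Title: Barcode-Gap Species Delimitation from Pairwise Genetic Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distance-based species delimitation for DNA barcode data.
    Computes uncorrected p and Kimura 2-parameter pairwise distances with
    pairwise deletion, profiles divergence by taxonomic level, locates the
    barcode gap separating intraspecific from interspecific divergence,
    partitions sequences into putative species by single-linkage threshold
    clustering, validates partitions with a canonical discriminant analysis
    and leave-one-out cross-validation on principal-coordinate scores, and
    compares divergence patterns across mitochondrial loci with Wilcoxon
    signed-rank tests. Includes a Kimura 2-parameter sequence simulator for
    generating species complexes and multi-gene panels with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    MASS,
    optparse
Config/testthat/edition: 3
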