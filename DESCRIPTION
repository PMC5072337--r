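Package: famforge
Title: Iterative Profile-Based Delineation of Membrane-Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delineating remote-homology families of polytopic
    membrane proteins such as the mitochondrial Tim17/Tim22/Tim23 carriers.
    Implements greedy identity clustering, position-specific profile
    construction with Gumbel e-value calibration, profile-to-sequence and
    profile-to-profile local alignment, glycine-zipper detection and column
    masking to guard against motif-only false positives, an iterative
    family-expansion loop, PROSITE-style motif scanning, hydropathy-based
    transmembrane-segment prediction, tandem two-domain splitting, and
    neighbor-joining subfamily classification with presence/absence
    summaries. Includes a synthetic membrane-protein superfamily generator
    with known truth labels for benchmarking the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
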