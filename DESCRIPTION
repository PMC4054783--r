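Package: esetools
Title: Concordance, Positional and Selection Analysis of Exonic Splice
    Enhancer Hexamer Catalogues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing catalogues of exonic splice enhancer (ESE)
    hexamers: set concordance against uniform and pool-sampling nulls with
    Monte Carlo significance, capture-recapture style estimation of the
    underlying true-ESE pool size, positional density profiling across
    intron-exon-intron layouts, the hexamer preference index (HPI) codon
    randomization statistic and codon usage-vs-distance slopes,
    four-fold degenerate site divergence and SNP-density contrasts between
    ESE, non-ESE and composition-matched pseudoESE sites, association tests
    with splice-site strength, intron length and expression covariates, and
    a synthetic-data generator providing ground-truth inputs for every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
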