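Package: cfescan
Title: Collateral Fitness Effect Landscapes from Growth-Competition Deep
    Mutational Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for deep-mutational-scanning growth
    competitions of site-saturation (NNN) codon libraries, as used to map
    collateral fitness effects of coding mutations. Converts merged amplicon
    reads into per-codon variant counts with quality filters, estimates
    allele fitness and selection coefficients from enrichment relative to
    pooled wild-type synonyms with an analytic (delta-method) variance,
    makes dual-replica significance calls, summarises fitness landscapes
    (percent deleterious, distributions of fitness effects, position-by-
    amino-acid matrices with domain annotations), detects condition-
    dependent shifts via Wilcoxon signed-rank and codon-pooled t-tests, and
    correlates fitness with externally predicted folding-stability changes.
    Includes a seeded forward simulator of the competition experiment with
    known ground truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    graphics,
    jsonlite,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
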