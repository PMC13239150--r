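Package: pleiopc
Title: Latent Components of Cross-Disorder GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes a SNP-by-disorder matrix of GWAS association Z-scores
    into latent components by singular value decomposition and characterises
    the components: variance explained, SNP and phenotype contributions,
    squared cosines, gene-set over-representation of component-defining SNPs,
    and Pearson correlation of SNP-loading Z-scores with external GWAS.
    Component polygenic scores are evaluated from summary statistics alone via
    allelic-count reconstruction: group-wise polygenic-score means and
    standard deviations with a Welch t-test, case-case GWAS between disorder
    pairs, and inverse-variance subtraction of overlapping cohorts. Includes
    summary-statistics harmonisation to a reference panel, priority-based LD
    clumping, and a synthetic multi-trait GWAS generator with planted low-rank
    factor structure so the full pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
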