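Package: conjfdr
Title: Conditional and Conjunctional False Discovery Rate Analysis for
    Cross-Trait GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying shared genetic risk between two traits
    from genome-wide association study (GWAS) summary statistics. Implements
    genomic-control correction from intergenic SNPs, stratified (conditional)
    Q-Q and fold-enrichment curves, an empirical bidirectional conditional
    false discovery rate (cFDR) lookup table with bilinear interpolation, the
    conjunctional FDR (the maximum of the two directional cFDRs), random LD
    pruning into near-independent SNP sets, greedy LD clumping to index SNPs,
    region-exclusion re-analysis, and a synthetic two-trait GWAS generator
    with block LD and planted shared loci for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
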