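Package: popsweep
Title: Selective Sweep Scanning and Trait Linking in Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide selective sweep detection for multi-population
    resequencing panels. Computes windowed nucleotide diversity (theta-pi),
    pairwise Weir-Cockerham FST, the population branch statistic (PBS), the
    log2 diversity-ratio statistic, and a cross-population composite
    likelihood ratio (XP-CLR) scan over a shared sliding-window grid, then
    calls putative sweeps where at least two of the three scan statistics
    fall in their top 5 percent tails. Called sweeps are merged, annotated
    with gene models, and linked to traits via haplotype enumeration,
    allele-class phenotype tests, expression-phenotype correlation, and
    overlap with association loci. A Balding-Nichols simulator generates
    multi-population genotype data with planted sweeps, phenotypes, and
    expression so that every stage is testable against known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    vcfR,
    rtracklayer,
    GenomicRanges,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
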