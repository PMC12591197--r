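Package: chimerase
Title: Donor Deconvolution of Periclinal Chimeras from Allele-Specific
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to dissect the cell-layer composition of periclinal
    graft chimeras from bulk RNA-seq allele counts. Given variant calls
    for the two donor genotypes and allelic depths observed in chimera
    tissue, the package identifies donor-diagnostic SNP sites (positions
    where the donors are homozygous for different alleles), classifies
    the donor of origin of every expressed site, estimates the fraction
    of the tissue transcript pool contributed by each donor (equivalently
    by the L1 versus L2/L3 meristem layers) with an error-aware binomial
    maximum-likelihood estimator and bootstrap confidence intervals, and
    classifies genes as layer-specific from their pooled allele
    frequencies. A seeded simulator generates chimeric datasets with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
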