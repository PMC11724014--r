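Package: twohitscan
Title: Germline and Tumour Two-Hit Validation of Cancer Predisposition Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrated germline plus tumour sequencing analysis for validating
    candidate cancer-predisposition genes under the two-hit model. Implements
    rare loss-of-function case-control burden statistics (cross-product odds
    ratios and one-sided exact p-values), tumour purity estimation from somatic
    variant allele fractions with multi-estimator consensus, purity-adjusted
    allelic-status ("two-hit") classification of germline variants in tumours,
    genomic-scar homologous-recombination-deficiency scoring (LOH + TAI + LST),
    and SBS96 mutational-signature refitting with a bootstrap sparsity filter,
    together with a synthetic-data generator that provides ground-truth cohorts,
    tumours and mutational catalogues for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    vcfR,
    pracma,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
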