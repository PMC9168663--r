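Package: bicyclr
Title: Gene-Structure-Based Detection of Bicycle-Like Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects candidate members of structurally stereotyped gene
    families (such as the aphid bicycle genes, which carry many short
    internal coding exons predominantly of phase 2) from genome
    annotations alone.  Extracts eight coding-structure predictors from
    GFF3 gene models, fits a binomial logit-link classifier with a
    precision/recall-equalized probability cutoff, supports
    cross-validation and predictor ablation, and corroborates candidate
    homology with an intron-position concordance statistic computed over
    gapped protein alignments with a resampling null.  Includes a
    synthetic annotation and alignment simulator with recorded ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    optparse,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
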