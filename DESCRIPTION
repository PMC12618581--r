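Package: diatomsex
Title: Conserved Transcriptomic Markers of Diatom Sexual Reproduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery of conserved transcriptomic marker gene families for
    sexual reproduction in diatoms from multi-species RNA-seq experiments,
    and detection of sexual-reproduction events in environmental
    metatranscriptomes. Implements CPM/TPM computation and trimmed-mean-of-M
    (TMM) library normalization, a fold-change-threshold differential
    expression test with Sidak gene-level aggregation and stage-wise
    Holm confirmation, five-step data-driven marker discovery with atlas
    specificity filtering, matched control-marker selection, HMMER hit
    filtering and phylogenetic clade selection of environmental homologs,
    MAG-level TPM co-expression event calling against percentile-calibrated
    thresholds, a control-marker false-positive audit, Mann-Whitney
    abundance association, and seeded synthetic-data generators that
    emulate every input with ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
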