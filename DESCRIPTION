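Package: coabundance
Title: Protein Complex Constraints on Proteome Dysregulation in Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for studying how protein-complex organization
    constrains protein-abundance dysregulation in cancer proteomics.
    Implements tumor-versus-normal differential abundance testing (Wilcoxon
    rank tests with Bonferroni correction and median log2 fold changes),
    chi-square association of differential proteins with complex membership
    including an abundance-matched background construction, all-pairs
    Spearman co-abundance correlation across tumor samples with cross-cohort
    pooling, five protein-interaction classifications (stoichiometric parity
    from chain counts, complex co-occurrence Jaccard, context-specific
    versus general detection across cell lines, competitive versus
    cooperative binding from interface-residue overlap, and curated
    transient versus permanent labels), and pairwise regression of
    abundances with a copy-number-based dependent-variable rule. A
    synthetic-data module generates paired cohorts with planted
    co-regulation, differential effects and interaction labels so every
    stage has a ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
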