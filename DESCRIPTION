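Package: monoqtl
Title: Monocyte Transcriptome eQTL Mapping and Risk-Factor Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested reimplementation of a genome-wide monocyte
    expression-genetics workflow: expression pre-processing (arcsinh
    transform, detection filtering, quantile normalization, gene-symbol
    filtering), genotype quality control (minor allele frequency, call
    rate, Hardy-Weinberg equilibrium), a genome-wide SNP-by-expression
    ANOVA scan with genotype-group merging, Kruskal-Wallis confirmation
    and Fisher-combined X-chromosome tests, cis/trans annotation and
    tiered eQTL summaries, linkage-disequilibrium utilities and
    polymorphic-probe flagging, expression-by-risk-factor association
    with covariate adjustment schemes and cis-eSNP enrichment odds
    ratios, SNP-by-risk-factor interaction scanning, split-half
    stability selection of independent expression correlates,
    SNP-expression-phenotype mediation-compatibility triangle tests
    with outcome attenuation analysis, and analytic study-design
    calculators. A synthetic-cohort simulator with a ledger of planted
    effects drives end-to-end parameter-recovery testing at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
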