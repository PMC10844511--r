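Package: gonodyn
Title: Gene Activation and Repression Dynamics During Gonadal Sex Differentiation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative analysis of gene expression dynamics during gonadal
    sex differentiation. Runs within-sex stage contrasts (moderated
    t-statistics with empirical-Bayes variance shrinkage for microarray-style
    intensities; negative-binomial Wald tests with median-of-ratios
    normalization, Cook's-distance outlier flagging and independent filtering
    for RNA-seq counts), combines the two per-sex fold changes into a
    fold-change-plane classification of male-enriched (MEG), female-enriched
    (FEG) and shared stage-regulated genes together with the regulatory
    mechanism behind the enrichment (activation in the enriched sex,
    repression in the opposite sex, or both), and compares results across
    species: key-gene panels, top-gene marker discovery, and conserved-pathway
    overrepresentation. A synthetic-data generator with planted ground truth
    supports end-to-end validation without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
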