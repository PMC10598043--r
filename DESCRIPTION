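Package: NicheGradients
Title: Dual-Gradient Classification of Soil Bacterial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies OTUs of a soil bacterial community along two gradients: a
    habitat-specialization gradient (Levins niche breadth against a permutation null)
    and an abundance gradient (six categories defined by 1% and 0.01% relative-abundance
    thresholds, collapsed to abundant/medium/rare). Computes per-subgroup alpha
    diversity (Shannon, Simpson, three evenness indices, richness) with one-way ANOVA
    group letters, and compares subgroup community structure across afforestation stand
    types by NMDS, ANOSIM, Mantel tests (including 3-D spatial distance) and redundancy
    analysis with Monte-Carlo permutation tests. A synthetic-community generator with
    planted habitat archetypes and abundance classes makes every stage testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
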