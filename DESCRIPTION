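Package: heterokit
Title: Dissecting Heterosis into Dominance and Digenic Epistasis in Multi-Hybrid Maize Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic toolkit for multi-environment multi-hybrid trials:
    two-stage adjusted means and mid-parent/better-parent heterosis statistics,
    combining-ability (GCA/SCA) variance decomposition by EM-REML, Rogers' and
    dominance-weighted heterotic genetic distances, windowed Weir-Cockerham Fst and
    nucleotide-diversity sweep scans, multi-kernel Bayesian partitioning of
    mid-parent-heterosis variance into dominance and additive-by-additive,
    additive-by-dominance and dominance-by-dominance epistatic components, and a
    three-step genome-wide scan that integrates significant component effects into
    per-locus heterotic effects with permutation validation. Includes a synthetic-data
    generator (diverged parental pools, diallel and NC II crossing designs, epistatic
    trait architectures, plot-level phenotypes) so every stage is testable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
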