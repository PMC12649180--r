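Package: avihazard
Title: Avian Community Diversity and Airport Bird-Strike Hazard Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing bird survey data collected along transects in
    and around airports: sampling-adequacy estimators (species accumulation
    curves, Chao1/Chao2, rarefaction-extrapolation, sample coverage),
    dominance classification, functional and phylogenetic diversity (Gower
    distance, principal coordinates analysis, UPGMA functional dendrograms,
    Faith's PD, mean pairwise distances), richness-constrained null models
    with standardized effect sizes, a composite bird-strike risk index with
    four-tier classification, and nonparametric habitat/season comparisons.
    Includes a synthetic-data generator (Yule trees, Brownian-motion traits,
    habitat-filtered surveys) so every stage can be exercised with known
    ground truth.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    vegan,
    cluster,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
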