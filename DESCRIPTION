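Package: phytosurvey
Title: Quantitative Analysis of Quadrat-Based Plant Diversity Surveys
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for the quantitative analysis of quadrat-based vegetation
    surveys: phytosociological statistics (frequency, density, cover and their
    relative forms), alpha diversity (Shannon, Simpson, Pielou evenness,
    Margalef/Menhinick richness) with rank-sum comparisons across soil groups,
    beta diversity via Bray-Curtis dissimilarity with one-way PERMANOVA and
    principal coordinates ordination, Pearson association of phytosociological
    parameters, and quantitative SWOT importance-coefficient scoring. Includes
    a seeded synthetic-survey generator emulating a multi-site, multi-layer
    quadrat design so every pipeline stage is testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
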