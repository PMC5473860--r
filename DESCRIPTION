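Package: fdtraitkit
Title: Trait Choice Methods for Functional Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for choosing which quantitative traits enter functional
    diversity indices. Estimates the intrinsic dimensionality of a species by
    trait matrix (Kaiser's rule, Horn's parallel analysis, a scree heuristic),
    selects key trait subsets by matrix-correlation criteria (the RM
    coefficient, Yanai's Generalized Coefficient of Determination, and the RV
    coefficient) or by highest principal-component loadings, and computes four
    functional diversity indices (FAD, dendrogram-based FD, Rao's quadratic
    entropy, and functional dispersion FDis) on any trait subset or on
    principal-component pseudo-traits. A complete search evaluates every trait
    combination against an ecosystem property (species richness by default)
    and benchmarks the selection methods by closeness of association
    (coefficient of determination), with a two-way ANOVA comparison across
    datasets. Includes seeded generators for trait matrices with planted
    factor dimensionality and for community tables with planted
    richness-diversity associations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, MASS, multcomp
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
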