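Package: toothrqa
Title: Recurrence Quantification of Elemental Biomarker Time-Series from Teeth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cyclical elemental metabolism recorded in
    tooth matrix biomarkers. Implements time-delay embedding, recurrence and
    cross-recurrence matrices, and the dynamical features commonly derived
    from them (determinism, mean diagonal length, entropy, recurrence time);
    a cohort-level feature pipeline over single-element and zinc-pair
    pathways; twin-clustered linear mixed models with pathway-stratified
    false discovery rate control; principal component analysis with a joint
    Kaiser/variance retention rule; and linear discriminant analysis with
    correlation-based standardized loadings. A synthetic twin-cohort
    generator emulating laser-ablation ICP-MS tooth profiles makes every
    stage testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
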