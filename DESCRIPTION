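Package: antmorph
Title: Morphometric Analysis and Wild-Type Reconstruction for Parasitized Ants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying species-specific morphological shifts caused
    by cestode infection in ant workers, for classifying specimens to species
    from linear trait measurements plus infection status with a feed-forward
    neural network, and for reconstructing the putative healthy (wild-type)
    trait values of infected specimens by Gaussian distribution mapping.
    Includes a synthetic-data generator emulating the group structure of
    multi-species host-parasite morphometric studies, sequential ANOVA of the
    trait-by-infection-by-species design, marginal-mean infection contrasts
    with Bonferroni adjustment, stratified k-fold cross-validation with
    confusion-matrix performance measures including the multiclass Matthews
    correlation coefficient, and per-species principal component ordination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    emmeans,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
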