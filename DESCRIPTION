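Package: rootlda
Title: Discriminant Analysis of Seedling Root System Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating two-dimensional seedling root system
    architecture to group labels such as nutrient uptake efficiency class
    and growth-medium treatment. The pipeline converts per-plant sets of
    seminal and lateral root polylines into a pairwise root-system
    distance, embeds the distances with classical multidimensional
    scaling into shape coordinates, combines these with standard
    image-derived root traits, and analyses the resulting trait table
    with multi-group linear discriminant analysis, Mahalanobis group
    distances, variable-subset selection by the zeta-squared
    (Hotelling-Lawley) criterion, bootstrap inference on discriminant
    loadings, and block-permutation significance tests. A seeded
    synthetic root-system generator with group-dependent architecture
    makes every stage testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    xml2,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
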