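Package: gensil
Title: Generalized Silhouette Width for Cluster Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cluster validity assessment with the generalized (power-mean)
    silhouette width. Within- and between-cluster average distances entering
    the silhouette index are computed with the generalized mean of exponent p,
    which interpolates between minimum (p = -Inf), harmonic, geometric,
    arithmetic (the classic silhouette, p = 1), quadratic means and maximum
    (p = +Inf), shifting the index's sensitivity between connectedness and
    compactness. Includes numerically safe power means for all extended-real
    exponents, per-object silhouette tables with misclassification summaries,
    silhouette profiles over grids of p, native Lance-Williams agglomerative
    clustering (single, group-average, complete and flexible-beta linkage)
    with tree cutting, seeded two-dimensional benchmark point-pattern
    generators, and experiment drivers comparing clustering methods across
    cluster numbers and p.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp
Suggests:
    cluster,
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
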