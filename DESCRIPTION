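Package: shapeselect
Title: Multivariate Selection Analysis on Geometric Morphometric Shape Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating pre- and post-copulatory sexual selection on
    size and shape traits digitized as two-dimensional landmark outlines.
    Reads and writes the TPS landmark dialect and slider files, performs
    generalized Procrustes alignment with sliding semilandmarks, computes
    centroid size and relative warps, and feeds the resulting trait set into
    Lande-Arnold selection-gradient estimation (linear, quadratic and
    correlational gradients with permutation inference), canonical analysis of
    the gamma matrix with double-regression estimates and eigenvalue
    permutation tests, sequential-model-building comparison of selection
    episodes, thin-plate-spline fitness-surface visualization with
    GCV-selected smoothing, and ANOVA-based repeatability. A synthetic-data
    generator with known ground truth emulates a two-episode mating and
    fertilization study design so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
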