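Package: rootposture
Title: Quantitative Phenotyping of Root Posture and Curvature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to quantify the posture of plant primary roots from
    digitized centerline coordinates. Traces are resampled to a uniform
    arc-length density by spline interpolation; a per-point curvature
    index is computed from turning angles with moving-average smoothing
    and end trimming; whole-root posture indices (root length,
    horizontal and vertical growth indices, straightness index) and
    gravitropic root-tip angles are derived; genotypes or treatments are
    compared with nonparametric statistics (Kruskal-Wallis, Steel-Dwass,
    Brunner-Munzel) and compact letter displays. A synthetic wavy-root
    generator with analytic ground truth supports validation and power
    exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    withr,
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
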