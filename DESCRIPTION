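Package: amyquant
Title: Semi-Quantitative Amyloid-PET Indices on Dual Time-Point Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates dual time-point amyloid-PET phantom cohorts with known
    ground-truth amyloid burden, perfusion and atrophy; computes five
    semi-quantitative regional indices (SUVr, ELBA-style rank contrast,
    time-delayed ratio, white-matter-referenced ratio, and a kinetic slope
    index used as reference); and runs the full statistical comparison:
    z-scoring, Bland-Altman agreement with bootstrap confidence intervals,
    inverse-dispersion score fusion, Pearson correlations, residual
    independence checks, bootstrap ROC analysis against class labels, and
    age/thickness regressions in amyloid-negative subjects with collinearity
    screening and Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
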