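Package: limbalign
Title: Separating Pose from Neutral Alignment in Articulated Statistical Shape Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for point-distribution (statistical) shape models of
    articulated skeletal anatomy. Implements generalized Procrustes
    alignment, PCA shape models, and a partial-least-squares pipeline that
    separates scan-time positional noise (pose) from the neutral inter-bone
    alignment of multi-bone joint constructs: decoupled and articulated
    models, a regressed neutral-alignment model with left/right
    error-evolution component selection, recoupling that preserves original
    bone geometry, and an instant one-step denoiser. Includes a synthetic
    articulated lower-limb landmark generator with ground-truth neutral
    alignment, mock and rescan validation reports, and sexual-dimorphism
    analysis (canonical correlation, PLS-regression explained variance,
    amplified effect shapes, per-landmark permutation significance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
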