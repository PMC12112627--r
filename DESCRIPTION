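Package: calcimorph
Title: Morphometry of Intracranial Carotid Artery Calcifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic morphometry of intracranial carotid artery (ICA)
    calcifications from CT angiography style volumes. From a contrast-filled
    lumen segmentation (100-600 HU) and high-density calcification voxels
    (>600 HU), the package extracts a luminal centerline, slices the artery
    perpendicular to it every 0.2 mm, casts 360 radial rays per slice, and
    measures calcification area, arc width, thickness and gap to the lumen,
    artery-level tortuosity, longitudinal calcification extent, lumen surface
    contact, calcification-attributable stenosis with severity categories,
    Bouthillier C2-C6 segment labelling and a 4-way spatial orientation.
    Includes parametric vessel phantoms with closed-form ground truth for
    every metric, and the statistical layer used to compare artery sides:
    paired Wilcoxon signed-rank tests, chi-squared tests, median/IQR
    summaries and two-way absolute-agreement intraclass correlation
    coefficients with 95% confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
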