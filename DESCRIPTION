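Package: lumenmap
Title: Quantitative Analysis of Synaptic Vesicle Luminal Assemblies in
    Electron Tomography Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of the luminal macromolecular
    assembly of synaptic vesicles in electron-tomography volumes, exercised
    end-to-end on synthetic active-zone phantoms with known ground truth.
    Includes a phantom generator for stained frog neuromuscular-junction
    active-zone scenes; MRC volume and PLY surface I/O; virtual slicing,
    gray-scale segmentation and isodensity surface extraction; vesicle
    morphometry (five-axis diameters, sphere and spherical-zone areas, lumen
    fill fractions); reference-free dual-phase rigid alignment-model building
    by gray-scale density and by iterative-closest-point surface registration;
    active-zone-referenced orientation classification; membrane connection-site
    extraction, transmembrane pairing, band detection, Robinson-projected
    spherical maps and composite maps; and regional stain-density statistics
    (one-way ANOVA with Tukey post hoc from raw voxels or summary statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
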