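Package: tracemapr
Title: Whole-Brain Input/Output Connectivity Quantification from Labeled Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies whole-brain neural connectivity from 3D fluorescence
    volumes pre-registered to a hierarchical brain atlas. Detects labeled
    axonal projection signal per coronal section (background estimation,
    Gaussian filtering, clipped Yen thresholding), validates signal
    connectivity to the injection site by multistencils fast marching on a
    10-micron signal-density grid with back-tracking path confidence,
    localizes input-neuron somata, aggregates both into normalized
    per-region connectivity profiles with injection-site exclusion, and
    compares profiles across groups (Pearson correlation, one-way ANOVA with
    Tukey HSD, hierarchical clustering with multiscale bootstrap support).
    A synthetic-data module generates toy atlases and labeled volumes with
    known ground truth so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    RNifti,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
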