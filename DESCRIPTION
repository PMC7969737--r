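Package: doughscope
Title: Quantitative Image Analysis for Optically Cleared Wheat Dough
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying fluorescence and transmitted-light imaging
    of optically cleared wheat-based samples: transparency readouts (opacity,
    Michelson-type grid contrast, linear expansion, stress-strain resampling),
    Gaussian point-spread-function fitting for resolution estimation,
    histogram-mode variance as a depth-resolved image-quality score, Otsu
    segmentation with 3D connected-component volumetrics of the gluten phase,
    and skeleton-based morphometrics of the gluten network (junction density,
    branch length, endpoint rate, gliding-box lacunarity). A synthetic-scene
    generator emulates honeycomb gluten walls around starch-granule voids,
    sub-resolution fluorescent beads under a Gaussian PSF, grid-pattern
    transmission targets, and depth-dependent signal degradation, so the whole
    pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    EBImage,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
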