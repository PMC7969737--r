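# doughscope

Quantitative image analysis for optically cleared wheat-based samples.

Clearing a noodle or dough piece and imaging it by two-photon or confocal
optical sectioning turns the gluten network — the protein skeleton that wraps
~30 µm starch granules in a honeycomb — into a 3D fluorescence volume that
can be measured rather than just looked at. `doughscope` implements the
measurement side of that workflow for food scientists and microscopists:

* **Clearing performance** — opacity of transmitted-light photographs
  (background grey / sample grey; 1 = fully transparent), Michelson-type
  grid contrast `C = (g_max − g_min) / (g_max + g_min)` over a plot-profile
  window, linear expansion ratios, and piecewise-linear resampling of
  compression stress–strain curves on the standard strain grid
  0.1, 0.2, …, 0.9.
* **Resolution** — Gaussian PSF fitting of bead intensity profiles with the
  FWHM-parameterized peak model
  `I(x) = I0 + A·exp{−4 ln2 (x − xc)² / w²} / (w·√(π / 4 ln2))`,
  in which the fitted `w` *is* the full width at half maximum, and
  mean ± SD summaries over replicate beads.
* **Depth-resolved image quality** — the histogram-mode variance
  `VAR = Σ (I − Ip)² F(I)` per optical section (Ip: intensity at the
  histogram peak top; F: normalized frequency with clipped levels 0 and
  2^bit − 1 excluded), and its profile against imaging depth.
* **Segmentation and volumetrics** — Otsu thresholding on the native
  bit-depth histogram, gluten area fractions, 3D connected-component
  labeling (6/18/26 connectivity, compiled) with per-clump physical volumes
  and volume-distribution summaries.
* **Network morphometrics** — topology-preserving skeletonization of a
  gluten mask with junction/endpoint classification, geodesic branch
  lengths, gliding-box lacunarity, and the five-variable summary (area %,
  junction density, mean gluten length, endpoint rate, mean lacunarity)
  familiar from vessel-analysis tools.
* **Synthetic scenes** — generators for honeycomb wall phantoms with known
  wall fraction, sub-resolution beads under a known PSF, grid-pattern
  transmission targets with controllable blur/scatter, and depth-dependent
  attenuation + noise, so the entire pipeline is testable without microscope
  data.

Data containers are S4 (`ImageStack`, `BinaryMask`, `PlotProfile`,
`GaussianFit`, `IntensityHistogram`, `SkeletonGraph`, `NetworkMetrics`),
with multi-page TIFF I/O (`readStack`/`writeStack`, voxel size in a JSON
sidecar) and a CLI wrapper at
`system.file("scripts", "doughscope", package = "doughscope")`.

## Worked example

```r
library(doughscope)

## a honeycomb phantom: bright gluten walls around 15-um-radius voids
cfg <- SceneConfig(c(120, 128, 128), voxelSizeUm = 1,
                   granuleSpacingUm = 46, rngSeed = 11)
stk <- makeHoneycombStack(cfg)
stk
#> ImageStack: 120 x 128 x 128 voxels (z,y,x), voxel 1 x 1 x 1 um, 12-bit
#>   intensity range [500, 3000]

## segmentation recovers the generator's analytic wall fraction
round(100 * wallFraction(cfg), 2)    # ground truth:       94.25 %
round(areaFraction(binarize(stk)), 2)  # Otsu + counting:  94.25 %

## PSF fitting: regenerate a bead profile from a known parameter set and
## refit it from data-driven starting values
x <- seq(0, 10, by = 0.05)
fit <- fitPSF(PlotProfile(x, gaussianPeak(x, 156.2, 5.16, 1346.9, 0.509)))
fit
#> GaussianFit: I0 = 156.2, xc = 5.16 um, A = 1346.9, FWHM w = 0.509 um
#>   rss = 0, converged = TRUE

## network morphometrics of a void-rich optical section
vf  <- sapply(1:120, function(i) mean(getSlice(stk, i) < 1000))
img <- ifelse(getSlice(stk, which.max(vf)) > 1500, 200, 30)
networkMetrics(img, NetworkParams(), pixelSizeUm = 1)
#> NetworkMetrics:
#>   gluten area        81.88 %
#>   junction density   0.0003662 / um^2  (6 junctions)
#>   avg gluten length  64.04 um
#>   endpoints rate     0 / um^2  (0 endpoints)
#>   mean lacunarity    1.174
```

The wall fraction line reads: the phantom's voids occupy 5.75% of the
volume by construction, and Otsu segmentation of the rendered stack recovers
the complementary 94.25% wall fraction to two decimals. The PSF block shows
the fitter recovering the generating parameters of a noiseless profile
exactly (`rss = 0`). The morphometrics block quantifies one section of the
honeycomb: dense walls (82% area), a handful of wall junctions, no free
branch ends, and near-uniform spatial coverage (lacunarity close to 1).

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "doughscope",
                               load_package = "installed")'
```

The suite checks every operation against independent brute-force oracles
(exhaustive Otsu scans, recursive flood fill, all-box lacunarity
enumeration, edge-accounting branch walks, term-by-term variance sums) and
property-style invariants on seeded random inputs.

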