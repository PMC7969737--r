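---
title: "Methods: quantifying gluten structure in optically cleared dough"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying gluten structure in optically cleared dough}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doughscope)
```

`doughscope` measures what optical clearing makes visible in wheat-based
samples: how transparent the sample became, how finely it can be imaged, how
image quality degrades with depth, how much gluten there is, and how the
gluten network is shaped. This vignette explains each model, the parameters
that matter, the numerical choices, and what the synthetic test scenes do
and do not establish about real microscope data.

## Transparency readouts

**Opacity** is the ratio of background mean grey to sample mean grey in a
transmitted-light photograph. The direction matters: an opaque sample
transmits less light, so it photographs darker than the reference background
and its opacity exceeds 1, falling towards 1 as clearing proceeds. The
choice of sample and background regions is left to the caller — the package
takes two mean grey values, because which region is a fair reference depends
on the dish, the illumination and the experiment.

**Grid contrast** scores how visibly a grid-printed film shows through the
sample: `profileContrast()` takes the Michelson-type ratio
\((g_{max}-g_{min})/(g_{max}+g_{min})\) of grey values inside a window of a
line profile (`extractProfile()`: bilinear interpolation at a uniform
spacing of at most one pixel, optional averaging over parallel lines, 1 px
averaging width by default). The conventional window for grid photographs is
5 mm. When no window is given the whole profile is used; the package never
searches for the best-contrast window, because a maximum-contrast search
would bias the readout upwards — the window is an acquisition decision, not
a fitted quantity.

**Linear expansion** is a plain width ratio, and **stress–strain
resampling** interpolates stress at the standard strain grid 0.1–0.9 in
steps of 0.1. Interpolation is piecewise linear — the simplest method
consistent with resampling between measured knots — and extrapolation
beyond the measured strain range is an error rather than a guess.

## Resolution from bead profiles

Sub-resolution fluorescent beads image as the system's point spread
function. A line profile through a bead is fit with
\[
I(x) = I_0 + \frac{A\,\exp\{-4\ln 2\,(x-x_c)^2/w^2\}}{w\sqrt{\pi/4\ln 2}},
\]
a Gaussian parameterized so that \(w\) is directly the full width at half
maximum and \(A\) the peak area. Fitting is Levenberg–Marquardt least
squares (relative tolerance \(10^{-10}\), at most 1000 evaluations), a
smooth four-parameter problem for which LM is the standard choice.
Positivity of \(w\) is enforced by fitting \(\log w\) internally. Starting
values are always data-driven — baseline from the profile minimum, centre
from the argmax, width from the half-maximum crossings found by linear
interpolation, area from width × height — so the fit never needs, and never
receives, the truth it is supposed to recover. Profiles must contain a
strict interior maximum; a monotone profile is a setup error, while
optimizer non-convergence is reported through the `converged` flag with
best-effort parameters. Replicate fits are summarized as mean ± SD of
\(w\) (sample SD, \(n-1\) denominator). Only lateral (x) profiles are
calibrated by the bead phantom tests; the same fitter can be applied to
axial profiles, but axial PSFs of real systems are asymmetric and wider, so
such fits should be treated as descriptive.

## Depth-resolved image quality

Each optical section is scored by the variance of its intensity histogram
about the histogram *mode*:
\(\mathrm{VAR} = \sum_I (I-I_p)^2 F(I)\), with \(I_p\) the intensity at the
histogram peak and \(F\) the normalized frequency. Using the mode rather
than the mean is deliberate — deep, degraded sections collapse towards a
single dominant level, and distance from that dominant level is what the
score should penalize; the test suite pins an asymmetric case where
mode-variance and mean-variance differ. Clipped levels — 0 (blocked-up
shadows) and \(2^{\mathrm{bit}}-1\) (blown-out highlights) — are removed
before normalization, because those are the only levels at which clipping is
identifiable without acquisition metadata; frequencies are renormalized over
the retained levels afterwards, so they always sum to 1. Ties for the mode
break to the lowest intensity, which keeps the statistic deterministic.
Native 12-bit levels are used without re-binning. In a depth profile, the
slice at 1-based index \(i\) sits at depth \((i-1)\times\) z-pitch, and a
degenerate slice yields `NA` rather than aborting the profile.

Because real acquisitions re-tune detector settings per depth, absolute VAR
values are not comparable across instruments or samples; only the shape of
the VAR-versus-depth profile is. The package therefore validates the
qualitative decline on synthetic stacks, not absolute scores.

## Segmentation and volumetrics

Otsu's threshold is computed on the native bit-depth histogram (no 8-bit
rescale), maximizing between-class variance over every candidate level,
with ties broken to the lowest level and foreground defined as *strictly
greater* than the threshold. Connected components in 3D default to
26-connectivity (faces, edges, corners): gluten walls are thin at voxel
scale and fragment spuriously under 6-connectivity. The connectivity used is
recorded in the output, since no single choice is canonical. Volumes are
voxel counts times the product of the three voxel pitches, so anisotropic
stacks are handled; connectivity itself stays purely topological. Volume
distributions additionally report the fraction of total volume held by the
largest clumps, the natural summary when a few large aggregates dominate.

## Network morphometrics

The five-variable gluten-network summary is computed natively from a binary
mask:

1. **Enhance and binarize** — Gaussian smoothing at
   \(\sigma = \text{thickness}/2\) where thickness (default 8 px) is the
   expected wall width; pixels whose original intensity falls outside the
   analyzed window (default 0–255, i.e. everything on 8-bit data) are
   excluded from both the mask and the analyzed area; Otsu on the smoothed
   image. Hole filling is off by default.
2. **Despeckle** — 8-connected components strictly smaller than 30 px are
   removed ("under 30": a 30-px component stays).
3. **Skeletonize** — Guo–Hall two-subiteration thinning, which preserves
   topology and leaves already-thin structures (lines, rings, crossings)
   untouched.
4. **Classify** — skeleton pixels with one 8-neighbour are endpoints, with
   three or more are junction pixels; 8-adjacent junction pixels merge into
   one junction cluster counted once, because thinning produces small pixel
   clusters at crossings. A consequence worth knowing: pixels diagonally
   adjacent to a crossing also have ≥ 3 neighbours, so a plus-shaped
   crossing yields a 5-pixel cluster and arm branches measure from the
   cluster boundary, not the geometric centre.
5. **Measure** — branches are node-to-node paths with geodesic length
   (orthogonal step 1, diagonal step \(\sqrt 2\), times pixel pitch);
   node-free cycles are traced as single closed branches. Gliding-box
   lacunarity \(\Lambda(r) = \langle M^2\rangle/\langle M\rangle^2\) is
   averaged over box sizes (default: powers of 2 from 2 px to a quarter of
   the smaller image dimension), with empty-mean box sizes excluded with a
   warning.

Densities are reported both per µm² of *analyzed* area and as raw counts,
since panel-style summaries are often unit-free. "Average gluten length" is
the mean branch length; with the branch decomposition used here this
coincides with total skeleton path length divided by branch count.
Established vessel-analysis tools compute a similar variable family, but
their internal enhancement steps are unpublished; this package defines the
metric family explicitly on its own masks and makes no claim of numeric
equality with any particular tool's output.

## Synthetic scenes: what they emulate, and what they do not

The generators provide ground truth the analyses can be checked against:

* **Honeycomb phantoms** place dark spherical voids (default radius 15 µm,
  emulating ~30 µm starch granules) on a hexagonal-close-packed lattice
  with 10% positional jitter, walls bright (3000 counts) over background
  (500 counts) at 12-bit. Only voids fully inside the volume are kept and
  realized centres are checked pairwise, so the analytic wall fraction
  \(1 - n\cdot\frac{4}{3}\pi r^3/V\) is exact and overlapping-void
  configurations are a hard error. Test scenes use a 46 µm lattice spacing:
  the worst-case jitter displacement (\(\sqrt3\times 0.1\,a\) per centre)
  then never brings two 15-µm voids into contact. Wall thickness is a free
  parameter of the phantom, not calibrated to any measured dough — real
  gluten area fractions are far lower than the phantom's, so the phantom
  validates *recovery of a known fraction*, not realism of the fraction.
* **Bead phantoms** render spheres convolved with an isotropic Gaussian PSF
  (closed-form radial profile, kernels truncated at 4σ). For bead diameters
  well below the FWHM the imaged spot's width converges to the PSF FWHM as
  the voxel shrinks; the tests check the error at least halves from 0.1 µm
  to 0.05 µm voxels.
* **Grid targets** are dark lines on a bright field, blurred and then
  blended towards the image mean by a scatter level in [0, 1] — enough
  structure to give contrast an analytic value at zero blur and a provably
  monotone decline in scatter.
* **Depth degradation** scales the slice at depth \(z\) by
  \(e^{-\mu z}\) before detector noise. The default
  \(\mu = 6\times10^{-4}\,\mu m^{-1}\) reproduces a roughly six-fold VAR
  decline over 1.5 mm, the magnitude of quality loss reported for deep
  two-photon imaging of cleared noodles. The depth-trend test replicates one
  void-rich section down a 2 mm stack so that content is constant and only
  the depth effect varies — the correct control, but also a reminder that
  the generator does not emulate content variation, refractive-index
  mismatch, or the per-depth detector re-tuning of real acquisitions.

All generators are bit-reproducible under a fixed seed: noise is drawn in a
locally seeded RNG scope that restores the caller's RNG state. Gaussian
noise adds counts at the stated SD; Poisson noise treats the scale as a
detector gain. Values are clipped to \([0, 2^{\mathrm{bit}}-1]\) and rounded
after noise. Voxel indices are 0-based in physical terms: the voxel at index
\(i\) is centred at \((i+0.5)\times\) pitch.

Passing against these phantoms shows the *algorithms* are correct on data
with known structure. It does not show that a particular dough image is
segmented correctly — real sections have texture within walls, out-of-focus
haze and staining variability that no phantom here reproduces.

## Problem sizes and tolerances

The shipped tests use phantoms of up to \(120\times128\times128\) voxels,
100-slice depth stacks, 200 random Otsu images up to 64², 100 random 3D
masks up to 16³ against a flood-fill oracle, 50 random lacunarity masks up
to 32² against all-box enumeration, and 1000 random histograms against
term-by-term summation — sizes at which the brute-force oracles themselves
are exact and fast. Oracle comparisons are exact or at \(10^{-9}\)
relative; fit round-trips are checked to 3 significant figures; the
honeycomb fraction recovery is checked to 1% relative, which is dominated
by voxelization of sphere surfaces at 1 µm pitch.

## Known limitations

* Skeleton branch lengths assume isotropic pixels; anisotropic 2D sections
  should be resampled first.
* Lacunarity normalization conventions differ across the literature; the
  plain gliding-box ratio used here is stated in the output and should not
  be numerically compared against tools using normalized variants.
* 3D skeletonization is out of scope; network morphometrics are per-section.
* TIFF I/O stores counts in a 16-bit container with a JSON sidecar for
  voxel size and bit depth; vendor microscope formats are not read.
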