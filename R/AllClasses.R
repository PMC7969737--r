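#' @import methods
NULL

#' ImageStack: a 3D fluorescence intensity volume
#'
#' The unit of all volumetric analysis. Voxel data are stored as a numeric
#' array in \code{(z, y, x)} axis order; the physical position of the voxel
#' with 0-based index \code{i} along an axis is \code{(i + 0.5) * voxelSize}
#' (voxel-centre convention). Intensities are integer detector counts in
#' \code{[0, 2^bitDepth - 1]}.
#'
#' @slot data numeric array, dim \code{(nz, ny, nx)}.
#' @slot voxelSizeUm positive numeric length 3, voxel pitch in micrometres
#'   in \code{(z, y, x)} order.
#' @slot bitDepth integer, detector bit depth (default 12, as for two-photon
#'   acquisition).
#' @exportClass ImageStack
setClass("ImageStack",
  representation(data = "array", voxelSizeUm = "numeric", bitDepth = "integer"),
  prototype(bitDepth = 12L)
)

setValidity("ImageStack", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array (z, y, x)")
  if (length(object@voxelSizeUm) != 3L || any(!is.finite(object@voxelSizeUm)) ||
      any(object@voxelSizeUm <= 0))
    msg <- c(msg, "voxelSizeUm must be 3 positive values (z, y, x)")
  if (length(object@bitDepth) != 1L || object@bitDepth < 1L ||
      object@bitDepth > 16L)
    msg <- c(msg, "bitDepth must be a single integer in [1, 16]")
  if (length(object@data) && (min(object@data) < 0 ||
      max(object@data) > 2^object@bitDepth - 1))
    msg <- c(msg, "voxel values must lie in [0, 2^bitDepth - 1]")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageStack
#'
#' @param data numeric 3D array in \code{(z, y, x)} order, or a matrix
#'   (promoted to a single-slice stack).
#' @param voxelSizeUm voxel pitch in micrometres, \code{(z, y, x)}; a single
#'   value is recycled isotropically.
#' @param bitDepth integer bit depth, default 12.
#' @return An \linkS4class{ImageStack}.
#' @examples
#' s <- ImageStack(array(0, c(2, 4, 4)), voxelSizeUm = 1)
#' dim(s)
#' @export
ImageStack <- function(data, voxelSizeUm, bitDepth = 12L) {
  if (is.matrix(data)) data <- array(data, c(1L, nrow(data), ncol(data)))
  if (length(voxelSizeUm) == 1L) voxelSizeUm <- rep(voxelSizeUm, 3L)
  new("ImageStack", data = data, voxelSizeUm = as.numeric(voxelSizeUm),
      bitDepth = as.integer(bitDepth))
}

#' BinaryMask: a segmented foreground mask
#'
#' Logical 2D or 3D grid marking segmented (gluten) voxels, together with the
#' physical voxel size and the number of pixels that were actually analyzed
#' (pixels excluded by an intensity window do not count towards densities).
#'
#' @slot values logical array (2D or 3D).
#' @slot voxelSizeUm positive numeric, one pitch per array dimension.
#' @slot analyzedPx number of pixels/voxels in the analyzed region.
#' @slot metadata list of provenance fields (threshold, connectivity, ...).
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(values = "array", voxelSizeUm = "numeric",
                 analyzedPx = "numeric", metadata = "list"),
  prototype(metadata = list())
)

setValidity("BinaryMask", function(object) {
  msg <- character()
  nd <- length(dim(object@values))
  if (!nd %in% c(2L, 3L)) msg <- c(msg, "values must be 2D or 3D")
  if (!is.logical(object@values)) msg <- c(msg, "values must be logical")
  if (length(object@voxelSizeUm) != nd || any(object@voxelSizeUm <= 0))
    msg <- c(msg, "voxelSizeUm must give one positive pitch per dimension")
  if (object@analyzedPx < 0 || object@analyzedPx > length(object@values))
    msg <- c(msg, "analyzedPx must be in [0, number of cells]")
  if (length(msg)) msg else TRUE
})

#' Construct a BinaryMask
#'
#' @param values logical matrix or 3D array.
#' @param voxelSizeUm physical pitch per dimension (recycled if scalar).
#' @param analyzedPx analyzed-region size in pixels; defaults to all.
#' @param metadata optional provenance list.
#' @return A \linkS4class{BinaryMask}.
#' @export
BinaryMask <- function(values, voxelSizeUm = 1, analyzedPx = length(values),
                       metadata = list()) {
  if (is.matrix(values) && !is.array(values)) values <- as.array(values)
  storage.mode(values) <- "logical"
  nd <- length(dim(values))
  if (length(voxelSizeUm) == 1L) voxelSizeUm <- rep(voxelSizeUm, nd)
  new("BinaryMask", values = values, voxelSizeUm = as.numeric(voxelSizeUm),
      analyzedPx = as.numeric(analyzedPx), metadata = metadata)
}

#' PlotProfile: grey values sampled along a line
#'
#' Ordered (position, grey value) samples along a measurement line, the input
#' to grid-contrast computation and Gaussian PSF fitting.
#'
#' @slot positionsUm strictly increasing positions in micrometres.
#' @slot grey nonnegative grey values, same length.
#' @exportClass PlotProfile
setClass("PlotProfile",
  representation(positionsUm = "numeric", grey = "numeric"))

setValidity("PlotProfile", function(object) {
  msg <- character()
  if (length(object@positionsUm) < 2L)
    msg <- c(msg, "a profile needs at least 2 samples")
  if (length(object@positionsUm) != length(object@grey))
    msg <- c(msg, "positions and grey values must have equal length")
  if (any(diff(object@positionsUm) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (any(object@grey < 0)) msg <- c(msg, "grey values must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a PlotProfile
#' @param positionsUm strictly increasing positions (µm).
#' @param grey nonnegative grey values.
#' @return A \linkS4class{PlotProfile}.
#' @export
PlotProfile <- function(positionsUm, grey)
  new("PlotProfile", positionsUm = as.numeric(positionsUm),
      grey = as.numeric(grey))

#' ContrastResult: Michelson-type contrast over a profile window
#'
#' @slot c contrast \eqn{(g_{max}-g_{min})/(g_{max}+g_{min})}, in [0, 1].
#' @slot gMax,gMin extreme grey levels inside the window.
#' @slot windowStartUm,windowEndUm window bounds in micrometres.
#' @exportClass ContrastResult
setClass("ContrastResult",
  representation(c = "numeric", gMax = "numeric", gMin = "numeric",
                 windowStartUm = "numeric", windowEndUm = "numeric"))

setValidity("ContrastResult", function(object) {
  msg <- character()
  if (object@gMin < 0 || object@gMax < object@gMin)
    msg <- c(msg, "need gMax >= gMin >= 0")
  if (object@c < 0 || object@c > 1) msg <- c(msg, "contrast must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' GaussianFit: fitted Gaussian PSF parameters
#'
#' Parameters of the peak model
#' \deqn{I(x) = I_0 + A \exp\{-4\ln 2\,(x-x_c)^2/w^2\} / (w\sqrt{\pi/4\ln 2})}
#' in which \code{w} is directly the full width at half maximum and \code{a}
#' the peak area.
#'
#' @slot i0 baseline intensity (counts).
#' @slot xc peak centre (µm).
#' @slot a area-like coefficient (counts·µm).
#' @slot w FWHM (µm), strictly positive.
#' @slot rss residual sum of squares of the fit.
#' @slot converged logical optimizer status.
#' @exportClass GaussianFit
setClass("GaussianFit",
  representation(i0 = "numeric", xc = "numeric", a = "numeric", w = "numeric",
                 rss = "numeric", converged = "logical"))

setValidity("GaussianFit", function(object) {
  msg <- character()
  if (object@w <= 0) msg <- c(msg, "w (FWHM) must be positive")
  if (object@rss < 0) msg <- c(msg, "rss must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' IntensityHistogram: normalized per-level intensity frequencies
#'
#' Houses the normalized frequency \code{F(I)} and the peak-top level used by
#' the histogram-mode variance quality score. Only levels with nonzero counts
#' are retained; when clipped levels are excluded, normalization happens after
#' the exclusion so retained frequencies sum to 1.
#'
#' @slot levels integer intensity levels present.
#' @slot freq normalized frequencies (sum 1).
#' @slot bitDepth integer bit depth.
#' @slot peakLevel the modal level \code{I_p} (lowest level among ties).
#' @slot excludedLevels levels removed before normalization.
#' @exportClass IntensityHistogram
setClass("IntensityHistogram",
  representation(levels = "integer", freq = "numeric", bitDepth = "integer",
                 peakLevel = "integer", excludedLevels = "integer"))

setValidity("IntensityHistogram", function(object) {
  msg <- character()
  if (length(object@levels) != length(object@freq))
    msg <- c(msg, "levels and freq must have equal length")
  if (length(object@freq)) {
    if (any(object@freq < 0)) msg <- c(msg, "frequencies must be nonnegative")
    if (abs(sum(object@freq) - 1) > 1e-12)
      msg <- c(msg, "frequencies must sum to 1")
    if (!object@peakLevel %in% object@levels)
      msg <- c(msg, "peakLevel must be one of the retained levels")
  }
  if (length(msg)) msg else TRUE
})

#' SceneConfig: parameters of the synthetic honeycomb scene
#'
#' Describes the phantom the generators emulate: bright gluten walls
#' surrounding dark spherical starch-granule voids (default void radius 15 µm,
#' i.e. ~30 µm granules) on a jittered hexagonal-close-packed lattice.
#'
#' @slot shapeVoxels integer triple (nz, ny, nx).
#' @slot voxelSizeUm positive triple (z, y, x) in µm.
#' @slot granuleRadiusUm void radius (µm), default 15.
#' @slot granuleSpacingUm lattice nearest-neighbour distance (µm).
#' @slot wallIntensity,backgroundIntensity wall/void counts; wall > background.
#' @slot noiseModel one of \code{"none"}, \code{"gaussian"}, \code{"poisson"}.
#' @slot noiseScale nonnegative noise scale (gaussian sd, or poisson gain).
#' @slot jitterFrac lattice jitter as a fraction of spacing, default 0.1.
#' @slot bitDepth integer bit depth, default 12.
#' @slot rngSeed integer seed making generation reproducible.
#' @exportClass SceneConfig
setClass("SceneConfig",
  representation(shapeVoxels = "integer", voxelSizeUm = "numeric",
                 granuleRadiusUm = "numeric", granuleSpacingUm = "numeric",
                 wallIntensity = "numeric", backgroundIntensity = "numeric",
                 noiseModel = "character", noiseScale = "numeric",
                 jitterFrac = "numeric", bitDepth = "integer",
                 rngSeed = "integer"))

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (length(object@shapeVoxels) != 3L || any(object@shapeVoxels < 1L))
    msg <- c(msg, "shapeVoxels must be 3 positive integers")
  if (length(object@voxelSizeUm) != 3L || any(object@voxelSizeUm <= 0))
    msg <- c(msg, "voxelSizeUm must be 3 positive values")
  if (object@granuleRadiusUm <= 0) msg <- c(msg, "granuleRadiusUm must be > 0")
  if (object@granuleSpacingUm <= 0)
    msg <- c(msg, "granuleSpacingUm must be > 0")
  if (object@granuleRadiusUm >= object@granuleSpacingUm / 2)
    msg <- c(msg, "need granuleRadiusUm < granuleSpacingUm/2 (non-overlapping voids)")
  if (object@wallIntensity <= object@backgroundIntensity)
    msg <- c(msg, "wallIntensity must exceed backgroundIntensity")
  if (object@backgroundIntensity < 0)
    msg <- c(msg, "backgroundIntensity must be nonnegative")
  if (!object@noiseModel %in% c("none", "gaussian", "poisson"))
    msg <- c(msg, "noiseModel must be none/gaussian/poisson")
  if (object@noiseScale < 0) msg <- c(msg, "noiseScale must be nonnegative")
  if (object@jitterFrac < 0 || object@jitterFrac >= 0.5)
    msg <- c(msg, "jitterFrac must be in [0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' Construct a SceneConfig
#'
#' @param shapeVoxels integer triple (nz, ny, nx).
#' @param voxelSizeUm voxel pitch (µm); scalar recycled.
#' @param granuleRadiusUm starch-void radius (µm), default 15.
#' @param granuleSpacingUm lattice spacing (µm).
#' @param wallIntensity,backgroundIntensity wall and void counts
#'   (defaults 3000 / 500, 12-bit scale).
#' @param noiseModel,noiseScale detector noise model and scale.
#' @param jitterFrac lattice jitter fraction, default 0.1.
#' @param bitDepth default 12.
#' @param rngSeed integer seed, default 1.
#' @return A \linkS4class{SceneConfig}.
#' @export
SceneConfig <- function(shapeVoxels, voxelSizeUm = 1, granuleRadiusUm = 15,
                        granuleSpacingUm = 46, wallIntensity = 3000,
                        backgroundIntensity = 500,
                        noiseModel = c("none", "gaussian", "poisson"),
                        noiseScale = 0, jitterFrac = 0.1, bitDepth = 12L,
                        rngSeed = 1L) {
  if (length(voxelSizeUm) == 1L) voxelSizeUm <- rep(voxelSizeUm, 3L)
  new("SceneConfig", shapeVoxels = as.integer(shapeVoxels),
      voxelSizeUm = as.numeric(voxelSizeUm),
      granuleRadiusUm = granuleRadiusUm, granuleSpacingUm = granuleSpacingUm,
      wallIntensity = wallIntensity, backgroundIntensity = backgroundIntensity,
      noiseModel = match.arg(noiseModel), noiseScale = noiseScale,
      jitterFrac = jitterFrac, bitDepth = as.integer(bitDepth),
      rngSeed = as.integer(rngSeed))
}

#' NetworkParams: protein-network analysis settings
#'
#' The settings applied before skeleton morphometrics, mirroring the
#' vessel-analysis convention: a characteristic structure thickness driving
#' the smoothing scale, an intensity window restricting the analyzed region,
#' a small-particle removal threshold and an (off by default) hole filling
#' switch.
#'
#' @slot vesselThicknessPx expected structure thickness (px), default 8.
#' @slot intensityLow,intensityHigh analyzed intensity window, default 0-255.
#' @slot minParticlePx components strictly smaller than this are removed,
#'   default 30.
#' @slot fillHoles fill background holes enclosed by foreground, default FALSE.
#' @exportClass NetworkParams
setClass("NetworkParams",
  representation(vesselThicknessPx = "integer", intensityLow = "numeric",
                 intensityHigh = "numeric", minParticlePx = "integer",
                 fillHoles = "logical"))

setValidity("NetworkParams", function(object) {
  msg <- character()
  if (object@vesselThicknessPx < 1L)
    msg <- c(msg, "vesselThicknessPx must be >= 1")
  if (object@intensityLow > object@intensityHigh)
    msg <- c(msg, "need intensityLow <= intensityHigh")
  if (object@minParticlePx < 0L) msg <- c(msg, "minParticlePx must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct NetworkParams
#' @param vesselThicknessPx structure thickness in pixels (default 8).
#' @param intensityLow,intensityHigh analyzed intensity window (default 0, 255).
#' @param minParticlePx small-particle threshold (default 30; components with
#'   fewer pixels are removed, "under 30" read strictly).
#' @param fillHoles logical, default FALSE.
#' @return A \linkS4class{NetworkParams}.
#' @export
NetworkParams <- function(vesselThicknessPx = 8L, intensityLow = 0,
                          intensityHigh = 255, minParticlePx = 30L,
                          fillHoles = FALSE)
  new("NetworkParams", vesselThicknessPx = as.integer(vesselThicknessPx),
      intensityLow = intensityLow, intensityHigh = intensityHigh,
      minParticlePx = as.integer(minParticlePx), fillHoles = fillHoles)

#' SkeletonGraph: classified medial skeleton of a binary mask
#'
#' One-pixel-wide skeleton with its pixels classified by 8-neighbour count:
#' endpoints (1 neighbour), junction pixels (>= 3 neighbours, merged into
#' 8-connected junction clusters counted once) and branch pixels, plus the
#' traced node-to-node branches with geodesic lengths (orthogonal step 1,
#' diagonal step sqrt(2), times pixel size).
#'
#' @slot skeleton logical matrix of skeleton pixels.
#' @slot pixelSizeUm pixel pitch (µm).
#' @slot endpoints integer matrix (row, col) of endpoint pixels.
#' @slot junctionPixels integer matrix (row, col) of junction pixels.
#' @slot junctionCluster integer cluster id per junction pixel.
#' @slot branches data.frame with columns \code{branch}, \code{n_px},
#'   \code{length_px}, \code{length_um}, \code{closed}.
#' @exportClass SkeletonGraph
setClass("SkeletonGraph",
  representation(skeleton = "matrix", pixelSizeUm = "numeric",
                 endpoints = "matrix", junctionPixels = "matrix",
                 junctionCluster = "integer", branches = "data.frame"))

#' NetworkMetrics: the five gluten-network morphometrics
#'
#' Area percentage of the gluten phase, junction density, mean branch
#' (gluten) length, endpoint rate and mean gliding-box lacunarity of a binary
#' gluten mask. Densities are reported both per µm² of analyzed area and as
#' raw counts.
#'
#' @slot glutenAreaPercent foreground percentage of the analyzed region.
#' @slot junctionCount,endpointCount raw counts.
#' @slot junctionDensityUm2,endpointsRateUm2 counts per µm² analyzed area.
#' @slot avgGlutenLengthUm mean branch geodesic length (µm).
#' @slot meanLacunarity mean gliding-box lacunarity (>= 1 when defined).
#' @slot analyzedAreaUm2 analyzed area (µm²).
#' @slot branchLengthsUm individual branch lengths (µm).
#' @exportClass NetworkMetrics
setClass("NetworkMetrics",
  representation(glutenAreaPercent = "numeric", junctionCount = "numeric",
                 junctionDensityUm2 = "numeric", avgGlutenLengthUm = "numeric",
                 endpointCount = "numeric", endpointsRateUm2 = "numeric",
                 meanLacunarity = "numeric", analyzedAreaUm2 = "numeric",
                 branchLengthsUm = "numeric"))

#' StressStrainCurve: a compression test record
#'
#' @slot strain nondecreasing strain values in [0, 1].
#' @slot stress nonnegative stress (instrument units or Pa).
#' @exportClass StressStrainCurve
setClass("StressStrainCurve",
  representation(strain = "numeric", stress = "numeric"))

setValidity("StressStrainCurve", function(object) {
  msg <- character()
  if (length(object@strain) != length(object@stress))
    msg <- c(msg, "strain and stress must have equal length")
  if (length(object@strain) < 2L) msg <- c(msg, "need at least 2 points")
  if (any(object@strain < 0 | object@strain > 1))
    msg <- c(msg, "strain must lie in [0, 1]")
  if (any(diff(object@strain) < 0)) msg <- c(msg, "strain must be nondecreasing")
  if (any(object@stress < 0)) msg <- c(msg, "stress must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a StressStrainCurve
#' @param strain nondecreasing strain in [0, 1].
#' @param stress nonnegative stress values.
#' @return A \linkS4class{StressStrainCurve}.
#' @export
StressStrainCurve <- function(strain, stress)
  new("StressStrainCurve", strain = as.numeric(strain),
      stress = as.numeric(stress))
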