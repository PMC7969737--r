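#' Voxel size accessor
#' @param x an object with physical voxel/pixel sizes.
#' @return numeric vector of pitches in micrometres.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Bit depth accessor
#' @param x an object carrying a detector bit depth.
#' @return integer bit depth.
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' Extract a z-slice from a stack
#' @param x an \linkS4class{ImageStack}.
#' @param z 1-based slice index.
#' @return numeric matrix (y, x).
#' @export
setGeneric("getSlice", function(x, z) standardGeneric("getSlice"))

#' Fitted FWHM accessor
#' @param x a \linkS4class{GaussianFit}.
#' @return FWHM in micrometres.
#' @export
setGeneric("fwhm", function(x) standardGeneric("fwhm"))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "ImageStack", function(x) x@voxelSizeUm)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "BinaryMask", function(x) x@voxelSizeUm)

#' @rdname bitDepth
#' @export
setMethod("bitDepth", "ImageStack", function(x) x@bitDepth)

#' @rdname bitDepth
#' @export
setMethod("bitDepth", "IntensityHistogram", function(x) x@bitDepth)

#' @describeIn ImageStack dimensions (nz, ny, nx).
#' @param x an ImageStack.
#' @export
setMethod("dim", "ImageStack", function(x) dim(x@data))

#' @rdname getSlice
#' @export
setMethod("getSlice", "ImageStack", function(x, z) {
  stopifnot(z >= 1L, z <= dim(x@data)[1L])
  x@data[z, , , drop = TRUE]
})

#' @rdname fwhm
#' @export
setMethod("fwhm", "GaussianFit", function(x) x@w)

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "ImageStack: %d x %d x %d voxels (z,y,x), voxel %.3g x %.3g x %.3g um, %d-bit\n",
    d[1], d[2], d[3], object@voxelSizeUm[1], object@voxelSizeUm[2],
    object@voxelSizeUm[3], object@bitDepth))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("BinaryMask: %s, %.2f%% foreground (%g analyzed px)\n",
              paste(d, collapse = " x "),
              100 * sum(object@values) / length(object@values),
              object@analyzedPx))
})

setMethod("show", "PlotProfile", function(object) {
  cat(sprintf("PlotProfile: %d samples over [%.3g, %.3g] um, grey [%.4g, %.4g]\n",
              length(object@grey), min(object@positionsUm),
              max(object@positionsUm), min(object@grey), max(object@grey)))
})

setMethod("show", "ContrastResult", function(object) {
  cat(sprintf("Contrast C = %.4f (gmax %.4g, gmin %.4g) on [%.4g, %.4g] um\n",
              object@c, object@gMax, object@gMin, object@windowStartUm,
              object@windowEndUm))
})

setMethod("show", "GaussianFit", function(object) {
  cat(sprintf(
    "GaussianFit: I0 = %.4g, xc = %.4g um, A = %.5g, FWHM w = %.4g um\n",
    object@i0, object@xc, object@a, object@w))
  cat(sprintf("  rss = %.4g, converged = %s\n", object@rss, object@converged))
})

setMethod("show", "IntensityHistogram", function(object) {
  cat(sprintf(
    "IntensityHistogram: %d retained levels (%d-bit), peak level %d\n",
    length(object@levels), object@bitDepth, object@peakLevel))
  if (length(object@excludedLevels))
    cat("  excluded levels:", paste(object@excludedLevels, collapse = ", "), "\n")
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(
    "SceneConfig: %s voxels at %s um; voids r=%g um on %g um lattice (jitter %.2f)\n",
    paste(object@shapeVoxels, collapse = "x"),
    paste(signif(object@voxelSizeUm, 3), collapse = "x"),
    object@granuleRadiusUm, object@granuleSpacingUm, object@jitterFrac))
  cat(sprintf("  wall %g / background %g counts (%d-bit), noise %s (scale %g), seed %d\n",
              object@wallIntensity, object@backgroundIntensity,
              object@bitDepth, object@noiseModel, object@noiseScale,
              object@rngSeed))
})

setMethod("show", "SkeletonGraph", function(object) {
  cat(sprintf(
    "SkeletonGraph: %d skeleton px, %d endpoints, %d junction clusters, %d branches\n",
    sum(object@skeleton), nrow(object@endpoints),
    if (length(object@junctionCluster)) max(object@junctionCluster) else 0L,
    nrow(object@branches)))
})

setMethod("show", "NetworkMetrics", function(object) {
  cat("NetworkMetrics:\n")
  cat(sprintf("  gluten area        %.2f %%\n", object@glutenAreaPercent))
  cat(sprintf("  junction density   %.4g / um^2  (%g junctions)\n",
              object@junctionDensityUm2, object@junctionCount))
  cat(sprintf("  avg gluten length  %.4g um\n", object@avgGlutenLengthUm))
  cat(sprintf("  endpoints rate     %.4g / um^2  (%g endpoints)\n",
              object@endpointsRateUm2, object@endpointCount))
  cat(sprintf("  mean lacunarity    %.4g\n", object@meanLacunarity))
})

setMethod("show", "StressStrainCurve", function(object) {
  cat(sprintf("StressStrainCurve: %d points, strain [%.3g, %.3g], stress [%.4g, %.4g]\n",
              length(object@strain), min(object@strain), max(object@strain),
              min(object@stress), max(object@stress)))
})
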