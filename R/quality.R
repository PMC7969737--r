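#' Per-level intensity histogram
#'
#' Tabulates integer intensity levels of an image or stack slice. When
#' \code{excludeClipped} is TRUE (the default), the two clipped levels — 0
#' (blocked-up shadows) and \code{2^bitDepth - 1} (blown-out highlights) —
#' are removed before normalization, so the retained frequencies sum to 1.
#' The peak level is the mode of the retained histogram; ties break to the
#' lowest intensity.
#'
#' @param image numeric matrix, array or single-slice
#'   \linkS4class{ImageStack}; integer-valued pixels in
#'   \code{[0, 2^bitDepth - 1]}.
#' @param bitDepth integer bit depth (default 12, or taken from the stack).
#' @param excludeClipped drop levels 0 and \code{2^bitDepth - 1}, default TRUE.
#' @return An \linkS4class{IntensityHistogram}.
#' @export
intensityHistogram <- function(image, bitDepth = 12L, excludeClipped = TRUE) {
  if (is(image, "ImageStack")) {
    bitDepth <- image@bitDepth
    vals <- image@data
  } else {
    vals <- image
  }
  vals <- as.vector(vals)
  vmax <- 2^bitDepth - 1
  if (any(vals < 0 | vals > vmax)) stop("pixel value outside [0, 2^bitDepth - 1]")
  if (any(vals != round(vals))) stop("pixel values must be integer levels")
  counts <- tabulate(as.integer(vals) + 1L, nbins = vmax + 1L)
  levels <- 0:vmax
  excluded <- integer()
  if (excludeClipped) {
    excluded <- c(0L, as.integer(vmax))
    keep <- !(levels %in% excluded)
    counts <- counts[keep]
    levels <- levels[keep]
  }
  nz <- counts > 0L
  counts <- counts[nz]
  levels <- levels[nz]
  if (!length(counts))
    stop("degenerate histogram: no retained intensity levels")
  freq <- counts / sum(counts)
  peak <- levels[which.max(freq)]   # which.max returns the first (lowest) tie
  new("IntensityHistogram", levels = as.integer(levels), freq = freq,
      bitDepth = as.integer(bitDepth), peakLevel = as.integer(peak),
      excludedLevels = excluded)
}

#' Histogram-mode variance (image-quality score)
#'
#' The quality statistic
#' \deqn{VAR = \sum_I (I - I_p)^2 F(I)}
#' over retained intensity levels, where \eqn{I_p} is the intensity at the
#' peak top of the histogram and \eqn{F(I)} the normalized frequency. This is
#' the variance about the histogram \emph{mode}, not the mean: a sharply
#' peaked (low-information, depth-degraded) image scores low, an image with
#' intensity spread over many levels scores high.
#'
#' @param hist an \linkS4class{IntensityHistogram}.
#' @return VAR in squared intensity units; 0 iff all mass is on one level.
#' @export
histogramVAR <- function(hist) {
  stopifnot(is(hist, "IntensityHistogram"))
  validObject(hist)
  sum((hist@levels - hist@peakLevel)^2 * hist@freq)
}

#' Depth profile of image quality through a stack
#'
#' Computes the histogram-mode variance slice by slice; the depth of slice i
#' (1-based) is \code{(i - 1) * z voxel size}. A slice whose histogram is
#' degenerate (e.g. fully clipped) yields NA rather than an error.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param excludeClipped passed to \code{\link{intensityHistogram}}.
#' @return data.frame with columns \code{depth_um} and \code{var}.
#' @export
depthQualityProfile <- function(stack, excludeClipped = TRUE) {
  stopifnot(is(stack, "ImageStack"))
  nz <- dim(stack)[1L]
  if (nz == 0L) stop("stack is empty")
  vz <- stack@voxelSizeUm[1L]
  vars <- vapply(seq_len(nz), function(i) {
    tryCatch(
      histogramVAR(intensityHistogram(getSlice(stack, i), stack@bitDepth,
                                      excludeClipped)),
      error = function(e) NA_real_)
  }, numeric(1))
  data.frame(depth_um = (seq_len(nz) - 1L) * vz, var = vars)
}
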