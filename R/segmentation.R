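#' Otsu threshold on the native-bit-depth histogram
#'
#' Returns the intensity level t maximizing the between-class variance of the
#' two classes split at t (class 1: levels <= t; class 2: levels > t),
#' computed on the full integer-level histogram without rescaling. Ties break
#' to the lowest level. Foreground is by convention strictly greater than the
#' threshold (see \code{\link{binarize}}).
#'
#' @param image numeric matrix/array or \linkS4class{ImageStack} with
#'   integer-valued pixels; needs at least 2 distinct levels.
#' @param bitDepth integer bit depth (default 12, or from the stack).
#' @return the threshold level (integer).
#' @export
otsuThreshold <- function(image, bitDepth = 12L) {
  if (is(image, "ImageStack")) {
    bitDepth <- image@bitDepth
    vals <- as.vector(image@data)
  } else vals <- as.vector(image)
  vmax <- 2^bitDepth - 1
  if (any(vals < 0 | vals > vmax)) stop("pixel value outside [0, 2^bitDepth - 1]")
  vals <- as.integer(round(vals))
  if (length(unique(vals)) < 2L)
    stop("degenerate image: fewer than 2 distinct levels")
  counts <- tabulate(vals + 1L, nbins = vmax + 1L)
  p <- counts / sum(counts)
  lev <- 0:vmax
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  muT <- mu[length(mu)]
  valid <- w0 > 0 & w0 < 1
  sb2 <- rep(-Inf, length(lev))
  sb2[valid] <- (muT * w0[valid] - mu[valid])^2 / (w0[valid] * (1 - w0[valid]))
  lev[which.max(sb2)]
}

#' Binarize an image at a threshold
#'
#' Foreground is strictly greater than the threshold.
#'
#' @param image matrix/array or \linkS4class{ImageStack}.
#' @param threshold threshold level; default: \code{\link{otsuThreshold}}.
#' @param bitDepth used when \code{threshold} must be computed.
#' @return A \linkS4class{BinaryMask} (voxel sizes taken from the stack when
#'   available).
#' @export
binarize <- function(image, threshold = NULL, bitDepth = 12L) {
  if (is(image, "ImageStack")) {
    vs <- image@voxelSizeUm
    if (is.null(threshold)) threshold <- otsuThreshold(image)
    vals <- image@data > threshold
    BinaryMask(vals, vs, metadata = list(threshold = threshold))
  } else {
    if (is.null(threshold)) threshold <- otsuThreshold(image, bitDepth)
    BinaryMask(image > threshold, metadata = list(threshold = threshold))
  }
}

#' Foreground area (or volume) fraction of a mask
#'
#' @param mask a \linkS4class{BinaryMask} or logical array.
#' @return foreground percentage of all cells, in [0, 100].
#' @export
areaFraction <- function(mask) {
  v <- if (is(mask, "BinaryMask")) mask@values else mask
  if (!length(v)) stop("mask is empty")
  100 * sum(v) / length(v)
}

#' Label connected components of a binary mask
#'
#' Maximal connected foreground components under the stated connectivity,
#' labeled 1..K in deterministic scan order. 3D masks support face (6),
#' face+edge (18) and face+edge+corner (26) connectivity; 2D masks support
#' 4 and 8.
#'
#' @param mask a \linkS4class{BinaryMask} or logical array.
#' @param connectivity 6, 18 or 26 for 3D masks (default 26: thin gluten
#'   walls fragment spuriously under stricter connectivities); 4 or 8 for 2D
#'   masks (default 8).
#' @return list with \code{labels} (integer array, 0 = background) and
#'   \code{table}, a data.frame with columns \code{label},
#'   \code{voxel_count} and \code{volume_um3} (voxel count times the product
#'   of the voxel dimensions).
#' @export
labelComponents <- function(mask, connectivity = NULL) {
  if (is(mask, "BinaryMask")) {
    v <- mask@values
    vs <- mask@voxelSizeUm
  } else {
    v <- mask
    vs <- rep(1, length(dim(v)))
  }
  nd <- length(dim(v))
  if (nd == 2L) {
    if (is.null(connectivity)) connectivity <- 8L
    if (!connectivity %in% c(4L, 8L)) stop("2D connectivity must be 4 or 8")
    conn3 <- if (connectivity == 4L) 6L else 26L
    arr <- array(v, c(1L, dim(v)))
  } else if (nd == 3L) {
    if (is.null(connectivity)) connectivity <- 26L
    if (!connectivity %in% c(6L, 18L, 26L))
      stop("3D connectivity must be 6, 18 or 26")
    conn3 <- as.integer(connectivity)
    arr <- v
  } else stop("mask must be 2D or 3D")
  labels <- .label_cc(as.logical(arr), dim(arr), conn3)
  if (nd == 2L) labels <- array(labels, dim(v))
  k <- max(labels)
  cnt <- if (k > 0) tabulate(labels[labels > 0L], nbins = k) else integer()
  voxvol <- prod(vs)
  list(labels = labels,
       table = data.frame(label = seq_len(k), voxel_count = cnt,
                          volume_um3 = cnt * voxvol),
       connectivity = as.integer(connectivity))
}

#' Volume distribution of labeled gluten clumps
#'
#' Bins per-component physical volumes and reports how concentrated the
#' total gluten volume is in the largest clumps.
#'
#' @param table component table from \code{\link{labelComponents}} (columns
#'   \code{label}, \code{voxel_count}, \code{volume_um3}).
#' @param binEdgesUm3 histogram bin edges (µm³); default: 10 equal-width bins
#'   spanning \code{[0, max volume]}.
#' @param topK report the cumulative volume fraction of the largest k
#'   components for k = 1..topK (default 5, capped at the component count).
#' @return list with \code{histogram} (data.frame \code{bin_low_um3},
#'   \code{bin_high_um3}, \code{count}), \code{total_volume_um3} and
#'   \code{top_fraction} (named numeric). An empty table yields empty
#'   results with a warning.
#' @export
volumeDistribution <- function(table, binEdgesUm3 = NULL, topK = 5L) {
  if (nrow(table) == 0L) {
    warning("empty component table")
    return(list(histogram = data.frame(bin_low_um3 = numeric(),
                                       bin_high_um3 = numeric(),
                                       count = integer()),
                total_volume_um3 = 0, top_fraction = numeric()))
  }
  vols <- table$volume_um3
  if (is.null(binEdgesUm3))
    binEdgesUm3 <- seq(0, max(vols), length.out = 11L)
  counts <- as.integer(table(cut(vols, binEdgesUm3, include.lowest = TRUE,
                                 right = TRUE)))
  total <- sum(vols)
  kk <- seq_len(min(topK, length(vols)))
  topfrac <- cumsum(sort(vols, decreasing = TRUE))[kk] / total
  names(topfrac) <- paste0("top", kk)
  list(histogram = data.frame(bin_low_um3 = head(binEdgesUm3, -1L),
                              bin_high_um3 = binEdgesUm3[-1L],
                              count = counts),
       total_volume_um3 = total,
       top_fraction = topfrac)
}
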