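#' Opacity of a transmitted-light image
#'
#' Transparency readout of a cleared sample photographed with white
#' transillumination: the mean grey value of the background (reference region
#' of the dish) divided by the mean grey value of the sample. An opaque sample
#' transmits less light, so opacity is > 1 and tends to 1 as the sample
#' becomes fully transparent.
#'
#' @param sampleMeanGrey mean grey level over the sample region (> 0).
#' @param backgroundMeanGrey mean grey level over the background region (> 0).
#' @return opacity ratio (dimensionless).
#' @examples
#' computeOpacity(50, 200)   # strongly opaque: 4
#' computeOpacity(200, 200)  # fully transparent: 1
#' @export
computeOpacity <- function(sampleMeanGrey, backgroundMeanGrey) {
  if (any(sampleMeanGrey <= 0) || any(backgroundMeanGrey <= 0))
    stop("grey values must be positive")
  backgroundMeanGrey / sampleMeanGrey
}

#' Linear expansion ratio
#'
#' Ratio of sample width after treatment to a reference width, quantifying
#' clearing-induced swelling.
#'
#' @param widthTUm sample width at time t (µm or any fixed unit), > 0.
#' @param widthReferenceUm reference width in the same unit, > 0.
#' @return expansion ratio.
#' @export
linearExpansion <- function(widthTUm, widthReferenceUm) {
  if (any(widthTUm <= 0) || any(widthReferenceUm <= 0))
    stop("widths must be positive")
  widthTUm / widthReferenceUm
}

#' Extract a grey-value profile along a line
#'
#' Samples grey values by bilinear interpolation along the segment from
#' \code{startPx} to \code{endPx} (continuous 0-based pixel coordinates,
#' \code{c(x, y)}), optionally averaging over parallel lines offset
#' perpendicular to the segment. Sampling is uniform with spacing at most one
#' pixel, and the profile extent equals the Euclidean endpoint distance times
#' \code{pixelSizeUm} exactly.
#'
#' @param image matrix or single-slice \linkS4class{ImageStack}.
#' @param startPx,endPx numeric pairs \code{c(x, y)}, 0-based pixel coords.
#' @param pixelSizeUm pixel pitch (µm).
#' @param averagingWidthPx odd integer; number of parallel lines averaged.
#' @return A \linkS4class{PlotProfile}.
#' @export
extractProfile <- function(image, startPx, endPx, pixelSizeUm = 1,
                           averagingWidthPx = 1L) {
  img <- as_image_matrix(image)
  check_positive_scalar(pixelSizeUm, "pixelSizeUm")
  if (averagingWidthPx < 1L || averagingWidthPx %% 2L == 0L)
    stop("averagingWidthPx must be a positive odd integer")
  dx <- endPx[1] - startPx[1]
  dy <- endPx[2] - startPx[2]
  L <- sqrt(dx^2 + dy^2)
  if (L == 0) stop("profile endpoints coincide")
  n <- ceiling(L) + 1L
  t <- seq(0, L, length.out = n)
  ux <- dx / L; uy <- dy / L
  px <- -uy; py <- ux                      # unit perpendicular
  offs <- seq_len(averagingWidthPx) - (averagingWidthPx + 1L) / 2
  grey <- rowMeans(vapply(offs, function(o) {
    bilinear_sample(img, startPx[1] + t * ux + o * px,
                    startPx[2] + t * uy + o * py)
  }, numeric(n)))
  PlotProfile(t * pixelSizeUm, grey)
}

#' Michelson-type contrast of a profile window
#'
#' Contrast \eqn{C = (g_{max} - g_{min}) / (g_{max} + g_{min})} of the grey
#' values inside a window of a plot profile, the readout used to score how
#' visibly a grid pattern penetrates a cleared sample. The canonical window
#' is 5 mm long; by default the whole profile is used (no window search is
#' performed — the caller chooses the window).
#'
#' @param profile a \linkS4class{PlotProfile}.
#' @param windowStartUm window start (µm); default: profile start.
#' @param windowLengthUm window length (µm); default: to the profile end.
#'   The conventional choice for grid photographs is 5000 µm.
#' @return A \linkS4class{ContrastResult}.
#' @export
profileContrast <- function(profile, windowStartUm = NULL,
                            windowLengthUm = NULL) {
  stopifnot(is(profile, "PlotProfile"))
  validObject(profile)
  pos <- profile@positionsUm
  if (is.null(windowStartUm)) windowStartUm <- pos[1L]
  wEnd <- if (is.null(windowLengthUm)) pos[length(pos)] else
    windowStartUm + windowLengthUm
  if (windowStartUm < pos[1L] - 1e-9 || wEnd > pos[length(pos)] + 1e-9)
    stop("window extends beyond the profile extent")
  sel <- pos >= windowStartUm - 1e-9 & pos <= wEnd + 1e-9
  if (sum(sel) < 2L) stop("window contains fewer than 2 samples")
  g <- profile@grey[sel]
  gMax <- max(g); gMin <- min(g)
  if (gMax + gMin == 0) stop("contrast undefined: gmax + gmin = 0")
  new("ContrastResult", c = (gMax - gMin) / (gMax + gMin), gMax = gMax,
      gMin = gMin, windowStartUm = windowStartUm, windowEndUm = wEnd)
}

#' Resample a stress-strain curve on a strain grid
#'
#' Piecewise-linear interpolation of stress at given strain values; the
#' conventional reporting grid for compression tests is strain 0.1 to 0.9 in
#' steps of 0.1. No extrapolation: grid points outside the measured strain
#' range are an error.
#'
#' @param curve a \linkS4class{StressStrainCurve}.
#' @param strainGrid strain values to interpolate at
#'   (default \code{seq(0.1, 0.9, by = 0.1)}).
#' @return data.frame with columns \code{strain} and \code{stress}.
#' @export
resampleStressStrain <- function(curve, strainGrid = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(is(curve, "StressStrainCurve"))
  validObject(curve)
  rng <- range(curve@strain)
  if (any(strainGrid < rng[1] - 1e-12 | strainGrid > rng[2] + 1e-12))
    stop("strain grid point outside the measured range (no extrapolation)")
  st <- stats::approx(curve@strain, curve@stress, xout = strainGrid,
                      ties = "ordered")$y
  data.frame(strain = strainGrid, stress = st)
}
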