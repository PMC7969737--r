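#' Gaussian peak model with FWHM parameterization
#'
#' The bead intensity model
#' \deqn{I(x) = I_0 + \frac{A \exp\{-4\ln 2\,(x - x_c)^2 / w^2\}}
#'   {w \sqrt{\pi / 4\ln 2}}}
#' in which \code{i0} is the baseline fluorescence, \code{xc} the peak
#' centre, \code{a} the peak area and \code{w} directly the full width at
#' half maximum — so the fitted \code{w} is the resolution estimate.
#'
#' @param x positions (µm).
#' @param i0 baseline intensity (counts).
#' @param xc peak centre (µm).
#' @param a area coefficient (counts·µm).
#' @param w FWHM (µm), > 0.
#' @return model intensities at \code{x}.
#' @examples
#' gaussianPeak(5.16, i0 = 156.2, xc = 5.16, a = 1346.9, w = 0.509)
#' @export
gaussianPeak <- function(x, i0, xc, a, w) {
  if (w <= 0) stop("w (FWHM) must be positive")
  i0 + a * exp(-4 * log(2) * (x - xc)^2 / w^2) / (w * sqrt(pi / (4 * log(2))))
}

# Data-driven starting values: baseline from the minimum, centre from the
# argmax, width from the empirical full width at half of (max - min) found by
# linear interpolation of the half-level crossings.
psf_start_values <- function(x, y) {
  i0 <- min(y)
  m <- which.max(y)
  if (m == 1L || m == length(y) || max(y) <= i0)
    stop("profile has no strict interior maximum; cannot set up a peak fit")
  half <- i0 + (y[m] - i0) / 2
  cross <- function(idx) {
    # linear interpolation of the crossing between consecutive samples
    i1 <- idx[1]; i2 <- idx[2]
    x[i1] + (half - y[i1]) * (x[i2] - x[i1]) / (y[i2] - y[i1])
  }
  left <- which(y[seq_len(m - 1L)] <= half)
  right <- which(y[seq(m + 1L, length(y))] <= half) + m
  w0 <- if (length(left) && length(right)) {
    l <- max(left); r <- min(right)
    cross(c(r - 1L, r)) - cross(c(l, l + 1L))
  } else {
    diff(range(x)) / 4    # broad peak: fall back to a quarter of the span
  }
  if (!is.finite(w0) || w0 <= 0) w0 <- diff(range(x)) / 4
  a0 <- (y[m] - i0) * w0 * sqrt(pi / (4 * log(2)))
  list(i0 = i0, xc = x[m], a = a0, w = w0)
}

#' Fit the Gaussian PSF model to a bead profile
#'
#' Levenberg-Marquardt least-squares fit of \code{\link{gaussianPeak}} to an
#' intensity profile through a fluorescent bead. Starting values are derived
#' from the data (never supplied externally); positivity of the FWHM is
#' enforced by fitting \code{log w} internally.
#'
#' @param profile a \linkS4class{PlotProfile} with at least 5 samples and a
#'   strict interior maximum.
#' @return A \linkS4class{GaussianFit}. Non-convergence is reported through
#'   the \code{converged} slot with best-effort parameters, not an error.
#' @export
fitPSF <- function(profile) {
  stopifnot(is(profile, "PlotProfile"))
  validObject(profile)
  x <- profile@positionsUm
  y <- profile@grey
  if (length(x) < 5L) stop("need at least 5 profile samples")
  s <- psf_start_values(x, y)
  dat <- data.frame(x = x, y = y)
  k <- sqrt(pi / (4 * log(2)))
  fit <- minpack.lm::nlsLM(
    y ~ i0 + a * exp(-4 * log(2) * (x - xc)^2 / exp(2 * lw)) / (exp(lw) * k),
    data = dat,
    start = list(i0 = s$i0, xc = s$xc, a = s$a, lw = log(s$w)),
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                         maxiter = 1000, maxfev = 1000))
  co <- stats::coef(fit)
  new("GaussianFit", i0 = unname(co["i0"]), xc = unname(co["xc"]),
      a = unname(co["a"]), w = unname(exp(co["lw"])),
      rss = stats::deviance(fit), converged = isTRUE(fit$convInfo$isConv))
}

#' Summarize FWHM across bead fits
#'
#' Sample mean and SD (n - 1 denominator) of the fitted FWHM over replicate
#' bead measurements — the "resolution = mean ± SD" reporting convention.
#'
#' @param fits list of converged \linkS4class{GaussianFit} objects.
#' @return list with \code{meanFwhmUm}, \code{sdFwhmUm} (0 for a single
#'   fit) and \code{n}.
#' @export
resolutionSummary <- function(fits) {
  if (length(fits) == 0L) stop("need at least one fit")
  ok <- vapply(fits, function(f) is(f, "GaussianFit"), logical(1))
  if (!all(ok)) stop("all elements must be GaussianFit objects")
  if (!all(vapply(fits, function(f) f@converged, logical(1))))
    stop("all fits must have converged")
  ws <- vapply(fits, fwhm, numeric(1))
  list(meanFwhmUm = mean(ws),
       sdFwhmUm = if (length(ws) > 1L) stats::sd(ws) else 0,
       n = length(ws))
}
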