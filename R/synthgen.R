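#' @useDynLib doughscope, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Jittered hexagonal-close-packed void centres (um), restricted to spheres
# fully inside the scene so the analytic void volume is exact. Deterministic
# for a fixed config (seed included).
honeycomb_centers <- function(config) {
  a <- config@granuleSpacingUm
  r <- config@granuleRadiusUm
  ext <- config@shapeVoxels * config@voxelSizeUm        # (Lz, Ly, Lx)
  dy <- a * sqrt(3) / 2
  dz <- a * sqrt(6) / 3
  ks <- seq(0L, ceiling(ext[1] / dz))
  js <- seq(0L, ceiling(ext[2] / dy))
  is <- seq(0L, ceiling(ext[3] / a))
  grid <- expand.grid(i = is, j = js, k = ks)
  bshift <- grid$k %% 2                                  # B layers of the ABAB stack
  cx <- a * (grid$i + 0.5 * (grid$j %% 2) + 0.5 * bshift)
  cy <- dy * grid$j + a * sqrt(3) / 6 * bshift
  cz <- dz * grid$k
  centers <- cbind(z = cz, y = cy, x = cx)
  if (config@jitterFrac > 0) {
    jit <- with_seed(config@rngSeed,
      matrix(stats::runif(length(centers), -1, 1), ncol = 3)) *
      config@jitterFrac * a
    centers <- centers + jit
  }
  keep <- centers[, 1] >= r & centers[, 1] <= ext[1] - r &
          centers[, 2] >= r & centers[, 2] <= ext[2] - r &
          centers[, 3] >= r & centers[, 3] <= ext[3] - r
  centers <- centers[keep, , drop = FALSE]
  if (nrow(centers) > 1L && min(stats::dist(centers)) < 2 * r)
    stop("overlapping voids: jittered centres closer than one void diameter; ",
         "reduce jitterFrac or granuleRadiusUm")
  centers
}

#' Analytic wall (foreground) fraction of a honeycomb scene
#'
#' The volume fraction occupied by gluten walls in the noise-free scene:
#' \code{1 - n * (4/3) pi r^3 / V}, exact because the generator only places
#' void spheres that are disjoint and fully inside the volume. Serves as the
#' ground truth that segmentation-based area fractions are checked against.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @return wall volume fraction in [0, 1].
#' @export
wallFraction <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  centers <- honeycomb_centers(config)
  vol <- prod(config@shapeVoxels * config@voxelSizeUm)
  1 - nrow(centers) * (4 / 3) * pi * config@granuleRadiusUm^3 / vol
}

#' Generate a honeycomb gluten-wall phantom stack
#'
#' Renders bright walls (\code{wallIntensity}) everywhere except inside dark
#' spherical voids (\code{backgroundIntensity}) placed on a jittered HCP
#' lattice — the geometry of a gluten network surrounding ~30 µm starch
#' granules. Deterministic for a fixed \code{rngSeed}.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @return An \linkS4class{ImageStack}.
#' @examples
#' cfg <- SceneConfig(c(32, 64, 64), voxelSizeUm = 1, rngSeed = 7)
#' stk <- makeHoneycombStack(cfg)
#' wallFraction(cfg)
#' @export
makeHoneycombStack <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  d <- config@shapeVoxels
  v <- config@voxelSizeUm
  r <- config@granuleRadiusUm
  vol <- array(config@wallIntensity, dim = d)
  centers <- honeycomb_centers(config)
  # voxel-centre positions per axis
  pos <- lapply(1:3, function(ax) (seq_len(d[ax]) - 0.5) * v[ax])
  for (ci in seq_len(nrow(centers))) {
    ctr <- centers[ci, ]
    idx <- lapply(1:3, function(ax) {
      which(abs(pos[[ax]] - ctr[ax]) <= r)
    })
    if (any(lengths(idx) == 0L)) next
    d2 <- lapply(1:3, function(ax) (pos[[ax]][idx[[ax]]] - ctr[ax])^2)
    cube <- outer(outer(d2[[1]], d2[[2]], "+"), d2[[3]], "+")
    inside <- cube <= r^2
    sub <- vol[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    sub[inside] <- config@backgroundIntensity
    vol[idx[[1]], idx[[2]], idx[[3]]] <- sub
  }
  vol[] <- apply_noise_and_quantize(vol, config@noiseModel, config@noiseScale,
                                    config@bitDepth, config@rngSeed)
  ImageStack(vol, config@voxelSizeUm, config@bitDepth)
}

# Radial profile of a uniform ball of radius R convolved with an isotropic
# Gaussian of sd sigma (closed form; r and R in the same units).
ball_gauss_profile <- function(r, R, sigma) {
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  out <- numeric(length(r))
  tiny <- r < 1e-9 * sigma
  if (any(!tiny)) {
    rr <- r[!tiny]
    out[!tiny] <- 0.5 * (erf((R - rr) / (sigma * sqrt(2))) +
                         erf((R + rr) / (sigma * sqrt(2)))) -
      sigma / (rr * sqrt(2 * pi)) *
        (exp(-(rr - R)^2 / (2 * sigma^2)) - exp(-(rr + R)^2 / (2 * sigma^2)))
  }
  if (any(tiny))
    out[tiny] <- erf(R / (sigma * sqrt(2))) -
      R * sqrt(2 / pi) / sigma * exp(-R^2 / (2 * sigma^2))
  out
}

#' Generate a fluorescent-bead calibration stack
#'
#' Each bead is a uniform sphere convolved with an isotropic Gaussian PSF of
#' the given FWHM (closed-form radial profile, truncated at 4 sigma), scaled
#' so its on-centre value equals \code{peak_intensity}, and added to the
#' scene's background baseline. Sub-resolution beads (diameter much smaller
#' than the FWHM) therefore image as Gaussian spots whose measured FWHM is
#' the PSF FWHM — the bead-based resolution calibration this emulates.
#'
#' @param beads data.frame with columns \code{x_um}, \code{y_um}, \code{z_um},
#'   \code{diameter_um}, \code{peak_intensity}; may have zero rows.
#' @param psfFwhmUm PSF full width at half maximum (µm), > 0.
#' @param config a \linkS4class{SceneConfig}; supplies scene shape, baseline
#'   (\code{backgroundIntensity}), bit depth and noise settings.
#' @return An \linkS4class{ImageStack}.
#' @export
makeBeadStack <- function(beads, psfFwhmUm, config) {
  stopifnot(is(config, "SceneConfig"))
  check_positive_scalar(psfFwhmUm, "psfFwhmUm")
  d <- config@shapeVoxels
  v <- config@voxelSizeUm
  ext <- d * v
  vol <- array(config@backgroundIntensity, dim = d)
  if (nrow(beads)) {
    need <- c("x_um", "y_um", "z_um", "diameter_um", "peak_intensity")
    if (!all(need %in% names(beads)))
      stop("beads needs columns ", paste(need, collapse = ", "))
    if (any(beads$diameter_um <= 0)) stop("bead diameter_um must be > 0")
    if (any(beads$z_um < 0 | beads$z_um > ext[1] |
            beads$y_um < 0 | beads$y_um > ext[2] |
            beads$x_um < 0 | beads$x_um > ext[3]))
      stop("bead centre outside scene bounds")
    sigma <- psfFwhmUm / (2 * sqrt(2 * log(2)))
    pos <- lapply(1:3, function(ax) (seq_len(d[ax]) - 0.5) * v[ax])
    for (bi in seq_len(nrow(beads))) {
      ctr <- c(beads$z_um[bi], beads$y_um[bi], beads$x_um[bi])
      R <- beads$diameter_um[bi] / 2
      reach <- R + 4 * sigma
      idx <- lapply(1:3, function(ax) which(abs(pos[[ax]] - ctr[ax]) <= reach))
      if (any(lengths(idx) == 0L)) next
      d2 <- lapply(1:3, function(ax) (pos[[ax]][idx[[ax]]] - ctr[ax])^2)
      rad <- sqrt(outer(outer(d2[[1]], d2[[2]], "+"), d2[[3]], "+"))
      prof <- ball_gauss_profile(as.vector(rad), R, sigma)
      peak0 <- ball_gauss_profile(0, R, sigma)
      add <- array(beads$peak_intensity[bi] * prof / peak0, dim = dim(rad))
      vol[idx[[1]], idx[[2]], idx[[3]]] <-
        vol[idx[[1]], idx[[2]], idx[[3]]] + add
    }
  }
  vol[] <- apply_noise_and_quantize(vol, config@noiseModel, config@noiseScale,
                                    config@bitDepth, config@rngSeed)
  ImageStack(vol, config@voxelSizeUm, config@bitDepth)
}

#' Generate a grid-pattern transmission image
#'
#' Emulates photographing a grid-printed film through a (partially cleared)
#' sample: dark grid lines on a bright background, Gaussian-blurred, then
#' blended towards the image mean by \code{scatterLevel} (1 gives a uniform
#' image, i.e. a fully scattering sample).
#'
#' @param gridSpacingUm grid period (µm).
#' @param lineWidthUm line width (µm), must be < \code{gridSpacingUm}.
#' @param blurFwhmUm Gaussian blur FWHM (µm); 0 for none.
#' @param scatterLevel scattering strength in [0, 1].
#' @param imageSize integer pair (ny, nx) in pixels.
#' @param pixelSizeUm pixel pitch (µm).
#' @param backgroundGrey,lineGrey grey levels of background and lines.
#' @return numeric matrix with attribute \code{pixelSizeUm}.
#' @export
makeGridTransmission <- function(gridSpacingUm, lineWidthUm, blurFwhmUm = 0,
                                 scatterLevel = 0, imageSize = c(256, 256),
                                 pixelSizeUm = 20,
                                 backgroundGrey = 200, lineGrey = 50) {
  check_positive_scalar(gridSpacingUm, "gridSpacingUm")
  check_positive_scalar(lineWidthUm, "lineWidthUm")
  if (lineWidthUm >= gridSpacingUm)
    stop("lineWidthUm must be smaller than gridSpacingUm")
  if (scatterLevel < 0 || scatterLevel > 1)
    stop("scatterLevel must be in [0, 1]")
  if (lineGrey > backgroundGrey)
    stop("lineGrey must not exceed backgroundGrey (dark lines on bright field)")
  ny <- imageSize[1]; nx <- imageSize[2]
  xs <- (seq_len(nx) - 0.5) * pixelSizeUm
  ys <- (seq_len(ny) - 0.5) * pixelSizeUm
  online <- function(p) {
    s <- gridSpacingUm
    abs(((p + s / 2) %% s) - s / 2) < lineWidthUm / 2
  }
  img <- matrix(backgroundGrey, ny, nx)
  img[online(ys), ] <- lineGrey
  img[, online(xs)] <- lineGrey
  if (blurFwhmUm > 0) {
    sigma_px <- blurFwhmUm / (2 * sqrt(2 * log(2))) / pixelSizeUm
    img <- EBImage::gblur(img, sigma = sigma_px, boundary = "replicate")
  }
  if (scatterLevel > 0)
    img <- (1 - scatterLevel) * img + scatterLevel * mean(img)
  attr(img, "pixelSizeUm") <- pixelSizeUm
  img
}

#' Apply depth-dependent signal degradation to a stack
#'
#' Scales the slice at depth z by \code{exp(-attenuationPerUm * z)} (depth 0
#' at the first slice) before applying detector noise, emulating the loss of
#' fluorescence signal and image quality with imaging depth. Deterministic
#' for a fixed seed.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param attenuationPerUm nonnegative attenuation coefficient (1/µm);
#'   the default 6e-4 reproduces a roughly six-fold quality drop over 1.5 mm.
#' @param noiseModel,noiseScale detector noise applied after attenuation.
#' @param rngSeed integer seed.
#' @return An \linkS4class{ImageStack} of the same geometry.
#' @export
applyDepthDegradation <- function(stack, attenuationPerUm = 6e-4,
                                  noiseModel = c("none", "gaussian", "poisson"),
                                  noiseScale = 0, rngSeed = 1L) {
  stopifnot(is(stack, "ImageStack"))
  noiseModel <- match.arg(noiseModel)
  if (attenuationPerUm < 0) stop("attenuationPerUm must be nonnegative")
  d <- dim(stack)
  if (d[1L] == 0L) stop("stack is empty")
  depths <- (seq_len(d[1L]) - 1L) * stack@voxelSizeUm[1L]
  vol <- stack@data * exp(-attenuationPerUm * depths)  # recycles over z (fastest axis)
  vol[] <- apply_noise_and_quantize(vol, noiseModel, noiseScale,
                                    stack@bitDepth, rngSeed)
  ImageStack(vol, stack@voxelSizeUm, stack@bitDepth)
}
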