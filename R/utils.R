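# Internal helpers shared across modules.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Apply detector noise, then clip to [0, 2^bit - 1] and round to integer
# counts. The poisson model treats noiseScale as a gain: v ~ gain *
# Poisson(v / gain); with noiseScale 0 or 1 it is plain shot noise.
apply_noise_and_quantize <- function(values, noiseModel, noiseScale, bitDepth,
                                     seed) {
  vmax <- 2^bitDepth - 1
  if (noiseModel == "gaussian" && noiseScale > 0) {
    values <- with_seed(seed,
      values + stats::rnorm(length(values), sd = noiseScale))
  } else if (noiseModel == "poisson") {
    gain <- if (noiseScale > 0) noiseScale else 1
    values <- with_seed(seed,
      gain * stats::rpois(length(values), pmax(values, 0) / gain))
  }
  round(pmin(pmax(values, 0), vmax))
}

# Bilinear interpolation of matrix `img` at continuous 0-based (x, y)
# positions, where pixel img[r, c] sits at x = c - 1, y = r - 1.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  if (any(x < 0 | x > nc - 1 | y < 0 | y > nr - 1))
    stop("sample point outside image bounds")
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  # degenerate axes (single row/col) fall back to clamped indexing
  if (nc == 1) x0 <- rep(0, length(x))
  if (nr == 1) y0 <- rep(0, length(y))
  fx <- x - x0; fy <- y - y0
  i0 <- y0 + 1; j0 <- x0 + 1
  i1 <- pmin(i0 + 1, nr); j1 <- pmin(j0 + 1, nc)
  v00 <- img[cbind(i0, j0)]; v01 <- img[cbind(i0, j1)]
  v10 <- img[cbind(i1, j0)]; v11 <- img[cbind(i1, j1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

# Coerce an image argument to a plain numeric matrix (2D) for pixel-level
# operations; accepts matrices and single-slice ImageStacks.
as_image_matrix <- function(image) {
  if (is(image, "ImageStack")) {
    if (dim(image)[1L] != 1L)
      stop("expected a 2D image; got a multi-slice stack")
    return(getSlice(image, 1L))
  }
  if (is.matrix(image)) return(image)
  stop("image must be a matrix or a single-slice ImageStack")
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("%s must be a single positive number", name))
  invisible(x)
}
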