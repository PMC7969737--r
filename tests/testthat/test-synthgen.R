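test_that("honeycomb foreground fraction matches a direct rasterization oracle", {
  cfg <- SceneConfig(c(60, 60, 60), voxelSizeUm = 1, granuleSpacingUm = 46,
                     rngSeed = 4)
  stk <- makeHoneycombStack(cfg)
  fg <- mean(stk@data > 1500)

  # oracle: test every voxel centre against every void sphere directly
  centers <- doughscope:::honeycomb_centers(cfg)
  pos <- (1:60) - 0.5
  inside <- array(FALSE, c(60, 60, 60))
  for (ci in seq_len(nrow(centers))) {
    dz2 <- (pos - centers[ci, 1])^2
    dy2 <- (pos - centers[ci, 2])^2
    dx2 <- (pos - centers[ci, 3])^2
    inside <- inside |
      (outer(outer(dz2, dy2, "+"), dx2, "+") <= cfg@granuleRadiusUm^2)
  }
  expect_equal(fg, mean(!inside), tolerance = 1e-12)

  # and the analytic wall fraction agrees within 1%
  expect_lt(abs(fg - wallFraction(cfg)) / wallFraction(cfg), 0.01)
})

test_that("void-free configuration yields a uniform slab at wall intensity", {
  cfg <- SceneConfig(c(8, 8, 8), voxelSizeUm = 1, granuleRadiusUm = 15,
                     granuleSpacingUm = 46)  # spheres cannot fit inside 8 um
  stk <- makeHoneycombStack(cfg)
  expect_true(all(stk@data == cfg@wallIntensity))
  expect_equal(wallFraction(cfg), 1)
})

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- test_scene(shape = c(40L, 48L, 48L), seed = 9L,
                    noise = "gaussian", noiseScale = 12)
  expect_identical(makeHoneycombStack(cfg)@data, makeHoneycombStack(cfg)@data)
  deg1 <- applyDepthDegradation(makeHoneycombStack(cfg), 1e-3, "poisson",
                                1, rngSeed = 3)
  deg2 <- applyDepthDegradation(makeHoneycombStack(cfg), 1e-3, "poisson",
                                1, rngSeed = 3)
  expect_identical(deg1@data, deg2@data)
})

test_that("scene invariants are enforced", {
  expect_error(SceneConfig(c(10, 10, 10), granuleRadiusUm = 25,
                           granuleSpacingUm = 46), "non-overlapping")
  expect_error(SceneConfig(c(10, 10, 10), wallIntensity = 100,
                           backgroundIntensity = 500), "exceed")
})

test_that("a sub-voxel bead images as a Gaussian with the PSF's FWHM", {
  cfg <- SceneConfig(c(41, 41, 41), voxelSizeUm = 0.1, granuleSpacingUm = 46,
                     backgroundIntensity = 100, rngSeed = 1)
  beads <- data.frame(x_um = 2.05, y_um = 2.05, z_um = 2.05,
                      diameter_um = 0.01, peak_intensity = 2000)
  stk <- makeBeadStack(beads, psfFwhmUm = 0.5, config = cfg)
  prof <- PlotProfile((1:41 - 0.5) * 0.1, stk@data[21, 21, ])
  f <- fitPSF(prof)
  expect_lt(abs(fwhm(f) - 0.5), 0.01)
})

test_that("bead profile FWHM error shrinks at least twofold per grid refinement", {
  measure <- function(vox) {
    n <- as.integer(round(4 / vox)) + 1L
    cfg <- SceneConfig(c(n, n, n), voxelSizeUm = vox, granuleSpacingUm = 46,
                       backgroundIntensity = 100, rngSeed = 1)
    b <- data.frame(x_um = 2, y_um = 2, z_um = 2, diameter_um = 0.01,
                    peak_intensity = 3000)
    stk <- makeBeadStack(b, 0.5, cfg)
    i0 <- as.integer(round(2 / vox + 0.5))
    fwhm(fitPSF(PlotProfile((seq_len(n) - 0.5) * vox, stk@data[i0, i0, ])))
  }
  e_coarse <- abs(measure(0.1) - 0.5)
  e_fine <- abs(measure(0.05) - 0.5)
  expect_lte(e_fine, e_coarse / 2 + 1e-9)
})

test_that("empty bead list gives a constant baseline; two distant beads give two maxima", {
  cfg <- SceneConfig(c(11, 11, 101), voxelSizeUm = 0.1, granuleSpacingUm = 46,
                     backgroundIntensity = 100, rngSeed = 1)
  empty <- makeBeadStack(data.frame(), 0.5, cfg)
  expect_true(all(empty@data == 100))

  beads <- data.frame(x_um = c(2.55, 7.55), y_um = 0.55, z_um = 0.55,
                      diameter_um = 0.01, peak_intensity = 2000)
  stk <- makeBeadStack(beads, 0.5, cfg)  # separation 5 um = 10 x FWHM
  line <- stk@data[6, 6, ]
  peaks <- which(diff(sign(diff(line))) == -2) + 1L
  expect_equal(sum(line[peaks] > 150), 2L)

  expect_error(
    makeBeadStack(data.frame(x_um = 50, y_um = 0.5, z_um = 0.5,
                             diameter_um = 0.01, peak_intensity = 1),
                  0.5, cfg), "outside scene bounds")
})

test_that("grid image reproduces the analytic contrast and degrades with scatter", {
  g <- makeGridTransmission(1000, 200, blurFwhmUm = 0, scatterLevel = 0,
                            imageSize = c(200, 200), pixelSizeUm = 20)
  # profile along a row between horizontal grid lines crosses the vertical lines
  p <- extractProfile(g, c(0, 24), c(199, 24), pixelSizeUm = 20)
  expect_equal(profileContrast(p)@c, (200 - 50) / (200 + 50), tolerance = 1e-12)

  cs <- vapply(seq(0, 1, length.out = 10), function(s) {
    gi <- makeGridTransmission(1000, 200, blurFwhmUm = 300, scatterLevel = s,
                               imageSize = c(100, 100), pixelSizeUm = 20)
    profileContrast(extractProfile(gi, c(0, 24), c(99, 24), 20))@c
  }, numeric(1))
  expect_true(all(diff(cs) <= 1e-12))
  expect_equal(cs[10], 0, tolerance = 1e-12)   # scatter 1: uniform image
})

test_that("depth degradation follows the closed-form attenuation and identity cases", {
  cfg <- test_scene(shape = c(30L, 32L, 32L), seed = 2L)
  stk <- makeHoneycombStack(cfg)
  expect_identical(applyDepthDegradation(stk, 0, "none")@data, stk@data)

  flat <- ImageStack(array(2000, c(20, 16, 16)), voxelSizeUm = c(10, 1, 1))
  mu <- 2e-3
  deg <- applyDepthDegradation(flat, mu, "none")
  depths <- (0:19) * 10
  means <- vapply(1:20, function(i) mean(getSlice(deg, i)), numeric(1))
  expect_true(all(abs(means - 2000 * exp(-mu * depths)) <= 0.5))
})
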