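test_that("enhance/binarize keeps a bright tube and respects the intensity window", {
  img <- matrix(20, 64, 64)
  img[29:36, ] <- 200                       # 8-px-wide bright tube
  mask <- enhanceAndBinarize(img, NetworkParams())
  expect_equal(mask@analyzedPx, 64 * 64)    # 0..255 window excludes nothing
  expect_true(all(mask@values[29:36, ]))    # tube fully inside the mask
  expect_false(any(mask@values[c(1:10, 55:64), ]))
  expect_true(is.numeric(mask@metadata$threshold))

  # a narrow window shrinks the analyzed region
  win <- NetworkParams(intensityLow = 10, intensityHigh = 255)
  img2 <- img; img2[1:3, 1:3] <- 5
  m2 <- enhanceAndBinarize(img2, win)
  expect_equal(m2@analyzedPx, 64 * 64 - 9)

  expect_error(enhanceAndBinarize(matrix(128, 32, 32), NetworkParams()),
               "degenerate")
})

test_that("despeckling removes components strictly under the pixel threshold", {
  m <- matrix(FALSE, 40, 80)
  m[5:9, 5:10] <- TRUE                   # 30 px: retained
  m[20, 20:48] <- TRUE                   # 29 px: removed
  m[35, 70] <- TRUE                      # singleton: removed
  out <- removeSmallParticles(m, 30L)
  expect_true(all(out@values[5:9, 5:10]))
  expect_false(any(out@values[20, ]))
  expect_false(out@values[35, 70])

  big <- matrix(TRUE, 20, 20)
  expect_identical(removeSmallParticles(big, 30L)@values, big)
  # idempotence: despeckling twice changes nothing
  expect_identical(removeSmallParticles(out, 30L)@values, out@values)
})

test_that("skeleton classification matches the canonical fixtures", {
  line <- line_mask(11L)
  sk <- skeletonizeMask(line)
  cl <- classifySkeletonPoints(sk)
  expect_equal(cl$junctionCount, 0L)
  expect_equal(cl$endpointCount, 2L)
  expect_equal(branchLengths(sk), 10)

  diag <- line_mask(11L, diagonal = TRUE)
  skd <- skeletonizeMask(diag)
  expect_equal(branchLengths(skd), 10 * sqrt(2), tolerance = 1e-12)

  plus <- plus_mask(21L, 7L)
  skp <- skeletonizeMask(plus)
  clp <- classifySkeletonPoints(skp)
  expect_equal(clp$junctionCount, 1L)
  expect_equal(clp$endpointCount, 4L)
  expect_equal(nrow(skp@branches), 4L)

  ring <- ring_mask(15L, 5L)
  skr <- skeletonizeMask(ring)
  clr <- classifySkeletonPoints(skr)
  expect_equal(clr$junctionCount, 0L)
  expect_equal(clr$endpointCount, 0L)
  expect_equal(nrow(skr@branches), 1L)
  expect_true(skr@branches$closed)
})

test_that("thinning a filled rectangle leaves one medial branch of the right length", {
  rect <- matrix(FALSE, 15, 60)
  rect[6:10, 6:55] <- TRUE
  sk <- skeletonizeMask(rect)
  expect_equal(nrow(sk@branches), 1L)
  expect_lt(abs(sum(branchLengths(sk)) - 49) / 49, 0.10)
})

test_that("skeletonization preserves the number of connected components", {
  set.seed(9)
  for (i in 1:5) {
    m <- matrix(FALSE, 48, 48)
    for (b in 1:4) {
      r0 <- sample(4:40, 1); c0 <- sample(4:40, 1)
      m[r0:(r0 + sample(2:6, 1)), c0:(c0 + sample(2:6, 1))] <- TRUE
    }
    sk <- skeletonizeMask(m)
    ncomp <- function(v) nrow(labelComponents(v, 8L)$table)
    expect_equal(ncomp(sk@skeleton), ncomp(m))
  }
})

test_that("branch lengths agree with the edge-accounting oracle", {
  fixtures <- list(plus_mask(21L, 7L), line_mask(11L),
                   line_mask(11L, diagonal = TRUE), ring_mask(15L, 5L))
  # an H shape: two verticals bridged by a crossbar
  h <- matrix(FALSE, 21, 21)
  h[4:18, 5] <- TRUE; h[4:18, 15] <- TRUE; h[11, 5:15] <- TRUE
  fixtures$h <- h
  for (m in fixtures) {
    sk <- skeletonizeMask(m)
    expect_equal(sum(branchLengths(sk)),
                 total_branch_length_oracle(sk@skeleton), tolerance = 1e-9)
  }
})

test_that("junction and endpoint counts are invariant under rotation and mirroring", {
  m <- matrix(FALSE, 31, 31)
  m[16, 4:28] <- TRUE; m[4:28, 16] <- TRUE; m[8:24, 8] <- TRUE
  counts <- function(v) {
    cl <- classifySkeletonPoints(skeletonizeMask(v))
    c(cl$junctionCount, cl$endpointCount)
  }
  base <- counts(m)
  expect_equal(counts(t(m)), base)                        # transpose
  expect_equal(counts(m[nrow(m):1, ]), base)              # vertical mirror
  expect_equal(counts(m[, ncol(m):1]), base)              # horizontal mirror
  expect_equal(counts(t(m)[nrow(m):1, ]), base)           # 90 degree rotation
})

test_that("gliding-box lacunarity matches exhaustive enumeration and its bounds", {
  full <- matrix(TRUE, 32, 32)
  lf <- lacunarity(full)
  expect_true(all(lf$perBox$lambda == 1))
  expect_equal(lf$mean, 1)

  # single-pixel closed form at r = 1: 1 / (fraction of boxes occupied)
  single <- matrix(FALSE, 16, 16); single[5, 7] <- TRUE
  expect_equal(lacunarity(single, boxSizes = 1)$mean, 256)

  set.seed(19)
  for (i in 1:10) {
    d <- sample(12:32, 2)
    m <- matrix(runif(prod(d)) < runif(1, 0.15, 0.7), d[1], d[2])
    got <- lacunarity(m, boxSizes = c(2, 4))
    expect_equal(got$perBox$lambda[1], lacunarity_oracle(m, 2), tolerance = 1e-12)
    expect_equal(got$perBox$lambda[2], lacunarity_oracle(m, 4), tolerance = 1e-12)
    expect_true(all(got$perBox$lambda >= 1, na.rm = TRUE))
  }

  empty <- matrix(FALSE, 16, 16)
  expect_warning(le <- lacunarity(empty, boxSizes = 2), "undefined")
  expect_true(is.nan(le$mean) || is.na(le$mean))
})

test_that("networkMetrics equals the manual composition of its stages", {
  cfg <- test_scene(seed = 23L)
  stk <- makeHoneycombStack(cfg)
  vf <- vapply(seq_len(dim(stk)[1]), function(i) mean(getSlice(stk, i) < 1000),
               numeric(1))
  img <- ifelse(getSlice(stk, which.max(vf)) > 1500, 200, 30)  # 8-bit-style section

  nm <- networkMetrics(img, NetworkParams(), pixelSizeUm = 1)

  mask <- removeSmallParticles(enhanceAndBinarize(img, NetworkParams()), 30L)
  sk <- skeletonizeMask(mask, 1)
  cl <- classifySkeletonPoints(sk)
  area <- mask@analyzedPx * 1
  expect_equal(nm@glutenAreaPercent, 100 * sum(mask@values) / mask@analyzedPx)
  expect_equal(nm@junctionCount, cl$junctionCount)
  expect_equal(nm@junctionDensityUm2, cl$junctionCount / area)
  expect_equal(nm@endpointsRateUm2, cl$endpointCount / area)
  expect_equal(nm@avgGlutenLengthUm, mean(branchLengths(sk)))
  expect_equal(nm@meanLacunarity, lacunarity(mask)$mean)
  expect_gt(nm@junctionCount, 0)
  expect_gte(nm@meanLacunarity, 1)

  # deterministic across runs
  nm2 <- networkMetrics(img, NetworkParams(), pixelSizeUm = 1)
  expect_equal(nm@branchLengthsUm, nm2@branchLengthsUm)
})

test_that("a sub-threshold speck leaves every metric unchanged; empty masks do not crash", {
  m <- matrix(FALSE, 64, 64)
  m[20, 10:50] <- TRUE; m[10:50, 30] <- TRUE
  speckled <- m; speckled[60, 60] <- TRUE; speckled[3, 60:62] <- TRUE
  a <- removeSmallParticles(m, 30L)
  b <- removeSmallParticles(speckled, 30L)
  expect_identical(a@values, b@values)
  ska <- skeletonizeMask(a); skb <- skeletonizeMask(b)
  expect_equal(branchLengths(ska), branchLengths(skb))

  # a lone faint speck: its smoothed blob stays under the particle threshold,
  # so the final mask is empty
  dot <- matrix(10, 32, 32); dot[16, 16] <- 200
  nm <- networkMetrics(dot, NetworkParams(vesselThicknessPx = 2),
                       pixelSizeUm = 1)
  expect_equal(nm@glutenAreaPercent, 0)
  expect_equal(nm@junctionCount, 0)
  expect_true(is.na(nm@meanLacunarity))
})

test_that("per-area metrics agree across image scales with identical physical content", {
  cfg <- test_scene(seed = 29L)
  stk <- makeHoneycombStack(cfg)
  vf <- vapply(seq_len(dim(stk)[1]), function(i) mean(getSlice(stk, i) < 1000),
               numeric(1))
  img1 <- ifelse(getSlice(stk, which.max(vf)) > 1500, 200, 30)
  img2 <- img1[rep(seq_len(nrow(img1)), each = 2),
               rep(seq_len(ncol(img1)), each = 2)]   # same scene at 0.5 um/px

  nm1 <- networkMetrics(img1, NetworkParams(vesselThicknessPx = 8),
                        pixelSizeUm = 1, boxSizes = c(8, 16))
  nm2 <- networkMetrics(img2, NetworkParams(vesselThicknessPx = 16),
                        pixelSizeUm = 0.5, boxSizes = c(16, 32))
  expect_lt(abs(nm1@glutenAreaPercent - nm2@glutenAreaPercent) /
              nm1@glutenAreaPercent, 0.05)
  expect_lt(abs(nm1@junctionDensityUm2 - nm2@junctionDensityUm2) /
              nm1@junctionDensityUm2, 0.05)
  expect_lt(abs(nm1@meanLacunarity - nm2@meanLacunarity) /
              nm1@meanLacunarity, 0.05)
})
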