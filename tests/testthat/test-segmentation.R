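test_that("Otsu separates a two-valued image and matches the exhaustive scan", {
  img <- matrix(c(rep(50, 50), rep(200, 50)), 10, 10)
  t0 <- otsuThreshold(img, 8L)
  expect_gte(t0, 50); expect_lt(t0, 200)
  mask <- binarize(img, t0)
  expect_equal(sum(mask@values), 50)
  expect_true(all(img[mask@values] == 200))

  set.seed(21)
  for (i in 1:20) {
    vals <- matrix(sample(0:255, 32 * 32, replace = TRUE,
                          prob = runif(256)^2), 32, 32)
    expect_equal(otsuThreshold(vals, 8L), otsu_oracle(as.vector(vals), 8L))
  }

  # histogram translation shifts the threshold by the same constant
  img2 <- matrix(sample(0:100, 256, replace = TRUE), 16, 16)
  expect_equal(otsuThreshold(img2 + 40, 8L), otsuThreshold(img2, 8L) + 40)

  expect_error(otsuThreshold(matrix(7, 4, 4), 8L), "degenerate")
})

test_that("area fraction is the foreground percentage with complement symmetry", {
  m <- matrix(FALSE, 10, 10)
  expect_equal(areaFraction(m), 0)
  m[1:5, ] <- TRUE
  expect_equal(areaFraction(m), 50)
  set.seed(3)
  r <- matrix(runif(400) < 0.3, 20, 20)
  expect_equal(areaFraction(r) + areaFraction(!r), 100)
})

test_that("3D labeling matches flood fill under 6 and 26 connectivity", {
  cube <- array(FALSE, c(12, 12, 12)); cube[2:11, 2:11, 2:11] <- TRUE
  lab <- labelComponents(cube, 26L)
  expect_equal(nrow(lab$table), 1L)
  expect_equal(lab$table$voxel_count, 1000L)

  # corner contact: one component under 26, two under 6
  corner <- array(FALSE, c(3, 3, 3))
  corner[1, 1, 1] <- TRUE; corner[2, 2, 2] <- TRUE
  expect_equal(nrow(labelComponents(corner, 26L)$table), 1L)
  expect_equal(nrow(labelComponents(corner, 6L)$table), 2L)

  set.seed(14)
  for (i in 1:20) {
    d <- sample(4:16, 3, replace = TRUE)
    mask <- random_mask3d(d, p = runif(1, 0.2, 0.6))
    for (conn in c(6L, 26L)) {
      got <- canonical_labels(labelComponents(mask, conn)$labels)
      want <- canonical_labels(floodfill_oracle(mask, conn))
      expect_identical(as.vector(got), as.vector(want))
    }
  }
})

test_that("component count never grows as connectivity is loosened", {
  set.seed(15)
  for (i in 1:8) {
    mask <- random_mask3d(c(10, 10, 10), p = 0.3)
    k <- vapply(c(6L, 18L, 26L), function(conn)
      nrow(labelComponents(mask, conn)$table), numeric(1))
    expect_true(all(diff(k) <= 0))
  }
})

test_that("volumes are conserved and anisotropic voxels use the voxel volume", {
  mask <- BinaryMask(random_mask3d(c(8, 9, 10), 0.4),
                     voxelSizeUm = c(2, 0.5, 0.7))
  lab <- labelComponents(mask, 26L)
  expect_equal(sum(lab$table$voxel_count), sum(mask@values))
  expect_equal(sum(lab$table$volume_um3), sum(mask@values) * 2 * 0.5 * 0.7)
  expect_equal(lab$table$label, seq_len(nrow(lab$table)))
})

test_that("volume distributions flag dominance of the largest clump", {
  # one 10x10x10 cube at 1 um voxels: single bin at volume 1000
  cube <- array(FALSE, c(14, 14, 14)); cube[3:12, 3:12, 3:12] <- TRUE
  tab <- labelComponents(BinaryMask(cube, 1), 26L)$table
  vd <- volumeDistribution(tab, binEdgesUm3 = c(0, 500, 1500))
  expect_equal(vd$histogram$count, c(0L, 1L))
  expect_equal(vd$total_volume_um3, 1000)

  # a giant clump plus scattered tiny ones: the giant holds > 90%
  big <- array(FALSE, c(24, 24, 24))
  big[2:21, 2:21, 2:21] <- TRUE                  # 8000 voxels
  big[23, c(2, 6, 10, 14, 18), c(2, 6, 10, 14, 18)] <- TRUE  # 25 singletons
  tab2 <- labelComponents(big, 26L)$table
  vd2 <- volumeDistribution(tab2, topK = 1L)
  expect_gt(unname(vd2$top_fraction["top1"]), 0.9)
  expect_equal(sum(tab2$volume_um3), vd2$total_volume_um3)

  expect_warning(vd0 <- volumeDistribution(tab2[0, ]), "empty")
  expect_equal(nrow(vd0$histogram), 0L)
})

test_that("labeling is stable under axis permutation of the mask", {
  set.seed(77)
  mask <- random_mask3d(c(7, 8, 9), 0.35)
  n1 <- nrow(labelComponents(mask, 26L)$table)
  n2 <- nrow(labelComponents(aperm(mask, c(3, 1, 2)), 26L)$table)
  expect_equal(n1, n2)
  sizes1 <- sort(labelComponents(mask, 26L)$table$voxel_count)
  sizes2 <- sort(labelComponents(aperm(mask, c(2, 3, 1)), 26L)$table$voxel_count)
  expect_equal(sizes1, sizes2)
})
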