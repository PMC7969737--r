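# Fixture builders shared across tests. All masks are generated in code.

plus_mask <- function(n = 21L, halfarm = 7L) {
  m <- matrix(FALSE, n, n)
  c0 <- (n + 1L) %/% 2L
  m[c0, (c0 - halfarm):(c0 + halfarm)] <- TRUE
  m[(c0 - halfarm):(c0 + halfarm), c0] <- TRUE
  m
}

ring_mask <- function(n = 15L, radius = 5L) {
  m <- matrix(FALSE, n, n)
  c0 <- (n + 1L) / 2
  for (t in seq(0, 2 * pi, length.out = 40L * radius)) {
    m[round(c0 + radius * sin(t)), round(c0 + radius * cos(t))] <- TRUE
  }
  # thin to a clean 1-px ring
  doughscope:::.guo_hall_thin(m)
}

line_mask <- function(n_px = 11L, nr = 9L, nc = 15L, diagonal = FALSE) {
  m <- matrix(FALSE, max(nr, n_px + 4L), max(nc, n_px + 4L))
  if (diagonal) {
    for (i in seq_len(n_px)) m[2L + i, 2L + i] <- TRUE
  } else {
    m[nr %/% 2L + 1L, 3L:(2L + n_px)] <- TRUE
  }
  m
}

random_mask3d <- function(dims, p = 0.4) {
  array(stats::runif(prod(dims)) < p, dims)
}

# A small scene used repeatedly: honeycomb thick enough in z to hold void
# layers (46 um lattice never overlaps under the default 0.1 jitter).
test_scene <- function(shape = c(120L, 128L, 128L), seed = 11L,
                       noise = "none", noiseScale = 0) {
  SceneConfig(shape, voxelSizeUm = 1, granuleSpacingUm = 46,
              noiseModel = noise, noiseScale = noiseScale, rngSeed = seed)
}
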