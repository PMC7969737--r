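# Independent brute-force oracles. These deliberately use naive algorithms
# (explicit loops, flood fill, exhaustive scans) so they share no code path
# with the implementation they check.

# Per-level frequency by direct counting.
histogram_tally_oracle <- function(vals, bitDepth, excludeClipped = TRUE) {
  vmax <- 2^bitDepth - 1
  drop <- if (excludeClipped) c(0, vmax) else numeric()
  vals <- vals[!(vals %in% drop)]
  lev <- sort(unique(vals))
  cnt <- vapply(lev, function(l) sum(vals == l), numeric(1))
  list(levels = lev, freq = cnt / sum(cnt))
}

# Term-by-term histogram-mode variance.
var_oracle <- function(levels, freq) {
  ip <- levels[which.max(freq)]
  tot <- 0
  for (i in seq_along(levels)) tot <- tot + (levels[i] - ip)^2 * freq[i]
  tot
}

# Exhaustive between-class variance scan over all candidate thresholds.
otsu_oracle <- function(vals, bitDepth) {
  cand <- 0:(2^bitDepth - 2)
  best <- -Inf; bestt <- NA
  for (t in cand) {
    lo <- vals[vals <= t]; hi <- vals[vals > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(vals)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-12) { best <- sb; bestt <- t }
  }
  bestt
}

# Frontier flood-fill labeling of a 3D logical array.
floodfill_oracle <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  s <- abs(offs$dz) + abs(offs$dy) + abs(offs$dx)
  offs <- offs[s > 0 & s <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ]
  labels <- array(0L, d)
  nextlab <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    nextlab <- nextlab + 1L
    frontier <- start
    labels[start] <- nextlab
    while (length(frontier)) {
      co <- arrayInd(frontier, d)
      nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
        cbind(co[, 1] + offs$dz[k], co[, 2] + offs$dy[k], co[, 3] + offs$dx[k])))
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique((nb[, 3] - 1L) * d[1] * d[2] + (nb[, 2] - 1L) * d[1] + nb[, 1])
      lin <- lin[mask[lin] & labels[lin] == 0L]
      labels[lin] <- nextlab
      frontier <- lin
    }
  }
  labels
}

# Canonical relabeling by order of first occurrence, so two labelings can be
# compared as partitions.
canonical_labels <- function(labels) {
  seen <- unique(labels[labels > 0L])
  map <- integer(max(c(labels, 0L)))
  map[seen] <- seq_along(seen)
  out <- labels
  out[labels > 0L] <- map[labels[labels > 0L]]
  out
}

# Exhaustive gliding-box lacunarity for one box size.
lacunarity_oracle <- function(mask, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  ms <- numeric(0)
  for (i in seq_len(nr - r + 1)) {
    for (j in seq_len(nc - r + 1)) {
      ms <- c(ms, sum(mask[i:(i + r - 1), j:(j + r - 1)]))
    }
  }
  if (mean(ms) == 0) return(NA_real_)
  mean(ms^2) / mean(ms)^2
}

# Total branch length of a skeleton by edge accounting: every 8-adjacency
# between skeleton pixels contributes its step weight once, except
# adjacencies internal to one junction cluster (those are not branch path
# edges). Independent of the implementation's path walking.
total_branch_length_oracle <- function(skel) {
  co <- which(skel, arr.ind = TRUE)
  nr <- nrow(skel); nc <- ncol(skel)
  deg <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- co[, 1] + dr; cc <- co[, 2] + dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    deg[co[ok, , drop = FALSE]] <- deg[co[ok, , drop = FALSE]] +
      skel[cbind(rr[ok], cc[ok])]
  }
  jmask <- skel & deg >= 3
  jlab <- canonical_labels(array(floodfill_oracle(
    array(jmask, c(1, nr, nc)), 26)[1, , ], c(nr, nc)))
  total <- 0
  for (k in seq_len(nrow(co))) {
    r <- co[k, 1]; c <- co[k, 2]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || !skel[rr, cc]) next
      # count each unordered pair once
      if ((cc - 1) * nr + rr <= (c - 1) * nr + r) next
      if (jmask[r, c] && jmask[rr, cc] && jlab[r, c] == jlab[rr, cc]) next
      total <- total + if (dr != 0 && dc != 0) sqrt(2) else 1
    }
  }
  total
}

# Two-point piecewise-linear interpolation by explicit segment search.
interp_oracle <- function(xs, ys, x0) {
  for (i in seq_len(length(xs) - 1)) {
    if (x0 >= xs[i] && x0 <= xs[i + 1]) {
      if (xs[i + 1] == xs[i]) return(ys[i])
      return(ys[i] + (ys[i + 1] - ys[i]) * (x0 - xs[i]) / (xs[i + 1] - xs[i]))
    }
  }
  NA_real_
}
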