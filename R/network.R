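# Skeleton-based gluten-network morphometrics: the five-variable family
# (area %, junction density, mean branch length, endpoint rate, mean
# lacunarity) computed natively from a binary mask.

#' Enhance and binarize an image for network analysis
#'
#' Vessel-style preprocessing: Gaussian smoothing at
#' \code{sigma = vesselThicknessPx / 2}, restriction of the analyzed region
#' to pixels whose original intensity lies in
#' \code{[intensityLow, intensityHigh]}, and Otsu thresholding of the
#' smoothed image over the analyzed region (foreground strictly above the
#' threshold). With the default window 0..255 on 8-bit data no pixel is
#' excluded.
#'
#' @param image numeric matrix (2D image, integer grey levels).
#' @param params a \linkS4class{NetworkParams}.
#' @param pixelSizeUm pixel pitch (µm), default 1.
#' @param bitDepth bit depth of the image, default 8.
#' @return A \linkS4class{BinaryMask} whose \code{analyzedPx} records the
#'   analyzed-region size and whose metadata records the threshold.
#' @export
enhanceAndBinarize <- function(image, params = NetworkParams(),
                               pixelSizeUm = 1, bitDepth = 8L) {
  img <- as_image_matrix(image)
  stopifnot(is(params, "NetworkParams"))
  validObject(params)
  analyzed <- img >= params@intensityLow & img <= params@intensityHigh
  if (!any(analyzed)) stop("no pixels inside the intensity window")
  if (length(unique(as.vector(img[analyzed]))) < 2L)
    stop("degenerate image: constant within the analyzed region")
  sigma <- params@vesselThicknessPx / 2
  sm <- EBImage::gblur(img, sigma = sigma, boundary = "replicate")
  sm <- round(pmin(pmax(sm, 0), 2^bitDepth - 1))
  thr <- otsuThreshold(sm[analyzed], bitDepth)
  values <- sm > thr & analyzed
  if (params@fillHoles) values <- fill_holes(values)
  BinaryMask(values, pixelSizeUm, analyzedPx = sum(analyzed),
             metadata = list(threshold = thr, sigma_px = sigma,
                             fill_holes = params@fillHoles))
}

# Fill background holes: background components (4-connected) that do not
# touch the image border become foreground.
fill_holes <- function(values) {
  lab <- labelComponents(!values, connectivity = 4L)$labels
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  values | array(lab > 0L & !(lab %in% border), dim(values))
}

#' Remove small particles from a binary mask
#'
#' Drops 8-connected foreground components strictly smaller than
#' \code{minParticlePx} pixels ("removed under n pixels": an n-pixel
#' component is retained).
#'
#' @param mask a \linkS4class{BinaryMask} (2D) or logical matrix.
#' @param minParticlePx integer threshold, default 30.
#' @return A \linkS4class{BinaryMask} with the same geometry and metadata.
#' @export
removeSmallParticles <- function(mask, minParticlePx = 30L) {
  bm <- if (is(mask, "BinaryMask")) mask else BinaryMask(mask)
  if (length(dim(bm@values)) != 2L) stop("expected a 2D mask")
  if (minParticlePx < 0L) stop("minParticlePx must be nonnegative")
  lab <- labelComponents(bm@values, connectivity = 8L)
  keep <- lab$table$label[lab$table$voxel_count >= minParticlePx]
  bm@values[] <- lab$labels %in% keep & bm@values
  bm
}

# 8-neighbour count of every pixel of a logical matrix.
neighbor_count <- function(v) {
  nr <- nrow(v); nc <- ncol(v)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- v
  cnt <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    cnt <- cnt + p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  cnt
}

#' Skeletonize a binary mask and build its graph
#'
#' Thins the mask to a 1-pixel-wide, topology-preserving medial skeleton
#' (Guo-Hall two-subiteration thinning), classifies skeleton pixels by their
#' 8-neighbour count (1 neighbour: endpoint; >= 3: junction pixel, with
#' 8-adjacent junction pixels merged into one junction cluster), and traces
#' the node-to-node branches with geodesic lengths (orthogonal step 1,
#' diagonal step sqrt(2), times the pixel size). Pure cycles with no nodes
#' (rings) are traced as single closed branches.
#'
#' @param mask a \linkS4class{BinaryMask} (2D) or logical matrix.
#' @param pixelSizeUm pixel pitch (µm); taken from the mask when available.
#' @return A \linkS4class{SkeletonGraph}. An empty mask yields an empty graph.
#' @export
skeletonizeMask <- function(mask, pixelSizeUm = NULL) {
  if (is(mask, "BinaryMask")) {
    v <- mask@values
    if (is.null(pixelSizeUm)) pixelSizeUm <- mask@voxelSizeUm[1L]
  } else {
    v <- mask
    if (is.null(pixelSizeUm)) pixelSizeUm <- 1
  }
  if (length(dim(v)) != 2L) stop("expected a 2D mask")
  skel <- .guo_hall_thin(v)
  build_skeleton_graph(skel, pixelSizeUm)
}

build_skeleton_graph <- function(skel, pixelSizeUm) {
  nr <- nrow(skel); nc <- ncol(skel)
  deg <- neighbor_count(skel)
  deg[!skel] <- -1L
  ep <- which(deg == 1L, arr.ind = TRUE)
  jp <- which(deg >= 3L, arr.ind = TRUE)
  # junction clusters: 8-connected groups of junction pixels count once
  jmask <- matrix(FALSE, nr, nc)
  jmask[jp] <- TRUE
  jlab <- if (nrow(jp)) labelComponents(jmask, connectivity = 8L)$labels
          else matrix(0L, nr, nc)
  jcluster <- if (nrow(jp)) jlab[jp] else integer()

  isnode <- matrix(FALSE, nr, nc)
  isnode[ep] <- TRUE
  isnode[jp] <- TRUE

  lin <- function(r, c) (c - 1L) * nr + r
  stepw <- function(r1, c1, r2, c2)
    ifelse(r1 != r2 & c1 != c2, sqrt(2), 1)
  nbrs <- function(r, c) {
    rs <- max(1L, r - 1L):min(nr, r + 1L)
    cs <- max(1L, c - 1L):min(nc, c + 1L)
    g <- expand.grid(r = rs, c = cs)
    g <- g[!(g$r == r & g$c == c), , drop = FALSE]
    g[skel[cbind(g$r, g$c)], , drop = FALSE]
  }

  visited <- matrix(FALSE, nr, nc)     # mid-branch pixels already traced
  edge_seen <- new.env(hash = TRUE)
  branches <- list()

  trace_from <- function(r0, c0, r1, c1) {
    # walk from node (r0,c0) through mid pixel (r1,c1) to the next node
    len <- stepw(r0, c0, r1, c1)
    npx <- 2L
    pr <- r0; pc <- c0; cr <- r1; cc <- c1
    repeat {
      visited[cr, cc] <<- TRUE
      nb <- nbrs(cr, cc)
      nb <- nb[!(nb$r == pr & nb$c == pc), , drop = FALSE]
      if (!nrow(nb)) break                       # dead end (defensive)
      nxt <- nb[1L, ]
      len <- len + stepw(cr, cc, nxt$r, nxt$c)
      npx <- npx + 1L
      if (isnode[nxt$r, nxt$c]) break
      pr <- cr; pc <- cc; cr <- nxt$r; cc <- nxt$c
    }
    list(n_px = npx, length_px = len)
  }

  nodes <- rbind(ep, jp)
  if (nrow(nodes)) {
    ord <- order(lin(nodes[, 1], nodes[, 2]))
    nodes <- nodes[ord, , drop = FALSE]
    for (i in seq_len(nrow(nodes))) {
      r <- nodes[i, 1]; c <- nodes[i, 2]
      nb <- nbrs(r, c)
      for (k in seq_len(nrow(nb))) {
        qr <- nb$r[k]; qc <- nb$c[k]
        if (isnode[qr, qc]) {
          # direct node-node contact; adjacent pixels of one junction
          # cluster are internal, not a branch
          if (jmask[r, c] && jmask[qr, qc] && jlab[r, c] == jlab[qr, qc])
            next
          key <- paste(sort(c(lin(r, c), lin(qr, qc))), collapse = "-")
          if (!is.null(edge_seen[[key]])) next
          edge_seen[[key]] <- TRUE
          branches[[length(branches) + 1L]] <-
            list(n_px = 2L, length_px = stepw(r, c, qr, qc), closed = FALSE)
        } else if (!visited[qr, qc]) {
          b <- trace_from(r, c, qr, qc)
          branches[[length(branches) + 1L]] <-
            c(b, list(closed = FALSE))
        }
      }
    }
  }

  # pure cycles: remaining unvisited degree-2 pixels
  left <- which(deg == 2L & !visited, arr.ind = TRUE)
  if (nrow(left)) {
    left <- left[order(lin(left[, 1], left[, 2])), , drop = FALSE]
    for (i in seq_len(nrow(left))) {
      r <- left[i, 1]; c <- left[i, 2]
      if (visited[r, c]) next
      visited[r, c] <- TRUE
      nb <- nbrs(r, c)
      if (!nrow(nb)) next
      len <- stepw(r, c, nb$r[1], nb$c[1])
      npx <- 1L
      pr <- r; pc <- c; cr <- nb$r[1]; cc <- nb$c[1]
      while (!(cr == r && cc == c)) {
        visited[cr, cc] <- TRUE
        npx <- npx + 1L
        nb2 <- nbrs(cr, cc)
        nb2 <- nb2[!(nb2$r == pr & nb2$c == pc), , drop = FALSE]
        if (!nrow(nb2)) break
        len <- len + stepw(cr, cc, nb2$r[1], nb2$c[1])
        pr <- cr; pc <- cc; cr <- nb2$r[1]; cc <- nb2$c[1]
      }
      branches[[length(branches) + 1L]] <-
        list(n_px = npx, length_px = len, closed = TRUE)
    }
  }

  bdf <- if (length(branches)) {
    data.frame(branch = seq_along(branches),
               n_px = vapply(branches, `[[`, integer(1), "n_px"),
               length_px = vapply(branches, `[[`, numeric(1), "length_px"),
               closed = vapply(branches, `[[`, logical(1), "closed"))
  } else {
    data.frame(branch = integer(), n_px = integer(), length_px = numeric(),
               closed = logical())
  }
  bdf$length_um <- bdf$length_px * pixelSizeUm
  new("SkeletonGraph", skeleton = skel, pixelSizeUm = pixelSizeUm,
      endpoints = unname(ep), junctionPixels = unname(jp),
      junctionCluster = as.integer(jcluster), branches = bdf)
}

#' Classify skeleton points into junction clusters and endpoints
#'
#' @param skel a \linkS4class{SkeletonGraph}.
#' @return list with \code{junctions} (list of coordinate matrices, one per
#'   junction cluster), \code{junctionCount}, \code{endpoints} (coordinate
#'   matrix) and \code{endpointCount}.
#' @export
classifySkeletonPoints <- function(skel) {
  stopifnot(is(skel, "SkeletonGraph"))
  cl <- skel@junctionCluster
  junctions <- if (length(cl))
    lapply(seq_len(max(cl)), function(k)
      skel@junctionPixels[cl == k, , drop = FALSE])
  else list()
  list(junctions = junctions, junctionCount = length(junctions),
       endpoints = skel@endpoints, endpointCount = nrow(skel@endpoints))
}

#' Branch lengths of a skeleton
#'
#' @param skel a \linkS4class{SkeletonGraph}.
#' @return numeric vector of geodesic branch lengths in micrometres.
#' @export
branchLengths <- function(skel) {
  stopifnot(is(skel, "SkeletonGraph"))
  skel@branches$length_um
}

#' Gliding-box lacunarity of a binary mask
#'
#' \eqn{\Lambda(r) = \langle M^2\rangle / \langle M\rangle^2} over all r-by-r
#' boxes at unit stride (M = foreground count per box), averaged over the
#' requested box sizes. \eqn{\Lambda \ge 1} whenever defined, with equality
#' iff the box masses are constant; gappier masks score higher. A box size
#' whose mean mass is zero is undefined and excluded with a warning.
#'
#' @param mask a \linkS4class{BinaryMask} (2D) or logical matrix.
#' @param boxSizes integer box edge lengths (px); default: powers of 2 from
#'   2 up to a quarter of the smaller image dimension.
#' @return list with \code{perBox} (data.frame \code{box_px}, \code{lambda})
#'   and \code{mean}, the mean over defined box sizes.
#' @export
lacunarity <- function(mask, boxSizes = NULL) {
  v <- if (is(mask, "BinaryMask")) mask@values else mask
  if (length(dim(v)) != 2L) stop("expected a 2D mask")
  nr <- nrow(v); nc <- ncol(v)
  if (is.null(boxSizes)) {
    kmax <- floor(log2(min(nr, nc) / 4))
    if (kmax < 1) stop("image too small for default box sizes; give boxSizes")
    boxSizes <- 2^(1:kmax)
  }
  if (any(boxSizes > min(nr, nc)))
    stop("box size exceeds the smaller image dimension")
  # summed-area table for O(1) box masses
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- t(apply(apply(v, 2L, cumsum), 1L, cumsum))
  lam <- vapply(boxSizes, function(r) {
    i <- seq_len(nr - r + 1L); j <- seq_len(nc - r + 1L)
    M <- S[i + r, j + r, drop = FALSE] - S[i, j + r, drop = FALSE] -
         S[i + r, j, drop = FALSE] + S[i, j, drop = FALSE]
    m1 <- mean(M)
    if (m1 == 0) return(NA_real_)
    mean(M^2) / m1^2
  }, numeric(1))
  if (anyNA(lam))
    warning("lacunarity undefined (empty boxes) for box sizes: ",
            paste(boxSizes[is.na(lam)], collapse = ", "))
  list(perBox = data.frame(box_px = boxSizes, lambda = lam),
       mean = mean(lam, na.rm = TRUE))
}

#' Full gluten-network morphometrics of a 2D image
#'
#' Runs the complete chain — enhance/binarize, small-particle removal,
#' skeletonization, junction/endpoint classification, branch measurement and
#' lacunarity — and reports the five-variable summary: gluten area
#' percentage of the analyzed region, junction density and endpoint rate per
#' µm² of analyzed area (raw counts are also kept), mean branch length (µm)
#' and mean gliding-box lacunarity.
#'
#' @param image numeric matrix (2D grey-level image).
#' @param params a \linkS4class{NetworkParams}.
#' @param pixelSizeUm pixel pitch (µm), default 1.
#' @param bitDepth image bit depth, default 8.
#' @param boxSizes lacunarity box sizes; default as in
#'   \code{\link{lacunarity}}.
#' @return A \linkS4class{NetworkMetrics}. An image whose mask is empty
#'   after despeckling yields zero counts and NA lacunarity, not an error.
#' @export
networkMetrics <- function(image, params = NetworkParams(), pixelSizeUm = 1,
                           bitDepth = 8L, boxSizes = NULL) {
  mask <- enhanceAndBinarize(image, params, pixelSizeUm, bitDepth)
  mask <- removeSmallParticles(mask, params@minParticlePx)
  analyzedArea <- mask@analyzedPx * pixelSizeUm^2
  nfg <- sum(mask@values)
  areaPct <- 100 * nfg / mask@analyzedPx
  if (nfg == 0L) {
    return(new("NetworkMetrics", glutenAreaPercent = 0, junctionCount = 0,
               junctionDensityUm2 = 0, avgGlutenLengthUm = 0,
               endpointCount = 0, endpointsRateUm2 = 0,
               meanLacunarity = NA_real_, analyzedAreaUm2 = analyzedArea,
               branchLengthsUm = numeric()))
  }
  skel <- skeletonizeMask(mask, pixelSizeUm)
  cls <- classifySkeletonPoints(skel)
  bl <- branchLengths(skel)
  lac <- lacunarity(mask, boxSizes)
  new("NetworkMetrics",
      glutenAreaPercent = areaPct,
      junctionCount = cls$junctionCount,
      junctionDensityUm2 = cls$junctionCount / analyzedArea,
      avgGlutenLengthUm = if (length(bl)) mean(bl) else 0,
      endpointCount = cls$endpointCount,
      endpointsRateUm2 = cls$endpointCount / analyzedArea,
      meanLacunarity = lac$mean,
      analyzedAreaUm2 = analyzedArea,
      branchLengthsUm = bl)
}
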