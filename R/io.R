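#' Read an image stack from a multi-page TIFF
#'
#' Pages become z-slices in \code{(z, y, x)} order. Pixel values are restored
#' to integer counts at the stated bit depth. Voxel size and bit depth are
#' taken from the JSON sidecar written by \code{\link{writeStack}}
#' (\code{<path>.json}) when present; explicit arguments override the
#' sidecar, and a missing voxel size with no override is an error.
#'
#' @param path TIFF file (single- or multi-page; 8/12-in-16/16-bit).
#' @param voxelSizeUm optional override, (z, y, x) µm.
#' @param bitDepth optional override.
#' @return An \linkS4class{ImageStack}.
#' @export
readStack <- function(path, voxelSizeUm = NULL, bitDepth = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    meta <- jsonlite::fromJSON(sidecar)
  if (is.null(bitDepth)) bitDepth <- meta$bit_depth
  if (is.null(bitDepth)) bitDepth <- 16L
  if (is.null(voxelSizeUm)) voxelSizeUm <- meta$voxel_size_um
  if (is.null(voxelSizeUm))
    stop("voxel size not found in sidecar metadata; pass voxelSizeUm")
  nz <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  vol <- array(0, c(nz, ny, nx))
  for (i in seq_len(nz))
    vol[i, , ] <- round(pages[[i]] * 65535)
  if (max(vol) > 2^bitDepth - 1)
    stop("stored values exceed the stated bit depth")
  ImageStack(vol, voxelSizeUm, as.integer(bitDepth))
}

#' Write an image stack as a multi-page TIFF with sidecar metadata
#'
#' Values are stored in a 16-bit container (integer counts are preserved
#' exactly); voxel size, bit depth and any extra fields go to a JSON sidecar
#' at \code{<path>.json}.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output TIFF path.
#' @param extra named list merged into the sidecar metadata (e.g. the
#'   generating seed and parameters).
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path, extra = list()) {
  stopifnot(is(stack, "ImageStack"))
  d <- dim(stack)
  pages <- lapply(seq_len(d[1L]), function(i) getSlice(stack, i) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- c(list(voxel_size_um = stack@voxelSizeUm,
                 bit_depth = stack@bitDepth,
                 axis_order = "zyx"), extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a stress-strain CSV
#'
#' Expects columns \code{strain} and \code{stress}.
#'
#' @param path CSV file path.
#' @return A \linkS4class{StressStrainCurve}.
#' @export
readStressStrain <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("strain", "stress") %in% names(df)))
    stop("CSV needs columns 'strain' and 'stress'")
  StressStrainCurve(df$strain, df$stress)
}

#' Write result tables and summaries with a manifest
#'
#' Each named data.frame is written as \code{<name>.csv} and each other
#' element as \code{<name>.json}; a \code{manifest.json} lists every file
#' with the producing operation name, the parameters and the seed, so a run
#' is fully reproducible from its output directory.
#'
#' @param tables named list of data.frames and/or list-like summaries.
#' @param outdir output directory (created if needed).
#' @param params named list of parameters recorded in the manifest.
#' @param seed integer seed recorded in the manifest.
#' @return the manifest, invisibly.
#' @export
writeResults <- function(tables, outdir, params = list(), seed = NULL) {
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  entries <- list()
  for (nm in names(tables)) {
    x <- tables[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(outdir, paste0(nm, ".csv"))
      utils::write.csv(x, f, row.names = FALSE)
    } else {
      f <- file.path(outdir, paste0(nm, ".json"))
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
    }
    entries[[length(entries) + 1L]] <-
      list(file = basename(f), operation = nm)
  }
  manifest <- list(files = entries, params = params, seed = seed)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
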