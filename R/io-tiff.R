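# Multi-page TIFF stacks via the tiff package. Pages are written as 16-bit
# grayscale, one page per axial slice, so integer grey values in [0, 65535]
# round-trip exactly. Plain TIFF carries no voxel-spacing or calibration
# metadata, so spacing is supplied by the caller on read (default 1 mm) and
# the calibrated flag of a read stack is always FALSE; use MetaImage when
# the metadata must travel with the file.

write_tiff_stack <- function(voxels, spacing, path, calibrated = FALSE) {
  d <- dim(voxels)
  if (min(voxels) < 0 || max(voxels) > 65535 || any(voxels != round(voxels)))
    stop("TIFF output stores 16-bit integers; voxel values must be integers ",
         "in [0, 65535] (use MetaImage for fractional grey values)",
         call. = FALSE)
  pages <- lapply(seq_len(d[3]), function(k) t(voxels[, , k]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW",
                  reduce = FALSE)
  invisible(path)
}

read_tiff_stack <- function(path, spacing = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("empty TIFF stack: ", path, call. = FALSE)
  dims <- vapply(pages, dim, numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("TIFF pages have inconsistent dimensions: cannot form a single grid",
         call. = FALSE)
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  ny <- dims[1, 1]; nx <- dims[2, 1]
  vox <- array(0, c(nx, ny, length(pages)))
  for (k in seq_along(pages)) vox[, , k] <- t(pages[[k]])
  calibrated_volume(vox, spacing = spacing, calibrated = FALSE)
}
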