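#' Read a volumetric image
#'
#' Reads a 3D grey-value image from a DICOM series (a directory of slice
#' files), a multi-page TIFF stack, or a MetaImage file (`.mha`/`.mhd`).
#' Voxel spacing is taken from file metadata where the format carries it
#' (DICOM `PixelSpacing` + slice positions, MetaImage `ElementSpacing`);
#' plain TIFF stacks carry none, so `spacing` may be supplied. The
#' `calibrated` flag of the result is `FALSE` unless the file metadata
#' asserts the 0--1064 bone-fraction scale (written by [write_volume()]).
#'
#' Supported encodings: DICOM explicit-VR little-endian, uncompressed 16-bit
#' monochrome; 16-bit grayscale TIFF; MetaImage with any integer or float
#' element type, little-endian.
#'
#' @param path file (TIFF/MetaImage) or directory (DICOM series).
#' @param format_hint one of `"auto"`, `"dicom_series"`, `"tiff_stack"`,
#'   `"metaimage"`. With `"auto"`, directories are read as DICOM series and
#'   files by extension.
#' @param spacing optional length-3 voxel spacing in mm, used for TIFF stacks
#'   without embedded spacing metadata.
#' @return A [calibrated_volume()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, format_hint = c("auto", "dicom_series",
                                              "tiff_stack", "metaimage"),
                        spacing = NULL) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path))
    stop("path does not exist: ", path, call. = FALSE)
  if (format_hint == "auto") {
    format_hint <- if (dir.exists(path)) "dicom_series"
    else switch(tolower(tools::file_ext(path)),
                tif = , tiff = "tiff_stack",
                mha = , mhd = "metaimage",
                dcm = "dicom_series",
                stop("cannot infer format of ", path,
                     "; pass `format_hint`", call. = FALSE))
  }
  switch(format_hint,
         dicom_series = read_dicom_series(path),
         tiff_stack = read_tiff_stack(path, spacing = spacing),
         metaimage = read_metaimage(path))
}

#' Write a volumetric image or mask
#'
#' Writes a [calibrated_volume()] or [binary_mask()] to disk. MetaImage
#' volumes are stored as 64-bit floats (lossless for any grey values);
#' DICOM and TIFF store 16-bit integers, so voxel values must be integers in
#' `[0, 65535]` for those formats. Masks are stored as 8-bit MetaImage or as
#' 0/1-valued 16-bit DICOM/TIFF. Calibration and spacing metadata are
#' embedded so that [read_volume()] restores them.
#'
#' @param v a [calibrated_volume()] or [binary_mask()].
#' @param path output file (`.tif`, `.mha`, `.mhd`) or directory (DICOM).
#' @param format one of `"auto"`, `"dicom_series"`, `"tiff_stack"`,
#'   `"metaimage"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, format = c("auto", "dicom_series",
                                             "tiff_stack", "metaimage")) {
  format <- match.arg(format)
  is_mask <- inherits(v, "binary_mask")
  if (!is_mask && !inherits(v, "calibrated_volume"))
    stop("`v` must be a calibrated_volume or binary_mask", call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tif", "tiff")) "tiff_stack"
    else if (ext %in% c("mha", "mhd")) "metaimage"
    else "dicom_series"
  }
  calibrated <- !is_mask && isTRUE(v$calibrated)
  switch(format,
         metaimage = write_metaimage(v$voxels, v$spacing, v$origin, path,
                                     element_type = if (is_mask) "MET_UCHAR"
                                     else "MET_DOUBLE",
                                     calibrated = calibrated),
         tiff_stack = write_tiff_stack(v$voxels, v$spacing, path,
                                       calibrated = calibrated),
         dicom_series = write_dicom_series(v$voxels, v$spacing, v$origin, path,
                                           calibrated = calibrated))
  invisible(path)
}

#' Calibrate grey values to the 0--1064 bone-fraction scale
#'
#' Linearly maps raw scanner grey values so that `air_value` becomes 0 (no
#' bone, only air) and `bone_value` becomes 1064 (100% bone), then clips to
#' `[0, 1064]`. The result carries `calibrated = TRUE` and is the scale on
#' which BV/TV densitometry (see [bvtv()]) is defined. The mapping is assumed
#' linear; the calibration references are user-supplied.
#'
#' @param v a [calibrated_volume()] (typically uncalibrated raw greys).
#' @param air_value raw grey value of pure air.
#' @param bone_value raw grey value of 100% bone; must exceed `air_value`.
#' @return A calibrated [calibrated_volume()] with voxels in `[0, 1064]`.
#' @examples
#' v <- calibrated_volume(array(c(100, 500, 900, 1200), c(1, 2, 2)))
#' rescale_grayscale(v, air_value = 100, bone_value = 900)
#' @export
rescale_grayscale <- function(v, air_value, bone_value) {
  stopifnot(inherits(v, "calibrated_volume"))
  if (!(bone_value > air_value))
    stop("`bone_value` must be greater than `air_value`", call. = FALSE)
  g <- 1064 * (v$voxels - air_value) / (bone_value - air_value)
  g[g < 0] <- 0
  g[g > 1064] <- 1064
  calibrated_volume(g, spacing = v$spacing, origin = v$origin,
                    calibrated = TRUE)
}

#' Downsample a volume by block-mean pooling
#'
#' Averages `factor^3` blocks of voxels; spacing is multiplied by `factor`.
#' Trailing partial blocks are averaged over the voxels they actually
#' contain. Used to bring working volumes to a tractable resolution before
#' segmentation (the default working resolution keeps the largest dimension
#' at or below 512, see [working_resolution_factor()]).
#'
#' @param v a [calibrated_volume()].
#' @param factor positive integer pooling factor; 1 returns `v` unchanged.
#' @return A [calibrated_volume()] with `ceiling(dim / factor)` voxels.
#' @export
downsample <- function(v, factor) {
  stopifnot(inherits(v, "calibrated_volume"))
  factor <- as.integer(factor)
  if (length(factor) != 1L || is.na(factor) || factor < 1L)
    stop("`factor` must be a positive integer", call. = FALSE)
  if (factor == 1L) return(v)
  a <- v$voxels
  for (axis in 1:3) {
    d <- dim(a)
    n <- d[axis]
    ng <- ceiling(n / factor)
    pad <- ng * factor - n
    if (pad > 0) {
      dpad <- d; dpad[axis] <- pad
      a <- .abind_axis(a, array(NA_real_, dpad), axis)
    }
    # move `axis` first, reshape to (factor, ng, rest), mean over dim 1
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    dim(ap) <- c(factor, ng, dp[2], dp[3])
    m <- colMeans(ap, na.rm = TRUE, dims = 1L)
    dim(m) <- c(ng, dp[2], dp[3])
    a <- aperm(m, order(perm))
  }
  calibrated_volume(a, spacing = v$spacing * factor, origin = v$origin,
                    calibrated = v$calibrated)
}

# bind two arrays along `axis`
.abind_axis <- function(a, b, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm); bp <- aperm(b, perm)
  da <- dim(ap); db <- dim(bp)
  out <- array(NA_real_, c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- ap
  out[da[1] + seq_len(db[1]), , ] <- bp
  aperm(out, order(perm))
}

#' Default working-resolution pooling factor
#'
#' Smallest integer pooling factor that brings the largest volume dimension
#' to at most `max_dim` voxels (default 512), the package's default working
#' resolution for segmentation.
#'
#' @param v a [calibrated_volume()].
#' @param max_dim target upper bound on the largest dimension.
#' @return A positive integer suitable for [downsample()].
#' @export
working_resolution_factor <- function(v, max_dim = 512L) {
  as.integer(ceiling(max(dim(v$voxels)) / max_dim))
}

#' Extract central orthogonal midplanes
#'
#' Returns the three central index slices of a volume: axial (fixed z),
#' coronal (fixed y) and sagittal (fixed x). With 0-based indexing the
#' central index along an axis of length `n` is `floor(n/2)`. Midplanes are
#' the quick-look QC images of a segmentation run.
#'
#' @param v a [calibrated_volume()] or [binary_mask()].
#' @return A list with 2D matrices `axial`, `coronal`, `sagittal`.
#' @export
extract_midplanes <- function(v) {
  a <- v$voxels
  d <- dim(a)
  if (any(d < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  mid <- floor(d / 2) + 1L  # floor(n/2) in 0-based indexing
  list(axial = a[, , mid[3]],
       coronal = a[, mid[2], ],
       sagittal = a[mid[1], , ])
}
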