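#' Calibrated volumetric image
#'
#' Container for a 3D grey-value image on a regular voxel grid. Grey values are
#' dimensionless; after calibration (see [rescale_grayscale()]) they live on the
#' 0--1064 bone-fraction scale, where 0 is air (no bone) and 1064 is 100% bone.
#' Voxel indexing is 0-based in world terms: the centre of voxel
#' `(i, j, k)` (0-based) sits at `origin + c(i, j, k) * spacing`, all lengths
#' in millimetres.
#'
#' @param voxels numeric 3D array of grey values, dimension `(nx, ny, nz)`.
#' @param spacing numeric length-3, per-axis voxel size in mm; all `> 0`.
#' @param origin numeric length-3, world position (mm) of voxel `(0,0,0)`.
#' @param calibrated logical; `TRUE` asserts the 0--1064 bone-fraction scale,
#'   in which case all voxels must lie in `[0, 1064]`.
#' @return An object of class `calibrated_volume`: a list with elements
#'   `voxels`, `spacing`, `origin`, `calibrated`.
#' @seealso [binary_mask()], [read_volume()], [rescale_grayscale()]
#' @examples
#' v <- calibrated_volume(array(532, c(4, 4, 4)), spacing = c(0.5, 0.5, 0.5),
#'                        calibrated = TRUE)
#' v
#' @export
calibrated_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                              calibrated = FALSE) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  storage.mode(voxels) <- "double"
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  calibrated <- isTRUE(calibrated)
  if (calibrated) {
    rng <- range(voxels)
    if (rng[1] < 0 || rng[2] > 1064)
      stop("calibrated volumes must have grey values in [0, 1064]; got [",
           signif(rng[1], 6), ", ", signif(rng[2], 6), "]", call. = FALSE)
  }
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 calibrated = calibrated),
            class = "calibrated_volume")
}

#' Binary voxel mask
#'
#' A voxel mask (values exactly 0 or 1) sharing the grid of a parent
#' [calibrated_volume()]: same dimensions, spacing and origin. Used for the
#' whole-bone, cortex, spongiosa and trabecular-ROI segmentations.
#'
#' @param voxels 3D array whose values are all 0 or 1 (logical arrays are
#'   accepted and converted).
#' @inheritParams calibrated_volume
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  if (is.logical(voxels)) {
    v <- array(0L, dim(voxels)); v[voxels] <- 1L; voxels <- v
  } else {
    if (!all(voxels == 0 | voxels == 1))
      stop("mask values must be exactly 0 or 1", call. = FALSE)
    storage.mode(voxels) <- "integer"
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "binary_mask")
}

#' @export
print.calibrated_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<calibrated_volume> ", paste(d, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  cat("  grey range [", signif(min(x$voxels), 6), ", ",
      signif(max(x$voxels), 6), "]",
      if (x$calibrated) "  (calibrated 0-1064 bone-fraction scale)" else
        "  (uncalibrated)", "\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<binary_mask> ", paste(d, collapse = " x "), " voxels, ",
      sum(x$voxels), " foreground (",
      signif(100 * mean(x$voxels), 3), "%), spacing ",
      paste(signif(x$spacing, 4), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

# grid identity check shared by every masked operation
same_grid <- function(a, b) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b))
    stop("grids do not match (dimensions, spacing and origin must be identical)",
         call. = FALSE)
  invisible(TRUE)
}

# mask voxels as a logical array
mask_logical <- function(m) m$voxels == 1L

# wrap a logical/0-1 array in a mask on the grid of `like`
mask_like <- function(voxels, like) {
  binary_mask(voxels, spacing = like$spacing, origin = like$origin)
}

#' Dice similarity coefficient of two masks
#'
#' `2|A & B| / (|A| + |B|)`; 1 for identical masks, 0 for disjoint ones.
#' Conventionally 1 when both masks are empty.
#'
#' @param a,b [binary_mask()] objects on the same grid.
#' @return A number in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stop_if_grid_mismatch(a, b)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0) return(1)
  2 * sum(a$voxels == 1L & b$voxels == 1L) / (na + nb)
}
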