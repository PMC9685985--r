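#' Global threshold segmentation of the bone
#'
#' Thresholds the grey-value volume and keeps only the largest 26-connected
#' foreground component, which removes the embedding, the scanner holder and
#' other disconnected remnants. The default threshold is Otsu's method on the
#' grey-value histogram; a fixed grey value can be given instead. Note that
#' Otsu separates the two dominant histogram modes: on volumes whose
#' trabecular interior is much darker than the cortex it can cut between
#' trabecular bone and cortex rather than between air and bone, in which case
#' a fixed threshold between the air and trabecular grey levels should be
#' supplied.
#'
#' @param v a [calibrated_volume()].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param value grey-value threshold, required when `method = "fixed"`.
#' @return A [binary_mask()] of the whole bone (voxels `>=` threshold,
#'   largest connected component only).
#' @export
global_threshold <- function(v, method = c("otsu", "fixed"), value = NULL) {
  stopifnot(inherits(v, "calibrated_volume"))
  method <- match.arg(method)
  thr <- if (method == "fixed") {
    if (is.null(value) || !is.finite(value))
      stop("`value` must be given for method = \"fixed\"", call. = FALSE)
    value
  } else {
    threshold_otsu(as.vector(v$voxels))
  }
  fg <- v$voxels >= thr
  if (!any(fg))
    stop("segmentation error: threshold ", signif(thr, 6),
         " leaves an empty foreground", call. = FALSE)
  keep <- largest_component(fg, connectivity = 26L)
  m <- mask_like(keep, v)
  attr(m, "threshold") <- thr
  m
}

#' Separate cortex and spongiosa morphologically
#'
#' Splits the whole-bone mask into a cortical shell and the interior. The
#' bone mask is first closed with a Euclidean ball of radius `peel_radius`
#' voxels (sealing small cortical gaps), then eroded by the same ball; the
#' largest 26-connected interior component, intersected with the bone, is the
#' interior, and the cortex is everything else: `cortex = bone - interior`,
#' so the two partition the bone mask exactly.
#'
#' @param bone whole-bone [binary_mask()], nonempty.
#' @param peel_radius ball radius in voxels (`>= 1`); at the default working
#'   resolution 5 voxels suits a human femoral cortex.
#' @return A list with [binary_mask()] elements `cortex` and `interior`.
#' @export
split_cortex_spongiosa <- function(bone, peel_radius = 5) {
  stopifnot(inherits(bone, "binary_mask"))
  if (peel_radius < 1) stop("`peel_radius` must be >= 1", call. = FALSE)
  b <- mask_logical(bone)
  if (!any(b)) stop("segmentation error: empty bone mask", call. = FALSE)
  closed <- close_ball(b, peel_radius)
  interior <- erode_ball(closed, peel_radius) & b
  if (!any(interior))
    stop("segmentation error: erosion emptied the mask; reduce `peel_radius` ",
         "(wall appears thinner than ", peel_radius, " voxels)", call. = FALSE)
  interior <- largest_component(interior, connectivity = 26L)
  cortex <- b & !interior
  list(cortex = mask_like(cortex, bone), interior = mask_like(interior, bone))
}

#' Apply a manual-overlay correction to a mask
#'
#' Voxelwise union (`mode = "add"`) or set difference (`mode = "remove"`)
#' with an overlay mask drawn externally. This is the hook that replaces the
#' interactive editing of thin-cortex regions (e.g. the fossa trochanterica)
#' in an otherwise automatic pipeline.
#'
#' @param mask,overlay [binary_mask()] objects on the same grid.
#' @param mode `"add"` or `"remove"`.
#' @return A [binary_mask()].
#' @export
apply_manual_overlay <- function(mask, overlay, mode = c("add", "remove")) {
  mode <- match.arg(mode)
  stopifnot(inherits(mask, "binary_mask"), inherits(overlay, "binary_mask"))
  stop_if_grid_mismatch(mask, overlay)
  m <- mask_logical(mask); o <- mask_logical(overlay)
  mask_like(if (mode == "add") m | o else m & !o, mask)
}

#' Smooth a binary mask
#'
#' Gaussian-filters the 0/1 indicator field with physical width `sigma`
#' (millimetres, converted per axis to voxels) and re-binarizes at 0.5. This
#' gives the clean borderlines needed for surface export; `sigma = 0` returns
#' the mask unchanged. An isolated voxel disappears once `sigma` exceeds
#' about one voxel (its filtered peak falls below 0.5).
#'
#' @param mask a [binary_mask()].
#' @param sigma Gaussian standard deviation in mm, `>= 0`.
#' @return A [binary_mask()].
#' @export
smooth_mask <- function(mask, sigma) {
  stopifnot(inherits(mask, "binary_mask"))
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (sigma == 0) return(mask)
  f <- gaussian_filter3(mask$voxels + 0, sigma / mask$spacing)
  mask_like(f >= 0.5, mask)
}

#' Derive the spongiosa region from bone and cortex masks
#'
#' The spongiosa is the full endosteal cavity: the bone mask with internal
#' cavities filled, minus the cortex. Filling (6-connected background
#' components not reachable from the volume border) reproduces the
#' grey-value-inversion step that turns a subtracted shell into a solid
#' cavity region. The cortex is intersected with the filled bone first, so
#' `cortex` and the returned spongiosa are disjoint and together cover the
#' filled bone exactly.
#'
#' @param bone whole-bone [binary_mask()], nonempty.
#' @param cortex cortical [binary_mask()] on the same grid.
#' @return The spongiosa [binary_mask()].
#' @export
derive_spongiosa <- function(bone, cortex) {
  stopifnot(inherits(bone, "binary_mask"), inherits(cortex, "binary_mask"))
  stop_if_grid_mismatch(bone, cortex)
  b <- mask_logical(bone)
  if (!any(b)) stop("segmentation error: empty bone mask", call. = FALSE)
  filled <- fill_holes3(b)
  ctx <- mask_logical(cortex) & filled
  mask_like(filled & !ctx, bone)
}

#' Run the full femur segmentation pipeline
#'
#' Chains the segmentation stages on a calibrated volume: global threshold
#' with largest-component cleanup ([global_threshold()]), morphological
#' cortex/interior separation ([split_cortex_spongiosa()]), optional manual
#' overlay correction ([apply_manual_overlay()]), cortex smoothing
#' ([smooth_mask()]) and spongiosa derivation with cavity filling
#' ([derive_spongiosa()]).
#'
#' @param v a [calibrated_volume()].
#' @param threshold `"otsu"` or a fixed grey value.
#' @param peel_radius ball radius in voxels for the cortex split.
#' @param sigma cortex smoothing width in mm (0 disables smoothing).
#' @param overlay optional [binary_mask()] manual correction for the cortex.
#' @param overlay_mode `"add"` or `"remove"`.
#' @return An object of class `femur_segmentation`: a list with
#'   [binary_mask()] elements `bone`, `cortex`, `spongiosa` and the
#'   parameters used.
#' @seealso [export_surfaces()], [bvtv()]
#' @export
segment_femur <- function(v, threshold = "otsu", peel_radius = 5, sigma = 1,
                          overlay = NULL, overlay_mode = c("add", "remove")) {
  overlay_mode <- match.arg(overlay_mode)
  bone <- if (identical(threshold, "otsu"))
    global_threshold(v, "otsu")
  else
    global_threshold(v, "fixed", value = threshold)
  parts <- split_cortex_spongiosa(bone, peel_radius = peel_radius)
  cortex <- parts$cortex
  if (!is.null(overlay))
    cortex <- apply_manual_overlay(cortex, overlay, overlay_mode)
  if (sigma > 0) cortex <- smooth_mask(cortex, sigma)
  # containment after smoothing/overlay: cortex stays inside the filled bone
  spongiosa <- derive_spongiosa(bone, cortex)
  filled <- fill_holes3(mask_logical(bone))
  cortex <- mask_like(mask_logical(cortex) & filled, bone)
  structure(list(bone = bone, cortex = cortex, spongiosa = spongiosa,
                 threshold = attr(bone, "threshold"),
                 peel_radius = peel_radius, sigma = sigma),
            class = "femur_segmentation")
}

#' @export
print.femur_segmentation <- function(x, ...) {
  cat("<femur_segmentation>\n")
  cat("  threshold: ", signif(x$threshold, 6),
      ";  peel radius: ", x$peel_radius, " voxels;  smoothing sigma: ",
      x$sigma, " mm\n", sep = "")
  for (nm in c("bone", "cortex", "spongiosa"))
    cat(sprintf("  %-10s %d voxels\n", nm, sum(x[[nm]]$voxels)))
  invisible(x)
}

#' @export
plot.femur_segmentation <- function(x, ...) {
  mp <- extract_midplanes(x$bone)
  labels <- c("axial", "coronal", "sagittal")
  op <- graphics::par(mfrow = c(2, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show <- function(img, main) {
    graphics::image(img, col = grDevices::gray.colors(32, 0, 1), axes = FALSE,
                    main = main, useRaster = TRUE)
  }
  for (i in 1:3) show(mp[[i]], paste("bone", labels[i]))
  mpc <- extract_midplanes(x$cortex)
  mps <- extract_midplanes(x$spongiosa)
  for (i in 1:3) show(mpc[[i]] + 0.5 * mps[[i]],
                      paste("cortex+spongiosa", labels[i]))
  invisible(x)
}
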