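#' Grey-value sums over a trabecular region of interest
#'
#' On the 0--1064 bone-fraction scale, the sum of grey values over a region
#' of interest (ROI) measures how much bone the region contains, and the
#' voxel count measures its total volume. Grey values above 1064 (possible
#' only through rounding artefacts) are clipped before summing, since the
#' volume-fraction interpretation presumes the 0--1064 scale.
#'
#' @param v a calibrated [calibrated_volume()].
#' @param roi a nonempty [binary_mask()] on the same grid; by convention the
#'   spongiosa mask from [segment_femur()].
#' @return A list with `sum_gv_1064` (sum of ROI grey values) and `sum_gv_b`
#'   (ROI voxel count).
#' @seealso [bvtv()]
#' @export
grey_value_sums <- function(v, roi) {
  stopifnot(inherits(v, "calibrated_volume"), inherits(roi, "binary_mask"))
  if (!isTRUE(v$calibrated))
    stop("volume is not calibrated to the 0-1064 scale; run rescale_grayscale()",
         call. = FALSE)
  stop_if_grid_mismatch(v, roi)
  sel <- mask_logical(roi)
  n <- sum(sel)
  if (n == 0L) stop("ROI is empty", call. = FALSE)
  g <- v$voxels[sel]
  g[g > 1064] <- 1064
  list(sum_gv_1064 = sum(g), sum_gv_b = n)
}

#' Mean trabecular bone volume fraction (BV/TV)
#'
#' Mean bone volume over total volume of a trabecular ROI, computed from the
#' calibrated grey values as
#' \deqn{\overline{BV}/TV = \frac{\sum GV_{1064}}{1064 \cdot \sum GV_B}}
#' where \eqn{\sum GV_{1064}} is the sum of ROI grey values on the 0--1064
#' bone-fraction scale and \eqn{\sum GV_B} the number of ROI voxels. The
#' result lies in `[0, 1]`; typical proximal-femur trabecular values are
#' 0.10--0.16.
#'
#' @inheritParams grey_value_sums
#' @return An object of class `bvtv_result`: list with `sum_gv_1064`,
#'   `sum_gv_b` and `bvtv`.
#' @seealso [infill_from_bvtv()] for the downstream infill matching.
#' @examples
#' v <- calibrated_volume(array(532, c(4, 4, 4)), calibrated = TRUE)
#' roi <- binary_mask(array(1L, c(4, 4, 4)))
#' bvtv(v, roi)  # 0.5: half-scale grey everywhere
#' @export
bvtv <- function(v, roi) {
  s <- grey_value_sums(v, roi)
  structure(list(sum_gv_1064 = s$sum_gv_1064, sum_gv_b = s$sum_gv_b,
                 bvtv = s$sum_gv_1064 / (1064 * s$sum_gv_b)),
            class = "bvtv_result")
}

#' @export
print.bvtv_result <- function(x, ...) {
  cat("<bvtv_result>\n")
  cat("  sum of grey values (0-1064):", format(x$sum_gv_1064, big.mark = ","),
      "\n")
  cat("  ROI voxels:                 ", format(x$sum_gv_b, big.mark = ","),
      "\n")
  cat("  mean BV/TV:                 ", signif(x$bvtv, 4),
      sprintf(" (%.1f%%)\n", 100 * x$bvtv))
  invisible(x)
}
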