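#' Print-parameter report for a surrogate
#'
#' Assembles the slicer settings used for every printed surrogate: the
#' cortex is printed solid (linear pattern, 100% infill, two perimeters,
#' widened extrusion for layer adhesion) and the spongiosa as a
#' perimeter-free gyroid whose infill density comes from the
#' recommendation. The printing temperature is raised to 225 degrees C to
#' improve layer cohesion under compression. Only the spongiosa infill
#' density varies between surrogates; every other field is fixed.
#'
#' @param rec an `infill_recommendation` from [match_infill()] or
#'   [infill_from_bvtv()], or an integer infill percent.
#' @return An object of class `print_parameter_report`: nested list with
#'   elements `global`, `cortex`, `spongiosa`.
#' @seealso [format.print_parameter_report()] for the text rendering.
#' @export
print_parameter_report <- function(rec) {
  pct <- if (inherits(rec, "infill_recommendation")) rec$infill_percent
  else as.integer(rec)
  if (!is.finite(pct) || pct < 1 || pct > 100)
    stop("infill percent must lie in [1, 100]", call. = FALSE)
  structure(list(
    global = list(
      perimeter = 2L,
      printing_temperature_c = 225L,
      layer_height_mm = 0.20
    ),
    cortex = list(
      infill_pattern = "linear",
      infill_density_percent = 100L,
      ew_outer_contour_mm = 0.6,
      ew_contour_mm = 0.6,
      ew_infill_mm = 0.45,
      ew_massive_infill_mm = 0.6
    ),
    spongiosa = list(
      infill_pattern = "gyroid",
      perimeter = 0L,
      infill_density_percent = as.integer(pct)
    )
  ), class = "print_parameter_report")
}

#' Render a print-parameter report as text
#'
#' Deterministic: two reports built from the same recommendation render to
#' byte-identical text.
#'
#' @param x a `print_parameter_report`.
#' @param ... unused.
#' @return A character vector, one line per setting.
#' @export
format.print_parameter_report <- function(x, ...) {
  c("printing parameters",
    sprintf("  perimeter:            %d", x$global$perimeter),
    sprintf("  temperature:          %d C", x$global$printing_temperature_c),
    sprintf("  layer height:         %.2f mm", x$global$layer_height_mm),
    "cortex",
    sprintf("  infill pattern:       %s", x$cortex$infill_pattern),
    sprintf("  infill density:       %d%%", x$cortex$infill_density_percent),
    sprintf("  EW outer contour:     %.2f mm", x$cortex$ew_outer_contour_mm),
    sprintf("  EW contour:           %.2f mm", x$cortex$ew_contour_mm),
    sprintf("  EW infill:            %.2f mm", x$cortex$ew_infill_mm),
    sprintf("  EW massive infill:    %.2f mm", x$cortex$ew_massive_infill_mm),
    "spongiosa",
    sprintf("  infill pattern:       %s", x$spongiosa$infill_pattern),
    sprintf("  perimeter:            %d", x$spongiosa$perimeter),
    sprintf("  infill density:       %d%%",
            x$spongiosa$infill_density_percent))
}

#' @export
print.print_parameter_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
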