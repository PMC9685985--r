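#' Force--displacement curve
#'
#' A sampled compression-test record: machine displacement `u` (mm,
#' nondecreasing) and force `f` (N), both stored as positive magnitudes.
#' The sample rate is informational metadata only.
#'
#' @param u displacement samples in mm, nondecreasing, length `>= 2`.
#' @param f force samples in N, same length as `u`.
#' @param sample_rate sampling rate in Hz (metadata, default `NA`).
#' @return An object of class `fd_curve`.
#' @seealso [load_curve()], [ultimate_force()], [spring_stiffness()]
#' @export
fd_curve <- function(u, f, sample_rate = NA_real_) {
  u <- as.numeric(u); f <- as.numeric(f)
  if (length(u) != length(f))
    stop("`u` and `f` must have the same length", call. = FALSE)
  if (length(u) < 2L)
    stop("a curve needs at least 2 samples", call. = FALSE)
  if (any(!is.finite(u)) || any(!is.finite(f)))
    stop("`u` and `f` must be finite", call. = FALSE)
  if (any(diff(u) < 0))
    stop("`u` must be nondecreasing", call. = FALSE)
  structure(list(u = u, f = f, sample_rate = sample_rate),
            class = "fd_curve")
}

#' @export
print.fd_curve <- function(x, ...) {
  cat("<fd_curve> ", length(x$u), " samples, u in [",
      signif(min(x$u), 4), ", ", signif(max(x$u), 4), "] mm, peak force ",
      signif(max(x$f), 6), " N\n", sep = "")
  invisible(x)
}

#' @export
plot.fd_curve <- function(x, ...) {
  graphics::plot(x$u, x$f, type = "l", xlab = "displacement u [mm]",
                 ylab = "force F [N]", ...)
  invisible(x)
}

#' Load a force--displacement curve from CSV
#'
#' Reads a two-column CSV with header `displacement_mm,force_N` (comma
#' separator, decimal point). Rows with non-numeric entries are rejected
#' with an error naming the offending file lines; a file with fewer than
#' two valid rows is a format error.
#'
#' @param path CSV file path.
#' @param sample_rate optional sampling rate in Hz, stored as metadata.
#' @return An [fd_curve()].
#' @export
load_curve <- function(path, sample_rate = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  if (ncol(raw) < 2L)
    stop("format error: expected two columns (displacement mm, force N) in ",
         path, call. = FALSE)
  u <- suppressWarnings(as.numeric(raw[[1L]]))
  f <- suppressWarnings(as.numeric(raw[[2L]]))
  bad <- which(is.na(u) | is.na(f))
  if (length(bad))
    stop("format error: non-numeric entries in ", path, " at line",
         if (length(bad) > 1L) "s" else "", " ",
         paste(bad + 1L, collapse = ", "), " (line 1 is the header)",
         call. = FALSE)
  if (length(u) < 2L)
    stop("format error: fewer than 2 data rows in ", path, call. = FALSE)
  fd_curve(u, f, sample_rate = sample_rate)
}

#' Write a force--displacement curve to CSV
#'
#' Inverse of [load_curve()]: header `displacement_mm,force_N`, decimal
#' point, comma separator.
#'
#' @param curve an [fd_curve()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "fd_curve"))
  utils::write.csv(data.frame(displacement_mm = curve$u, force_N = curve$f),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
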