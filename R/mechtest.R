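#' Ultimate force of a compression test
#'
#' The ultimate force is the maximum compressive load over the record; the
#' displacement reported is where that maximum first occurs.
#'
#' @param curve an [fd_curve()].
#' @return A list with `f_ult` (N), `u_at_f_ult` (mm) and `index`.
#' @export
ultimate_force <- function(curve) {
  stopifnot(inherits(curve, "fd_curve"))
  i <- which.max(curve$f)
  list(f_ult = curve$f[i], u_at_f_ult = curve$u[i], index = i)
}

#' Spring stiffness by the best linear fit (maximum R^2)
#'
#' Fits the stiffness of a compression test as the slope of the best linear
#' region of the force--displacement curve. Printed and foam specimens show
#' a non-linear toe region at low loads while the contact area adapts, so
#' the analysis range starts at the first sample with force at least
#' `toe_fraction` of the ultimate force and ends at the ultimate force
#' (post-failure samples are ignored). Over all contiguous windows inside
#' that range whose displacement span is at least `min_window_fraction` of
#' the range span (and with at least 3 samples), an ordinary least-squares
#' line `f = k u + b` is fitted; the window with the maximum R^2 wins, ties
#' (within 1e-9) going to the larger displacement span and then the earlier
#' start. A span floor is necessary because unconstrained R^2 maximization
#' degenerates to near-two-point windows.
#'
#' @param curve an [fd_curve()] with at least 10 samples before the force
#'   maximum.
#' @param toe_fraction force threshold that ends the toe region, as a
#'   fraction of the ultimate force (default 0.10).
#' @param min_window_fraction minimum window displacement span as a fraction
#'   of the analysis-range span (default 0.20).
#' @return An object of class `stiffness_fit`: list with `k` (N/mm),
#'   `intercept` (N), `r2`, `window` (start/end sample indices of the best
#'   fit), `f_ult` (N), `u_at_f_ult` (mm), the analysis `range`, the
#'   parameters, and the curve.
#' @seealso [ultimate_force()], [summarize_group()],
#'   [modulus_from_cube_test()]
#' @examples
#' u <- seq(0, 5, by = 0.01)
#' s <- spring_stiffness(fd_curve(u, 1000 * u))
#' coef(s)   # k = 1000 N/mm
#' @export
spring_stiffness <- function(curve, toe_fraction = 0.10,
                             min_window_fraction = 0.20) {
  stopifnot(inherits(curve, "fd_curve"))
  if (toe_fraction < 0 || toe_fraction >= 1)
    stop("`toe_fraction` must lie in [0, 1)", call. = FALSE)
  if (min_window_fraction <= 0 || min_window_fraction > 1)
    stop("`min_window_fraction` must lie in (0, 1]", call. = FALSE)
  ult <- ultimate_force(curve)
  ipeak <- ult$index
  if (ipeak - 1L < 10L)
    stop("analysis error: need at least 10 samples before the force maximum",
         call. = FALSE)
  istart <- which(curve$f >= toe_fraction * ult$f_ult)[1L]
  if (istart >= ipeak)
    stop("analysis error: no samples between toe region and force maximum",
         call. = FALSE)
  idx <- istart:ipeak
  u <- curve$u[idx]; f <- curve$f[idx]
  span_total <- u[length(u)] - u[1L]
  if (span_total <= 0)
    stop("analysis error: analysis range has zero displacement span",
         call. = FALSE)
  min_span <- min_window_fraction * span_total
  # centred prefix sums for numerically stable windowed OLS
  uc <- u - mean(u); fc <- f - mean(f)
  c0 <- c(0, cumsum(rep(1, length(uc))))
  cu <- c(0, cumsum(uc));  cf <- c(0, cumsum(fc))
  cuu <- c(0, cumsum(uc * uc)); cff <- c(0, cumsum(fc * fc))
  cuf <- c(0, cumsum(uc * fc))
  m <- length(uc)
  best <- NULL
  for (i in seq_len(m - 2L)) {
    j <- (i + 2L):m
    ok <- (u[j] - u[i]) >= min_span
    if (!any(ok)) next
    j <- j[ok]
    n <- c0[j + 1L] - c0[i]
    su <- cu[j + 1L] - cu[i];  sf <- cf[j + 1L] - cf[i]
    suu <- cuu[j + 1L] - cuu[i]; sff <- cff[j + 1L] - cff[i]
    suf <- cuf[j + 1L] - cuf[i]
    sxx <- suu - su * su / n
    syy <- sff - sf * sf / n
    sxy <- suf - su * sf / n
    r2 <- ifelse(sxx > 0 & syy > 0, sxy * sxy / (sxx * syy), NA_real_)
    r2[r2 > 1] <- 1  # guard fp overshoot
    if (all(is.na(r2))) next
    # best end for this start: max r2 (ties within 1e-9 -> largest span)
    cand <- which(!is.na(r2) & r2 >= max(r2, na.rm = TRUE) - 1e-9)
    jb <- j[cand[which.max(u[j[cand]] - u[i])]]
    nb <- c0[jb + 1L] - c0[i]
    sxxb <- (cuu[jb + 1L] - cuu[i]) - (cu[jb + 1L] - cu[i])^2 / nb
    sxyb <- (cuf[jb + 1L] - cuf[i]) - (cu[jb + 1L] - cu[i]) *
      (cf[jb + 1L] - cf[i]) / nb
    syyb <- (cff[jb + 1L] - cff[i]) - (cf[jb + 1L] - cf[i])^2 / nb
    r2b <- min(1, sxyb^2 / (sxxb * syyb))
    rec <- list(i = i, j = jb, r2 = r2b, span = u[jb] - u[i],
                slope = sxyb / sxxb)
    if (is.null(best) ||
        rec$r2 > best$r2 + 1e-9 ||
        (rec$r2 >= best$r2 - 1e-9 && rec$span > best$span + 1e-12))
      best <- rec
  }
  if (is.null(best))
    stop("analysis error: analysis range shorter than the minimum window",
         call. = FALSE)
  # intercept on original (uncentred) scale
  wi <- best$i:best$j
  b <- mean(f[wi]) - best$slope * mean(u[wi])
  structure(list(k = best$slope, intercept = b, r2 = best$r2,
                 window = c(start = idx[best$i], end = idx[best$j]),
                 f_ult = ult$f_ult, u_at_f_ult = ult$u_at_f_ult,
                 range = c(start = istart, end = ipeak),
                 toe_fraction = toe_fraction,
                 min_window_fraction = min_window_fraction,
                 curve = curve),
            class = "stiffness_fit")
}

#' @export
print.stiffness_fit <- function(x, ...) {
  cat("<stiffness_fit>\n")
  cat("  ultimate force F_ult: ", signif(x$f_ult, 6), " N at u = ",
      signif(x$u_at_f_ult, 4), " mm\n", sep = "")
  cat("  spring stiffness k:   ", signif(x$k, 6), " N/mm  (R^2 = ",
      format(x$r2, digits = 6), ")\n", sep = "")
  cat("  fit window: samples ", x$window[1], "-", x$window[2],
      ", u in [", signif(x$curve$u[x$window[1]], 4), ", ",
      signif(x$curve$u[x$window[2]], 4), "] mm\n", sep = "")
  invisible(x)
}

#' @export
coef.stiffness_fit <- function(object, ...) {
  c(k = object$k, intercept = object$intercept)
}

#' @export
residuals.stiffness_fit <- function(object, ...) {
  wi <- object$window[1]:object$window[2]
  object$curve$f[wi] - (object$k * object$curve$u[wi] + object$intercept)
}

#' @export
plot.stiffness_fit <- function(x, ...) {
  graphics::plot(x$curve$u, x$curve$f, type = "l",
                 xlab = "displacement u [mm]", ylab = "force F [N]", ...)
  wi <- x$window[1]:x$window[2]
  graphics::lines(x$curve$u[wi], x$k * x$curve$u[wi] + x$intercept,
                  col = "red", lwd = 2)
  graphics::abline(h = x$f_ult, col = "blue", lty = 2)
  graphics::legend("bottomright",
                   legend = c("curve", "best linear fit", "F_ult"),
                   col = c("black", "red", "blue"), lty = c(1, 1, 2),
                   bty = "n")
  invisible(x)
}

#' Group summary of compression tests
#'
#' Mean and sample standard deviation (n - 1 denominator) of the ultimate
#' forces and spring stiffnesses of a test group, plus the group's mean
#' force--displacement curve with a pointwise SD band: each curve is
#' resampled by linear interpolation onto a common 200-point displacement
#' grid spanning the shortest curve's displacement range.
#'
#' @param results list of `stiffness_fit` objects (at least one).
#' @param curves optional list of [fd_curve()]s for the mean-curve band;
#'   defaults to the curves stored in `results`.
#' @return An object of class `test_group_summary`: `n`, `f_ult`
#'   (mean/sd), `k` (mean/sd), and `band` (grid `u`, `mean`, `sd`).
#'   With `n = 1` the SDs are reported as 0 and the summary is flagged.
#' @export
summarize_group <- function(results, curves = NULL) {
  if (inherits(results, "stiffness_fit")) results <- list(results)
  if (length(results) < 1L)
    stop("at least one result is required", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "stiffness_fit")))
  if (is.null(curves)) curves <- lapply(results, `[[`, "curve")
  fu <- vapply(results, `[[`, numeric(1), "f_ult")
  kk <- vapply(results, `[[`, numeric(1), "k")
  n <- length(results)
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  band <- NULL
  if (length(curves)) {
    lo <- max(vapply(curves, function(cv) min(cv$u), numeric(1)))
    hi <- min(vapply(curves, function(cv) max(cv$u), numeric(1)))
    grid <- seq(lo, hi, length.out = 200L)
    fm <- vapply(curves, function(cv)
      stats::approx(cv$u, cv$f, xout = grid, ties = "ordered")$y,
      numeric(200L))
    fm <- matrix(fm, nrow = 200L)
    band <- list(u = grid, mean = rowMeans(fm),
                 sd = apply(fm, 1L, sd0))
  }
  structure(list(n = n,
                 f_ult = c(mean = mean(fu), sd = sd0(fu)),
                 k = c(mean = mean(kk), sd = sd0(kk)),
                 single = n == 1L, band = band),
            class = "test_group_summary")
}

#' @export
print.test_group_summary <- function(x, ...) {
  cat("<test_group_summary> n = ", x$n,
      if (x$single) "  (single test: SD = 0 by convention)" else "",
      "\n", sep = "")
  cat(sprintf("  F_ult: %.1f +/- %.1f N\n", x$f_ult["mean"], x$f_ult["sd"]))
  cat(sprintf("  k:     %.1f +/- %.1f N/mm\n", x$k["mean"], x$k["sd"]))
  invisible(x)
}

#' @export
plot.test_group_summary <- function(x, ...) {
  if (is.null(x$band)) stop("no curves were summarized", call. = FALSE)
  b <- x$band
  graphics::plot(b$u, b$mean, type = "n",
                 ylim = range(c(b$mean - b$sd, b$mean + b$sd)),
                 xlab = "displacement u [mm]", ylab = "force F [N]", ...)
  graphics::polygon(c(b$u, rev(b$u)), c(b$mean - b$sd, rev(b$mean + b$sd)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(b$u, b$mean, lwd = 2, col = "steelblue4")
  invisible(x)
}

#' Cube compression-test record
#'
#' A compression test of a cube specimen (foam milled from a surrogate, or
#' a printed gyroid-infill cube): the cube edge length plus the recorded
#' force--displacement curve.
#'
#' @param edge_length cube edge length in mm, `> 0`.
#' @param curve an [fd_curve()].
#' @return An object of class `cube_test_record`.
#' @export
cube_test_record <- function(edge_length, curve) {
  if (!(is.numeric(edge_length) && length(edge_length) == 1L &&
        edge_length > 0))
    stop("`edge_length` must be a single positive number (mm)", call. = FALSE)
  stopifnot(inherits(curve, "fd_curve"))
  structure(list(edge_length = edge_length, curve = curve),
            class = "cube_test_record")
}

#' @export
print.cube_test_record <- function(x, ...) {
  cat("<cube_test_record> ", x$edge_length, " mm edge, ",
      length(x$curve$u), " samples\n", sep = "")
  invisible(x)
}

#' Young's modulus from a cube compression test
#'
#' Converts the recorded force--displacement curve to engineering stress
#' (`F / edge^2`) and strain (`u / edge`) and takes the slope of the best
#' linear stress--strain fit -- the same maximum-R^2 window search as
#' [spring_stiffness()], so toe regions are excluded identically. For a
#' cube, the modulus equals the force--displacement slope times
#' `edge / edge^2`, i.e. `slope / edge`.
#'
#' @param rec a [cube_test_record()] whose curve has at least 10 samples
#'   with increasing displacement before the force maximum.
#' @param toe_fraction,min_window_fraction passed to [spring_stiffness()].
#' @return Young's modulus in MPa.
#' @examples
#' u <- seq(0, 0.5, by = 0.005)
#' rec <- cube_test_record(10, fd_curve(u, 90.6 * u))
#' modulus_from_cube_test(rec)  # 9.06 MPa
#' @export
modulus_from_cube_test <- function(rec, toe_fraction = 0.10,
                                   min_window_fraction = 0.20) {
  stopifnot(inherits(rec, "cube_test_record"))
  L <- rec$edge_length
  if (max(rec$curve$u) - min(rec$curve$u) <= 0)
    stop("analysis error: curve has zero displacement span", call. = FALSE)
  ss <- fd_curve(rec$curve$u / L, rec$curve$f / L^2)
  fit <- spring_stiffness(ss, toe_fraction = toe_fraction,
                          min_window_fraction = min_window_fraction)
  unname(fit$k)
}
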