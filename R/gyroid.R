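#' Fit the gyroid infill-density to modulus calibration curve
#'
#' Fits the power curve \eqn{E = a \rho^g} through compression-test results
#' of gyroid-infill cubes by ordinary least squares of `log(modulus)` on
#' `log(infill)`. The fitted curve replaces the graphical look-up between
#' infill density and stiffness: [match_infill()] inverts it analytically.
#' Mean cube moduli drive the fit; per-point spreads, when given, are stored
#' for reporting only.
#'
#' @param infill infill volume fractions in `(0, 1]`, strictly increasing
#'   (at least two distinct values). A data frame with columns
#'   `infill`/`modulus` (and optionally `spread`) may be passed as the first
#'   argument instead.
#' @param modulus measured Young's moduli in MPa, all `> 0`.
#' @param spread optional modulus spreads (e.g. standard deviations) in MPa.
#' @return An object of class `gyroid_calibration` with components `points`
#'   (data frame), `a` (prefactor, MPa), `g` (exponent), `fit` (the
#'   underlying `lm` on log scales) and `residuals` (log-scale residuals).
#' @seealso [match_infill()], [infill_from_bvtv()], [modulus_from_cube_test()]
#' @examples
#' cal <- fit_gyroid_curve(reference_gyroid_points())
#' cal
#' match_infill(35.6, cal)
#' @export
fit_gyroid_curve <- function(infill, modulus = NULL, spread = NULL) {
  if (is.data.frame(infill)) {
    df <- infill
    if (!all(c("infill", "modulus") %in% names(df)))
      stop("data frame must have columns `infill` and `modulus`", call. = FALSE)
    spread <- df$spread
    modulus <- df$modulus
    infill <- df$infill
  }
  infill <- as.numeric(infill); modulus <- as.numeric(modulus)
  if (length(infill) != length(modulus))
    stop("`infill` and `modulus` must have the same length", call. = FALSE)
  if (length(unique(infill)) < 2L)
    stop("at least two distinct calibration points are required", call. = FALSE)
  if (any(!is.finite(infill)) || any(infill <= 0) || any(infill > 1))
    stop("infill fractions must lie in (0, 1]", call. = FALSE)
  if (any(!is.finite(modulus)) || any(modulus <= 0))
    stop("moduli must be strictly positive", call. = FALSE)
  ord <- order(infill)
  infill <- infill[ord]; modulus <- modulus[ord]
  if (!is.null(spread)) spread <- as.numeric(spread)[ord]
  if (any(diff(infill) <= 0))
    stop("infill fractions must be strictly increasing", call. = FALSE)
  fit <- stats::lm(log(modulus) ~ log(infill))
  a <- exp(unname(stats::coef(fit)[1L]))
  g <- unname(stats::coef(fit)[2L])
  points <- data.frame(infill = infill, modulus = modulus)
  if (!is.null(spread)) points$spread <- spread
  structure(list(points = points, a = a, g = g, fit = fit,
                 residuals = unname(stats::residuals(fit))),
            class = "gyroid_calibration")
}

#' @export
print.gyroid_calibration <- function(x, digits = 4, ...) {
  cat("<gyroid_calibration> E = a * rho^g fitted to ", nrow(x$points),
      " cube tests\n", sep = "")
  cat("  a = ", signif(x$a, digits), " MPa,  g = ", signif(x$g, digits),
      "\n", sep = "")
  cat("  calibrated modulus range: [",
      signif(min(x$points$modulus), digits), ", ",
      signif(max(x$points$modulus), digits), "] MPa\n", sep = "")
  invisible(x)
}

#' @export
summary.gyroid_calibration <- function(object, ...) {
  cat("Gyroid infill calibration, log-log ordinary least squares\n\n")
  print(object$points, row.names = FALSE)
  cat("\nfitted curve: E =", signif(object$a, 6), "MPa * rho^",
      signif(object$g, 6), "\n")
  cat("log-scale residuals:", paste(signif(object$residuals, 3),
                                    collapse = ", "), "\n")
  cat("residual standard error (log scale):",
      signif(summary(object$fit)$sigma, 4), "\n")
  invisible(object)
}

#' @export
coef.gyroid_calibration <- function(object, ...) {
  c(a = object$a, g = object$g)
}

#' @export
residuals.gyroid_calibration <- function(object, ...) object$residuals

#' Predict along the fitted gyroid calibration curve
#'
#' `type = "modulus"` evaluates the fitted curve at infill fractions;
#' `type = "infill"` inverts it at moduli (the unrounded counterpart of
#' [match_infill()]).
#'
#' @param object a `gyroid_calibration`.
#' @param newdata infill fractions or moduli, per `type`.
#' @param type `"modulus"` or `"infill"`.
#' @param ... unused.
#' @return Numeric vector.
#' @export
predict.gyroid_calibration <- function(object, newdata,
                                       type = c("modulus", "infill"), ...) {
  type <- match.arg(type)
  if (missing(newdata)) newdata <- object$points$infill
  if (type == "modulus") object$a * newdata^object$g
  else (newdata / object$a)^(1 / object$g)
}

#' @export
plot.gyroid_calibration <- function(x, ...) {
  rho <- seq(0.01, 1, length.out = 200)
  graphics::plot(100 * rho, x$a * rho^x$g, type = "l", log = "xy",
                 xlab = "gyroid infill density [%]",
                 ylab = "Young's modulus [MPa]",
                 main = "Gyroid infill calibration", ...)
  graphics::points(100 * x$points$infill, x$points$modulus, pch = 19,
                   col = "red")
  if (!is.null(x$points$spread))
    graphics::arrows(100 * x$points$infill,
                     pmax(x$points$modulus - x$points$spread, 1e-6),
                     100 * x$points$infill,
                     x$points$modulus + x$points$spread,
                     angle = 90, code = 3, length = 0.04, col = "red")
  invisible(x)
}

#' Simulate calibration moduli from the fitted curve
#'
#' Draws new cube-test moduli at the calibration infill fractions from the
#' fitted log-normal model (fitted curve times log-scale residual noise).
#'
#' @param object a `gyroid_calibration`.
#' @param nsim number of simulated replicates.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return A list of `nsim` data frames with columns `infill`, `modulus`.
#' @export
simulate.gyroid_calibration <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  sigma <- summary(object$fit)$sigma
  mu <- object$a * object$points$infill^object$g
  lapply(seq_len(nsim), function(i)
    data.frame(infill = object$points$infill,
               modulus = mu * exp(stats::rnorm(length(mu), 0, sigma))))
}

#' Match an infill density to a target modulus
#'
#' Inverts the fitted gyroid calibration curve at a target Young's modulus
#' and rounds to the nearest integer infill percent (ties round up), clamped
#' to `[1, 100]` -- slicers take integer infill percentages. The result is
#' flagged `extrapolated` when the target lies outside the modulus range
#' spanned by the calibration cubes.
#'
#' @param e_target target Young's modulus in MPa, `>= 0`.
#' @param cal a `gyroid_calibration` from [fit_gyroid_curve()].
#' @param provenance how the target modulus was obtained (recorded in the
#'   recommendation).
#' @return An object of class `infill_recommendation`: list with
#'   `target_modulus` (MPa), `infill_fraction` (unrounded), `infill_percent`
#'   (integer in 1--100), `extrapolated`, `provenance`.
#' @examples
#' cal <- fit_gyroid_curve(reference_gyroid_points())
#' match_infill(35.6, cal)   # 12%
#' match_infill(60, cal)     # 16%
#' @export
match_infill <- function(e_target, cal,
                         provenance = c("direct_modulus", "foam_modulus",
                                        "bvtv_via_power_law")) {
  provenance <- match.arg(provenance)
  stopifnot(inherits(cal, "gyroid_calibration"))
  if (!is.finite(e_target) || e_target < 0)
    stop("`e_target` must be a nonnegative modulus in MPa", call. = FALSE)
  rho <- if (e_target == 0) 0 else (e_target / cal$a)^(1 / cal$g)
  pct_raw <- 100 * rho
  pct <- floor(pct_raw + 0.5)  # nearest integer, ties up
  clamped <- pct < 1 || pct > 100
  pct <- min(100L, max(1L, as.integer(pct)))
  extrapolated <- clamped ||
    e_target < min(cal$points$modulus) || e_target > max(cal$points$modulus)
  structure(list(target_modulus = e_target, infill_fraction = rho,
                 infill_percent = pct, extrapolated = extrapolated,
                 provenance = provenance),
            class = "infill_recommendation")
}

#' Recommend an infill density for a measured BV/TV
#'
#' Chains the bone power law and the gyroid calibration: the trabecular
#' BV/TV is converted to an equivalent Young's modulus via
#' [power_law_eval()], and that modulus is matched to a gyroid infill
#' density via [match_infill()]. This is the analytic equivalent of reading
#' the BV/TV across to the bone curve and down to the gyroid cube curve on
#' the calibration graph.
#'
#' @param bvtv mean trabecular bone volume fraction in `[0, 1]` (a number or
#'   a [bvtv()] result).
#' @param m a [power_law()]; defaults to `power_law()` (6000 MPa, k = 2).
#' @param cal a `gyroid_calibration`.
#' @return An `infill_recommendation` with provenance
#'   `"bvtv_via_power_law"` and the input `bvtv` recorded.
#' @examples
#' cal <- fit_gyroid_curve(reference_gyroid_points())
#' infill_from_bvtv(0.158, cal = cal)  # ~150 MPa -> 27%
#' @export
infill_from_bvtv <- function(bvtv, m = power_law(), cal) {
  if (inherits(bvtv, "bvtv_result")) bvtv <- bvtv$bvtv
  e <- power_law_eval(m, bvtv)
  rec <- match_infill(e, cal, provenance = "bvtv_via_power_law")
  rec$bvtv <- bvtv
  rec
}

#' @export
print.infill_recommendation <- function(x, ...) {
  cat("<infill_recommendation>\n")
  if (!is.null(x$bvtv))
    cat("  BV/TV:          ", signif(x$bvtv, 4),
        sprintf(" (%.1f%%)\n", 100 * x$bvtv))
  cat("  target modulus: ", signif(x$target_modulus, 5), "MPa\n")
  cat("  gyroid infill:  ", x$infill_percent, "%",
      if (x$extrapolated) "  [extrapolated beyond calibration range]" else "",
      "\n", sep = "")
  cat("  provenance:     ", x$provenance, "\n")
  invisible(x)
}

#' Bundled gyroid cube calibration points
#'
#' The three printed gyroid-infill calibration cubes (30 mm edge, PLA,
#' longitudinal loading): infill fractions 0.10, 0.20, 0.40 with measured
#' Young's moduli 24.73, 89.91, 288.79 MPa and their spreads. Read from the
#' plain-text table bundled with the package.
#'
#' @return A data frame with columns `infill`, `modulus`, `spread`.
#' @export
reference_gyroid_points <- function() {
  utils::read.csv(system.file("extdata", "gyroid_cubes.csv",
                              package = "bonesurro"))
}

#' Bundled foam cube test summary
#'
#' Young's moduli of the polyurethane-foam cubes milled from commercial
#' femur surrogates (10 mm edge) plus the composite-bone datasheet value,
#' with the infill densities printed for their surrogates.
#'
#' @return A data frame with columns `sample`, `modulus`, `spread`,
#'   `printed_infill_percent`.
#' @export
reference_foam_tests <- function() {
  utils::read.csv(system.file("extdata", "foam_cubes.csv",
                              package = "bonesurro"))
}

#' Bundled human femur densitometry summary
#'
#' Trabecular BV/TV of the three human femora, the equivalent moduli read
#' from the calibration graph, and the infill densities printed for their
#' surrogates. The grey-value sums are carried for reference only: as
#' printed they are mutually inconsistent with the BV/TV definition
#' (apparently a units/exponent typo), so only the BV/TV percentages should
#' be used numerically.
#'
#' @return A data frame with columns `sample`, `sum_gv_1064`, `sum_gv_b`,
#'   `bvtv_percent`, `modulus_graph`, `printed_infill_percent`.
#' @export
reference_femora <- function() {
  utils::read.csv(system.file("extdata", "femora_bvtv.csv",
                              package = "bonesurro"))
}
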