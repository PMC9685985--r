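#' Bone modulus--density power law
#'
#' The effective Young's modulus of trabecular bone scales with its volume
#' fraction as \eqn{E_{eff} = E_{bone} \rho^k}, the classic Gibson--Ashby
#' form for cellular solids. Here \eqn{\rho} is either the bone volume
#' fraction BV/TV of a trabecular region or, for foam surrogates, the foam
#' density fraction. The defaults \eqn{E_{bone} = 6000} MPa and \eqn{k = 2}
#' give a mid-range fit to published modulus--density data over the
#' 0--40% density range relevant to the proximal femur.
#'
#' @param e_bone modulus scale in MPa at full density (`rho = 1`); `> 0`.
#' @param k power-law exponent; `> 0`.
#' @return An object of class `power_law`.
#' @seealso [power_law_eval()], [power_law_invert()], [infill_from_bvtv()]
#' @examples
#' m <- power_law()
#' power_law_eval(m, 0.158)   # ~150 MPa
#' power_law_invert(m, 150)
#' @export
power_law <- function(e_bone = 6000, k = 2) {
  if (!(is.numeric(e_bone) && length(e_bone) == 1L && e_bone > 0))
    stop("`e_bone` must be a single positive number (MPa)", call. = FALSE)
  if (!(is.numeric(k) && length(k) == 1L && k > 0))
    stop("`k` must be a single positive number", call. = FALSE)
  structure(list(e_bone = e_bone, k = k), class = "power_law")
}

#' @export
print.power_law <- function(x, ...) {
  cat("<power_law> E_eff = ", x$e_bone, " MPa * rho^", x$k, "\n", sep = "")
  invisible(x)
}

#' Evaluate the power law at a density fraction
#'
#' @param m a [power_law()].
#' @param rho density fraction(s) in `[0, 1]` (BV/TV or foam/infill
#'   fraction).
#' @return Effective Young's modulus in MPa, same length as `rho`.
#' @export
power_law_eval <- function(m, rho) {
  stopifnot(inherits(m, "power_law"))
  if (any(!is.finite(rho)) || any(rho < 0) || any(rho > 1))
    stop("`rho` must lie in [0, 1]", call. = FALSE)
  m$e_bone * rho^m$k
}

#' Invert the power law at a target modulus
#'
#' Returns the density fraction whose effective modulus equals `e`:
#' `rho = (e / e_bone)^(1/k)`. Round-trips with [power_law_eval()] to
#' floating-point precision.
#'
#' @param m a [power_law()].
#' @param e modulus value(s) in MPa, in `[0, e_bone]`.
#' @return Density fraction(s) in `[0, 1]`.
#' @export
power_law_invert <- function(m, e) {
  stopifnot(inherits(m, "power_law"))
  if (any(!is.finite(e)) || any(e < 0) || any(e > m$e_bone))
    stop("`e` must lie in [0, e_bone] = [0, ", m$e_bone, "] MPa",
         call. = FALSE)
  (e / m$e_bone)^(1 / m$k)
}

#' @export
predict.power_law <- function(object, rho, ...) power_law_eval(object, rho)

#' @export
coef.power_law <- function(object, ...) {
  c(e_bone = object$e_bone, k = object$k)
}
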