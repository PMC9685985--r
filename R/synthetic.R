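# Synthetic ground-truth generators: a femur-like calibrated volume and
# stance-compression test curves. Both are seeded and bit-reproducible, so
# every pipeline stage can be validated without scan or test-rig data.

# run `expr` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic femur-like phantom with known truth masks
#'
#' Builds a calibrated volume emulating a proximal femur scan: a stack of
#' circular cross-sections (shaft, drifting narrower neck, spherical head)
#' forms the outer profile; the cortical shell (all voxels within
#' `cortical_thickness` of the outer boundary) is set to grey 1064, and the
#' trabecular interior to `1064 * bvtv` plus optional clipped Gaussian
#' noise. Optional distractor blobs (embedding plate and holder) with
#' intermediate grey values exercise the largest-component cleanup of
#' [global_threshold()]. Trabecular grey values are homogeneous-mean rather
#' than structured: BV/TV densitometry depends only on the ROI mean, so
#' trabecular architecture is irrelevant to every downstream computation.
#'
#' The reported `true_bvtv` is the exact mean of the generated trabecular
#' grey values divided by 1064 (equal to `bvtv` when `noise_sd = 0`).
#'
#' @param dim grid dimensions `(nx, ny, nz)`.
#' @param spacing voxel spacing in mm.
#' @param bvtv target trabecular bone volume fraction in `[0, 1]`.
#' @param cortical_thickness cortical shell thickness in mm (at least one
#'   voxel, and smaller than the narrowest profile radius).
#' @param noise_sd trabecular grey-noise SD in grey levels (0--1064 scale).
#' @param distractors add embedding/holder blobs disconnected from the bone.
#' @param seed RNG seed for reproducibility (restores the caller's RNG
#'   state).
#' @return A list with `volume` (a calibrated [calibrated_volume()]),
#'   `truth` (list of [binary_mask()]s `bone`, `cortex`, `spongiosa`) and
#'   `true_bvtv`.
#' @examples
#' ph <- femur_phantom(dim = c(32, 32, 48), seed = 1)
#' bvtv(ph$volume, ph$truth$spongiosa)
#' @export
femur_phantom <- function(dim = c(64, 64, 96), spacing = c(1, 1, 1),
                          bvtv = 0.158, cortical_thickness = 3,
                          noise_sd = 0, distractors = TRUE, seed = NULL) {
  stopifnot(length(dim) == 3L, all(dim >= 16L))
  if (bvtv < 0 || bvtv > 1) stop("`bvtv` must lie in [0, 1]", call. = FALSE)
  t_vox <- cortical_thickness / spacing[1]
  if (t_vox < 1)
    stop("`cortical_thickness` must be at least one voxel", call. = FALSE)
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]
  # profile in voxel units, scaled to the grid
  cx0 <- nx / 2; cy0 <- ny / 2
  r_shaft <- 0.16 * min(nx, ny)
  r_neck <- 0.11 * min(nx, ny)
  r_head <- 0.18 * min(nx, ny)
  x_drift <- 0.16 * nx
  z0 <- max(4, round(0.05 * nz)); z1 <- nz - max(4, round(0.05 * nz))
  z_neck0 <- z0 + 0.45 * (z1 - z0)
  z_neck1 <- z0 + 0.75 * (z1 - z0)
  head_cz <- z0 + 0.87 * (z1 - z0)
  if (t_vox >= min(r_shaft, r_neck, r_head))
    stop("`cortical_thickness` exceeds the narrowest profile radius",
         call. = FALSE)
  xs <- seq_len(nx); ys <- seq_len(ny)
  dx2 <- outer((xs - cx0)^2, rep(1, ny))
  outer_mask <- array(FALSE, dim)
  for (k in seq_len(nz)) {
    if (k < z0 || k > z1) next
    if (k <= z_neck0) { r <- r_shaft; cx <- cx0 }
    else if (k <= z_neck1) {
      tt <- (k - z_neck0) / (z_neck1 - z_neck0)
      r <- r_shaft + tt * (r_neck - r_shaft)
      cx <- cx0 + tt * x_drift
    } else { r <- r_neck; cx <- cx0 + x_drift }
    d2 <- outer((xs - cx)^2, (ys - cy0)^2, `+`)
    sl <- d2 <= r^2
    dzh <- k - head_cz
    if (abs(dzh) <= r_head) {
      rh2 <- r_head^2 - dzh^2
      sl <- sl | (outer((xs - (cx0 + x_drift))^2, (ys - cy0)^2, `+`) <= rh2)
    }
    outer_mask[, , k] <- sl
  }
  cortex <- outer_mask & !erode_ball(outer_mask, t_vox)
  spong <- outer_mask & !cortex
  vox <- array(0, dim)
  vox[cortex] <- 1064
  n_tr <- sum(spong)
  tr <- rep(1064 * bvtv, n_tr)
  if (noise_sd > 0)
    tr <- with_seed(seed, pmin(1064, pmax(0, tr + stats::rnorm(n_tr, 0, noise_sd))))
  vox[spong] <- tr
  if (distractors) {
    # embedding plate at the bottom and a holder blob in a corner, both
    # separated from the bone by air
    plate_z <- seq_len(max(1, z0 - 3))
    vox[, , plate_z][vox[, , plate_z] == 0] <- 400
    hx <- seq_len(max(3, round(nx / 10)))
    hz <- (nz - max(3, round(nz / 12))):nz
    vox[hx, seq_len(max(3, round(ny / 10))), hz] <- 500
  }
  volume <- calibrated_volume(vox, spacing = spacing, calibrated = TRUE)
  truth <- list(bone = mask_like(outer_mask, volume),
                cortex = mask_like(cortex, volume),
                spongiosa = mask_like(spong, volume))
  true_bvtv <- if (n_tr > 0) sum(tr) / (1064 * n_tr) else NA_real_
  list(volume = volume, truth = truth, true_bvtv = true_bvtv,
       params = list(bvtv = bvtv, cortical_thickness = cortical_thickness,
                     noise_sd = noise_sd, seed = seed))
}

#' Synthetic stance-compression test curve with known truth
#'
#' Generates a force--displacement curve of the shape seen in femoral
#' stance-compression tests: a power-law toe region joining the linear
#' loading branch continuously in value and slope, a force peak at the
#' ultimate force, then linear post-peak softening. Gaussian force noise
#' (fraction of the ultimate force) is added with a fixed seed. Because
#' noise perturbs the realized peak, the reported truth records
#' `f_ult` as the maximum of the generated samples (identical to the
#' nominal `f_ult` for noiseless curves, whose analytic peak falls exactly
#' on a sample) and `k` as the noiseless slope.
#'
#' @param k true spring stiffness in N/mm.
#' @param f_ult nominal ultimate force in N.
#' @param toe_span toe-region displacement span in mm (0 disables the toe).
#' @param toe_exponent toe power-law exponent (`> 1`).
#' @param softening_span post-peak displacement span in mm.
#' @param softening_drop force drop over the softening span, as a fraction
#'   of the ultimate force.
#' @param step sampling step in mm.
#' @param noise_sd force-noise SD as a fraction of `f_ult`.
#' @param seed RNG seed.
#' @return A list with `curve` (an [fd_curve()]) and `truth`
#'   (list `k`, `f_ult`).
#' @examples
#' tc <- make_test_curve(k = 1600, f_ult = 8677, toe_span = 0.5)
#' fit <- spring_stiffness(tc$curve)
#' c(fit$k, tc$truth$k)
#' @export
make_test_curve <- function(k = 1600, f_ult = 8677, toe_span = 0.5,
                            toe_exponent = 2, softening_span = 1,
                            softening_drop = 0.4, step = 0.01,
                            noise_sd = 0, seed = NULL) {
  stopifnot(k > 0, f_ult > 0, step > 0, toe_span >= 0, toe_exponent > 1,
            softening_span >= 0)
  u0 <- toe_span; p <- toe_exponent
  if (u0 > 0 && k * u0 / p >= f_ult)
    stop("toe span so large that the linear span vanishes", call. = FALSE)
  b <- if (u0 > 0) u0 * (1 - 1 / p) else 0
  u_peak <- b + f_ult / k
  u_end <- u_peak + softening_span
  u <- seq(0, u_end, by = step)
  u <- sort(unique(c(u, u_peak)))
  f <- numeric(length(u))
  if (u0 > 0) {
    A <- k / (p * u0^(p - 1))
    toe <- u <= u0
    f[toe] <- A * u[toe]^p
  } else toe <- rep(FALSE, length(u))
  lin <- !toe & u <= u_peak
  f[lin] <- k * (u[lin] - b)
  post <- u > u_peak
  slope_soft <- if (softening_span > 0) softening_drop * f_ult / softening_span
  else 0
  f[post] <- pmax(0, f_ult - slope_soft * (u[post] - u_peak))
  if (noise_sd > 0)
    f <- with_seed(seed, f + stats::rnorm(length(f), 0, noise_sd * f_ult))
  curve <- fd_curve(u, f, sample_rate = NA_real_)
  list(curve = curve, truth = list(k = k, f_ult = max(f)))
}

#' Synthetic cube compression test with known modulus
#'
#' Linear-elastic cube loading: the force--displacement slope of a cube of
#' edge length `L` and modulus `E` is `E * L^2 / L = E * L` (N/mm). An
#' optional toe region and force noise are generated as in
#' [make_test_curve()]. [modulus_from_cube_test()] recovers `e_true` from
#' the record.
#'
#' @param e_true true Young's modulus in MPa.
#' @param edge cube edge length in mm.
#' @param max_strain strain at the end of the record.
#' @param toe_span,toe_exponent,step,noise_sd,seed as in
#'   [make_test_curve()].
#' @return A list with `record` (a [cube_test_record()]) and `truth`
#'   (list `modulus`, `slope`).
#' @examples
#' ct <- make_cube_curve(9.06, edge = 10)
#' modulus_from_cube_test(ct$record)
#' @export
make_cube_curve <- function(e_true, edge = 30, max_strain = 0.04,
                            toe_span = 0, toe_exponent = 2, step = NULL,
                            noise_sd = 0, seed = NULL) {
  stopifnot(e_true > 0, edge > 0, max_strain > 0)
  slope <- e_true * edge           # N/mm
  u_max <- max_strain * edge
  if (is.null(step)) step <- u_max / 100
  u0 <- toe_span; p <- toe_exponent
  u <- seq(0, u_max, by = step)
  f <- numeric(length(u))
  if (u0 > 0) {
    if (u0 >= u_max)
      stop("toe span so large that the linear span vanishes", call. = FALSE)
    A <- slope / (p * u0^(p - 1))
    b <- u0 * (1 - 1 / p)
    toe <- u <= u0
    f[toe] <- A * u[toe]^p
    f[!toe] <- slope * (u[!toe] - b)
  } else {
    f <- slope * u
  }
  f_peak <- max(f)
  if (noise_sd > 0)
    f <- with_seed(seed, f + stats::rnorm(length(f), 0, noise_sd * f_peak))
  rec <- cube_test_record(edge, fd_curve(u, f))
  list(record = rec, truth = list(modulus = e_true, slope = slope))
}
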