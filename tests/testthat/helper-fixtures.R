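# Shared fixture builders. Everything is generated in code; no data files.

# solid axis-aligned box mask inside a larger empty grid
box_mask <- function(grid = c(20, 20, 20), lo = c(5, 5, 5), hi = c(15, 15, 15),
                     spacing = c(1, 1, 1)) {
  g <- array(FALSE, grid)
  g[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  binary_mask(g, spacing = spacing)
}

# digital ball mask (voxel centres within radius r of the grid centre)
ball_mask <- function(n = 31, r = 10, spacing = c(1, 1, 1)) {
  ctr <- (n + 1) / 2
  idx <- which(array(TRUE, c(n, n, n)), arr.ind = TRUE)
  g <- array(FALSE, c(n, n, n))
  g[idx[rowSums((idx - ctr)^2) <= r^2, , drop = FALSE]] <- TRUE
  binary_mask(g, spacing = spacing)
}

# small random calibrated volume + full ROI
random_calibrated <- function(dim = c(6, 5, 4), seed = 1) {
  set.seed(seed)
  calibrated_volume(array(runif(prod(dim), 0, 1064), dim), calibrated = TRUE)
}

# compact phantom used in unit tests (fast to segment)
small_phantom <- function(...) {
  femur_phantom(dim = c(40, 40, 56), cortical_thickness = 3, ...)
}
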