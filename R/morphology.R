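# Vectorized 3D morphology on binary arrays. Everything here works on plain
# logical/numeric arrays in voxel units; the exported segmentation operations
# wrap these with grid bookkeeping. Distances are Euclidean in voxel units
# (working volumes are assumed near-isotropic; see the methods vignette).

# shift array along `axis` by `k` voxels: result[i] = a[i + k], out-of-range
# positions take `fill`
shift_axis <- function(a, k, axis, fill) {
  d <- dim(a)
  n <- d[axis]
  if (k == 0L) return(a)
  out <- array(fill, d)
  if (abs(k) >= n) return(out)
  idx_src <- vector("list", 3L)
  idx_dst <- vector("list", 3L)
  for (ax in 1:3) idx_src[[ax]] <- idx_dst[[ax]] <- seq_len(d[ax])
  if (k > 0) {
    idx_dst[[axis]] <- seq_len(n - k)
    idx_src[[axis]] <- (k + 1L):n
  } else {
    idx_dst[[axis]] <- (-k + 1L):n
    idx_src[[axis]] <- seq_len(n + k)
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# squared Euclidean distance (voxel units) from every voxel to the nearest
# voxel of `target` (logical array), truncated: exact for distances <= cap,
# Inf beyond. Separable sweep with offsets limited to |k| <= cap.
dist2_to <- function(target, cap) {
  cap <- max(1L, as.integer(ceiling(cap)))
  f <- array(Inf, dim(target))
  f[target] <- 0
  for (axis in 1:3) {
    g <- f
    for (k in seq.int(-cap, cap)) {
      if (k == 0L) next
      g <- pmin(g, shift_axis(f, k, axis, Inf) + k * k)
    }
    f <- g
  }
  f[f > cap * cap] <- Inf
  f
}

# erosion of logical `m` by a Euclidean ball of radius r (voxels): a voxel
# survives iff its distance to the background exceeds r
erode_ball <- function(m, r) {
  if (r <= 0) return(m)
  d2 <- dist2_to(!m, cap = floor(r) + 1)
  m & d2 > r * r
}

dilate_ball <- function(m, r) {
  if (r <= 0) return(m)
  d2 <- dist2_to(m, cap = floor(r) + 1)
  d2 <= r * r
}

close_ball <- function(m, r) {
  if (r <= 0) return(m)
  # pad so the dilated set never reaches the border: otherwise the outside
  # background vanishes there and the subsequent erosion under-erodes
  p <- as.integer(ceiling(r)) + 1L
  d <- dim(m)
  mp <- array(FALSE, d + 2L * p)
  mp[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])] <- m
  cp <- erode_ball(dilate_ball(mp, r), r)
  cp[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])]
}

# one-step binary dilation; 6-connected (face) or 26-connected (box, separable)
dilate1 <- function(m, connectivity = 26L) {
  out <- m
  if (connectivity == 6L) {
    for (axis in 1:3)
      out <- out | shift_axis(m, 1L, axis, FALSE) | shift_axis(m, -1L, axis, FALSE)
  } else {
    for (axis in 1:3)
      out <- out | shift_axis(out, 1L, axis, FALSE) | shift_axis(out, -1L, axis, FALSE)
  }
  out
}

# geodesic flood fill inside logical `region` from logical `seed`
flood_fill <- function(seed, region, connectivity = 26L) {
  comp <- seed & region
  if (!any(comp)) return(comp)
  repeat {
    grown <- dilate1(comp, connectivity) & region
    if (!any(grown & !comp)) return(comp)
    comp <- grown
  }
}

# connected components of logical `m`; returns list of logical arrays, largest
# first. Intended for masks with a handful of components (bone + distractors).
connected_components <- function(m, connectivity = 26L) {
  comps <- list()
  remaining <- m
  while (any(remaining)) {
    seed_idx <- which(remaining)[1L]
    seed <- array(FALSE, dim(m))
    seed[seed_idx] <- TRUE
    comp <- flood_fill(seed, remaining, connectivity)
    comps[[length(comps) + 1L]] <- comp
    remaining <- remaining & !comp
  }
  if (length(comps) > 1L)
    comps <- comps[order(vapply(comps, sum, numeric(1)), decreasing = TRUE)]
  comps
}

largest_component <- function(m, connectivity = 26L) {
  comps <- connected_components(m, connectivity)
  if (length(comps) == 0L) return(array(FALSE, dim(m)))
  comps[[1L]]
}

# fill cavities: background 6-connected components not reachable from the
# volume border are added to the mask (6-connected background complements the
# 26-connected foreground)
fill_holes3 <- function(m) {
  bg <- !m
  border <- array(FALSE, dim(m))
  d <- dim(m)
  border[c(1L, d[1]), , ] <- TRUE
  border[, c(1L, d[2]), ] <- TRUE
  border[, , c(1L, d[3])] <- TRUE
  outside <- flood_fill(border & bg, bg, connectivity = 6L)
  m | (bg & !outside)
}

# separable Gaussian convolution of a numeric array; per-axis sigma in voxels,
# zero padding at the borders, kernel truncated at 3 sigma
gaussian_filter3 <- function(a, sigma_vox) {
  out <- a
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    rad <- max(1L, as.integer(ceiling(3 * s)))
    w <- exp(-(seq.int(-rad, rad))^2 / (2 * s * s))
    w <- w / sum(w)
    acc <- array(0, dim(a))
    for (j in seq_along(w)) {
      k <- j - rad - 1L
      acc <- acc + w[j] * shift_axis(out, k, axis, 0)
    }
    out <- acc
  }
  out
}

# Otsu's threshold on a numeric vector: maximizes between-class variance over
# histogram bin edges; returns the optimal cut value
threshold_otsu <- function(x, nbins = 256L) {
  rng <- range(x)
  if (!(rng[2] > rng[1]))
    stop("cannot threshold a constant volume: no separable foreground",
         call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(
    pmin(nbins, pmax(1L, findInterval(x, breaks, rightmost.closed = TRUE))),
    nbins)
  p <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nbins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  # on a plateau of equal variance (clean two-level images) take its middle
  top <- which(sigma_b >= max(sigma_b) * (1 - 1e-12))
  breaks[top[ceiling(length(top) / 2)] + 1L]
}
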