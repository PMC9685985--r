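# Threshold, morphological cortex/spongiosa separation, overlays, smoothing
# and the full pipeline on phantoms with known truth.

test_that("global threshold keeps the bright region and drops small blobs", {
  v <- calibrated_volume(array(c(rep(100, 40), rep(900, 24)), c(4, 4, 4)))
  m <- global_threshold(v, "fixed", value = 500)
  expect_identical(mask_logical(m), v$voxels >= 500)
  expect_identical(mask_logical(global_threshold(v, "otsu")), v$voxels >= 500)
  expect_error(global_threshold(calibrated_volume(array(5, c(3, 3, 3))),
                                "otsu"), "constant")
  expect_error(global_threshold(v, "fixed", value = 1e6), "empty foreground")
  # disconnected holder blob smaller than the bone is removed
  g <- array(0, c(20, 20, 20))
  g[5:15, 5:15, 5:15] <- 900          # bone: 11^3 voxels
  g[1:3, 1:3, 1:3] <- 900             # holder: 27 voxels, air gap between
  mb <- global_threshold(calibrated_volume(g), "fixed", value = 500)
  expect_equal(sum(mb$voxels), 11^3)
  expect_equal(sum(mb$voxels[1:3, 1:3, 1:3]), 0)
})

test_that("cortex peeling matches the distance-to-surface oracle on a cube", {
  g <- array(FALSE, c(27, 27, 27)); g[4:24, 4:24, 4:24] <- TRUE
  bone <- binary_mask(g)
  sp <- split_cortex_spongiosa(bone, peel_radius = 2)
  # oracle: for a solid cube the Euclidean distance to the complement is the
  # minimum per-axis depth, so the 2-voxel shell is depth <= 2
  idx <- which(g, arr.ind = TRUE)
  depth <- pmin(idx[, 1] - 3, 25 - idx[, 1], idx[, 2] - 3, 25 - idx[, 2],
                idx[, 3] - 3, 25 - idx[, 3])
  oracle <- array(FALSE, c(27, 27, 27))
  oracle[idx[depth <= 2, , drop = FALSE]] <- TRUE
  expect_identical(mask_logical(sp$cortex), oracle)
  # partition identity holds exactly
  expect_true(all(sp$cortex$voxels + sp$interior$voxels == bone$voxels))
  expect_equal(sum(sp$cortex$voxels == 1L & sp$interior$voxels == 1L), 0)
})

test_that("over-peeling a thin wall is a segmentation error", {
  shell <- array(FALSE, c(22, 22, 22))
  shell[4:19, 4:19, 4:19] <- TRUE
  shell[7:16, 7:16, 7:16] <- FALSE    # 3-voxel wall around a 10-wide cavity
  expect_error(split_cortex_spongiosa(binary_mask(shell), peel_radius = 3),
               "reduce")
  expect_error(split_cortex_spongiosa(
    binary_mask(array(FALSE, c(5, 5, 5)))), "empty")
})

test_that("partition identity holds on random masks", {
  set.seed(11)
  for (rep in 1:3) {
    # union of two random solid boxes: irregular but always peelable
    g <- array(FALSE, c(20, 20, 20))
    for (b in 1:2) {
      lo <- sample(3:8, 3, replace = TRUE)
      hi <- lo + sample(5:9, 3, replace = TRUE)
      g[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    }
    bone <- binary_mask(g)
    sp <- split_cortex_spongiosa(bone, peel_radius = 1)
    expect_true(all(sp$cortex$voxels + sp$interior$voxels == bone$voxels))
    expect_equal(sum(sp$cortex$voxels == 1L & sp$interior$voxels == 1L), 0)
  }
})

test_that("manual overlays behave as set union / difference", {
  set.seed(3)
  a <- binary_mask(array(runif(6^3) > 0.5, c(6, 6, 6)))
  b <- binary_mask(array(runif(6^3) > 0.5, c(6, 6, 6)))
  empty <- binary_mask(array(FALSE, c(6, 6, 6)))
  expect_identical(apply_manual_overlay(a, empty, "add")$voxels, a$voxels)
  expect_identical(apply_manual_overlay(a, empty, "remove")$voxels, a$voxels)
  # inclusion-exclusion on the union
  un <- apply_manual_overlay(a, b, "add")
  expect_equal(sum(un$voxels),
               sum(a$voxels) + sum(b$voxels) -
                 sum(a$voxels == 1L & b$voxels == 1L))
  # adding then removing a disjoint overlay restores the original
  disj <- binary_mask(mask_logical(b) & !mask_logical(a))
  back <- apply_manual_overlay(apply_manual_overlay(a, disj, "add"),
                               disj, "remove")
  expect_identical(back$voxels, a$voxels)
  wrong <- binary_mask(array(FALSE, c(5, 5, 5)))
  expect_error(apply_manual_overlay(a, wrong), "grids")
})

test_that("mask smoothing is identity at sigma 0, mild on bulk, fatal to specks", {
  ball <- ball_mask(n = 31, r = 10)
  expect_identical(smooth_mask(ball, 0)$voxels, ball$voxels)
  sm <- smooth_mask(ball, 1)
  expect_lt(abs(sum(sm$voxels) - sum(ball$voxels)) / sum(ball$voxels), 0.05)
  # isolated voxel at sigma = 2 voxels: filtered peak is (discrete kernel
  # centre weight)^3 ~ 0.008 < 0.5, so the voxel disappears
  g <- array(0L, c(11, 11, 11)); g[6, 6, 6] <- 1L
  expect_equal(sum(smooth_mask(binary_mask(g), 2)$voxels), 0)
})

test_that("spongiosa derivation subtracts the cortex and fills the cavity", {
  # cortex == bone: nothing left
  bone <- box_mask()
  expect_equal(sum(derive_spongiosa(bone, bone)$voxels), 0)
  # hollow shell: spongiosa is the filled cavity (flood-fill oracle)
  shell <- array(FALSE, c(20, 20, 20))
  shell[4:16, 4:16, 4:16] <- TRUE
  shell[7:13, 7:13, 7:13] <- FALSE
  sb <- binary_mask(shell)
  sp <- derive_spongiosa(sb, sb)
  cavity <- array(FALSE, c(20, 20, 20)); cavity[7:13, 7:13, 7:13] <- TRUE
  expect_identical(mask_logical(sp), cavity)
  # solid 21^3 cube with 2-voxel shell: the core is 17^3
  g <- array(FALSE, c(27, 27, 27)); g[4:24, 4:24, 4:24] <- TRUE
  cube <- binary_mask(g)
  parts <- split_cortex_spongiosa(cube, peel_radius = 2)
  core <- derive_spongiosa(cube, parts$cortex)
  expect_equal(sum(core$voxels), 17^3)
  expect_error(derive_spongiosa(binary_mask(array(FALSE, c(4, 4, 4))),
                                binary_mask(array(FALSE, c(4, 4, 4)))),
               "empty")
})

test_that("the full pipeline recovers the phantom cortex (Dice >= 0.90) and
           partitions the bone exactly", {
  ph <- small_phantom(seed = 5)
  seg <- segment_femur(ph$volume, threshold = 80, peel_radius = 3, sigma = 1)
  expect_gte(dice_coefficient(seg$cortex, ph$truth$cortex), 0.90)
  expect_equal(dice_coefficient(seg$bone, ph$truth$bone), 1)
  # cortex and spongiosa are disjoint and cover the (hole-filled) bone
  expect_equal(sum(seg$cortex$voxels == 1L & seg$spongiosa$voxels == 1L), 0)
  expect_true(all((seg$cortex$voxels | seg$spongiosa$voxels) >= seg$bone$voxels))
  un <- seg$cortex$voxels + seg$spongiosa$voxels
  expect_true(all(un <= 1))
})

test_that("the overlay hook feeds corrections through the pipeline", {
  ph <- small_phantom(seed = 6)
  ov <- array(FALSE, dim(ph$volume$voxels)); ov[1:2, 1:2, 28] <- TRUE
  overlay <- binary_mask(ov, spacing = ph$volume$spacing)
  seg <- segment_femur(ph$volume, threshold = 80, peel_radius = 3, sigma = 0,
                       overlay = overlay, overlay_mode = "add")
  # overlay voxels lie outside the bone, so containment drops them again:
  # the pipeline never invents bone where the scan has none
  expect_equal(sum(seg$cortex$voxels[1:2, 1:2, 28]), 0)
})
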