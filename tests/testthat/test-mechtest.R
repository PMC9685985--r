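# Curve loading, ultimate force, max-R^2 stiffness fit, group summaries.

test_that("CSV curves load exactly and malformed input is diagnosed", {
  td <- withr::local_tempdir()
  p <- file.path(td, "c.csv")
  writeLines(c("displacement_mm,force_N", "0,0", "0.5,700", "1.0,1400"), p)
  cv <- load_curve(p)
  expect_identical(cv$u, c(0, 0.5, 1.0))
  expect_identical(cv$f, c(0, 700, 1400))
  writeLines("displacement_mm,force_N", p)
  expect_error(load_curve(p), "format error")
  rows <- sprintf("%g,%g", seq(0, 0.99, by = 0.01), seq(0, 99))
  rows[57] <- "0.56,broken"
  writeLines(c("displacement_mm,force_N", rows), p)
  expect_error(load_curve(p), "line 58")   # header is line 1
  # write/load round trip
  tc <- make_test_curve(noise_sd = 0.01, seed = 3)
  p2 <- file.path(td, "r.csv")
  write_curve(tc$curve, p2)
  cv2 <- load_curve(p2)
  expect_equal(cv2$u, tc$curve$u)
  expect_equal(cv2$f, tc$curve$f, tolerance = 1e-12)
})

test_that("curve validation catches malformed records", {
  expect_error(fd_curve(c(0, 1), c(0)), "same length")
  expect_error(fd_curve(c(0), c(1)), "at least 2")
  expect_error(fd_curve(c(0, 1, 0.5), c(0, 1, 2)), "nondecreasing")
})

test_that("ultimate force is the first global force maximum", {
  expect_equal(ultimate_force(fd_curve(c(0, 1, 2), c(0, 5, 3))),
               list(f_ult = 5, u_at_f_ult = 1, index = 2L))
  # plateau: first occurrence wins
  expect_equal(ultimate_force(fd_curve(c(0, 1, 2), c(0, 5, 5)))$u_at_f_ult, 1)
  tc <- make_test_curve(k = 1600, f_ult = 8677, toe_span = 0.5)
  expect_equal(ultimate_force(tc$curve)$f_ult, 8677)
})

test_that("stiffness of a perfect line is exact with R^2 = 1", {
  u <- seq(0, 5, by = 0.01)
  s <- spring_stiffness(fd_curve(u, 1000 * u))
  expect_equal(unname(coef(s)["k"]), 1000, tolerance = 1e-12)
  expect_equal(s$r2, 1, tolerance = 1e-12)
  # the winning window spans the whole post-toe range (largest-span tie-break)
  expect_equal(unname(s$window["end"] - s$window["start"]),
               unname(s$range["end"] - s$range["start"]))
})

test_that("a quadratic toe before a known linear branch is excluded", {
  # f = 200 u^2 up to 1 mm, then linear at 1500 N/mm to failure
  u <- seq(0, 4, by = 0.01)
  f <- ifelse(u <= 1, 200 * u^2, 200 + 1500 * (u - 1))
  s <- spring_stiffness(fd_curve(u, f))
  expect_equal(unname(coef(s)["k"]), 1500, tolerance = 0.02)
})

test_that("stiffness recovery tolerates 1% force noise (seeded replicates)", {
  errs <- vapply(1:30, function(seed) {
    tc <- make_test_curve(k = 1352, f_ult = 5197, toe_span = 0.4,
                          noise_sd = 0.01, seed = seed)
    s <- spring_stiffness(tc$curve)
    abs(s$k - 1352) / 1352
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("stiffness scales exactly with force and displacement units", {
  tc <- make_test_curve(k = 1600, f_ult = 8677, toe_span = 0.5)
  s <- spring_stiffness(tc$curve)
  s2 <- spring_stiffness(fd_curve(tc$curve$u, 2.5 * tc$curve$f))
  expect_equal(s2$k, 2.5 * s$k, tolerance = 1e-12)
  expect_equal(s2$f_ult, 2.5 * s$f_ult)
  s3 <- spring_stiffness(fd_curve(2 * tc$curve$u, tc$curve$f))
  expect_equal(s3$k, s$k / 2, tolerance = 1e-12)
})

test_that("stiffness is stable under 2x subsampling of a noiseless curve", {
  tc <- make_test_curve(k = 1104, f_ult = 3921, toe_span = 0.4)
  s <- spring_stiffness(tc$curve)
  idx <- seq(1, length(tc$curve$u), by = 2)
  s2 <- spring_stiffness(fd_curve(tc$curve$u[idx], tc$curve$f[idx]))
  expect_equal(s2$k, s$k, tolerance = 0.01)
})

test_that("degenerate analysis ranges raise analysis errors", {
  expect_error(spring_stiffness(fd_curve(c(0, 1, 2), c(0, 1, 2))),
               "at least 10 samples")
  # zero displacement span between toe and peak
  expect_error(spring_stiffness(fd_curve(rep(0, 13), seq_len(13) + 0)),
               "zero displacement span")
  # toe threshold reached only at the force maximum: nothing to fit
  expect_error(spring_stiffness(fd_curve(seq(0, 1.2, by = 0.1),
                                         c(rep(1, 12), 100))),
               "no samples between")
})

test_that("group summaries match hand arithmetic and handle n = 1", {
  fits <- lapply(1:3, function(i) {
    tc <- make_test_curve(k = 1000 + 300 * i, f_ult = 4000 + 500 * i,
                          toe_span = 0.3)
    spring_stiffness(tc$curve)
  })
  g <- summarize_group(fits)
  kk <- vapply(fits, `[[`, numeric(1), "k")
  fu <- vapply(fits, `[[`, numeric(1), "f_ult")
  expect_equal(unname(g$k["mean"]), mean(kk))
  expect_equal(unname(g$k["sd"]), sd(kk))           # n - 1 denominator
  expect_equal(unname(g$f_ult["mean"]), mean(fu))
  expect_equal(unname(g$f_ult["sd"]), sd(fu))
  expect_equal(g$n, 3L)
  # two identical curves: SD band identically zero
  g2 <- summarize_group(fits[c(1, 1)])
  expect_true(all(g2$band$sd == 0))
  expect_equal(length(g2$band$u), 200L)
  # single result: SD reported as 0 and flagged
  g1 <- summarize_group(fits[1])
  expect_equal(unname(g1$k["sd"]), 0)
  expect_true(g1$single)
  expect_error(summarize_group(list()), "at least one")
})
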