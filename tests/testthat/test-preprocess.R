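test_that("intensity normalization divides by the p99 of non-zero voxels", {
  v <- array(0, c(5, 5, 5))
  v[1:100] <- 5
  expect_equal(unique(as.numeric(normalize_intensity(v)[v != 0])), 1.0)
  # linear-interpolation percentile oracle on values 1..100
  v2 <- array(0, c(5, 5, 5))
  v2[1:100] <- sample(1:100)
  p99 <- as.numeric(quantile(1:100, 0.99, type = 7))
  expect_equal(max(normalize_intensity(v2)), 100 / p99)
  expect_true(all(normalize_intensity(v2)[v2 == 0] == 0))
  expect_error(normalize_intensity(array(0, c(4, 4, 4))), "all zero")
})

test_that("PD enhancement follows the elementwise formula", {
  io <- array(2, c(2, 1, 1)); ipd <- array(c(0, 4), c(2, 1, 1))
  expect_equal(as.numeric(enhance_with_pd(io, ipd)), c(8, 0))
  # constant PD image gives identically zero output
  expect_true(all(enhance_with_pd(io, array(3, c(2, 1, 1))) == 0))
  # linearity in I_orig and homogeneity in I_pd
  a <- array(runif(27), c(3, 3, 3)); pd <- array(runif(27), c(3, 3, 3))
  expect_equal(enhance_with_pd(2 * a, pd), 2 * enhance_with_pd(a, pd))
  expect_equal(enhance_with_pd(a, 3 * pd), 3 * enhance_with_pd(a, pd))
  expect_error(enhance_with_pd(a, array(1, c(2, 2, 2))), "grid")
})

test_that("cropping finds the tight bounding cuboid", {
  v <- array(0, c(10, 12, 9))
  v[4, 7, 2] <- 1
  cr <- crop_to_brain(v)
  expect_equal(dim(cr$volumes), c(1, 1, 1))
  expect_equal(cr$offset, c(3L, 6L, 1L))
  full <- array(1, c(5, 5, 5))
  expect_equal(crop_to_brain(full)$offset, c(0L, 0L, 0L))
  # ellipsoid: bounds equal min/max nonzero indices per axis
  ph <- small_phantom()
  m <- ph$truth$brain_mask
  cr2 <- crop_to_brain(m)
  idx <- which(m > 0, arr.ind = TRUE)
  expect_equal(dim(cr2$volumes), unname(apply(idx, 2, max) - apply(idx, 2, min) + 1L))
  expect_error(crop_to_brain(array(0, c(4, 4, 4))), "empty")
})

test_that("patch grid uses stride multiples with boundary clamping", {
  v <- array(1, c(80, 120, 100))
  ps <- extract_patches(v, c(80, 80, 80), 40)
  expect_equal(sort(unique(ps$origins[, 1])), 0L)
  expect_equal(sort(unique(ps$origins[, 2])), c(0L, 40L))
  expect_equal(sort(unique(ps$origins[, 3])), c(0L, 20L))
  # single patch when patch size equals the volume
  ps1 <- extract_patches(array(1, c(80, 80, 80)), c(80, 80, 80), 40)
  expect_equal(nrow(ps1$origins), 1L)
  expect_equal(ps1$origins[1, ], c(0L, 0L, 0L))
  # patches are copies of the source sub-volume
  v2 <- array(rnorm(64^3), c(64, 64, 64))
  ps2 <- extract_patches(v2, c(32, 32, 32), 32)
  o <- ps2$origins[4, ]
  expect_equal(as.numeric(ps2$patches[[4]]),
               as.numeric(v2[o[1] + 1:32, o[2] + 1:32, o[3] + 1:32]))
  expect_error(extract_patches(v2, c(32, 32, 32), 0), "stride")
})

test_that("patch selection keeps the least-background patches deterministically", {
  set.seed(21)
  v <- array(0, c(48, 48, 24))
  v[10:40, 5:45, 3:22] <- runif(31 * 41 * 20) + 0.5
  ps <- extract_patches(v, c(16, 16, 16), 16)
  keep <- select_training_patches(ps, 0.5)
  bg <- vapply(ps$patches, function(p) sum(p == 0), numeric(1))
  ord <- order(bg, ps$origins[, 1], ps$origins[, 2], ps$origins[, 3])
  expect_setequal(keep$kept, ord[seq_len(ceiling(0.5 * length(bg)))])
  # all-tie case: keeps ceil(N/2) first patches in lexicographic origin order
  vfull <- array(1, c(32, 32, 32))
  psf <- extract_patches(vfull, c(16, 16, 16), 16)
  kf <- select_training_patches(psf, 0.5)
  lex <- order(psf$origins[, 1], psf$origins[, 2], psf$origins[, 3])
  expect_equal(kf$kept, sort(lex[1:4]))
  expect_error(select_training_patches(ps, 0), "fraction")
})

test_that("augmentation is seeded, additive-then-multiplicative", {
  p <- array(runif(16^3 * 2), c(16, 16, 16, 2))
  expect_equal(augment_patch(p, 0, 0, seed = 1), p)
  a1 <- augment_patch(p, 0.05, 0.5, seed = 9)
  a2 <- augment_patch(p, 0.05, 0.5, seed = 9)
  expect_identical(a1, a2)
  # channel scaling only: each channel is an exact scalar multiple
  s <- augment_patch(p, 0, 0.5, seed = 5)
  r1 <- s[, , , 1] / p[, , , 1]
  expect_lt(diff(range(r1)), 1e-10)
  # noise only: empirical sd close to 0.05
  big <- array(0.5, c(48, 48, 48, 1))
  n <- augment_patch(big, 0.05, 0, seed = 2) - big
  expect_lt(abs(sd(n) - 0.05), 0.002)
})
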