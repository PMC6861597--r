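test_that("dice matches the confusion-matrix formula and conventions", {
  a <- array(0, c(4, 4, 4)); b <- array(0, c(4, 4, 4))
  a[1:4] <- 1
  expect_equal(dice(a, a), 1)
  b[5:8] <- 1
  expect_equal(dice(a, b), 0)
  # TP = 2, FP = 1, FN = 1 -> 4/6
  t <- array(0, c(4, 4, 4)); p <- array(0, c(4, 4, 4))
  t[c(1, 2, 3)] <- 1; p[c(2, 3, 4)] <- 1
  expect_equal(dice(t, p), 2 * 2 / (2 * 2 + 1 + 1))
  expect_equal(dice(t, p), dice(p, t))
  empty <- array(0, c(4, 4, 4))
  expect_equal(dice(empty, empty), 1)
  expect_equal(dice(t, empty), 0)
  expect_error(dice(t, array(0, c(3, 3, 3))), "grid")
})

test_that("avd is the relative volume error and ignores overlap", {
  t <- array(0, c(10, 10, 10)); t[1:100] <- 1
  p1 <- array(0, c(10, 10, 10)); p1[1:150] <- 1
  expect_equal(avd(t, p1), 0.5)
  p2 <- array(0, c(10, 10, 10)); p2[301:450] <- 1  # same volume, no overlap
  expect_equal(avd(t, p2), avd(t, p1))
  expect_equal(avd(t, t), 0)
  expect_error(avd(array(0, c(4, 4, 4)), t[1:4, 1:4, 1:4, drop = FALSE]), "empty")
})

test_that("hausdorff95 handles identities, known distances, and empties", {
  t <- array(0, c(16, 16, 16)); t[8, 8, 8] <- 1
  expect_equal(hausdorff95(t, t), 0)
  p <- array(0, c(16, 16, 16)); p[11, 8, 8] <- 1
  expect_equal(hausdorff95(t, p), 3)
  expect_equal(hausdorff95(t, p, spacing = c(2, 1, 1)), 6)
  expect_true(is.na(hausdorff95(t, array(0, c(16, 16, 16)))))
  # never exceeds the exact Hausdorff distance
  set.seed(31)
  for (i in 1:5) {
    a <- random_mask(); b <- random_mask()
    if (sum(a) == 0 || sum(b) == 0) next
    expect_lte(hausdorff95(a, b), hausdorff95(a, b, percentile = 1))
  }
})

test_that("lesion detection counts components by overlap", {
  t <- array(0, c(12, 12, 12))
  t[2:3, 2:3, 2] <- 1; t[8:9, 8:9, 8] <- 1  # two lesions
  p <- array(0, c(12, 12, 12))
  p[2, 2, 2] <- 1                            # covers the first only
  det <- lesion_detection(t, p)
  expect_equal(det$n_true, 2L)
  expect_equal(det$n_detected, 1L)
  expect_equal(det$n_false, 0L)
  expect_equal(det$l_tpr, 0.5)
  expect_equal(det$l_f1, 1)
  # perfect prediction
  det2 <- lesion_detection(t, t)
  expect_equal(det2$l_tpr, 1); expect_equal(det2$l_f1, 1)
  # a predicted component with no truth overlap is a false detection
  p[11, 11, 11] <- 1
  expect_equal(lesion_detection(t, p)$n_false, 1L)
})

test_that("fast metrics agree with brute-force oracles on random masks", {
  set.seed(7)
  for (i in 1:10) {
    a <- random_mask(c(12, 12, 12), 0.05)
    b <- random_mask(c(12, 12, 12), 0.05)
    if (sum(a) == 0 || sum(b) == 0) next
    expect_equal(dice(a, b), oracle_dice(a, b), tolerance = 1e-12)
    expect_equal(avd(a, b), oracle_avd(a, b), tolerance = 1e-12)
    expect_equal(hausdorff95(a, b), oracle_h95(a, b), tolerance = 1e-12)
    got <- lesion_detection(a, b)
    want <- oracle_lesions(a, b)
    expect_equal(got[c("n_true", "n_detected", "n_false")], want)
  }
})

test_that("component labelling matches the flood-fill oracle for both
           connectivities", {
  set.seed(17)
  m <- random_mask(c(10, 10, 10), 0.15)
  for (conn in c(6L, 26L)) {
    got <- label_components(m, conn)
    want <- oracle_label(m, conn)
    expect_equal(attr(got, "n"), attr(want, "n"))
    # same partition up to label names
    expect_equal(length(unique(paste(got, want)[m > 0])), attr(want, "n"))
  }
})

test_that("volume correlation returns r, slope, intercept", {
  v <- c(1, 4, 9, 16, 30)
  expect_equal(volume_correlation(v, v), list(r = 1, slope = 1, intercept = 0))
  vc <- volume_correlation(v, 2 * v + 5)
  expect_equal(vc$r, 1)
  expect_equal(vc$slope, 2)
  expect_equal(vc$intercept, 5)
  # textbook check on 4 hand pairs
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  vc2 <- volume_correlation(x, y)
  expect_equal(vc2$r, cov(x, y) / (sd(x) * sd(y)))
  expect_equal(vc2$slope, cov(x, y) / var(x))
  expect_error(volume_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("material matching recovers a known permutation", {
  ph <- small_phantom()
  S <- ph$truth$material_maps
  perm <- c(3L, 1L, 4L, 2L)
  Sp <- S[, , , order(perm)]  # predicted j holds truth material order(perm)[j]
  mt <- match_materials(Sp, S, ph$truth$brain_mask)
  expect_equal(mt$perm, perm)
  expect_gt(mt$mean_dice, 0.999)
})
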