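test_that("material maps partition the brain mask and respect the lesion load", {
  mm <- make_material_maps(c(48, 48, 48), n_materials = 4, lesion_fraction = 0.05,
                           seed = 1)
  tot <- apply(mm$maps, c(1, 2, 3), sum)
  expect_lt(max(abs(tot - mm$mask)), 1e-6)
  expect_true(all(mm$maps >= 0))
  expect_true(all(mm$maps[, , , 1][mm$mask == 0] == 0))
  # lesion volume close to the requested fraction of the WM region
  wm_region <- (mm$maps[, , , 3] + mm$maps[, , , 4]) > 0.5
  frac <- sum(mm$maps[, , , 4]) / sum(mm$mask * wm_region)
  expect_lt(abs(frac - 0.05), 0.02)
})

test_that("zero lesion fraction gives an identically zero lesion map", {
  mm <- make_material_maps(c(48, 48, 48), n_materials = 4, lesion_fraction = 0,
                           seed = 1)
  expect_identical(max(mm$maps[, , , 4]), 0)
  tot3 <- apply(mm$maps[, , , 1:3], c(1, 2, 3), sum)
  expect_lt(max(abs(tot3 - mm$mask)), 1e-6)
})

test_that("phantom generation is bit-reproducible and validates inputs", {
  a <- make_material_maps(c(16, 16, 16), 4, 0.05, seed = 3)
  b <- make_material_maps(c(16, 16, 16), 4, 0.05, seed = 3)
  expect_identical(a, b)
  expect_error(make_material_maps(c(8, 16, 16), 4), "shape")
  expect_error(make_material_maps(c(16, 16, 16), 1), "n_materials")
  expect_error(make_material_maps(c(16, 16, 16), 4, lesion_fraction = 1.2),
               "lesion_fraction")
})

test_that("bias fields are positive, mean-one over the mask, and seeded", {
  expect_equal(make_bias_field(c(16, 16, 16), amplitude = 0),
               array(1, c(16, 16, 16)))
  mask <- array(1, c(24, 24, 24))
  f <- make_bias_field(c(24, 24, 24), amplitude = 0.3, smoothness = 12,
                       seed = 7, mask = mask)
  expect_true(all(f > 0))
  expect_lt(abs(mean(f) - 1), 1e-6)
  f2 <- make_bias_field(c(24, 24, 24), amplitude = 0.3, smoothness = 12,
                        seed = 7, mask = mask)
  expect_identical(f, f2)
  expect_error(make_bias_field(c(16, 16, 16), amplitude = 1), "amplitude")
})

test_that("synthesized volumes equal the linear mixture when noise-free", {
  mm <- make_material_maps(c(24, 24, 24), 4, 0.05, seed = 5)
  w <- default_mixing_weights(4, 3)
  tr <- phantom_truth(mm$maps, w, NULL, mm$mask, noise_sd = 0, seed = 5)
  vols <- synthesize_volumes(tr)
  # dense per-voxel matrix multiply as oracle
  Smat <- matrix(mm$maps, prod(dim(mm$mask)), 4)
  expect_lt(max(abs(matrix(vols, ncol = 3) - Smat %*% w)), 1e-6)
  expect_true(all(vols[rep(mm$mask == 0, 3)] == 0))
})

test_that("identity-like mixing reproduces each material map exactly", {
  mm <- make_material_maps(c(16, 16, 16), 3, lesion_fraction = 0, seed = 2)
  w <- diag(3)
  rownames(w) <- phantom_material_names(3)
  tr <- phantom_truth(mm$maps, w, NULL, mm$mask, noise_sd = 0, seed = 2)
  vols <- synthesize_volumes(tr)
  for (i in 1:3) expect_lt(max(abs(vols[, , , i] - mm$maps[, , , i])), 1e-12)
})

test_that("additive noise has the expected half-normal deviation", {
  mm <- make_material_maps(c(32, 32, 32), 4, 0.05, seed = 9)
  w <- default_mixing_weights(4, 3)
  clean <- synthesize_volumes(phantom_truth(mm$maps, w, NULL, mm$mask, 0, seed = 9))
  noisy <- synthesize_volumes(phantom_truth(mm$maps, w, NULL, mm$mask, 0.05, seed = 9))
  # inside the mask and away from clipping, |noise| is half-normal with
  # mean 0.05 * sqrt(2/pi) ~ 0.0399
  sel <- rep(mm$mask > 0, 3) & (clean > 0.2)
  mad <- mean(abs(noisy[sel] - clean[sel]))
  expect_lt(abs(mad - 0.05 * sqrt(2 / pi)), 0.005)
})

test_that("default mixing rows are extreme rays (identifiable unmixing)", {
  # if any material row were a non-negative combination of the others,
  # exact alternative factorizations would exist and the ground-truth maps
  # would not be recoverable even in principle
  for (M in c(4L, 5L)) {
    w <- default_mixing_weights(M, 3L)
    for (i in seq_len(4L)) {  # CSF, GM, WM, WMH must all be extreme
      fit <- pracma::lsqnonneg(t(w[-i, , drop = FALSE]), w[i, ])
      resid <- sqrt(sum((t(w[-i, , drop = FALSE]) %*% fit$x - w[i, ])^2)) /
        sqrt(sum(w[i, ]^2))
      expect_gt(resid, 0.1)
    }
    expect_equal(qr(w)$rank, 3L)  # full rank in channel space
  }
  # lesion material brightest in the FLAIR-like channel
  w4 <- default_mixing_weights(4L, 3L)
  expect_equal(unname(which.max(w4[, "FLAIR"])), 4L)
})

test_that("phantom rejects negative mixing weights", {
  mm <- make_material_maps(c(16, 16, 16), 3, 0, seed = 1)
  w <- default_mixing_weights(3, 3); w[1, 1] <- -0.1
  expect_error(phantom_truth(mm$maps, w, NULL, mm$mask), "non-negative")
})

test_that("full phantom bundle is deterministic under its seed", {
  a <- segae_phantom(c(24, 24, 24), seed = 4, bias_amplitude = 0.3,
                     noise_sd = 0.05)
  b <- segae_phantom(c(24, 24, 24), seed = 4, bias_amplitude = 0.3,
                     noise_sd = 0.05)
  expect_identical(a$volumes, b$volumes)
  expect_true(all(a$truth$bias_fields[[1]] > 0))
})
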