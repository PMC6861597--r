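test_that("cosine proximity has the expected identities", {
  y <- rnorm(50)
  expect_equal(cosine_proximity(y, y), 1)
  expect_equal(cosine_proximity(c(1, 0), c(0, 1)), 0)
  yh <- rnorm(50)
  expect_equal(cosine_proximity(3.7 * y, yh), cosine_proximity(y, yh))
  # zero vectors are guarded by the norm floor
  expect_lt(abs(cosine_proximity(rep(0, 10), yh[1:10])), 1e-4)
})

test_that("the Laplacian filter annihilates constants and ramps, and matches
           the stencil on an impulse", {
  k <- laplace_kernel()
  expect_equal(sum(k), 0)
  const <- array(4, c(6, 6, 6))
  expect_true(all(abs(laplacian_filter(const)[2:5, 2:5, 2:5]) < 1e-12))
  ramp <- array(rep(1:6, 36), c(6, 6, 6))  # linear in x
  expect_true(all(abs(laplacian_filter(ramp)[2:5, 2:5, 2:5]) < 1e-12))
  imp <- array(0, c(5, 5, 5)); imp[3, 3, 3] <- 1
  resp <- laplacian_filter(imp)
  expect_equal(resp[2:4, 2:4, 2:4], k)
  expect_error(laplacian_filter(array(1, c(2, 5, 5))), "3 voxels")
})

test_that("reconstruction loss reaches -2 at perfect reconstruction and is
           scale invariant per channel", {
  set.seed(1)
  Y <- array(runif(8^3 * 2), c(8, 8, 8, 2))
  expect_equal(reconstruction_loss(Y, Y), -2)
  sc <- array(rep(c(2.5, 0.3), each = 8^3), c(8, 8, 8, 2))
  expect_lt(abs(reconstruction_loss(Y, Y * sc) - (-2)), 1e-6)
  # low-frequency corruption hurts the intensity term more than the
  # Laplacian term (the rationale for including the Laplacian)
  dim3 <- c(8, 8, 8)
  co <- expand.grid(x = 1:8, y = 1:8, z = 1:8)
  smooth_field <- array(0.5 * sin(co$x / 4), dim3)
  Y1 <- Y[, , , 1]
  Yc <- Y1 + smooth_field
  f_int <- cosine_proximity(Y1, Yc)
  f_lap <- cosine_proximity(laplacian_filter(Y1), laplacian_filter(Yc))
  expect_gt(f_lap, f_int)
})

test_that("activity regularizer matches closed forms for disjoint and
           identical maps", {
  S <- array(0, c(4, 4, 4, 3))
  S[1:20 + 0 * 64] <- 1   # disjoint supports per material
  S[(1:20) + 64 + 21] <- 1
  S[(1:20) + 128 + 42] <- 1
  alpha <- 0.0075
  expect_equal(activity_regularizer(S, alpha), alpha)
  one <- array(abs(rnorm(64)), c(4, 4, 4))
  Sid <- array(rep(one, 3), c(4, 4, 4, 3))
  expect_equal(activity_regularizer(Sid, alpha), alpha * 3)
  expect_equal(activity_regularizer(S, 0), 0)
  # bounds for non-negative maps
  set.seed(2)
  Sr <- array(abs(rnorm(4^3 * 3)), c(4, 4, 4, 3))
  r <- activity_regularizer(Sr, alpha)
  expect_gte(r, 0); expect_lte(r, alpha * 3 + 1e-12)
})

test_that("overlap increases the pairwise cosine monotonically", {
  vals <- sapply(0:6, function(shift) {
    a <- array(0, c(20, 5, 5)); b <- array(0, c(20, 5, 5))
    a[4:9, 2:4, 2:4] <- 1
    b[(4:9) + 6 - shift, 2:4, 2:4] <- 1  # shift 0 = disjoint, 6 = identical
    cosine_proximity(a, b)
  })
  expect_true(all(diff(vals) > 0))
})

test_that("total loss is additive and inherits scale invariance", {
  set.seed(3)
  Y <- array(runif(8^3 * 2) + 0.1, c(8, 8, 8, 2))
  S <- array(0, c(8, 8, 8, 3))
  S[, , , 1][1:100] <- 1; S[, , , 2][101:200] <- 1; S[, , , 3][201:300] <- 1
  expect_equal(total_loss(Y, Y, S, alpha = 0.0075), -2 + 0.0075)
  expect_equal(total_loss(Y, Y, S, alpha = 0), reconstruction_loss(Y, Y))
  Yh <- array(runif(8^3 * 2), c(8, 8, 8, 2))
  sc <- array(rep(c(1.7, 4.0), each = 8^3), c(8, 8, 8, 2))
  expect_lt(abs(total_loss(Y, Yh * sc, S, 0.0075) - total_loss(Y, Yh, S, 0.0075)),
            1e-6)
})

test_that("analytic loss gradients match central finite differences", {
  set.seed(4)
  d <- c(5, 5, 5)
  Y <- array(rnorm(prod(d) * 2), c(d, 2))
  Yh <- array(rnorm(prod(d) * 2), c(d, 2))
  S <- array(abs(rnorm(prod(d) * 3)), c(d, 3))
  g <- reconstruction_loss_grad(Y, Yh)
  idx <- sample(length(Yh), 12)
  num <- numeric_grad(function(x) reconstruction_loss(Y, x), Yh, idx)
  expect_lt(max(abs(num - g[idx]) / pmax(abs(num), abs(g[idx]), 1e-8)), 1e-4)
  ga <- activity_regularizer_grad(S, 0.02)
  idx <- sample(length(S), 12)
  num <- numeric_grad(function(x) activity_regularizer(x, 0.02), S, idx)
  expect_lt(max(abs(num - ga[idx]) / pmax(abs(num), abs(ga[idx]), 1e-8)), 1e-4)
})
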