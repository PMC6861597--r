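make_tiny_setup <- function(seed = 1L) {
  ph <- small_phantom()
  vols <- ph$volumes
  for (ch in 1:3) vols[, , , ch] <- normalize_intensity(vols[, , , ch])
  ps <- extract_patches(vols, c(24, 24, 24), 24)
  cfg <- network_config(3, 4, base_filters = 4)
  list(net = build_network(cfg, seed = seed), ps = ps)
}

test_that("a zero learning rate leaves the weights unchanged", {
  s <- make_tiny_setup()
  fit <- train_segae(s$net, s$ps, s$ps,
                     train_config(epochs = 1, learning_rate = 0, seed = 1))
  expect_identical(fit$network$params, s$net$params)
})

test_that("mixing weights stay non-negative through training", {
  s <- make_tiny_setup()
  fit <- train_segae(s$net, s$ps, s$ps,
                     train_config(epochs = 3, seed = 2))
  expect_gte(min(fit$network$params[["mix.W"]]), 0)
})

test_that("training is bit-reproducible under a fixed seed", {
  s <- make_tiny_setup()
  cfg <- train_config(epochs = 2, seed = 5)
  f1 <- train_segae(s$net, s$ps, s$ps, cfg)
  f2 <- train_segae(s$net, s$ps, s$ps, cfg)
  expect_identical(f1$network$params, f2$network$params)
  expect_identical(f1$log, f2$log)
})

test_that("the training loss decreases on the small phantom", {
  s <- make_tiny_setup()
  fit <- train_segae(s$net, s$ps, s$ps,
                     train_config(epochs = 12, seed = 3))
  expect_lt(median(tail(fit$log$total, 4)), median(head(fit$log$total, 4)))
  # the log carries all four terms
  expect_named(fit$log, c("epoch", "recon", "laplace", "regularizer", "total"))
  expect_true(all(is.finite(fit$log$total)))
})

test_that("misaligned patch/target sets are rejected", {
  s <- make_tiny_setup()
  tg <- s$ps
  tg$origins <- tg$origins + 1L
  expect_error(train_segae(s$net, s$ps, tg, train_config(epochs = 1)),
               "misaligned")
})

test_that("whole-network gradients match finite differences on a tiny case", {
  set.seed(8)
  cfg <- network_config(2, 3, base_filters = 4, n_scales = 2, n_blocks = 1)
  net <- build_network(cfg, seed = 3)
  d <- c(8, 8, 8)
  x <- array(abs(rnorm(prod(d) * 2)), c(d, 2)); x[1:2, , , ] <- 0
  y <- array(abs(rnorm(prod(d) * 2)), c(d, 2))
  mask <- array(as.numeric(apply(x != 0, c(1, 2, 3), any)), d)
  alpha <- 0.0075
  loss_of <- function(net) {
    fw <- segae_forward(net, x, mask = mask, training = TRUE)
    total_loss(y, fw$reconstruction, fw$S, alpha = alpha)
  }
  fw <- segae_forward(net, x, mask = mask, training = TRUE, want_cache = TRUE)
  G <- reconstruction_loss_grad(y, fw$reconstruction)
  dS <- activity_regularizer_grad(fw$S, alpha)
  grads <- segae:::segae_backward(net, fw, matrix(G, ncol = 2),
                                  matrix(dS, ncol = 3))
  h <- 1e-5
  # biases of the first layer sit exactly on the LReLU kink for zero
  # background input and are excluded (one-sided derivative)
  for (nm in c("enc1_b1.W", "down1.W", "enc2_b1.gamma", "up1.W",
               "dec1_b1.W", "dec1_b1.beta", "head.W", "mix.W")) {
    p <- net$params[[nm]]
    idx <- sample(length(p), min(3, length(p)))
    for (i in idx) {
      a <- net; a$params[[nm]][i] <- p[i] + h
      b <- net; b$params[[nm]][i] <- p[i] - h
      num <- (loss_of(a) - loss_of(b)) / (2 * h)
      ana <- grads[[nm]][i]
      expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-8), 1e-4)
    }
  }
})
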