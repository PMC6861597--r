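# The constrained convolutional autoencoder: a three-scale fully
# convolutional encoder-decoder emitting M Softmax material maps, masked
# by the patch brainmask, followed by a non-negative zero-bias 1x1x1
# mixing layer reconstructing the C input channels.

#' Network configuration
#'
#' @param in_channels number of input MRI channels C.
#' @param n_materials number of Softmax materials M (>= 2).
#' @param base_filters filters at the top scale (doubled per scale;
#'   default 16).
#' @param n_scales number of resolution scales (>= 2; default 3). Input
#'   patch dimensions must be divisible by `2^(n_scales - 1)`.
#' @param n_blocks convolution blocks per scale (default 2).
#' @param lrelu_slope negative-part slope of the leaky ReLU (default 0.1).
#' @param kernel_size convolution kernel edge (default 3).
#' @param bn_momentum running-average momentum of the batch-norm statistics.
#' @param bn_eps batch-norm variance floor.
#' @return object of class `network_config`.
#' @export
network_config <- function(in_channels, n_materials, base_filters = 16L,
                           n_scales = 3L, n_blocks = 2L, lrelu_slope = 0.1,
                           kernel_size = 3L, bn_momentum = 0.9,
                           bn_eps = 1e-3) {
  stopifnot(in_channels >= 1L, n_materials >= 2L, base_filters >= 4L,
            n_scales >= 2L, n_blocks >= 1L)
  structure(list(in_channels = as.integer(in_channels),
                 n_materials = as.integer(n_materials),
                 base_filters = as.integer(base_filters),
                 n_scales = as.integer(n_scales),
                 n_blocks = as.integer(n_blocks),
                 lrelu_slope = lrelu_slope,
                 kernel_size = as.integer(kernel_size),
                 bn_momentum = bn_momentum, bn_eps = bn_eps),
            class = "network_config")
}

# Glorot (Xavier) uniform initialization for a conv weight matrix of
# shape (k^3 * Cin) x Cout; draws from the current RNG stream.
glorot_conv <- function(k3, cin, cout) {
  fan_in <- k3 * cin; fan_out <- k3 * cout
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(k3 * cin * cout, -lim, lim), k3 * cin, cout)
}

# Layer table for the architecture: name, kernel, stride, pad, cin, cout,
# and whether the block carries LReLU + batch norm.
network_layers <- function(cfg) {
  S <- cfg$n_scales; nb <- cfg$n_blocks; F1 <- cfg$base_filters
  k <- cfg$kernel_size
  filt <- F1 * 2^(seq_len(S) - 1L)
  out <- list()
  add <- function(name, k, stride, pad, cin, cout, act = TRUE, bn = TRUE)
    out[[length(out) + 1L]] <<- list(name = name, k = k, stride = stride,
                                     pad = pad, cin = cin, cout = cout,
                                     act = act, bn = bn)
  cin <- cfg$in_channels
  for (s in seq_len(S)) {
    for (j in seq_len(nb)) {
      add(sprintf("enc%d_b%d", s, j), k, 1L, (k - 1L) %/% 2L, cin, filt[s])
      cin <- filt[s]
    }
    if (s < S) {
      add(sprintf("down%d", s), 2L, 2L, 0L, filt[s], filt[s + 1L])
      cin <- filt[s + 1L]
    }
  }
  for (s in rev(seq_len(S - 1L))) {
    add(sprintf("up%d", s), k, 1L, (k - 1L) %/% 2L, filt[s + 1L], filt[s])
    cin <- 2L * filt[s]  # concat with the encoder skip
    for (j in seq_len(nb)) {
      add(sprintf("dec%d_b%d", s, j), k, 1L, (k - 1L) %/% 2L, cin, filt[s])
      cin <- filt[s]
    }
  }
  add("head", k, 1L, (k - 1L) %/% 2L, filt[1L], cfg$n_materials,
      act = FALSE, bn = FALSE)
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Build the autoencoder
#'
#' Each block is a 3D convolution followed by a leaky ReLU and a batch
#' normalization layer (in that order). Downsampling uses 2x2x2 strided
#' convolutions; upsampling is 2x2x2 nearest-neighbour followed by a 3^3
#' convolution; encoder activations are concatenated into the decoder at
#' matching resolution (skip connections). The head convolution maps to M
#' channels and feeds the Softmax; the mixing layer is a 1x1x1 M -> C
#' convolution with non-negative weights and a fixed zero bias. All
#' convolution weights are Glorot-uniform, biases zero; building twice
#' with the same seed gives identical weights.
#'
#' @param config a [network_config].
#' @param seed integer seed for the initialization.
#' @return object of class `segae_network` with elements `config`,
#'   `params` (flat named list), `state` (batch-norm running statistics)
#'   and `layers` (architecture table).
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  layers <- network_layers(config)
  params <- list(); state <- list()
  with_seed(seed, {
    for (ly in layers) {
      k3 <- ly$k^3
      params[[paste0(ly$name, ".W")]] <- glorot_conv(k3, ly$cin, ly$cout)
      params[[paste0(ly$name, ".b")]] <- numeric(ly$cout)
      if (ly$bn) {
        params[[paste0(ly$name, ".gamma")]] <- rep(1, ly$cout)
        params[[paste0(ly$name, ".beta")]] <- numeric(ly$cout)
        state[[paste0(ly$name, ".rmean")]] <- numeric(ly$cout)
        state[[paste0(ly$name, ".rvar")]] <- rep(1, ly$cout)
      }
    }
    # mixing layer: 1x1x1, M -> C, non-negative, zero bias (not trainable).
    # Glorot draw clipped at zero: the non-negativity projection applied
    # from the first update onward also zeroes negative initial entries,
    # and the resulting sparse rows break the symmetry between materials.
    # A draw that silences an entire channel column or material row would
    # start the factorization with a dead channel/material (a trap the
    # projection cannot escape cleanly), so such draws are rejected and
    # redrawn from the same seeded stream.
    lim <- sqrt(6 / (config$n_materials + config$in_channels))
    repeat {
      w <- matrix(pmax(stats::runif(config$n_materials * config$in_channels,
                                    -lim, lim), 0),
                  config$n_materials, config$in_channels)
      if (all(colSums(w) > 0) && all(rowSums(w) > 0)) break
    }
    params[["mix.W"]] <- w
  })
  structure(list(config = config, params = params, state = state,
                 layers = layers, trained = FALSE),
            class = "segae_network")
}

#' Clip mixing weights at zero
#'
#' Projection step enforcing the non-negativity constraint of the mixing
#' layer after every optimizer update; the bias is fixed at zero and never
#' trained. Idempotent.
#'
#' @param w numeric matrix (or a `segae_network`, whose mixing weights are
#'   projected in place).
#' @return object of the same type with all mixing entries >= 0.
#' @export
project_nonnegative <- function(w) {
  if (inherits(w, "segae_network")) {
    w$params[["mix.W"]] <- pmax(w$params[["mix.W"]], 0)
    return(w)
  }
  pmax(w, 0)
}

lrelu <- function(x, slope) pmax(x, 0) + slope * pmin(x, 0)

.conv_mat <- function(x, W, b, k, stride, pad, slope = -1) {
  d <- dim(x)
  y <- cpp_conv3d_fw(as.numeric(x), as.integer(d), W, b,
                     as.integer(k), as.integer(stride), as.integer(pad),
                     slope)
  od <- (d[1:3] + 2L * pad - k) %/% stride + 1L
  list(y = y, outdim = as.integer(od))
}

# One conv [+ LReLU + BN] block. The LReLU is fused into the convolution
# kernel; batch norm runs in C++. Returns output array, cache for
# backward, and (in training) the batch statistics for running averages.
block_forward <- function(x, ly, net, training, want_cache) {
  cfg <- net$config
  W <- net$params[[paste0(ly$name, ".W")]]
  b <- net$params[[paste0(ly$name, ".b")]]
  cv <- .conv_mat(x, W, b, ly$k, ly$stride, ly$pad,
                  slope = if (ly$act) cfg$lrelu_slope else -1)
  out <- cv$y
  cache <- if (want_cache)
    list(x = as.numeric(x), indim = dim(x), outdim = cv$outdim) else NULL
  if (want_cache && ly$act && !ly$bn) cache$act <- out
  stats_upd <- NULL
  if (ly$bn) {
    bn <- cpp_bn_fw(out, net$params[[paste0(ly$name, ".gamma")]],
                    net$params[[paste0(ly$name, ".beta")]], cfg$bn_eps,
                    training,
                    net$state[[paste0(ly$name, ".rmean")]],
                    net$state[[paste0(ly$name, ".rvar")]])
    if (training) stats_upd <- list(mu = bn$mu, vv = bn$var)
    if (want_cache) { cache$act <- out; cache$mu <- bn$mu; cache$var <- bn$var }
    out <- bn$out
  }
  list(out = array(out, c(cv$outdim, ly$cout)), cache = cache,
       stats = stats_upd)
}

block_backward <- function(dout, ly, net, cache) {
  cfg <- net$config
  dmat <- matrix(dout, prod(cache$outdim), ly$cout)
  grads <- list()
  if (ly$bn) {
    bw <- cpp_bn_bw(dmat, cache$act, cache$mu, cache$var,
                    net$params[[paste0(ly$name, ".gamma")]], cfg$bn_eps,
                    if (ly$act) cfg$lrelu_slope else -1)
    grads[[paste0(ly$name, ".gamma")]] <- bw$dgamma
    grads[[paste0(ly$name, ".beta")]] <- bw$dbeta
    dmat <- bw$da
  } else if (ly$act) {
    slope <- cfg$lrelu_slope
    dmat <- dmat * (slope + (1 - slope) * (cache$act > 0))
  }
  W <- net$params[[paste0(ly$name, ".W")]]
  bw <- cpp_conv3d_bw(cache$x, as.integer(cache$indim), dmat, W,
                      as.integer(ly$k), as.integer(ly$stride),
                      as.integer(ly$pad))
  grads[[paste0(ly$name, ".W")]] <- bw$dW
  grads[[paste0(ly$name, ".b")]] <- colSums(dmat)
  list(dx = array(bw$dx, cache$indim), grads = grads)
}

upsample2 <- function(x) {
  d <- dim(x)
  array(cpp_upsample2(as.numeric(x), as.integer(d)), c(2L * d[1:3], d[4]))
}

downsum2 <- function(dx) {  # adjoint of nearest-neighbour 2x upsampling
  d <- dim(dx)
  array(cpp_downsum2(as.numeric(dx), as.integer(d)), c(d[1:3] %/% 2L, d[4]))
}

concat4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1:3], da[4] + db[4]))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass through the autoencoder
#'
#' Computes the brainmask (1 where any input channel is non-zero, unless a
#' mask is supplied), the masked Softmax material maps S, and the linear
#' reconstruction `Yhat_c = sum_i w[i,c] S_i`. Outside the mask both S and
#' the reconstruction are exactly 0, and inside it the maps sum to 1.
#'
#' @param network a built `segae_network` (see [build_network()]).
#' @param patch 4D array (X, Y, Z, C); spatial dimensions must be divisible
#'   by `2^(n_scales - 1)`.
#' @param mask optional 3D binary array overriding the brainmask derived
#'   from the patch (used in training, where the input is noise-augmented
#'   but the mask must come from the clean patch).
#' @param training use per-batch batch-norm statistics (TRUE) or running
#'   averages (FALSE).
#' @param want_cache keep intermediate activations for backpropagation
#'   (internal use).
#' @return list with `S` (X, Y, Z, M), `reconstruction` (X, Y, Z, C),
#'   `mask`, and optionally `cache`/`bn_stats`.
#' @export
segae_forward <- function(network, patch, mask = NULL, training = FALSE,
                          want_cache = FALSE) {
  stopifnot(inherits(network, "segae_network"))
  if (!all(is.finite(patch))) stop("non-finite values in input patch", call. = FALSE)
  cfg <- network$config
  d <- dim(patch)
  if (length(d) != 4L || d[4] != cfg$in_channels)
    stop(sprintf("patch must be X x Y x Z x %d", cfg$in_channels), call. = FALSE)
  div <- 2L^(cfg$n_scales - 1L)
  if (any(d[1:3] %% div != 0L))
    stop(sprintf("patch dimensions must be divisible by %d for %d scales",
                 div, cfg$n_scales), call. = FALSE)
  if (is.null(mask)) mask <- brainmask_from(patch)
  S <- cfg$n_scales; nb <- cfg$n_blocks
  caches <- list(); stats <- list()
  run <- function(x, name) {
    r <- block_forward(x, network$layers[[name]], network, training, want_cache)
    if (want_cache) caches[[name]] <<- r$cache
    if (!is.null(r$stats)) stats[[name]] <<- r$stats
    r$out
  }
  cur <- patch
  skips <- vector("list", S)
  for (s in seq_len(S)) {
    for (j in seq_len(nb)) cur <- run(cur, sprintf("enc%d_b%d", s, j))
    skips[[s]] <- cur
    if (s < S) cur <- run(cur, sprintf("down%d", s))
  }
  for (s in rev(seq_len(S - 1L))) {
    cur <- upsample2(cur)
    cur <- run(cur, sprintf("up%d", s))
    cur <- concat4(cur, skips[[s]])
    for (j in seq_len(nb)) cur <- run(cur, sprintf("dec%d_b%d", s, j))
  }
  z <- run(cur, "head")
  zm <- as_mat(z)
  P <- softmax_rows(zm)
  maskv <- as.numeric(mask)
  Smat <- P * maskv
  Yhat <- Smat %*% network$params[["mix.W"]]
  out <- list(S = array(Smat, c(d[1:3], cfg$n_materials)),
              reconstruction = array(Yhat, d), mask = mask)
  if (want_cache) {
    caches$.softmax <- list(P = P, maskv = maskv, Smat = Smat, dim3 = d[1:3])
    out$cache <- caches
  }
  if (training) out$bn_stats <- stats
  out
}

# Backward pass: given dL/dYhat (N x C) and the direct dL/dS (N x M, from
# the regularizer), accumulate gradients for every parameter.
segae_backward <- function(network, fwd, dYhat, dS_direct = NULL) {
  cfg <- network$config
  caches <- fwd$cache
  sm <- caches$.softmax
  dSmat <- dYhat %*% t(network$params[["mix.W"]])
  if (!is.null(dS_direct)) dSmat <- dSmat + dS_direct
  grads <- list(mix.W = crossprod(sm$Smat, dYhat))
  dP <- dSmat * sm$maskv
  dz <- sm$P * (dP - rowSums(dP * sm$P))
  S <- cfg$n_scales; nb <- cfg$n_blocks
  back <- function(dout, name) {
    r <- block_backward(dout, network$layers[[name]], network, caches[[name]])
    for (nm in names(r$grads)) grads[[nm]] <<- r$grads[[nm]]
    r$dx
  }
  cur <- back(array(dz, c(sm$dim3, cfg$n_materials)), "head")
  dskips <- vector("list", S)
  for (s in seq_len(S - 1L)) {
    for (j in rev(seq_len(nb))) cur <- back(cur, sprintf("dec%d_b%d", s, j))
    # split the concat: first half came from the up conv, second from skip
    half <- dim(cur)[4] %/% 2L
    dup <- cur[, , , seq_len(half), drop = FALSE]
    dskips[[s]] <- cur[, , , half + seq_len(half), drop = FALSE]
    cur <- downsum2(back(dup, sprintf("up%d", s)))
  }
  # encoder sweep (from the bottleneck up), adding skip gradients
  for (s in rev(seq_len(S))) {
    if (s < S) cur <- back(cur, sprintf("down%d", s))
    if (!is.null(dskips[[s]])) cur <- cur + dskips[[s]]
    for (j in rev(seq_len(nb))) cur <- back(cur, sprintf("enc%d_b%d", s, j))
  }
  grads
}
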