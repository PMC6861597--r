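# Scale-invariant reconstruction loss (cosine proximity on intensities and
# on their discrete Laplacian) and the anti-overlap activity regularizer,
# with analytic gradients.

.norm_floor <- function(v, eps) max(sqrt(sum(v * v)), eps)

#' Cosine proximity between two vectors
#'
#' `f(y, yhat) = (y . yhat) / (max(||y||, eps) * max(||yhat||, eps))`.
#' Scale invariant: `f(a*y, yhat) = f(y, yhat)` for any `a > 0`. The norm
#' floor `eps` guards all-zero vectors (empty materials, masked patches),
#' for which the value is ~0.
#'
#' @param y,y_hat numeric vectors (or arrays) of equal length.
#' @param eps norm floor (default 1e-8).
#' @return scalar in `[-1, 1]` for non-degenerate inputs.
#' @export
cosine_proximity <- function(y, y_hat, eps = 1e-8) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  stopifnot(length(y) == length(y_hat))
  sum(y * y_hat) / (.norm_floor(y, eps) * .norm_floor(y_hat, eps))
}

# d f(y, y_hat) / d y_hat (y treated as constant).
cosine_proximity_grad <- function(y, y_hat, eps = 1e-8) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  ny <- sqrt(sum(y * y)); nyh <- sqrt(sum(y_hat * y_hat))
  a <- max(ny, eps); b <- max(nyh, eps)
  f <- sum(y * y_hat) / (a * b)
  g <- y / (a * b)
  if (nyh > eps) g <- g - f * y_hat / (nyh * nyh)
  g
}

#' The fixed 3x3x3 discrete Laplace kernel
#'
#' Slices 1 and 3 have a single 1 at the centre; slice 2 is the 2D
#' 5-point stencil with -6 at the centre. Entries sum to 0 and the kernel
#' is symmetric under axis permutation and reflection.
#'
#' @return 3x3x3 numeric array.
#' @export
laplace_kernel <- function() {
  k <- array(0, c(3, 3, 3))
  k[2, 2, 1] <- 1
  k[2, 2, 3] <- 1
  k[, , 2] <- matrix(c(0, 1, 0, 1, -6, 1, 0, 1, 0), 3, 3)
  k
}

#' Apply the 3D discrete Laplace operator
#'
#' Convolution with [laplace_kernel()] using zero padding, so interior
#' voxels get the 6-neighbour Laplacian (sum of neighbours minus 6x the
#' centre). Annihilates constant and affine volumes at interior voxels.
#' Self-adjoint under zero padding, so it is its own gradient operator.
#'
#' @param volume 3D array with at least 3 voxels per axis.
#' @return 3D array of the same size.
#' @export
laplacian_filter <- function(volume) {
  check_volume3d(volume)
  d <- dim(volume)
  if (any(d < 3L)) stop("`volume` must have >= 3 voxels per axis", call. = FALSE)
  p <- array(0, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- volume
  i <- 2:(d[1] + 1); j <- 2:(d[2] + 1); k <- 2:(d[3] + 1)
  p[i - 1, j, k] + p[i + 1, j, k] + p[i, j - 1, k] + p[i, j + 1, k] +
    p[i, j, k - 1] + p[i, j, k + 1] - 6 * volume
}

.chans <- function(Y) {
  d <- dim(Y)
  if (is.null(d) || length(d) == 3L) list(dim3 = d %||% length(Y), C = 1L)
  else list(dim3 = d[1:3], C = d[4])
}
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scale-invariant reconstruction loss
#'
#' `-(1/C) * sum_c [ f(Y_c, Yhat_c) + f(K*Y_c, K*Yhat_c) ]` where `f` is
#' the cosine proximity and `K` the discrete Laplace operator. The
#' Laplacian term improves robustness to slowly varying intensity
#' inhomogeneity. Minimum -2, attained when every channel and its
#' Laplacian are positively collinear with the target; invariant to
#' positive per-channel rescaling of `Y_hat`.
#'
#' @param Y,Y_hat 4D arrays (X, Y, Z, C) (3D treated as C = 1) of equal shape.
#' @param include_laplacian include the Laplacian term (default TRUE).
#' @param eps norm floor for the cosine.
#' @return scalar in `[-2, 2]` (`[-1, 1]` without the Laplacian term).
#' @export
reconstruction_loss <- function(Y, Y_hat, include_laplacian = TRUE, eps = 1e-8) {
  check_same_grid(Y, Y_hat, "`Y` and `Y_hat`")
  ch <- .chans(Y)
  Ym <- as_mat(array(Y, c(ch$dim3, ch$C))); Yh <- as_mat(array(Y_hat, c(ch$dim3, ch$C)))
  acc <- 0
  for (cc in seq_len(ch$C)) {
    acc <- acc + cosine_proximity(Ym[, cc], Yh[, cc], eps)
    if (include_laplacian) {
      ky <- laplacian_filter(array(Ym[, cc], ch$dim3))
      kh <- laplacian_filter(array(Yh[, cc], ch$dim3))
      acc <- acc + cosine_proximity(ky, kh, eps)
    }
  }
  -acc / ch$C
}

#' Gradient of the reconstruction loss with respect to `Y_hat`
#'
#' @inheritParams reconstruction_loss
#' @return array shaped like `Y_hat`.
#' @export
reconstruction_loss_grad <- function(Y, Y_hat, include_laplacian = TRUE,
                                     eps = 1e-8) {
  check_same_grid(Y, Y_hat, "`Y` and `Y_hat`")
  ch <- .chans(Y)
  Ym <- as_mat(array(Y, c(ch$dim3, ch$C))); Yh <- as_mat(array(Y_hat, c(ch$dim3, ch$C)))
  G <- matrix(0, nrow(Ym), ch$C)
  for (cc in seq_len(ch$C)) {
    g <- cosine_proximity_grad(Ym[, cc], Yh[, cc], eps)
    if (include_laplacian) {
      ky <- laplacian_filter(array(Ym[, cc], ch$dim3))
      kh <- laplacian_filter(array(Yh[, cc], ch$dim3))
      gl <- cosine_proximity_grad(ky, kh, eps)
      # adjoint of zero-padded convolution with the symmetric kernel
      g <- g + as.numeric(laplacian_filter(array(gl, ch$dim3)))
    }
    G[, cc] <- g
  }
  array(-G / ch$C, dim(Y_hat))
}

#' Anti-overlap activity regularizer
#'
#' `(alpha / M) * sum_i sum_j f(S_i, S_j)` over all ordered material pairs,
#' diagonal included as written (each diagonal term contributes a constant
#' 1 with zero gradient). Equals `alpha` for pairwise-disjoint maps and
#' `alpha * M` when all maps are identical and non-zero.
#'
#' @param S 4D array (X, Y, Z, M) of soft material maps, or an N x M matrix.
#' @param alpha regularization coefficient (>= 0). The reference settings
#'   are 0.0075 (four-sequence cohort) and 0.02 (two-sequence cohort).
#' @param eps norm floor for the cosine.
#' @return non-negative scalar (for non-negative maps).
#' @export
activity_regularizer <- function(S, alpha, eps = 1e-8) {
  stopifnot(alpha >= 0)
  Sm <- if (is.matrix(S)) S else as_mat(S)
  M <- ncol(Sm)
  if (alpha == 0) return(0)
  nrm <- pmax(sqrt(colSums(Sm^2)), eps)
  G <- crossprod(Sm) / tcrossprod(nrm)
  alpha / M * sum(G)
}

#' Gradient of the activity regularizer with respect to the maps
#'
#' @inheritParams activity_regularizer
#' @return array/matrix shaped like `S`.
#' @export
activity_regularizer_grad <- function(S, alpha, eps = 1e-8) {
  Sm <- if (is.matrix(S)) S else as_mat(S)
  M <- ncol(Sm)
  G <- matrix(0, nrow(Sm), M)
  if (alpha > 0 && M >= 2) {
    nrm <- sqrt(colSums(Sm^2))
    fl <- pmax(nrm, eps)
    dots <- crossprod(Sm)
    # S_i appears in the double sum both as first argument (terms (i,j)) and
    # as second (terms (j,i)); by symmetry of f both contribute the same
    # derivative, hence the factor 2 per ordered pair below.
    for (i in seq_len(M)) for (j in seq_len(M)) {
      if (i == j) next  # f(s, s) is scale invariant: zero gradient
      f <- dots[i, j] / (fl[i] * fl[j])
      g <- Sm[, j] / (fl[i] * fl[j])
      if (nrm[i] > eps) g <- g - f * Sm[, i] / (nrm[i]^2)
      G[, i] <- G[, i] + 2 * (alpha / M) * g
    }
  }
  if (is.matrix(S)) G else array(G, dim(S))
}

#' Total training objective
#'
#' Reconstruction loss plus activity regularizer. Invariant to positive
#' per-channel rescaling of the reconstruction: this is what lets the
#' mixing weights absorb the arbitrary intensity scale of each sequence.
#'
#' @param Y target patch (4D array).
#' @param Y_hat reconstruction (4D array, same shape).
#' @param S soft material maps (4D array, same spatial grid, M channels).
#' @param alpha regularization coefficient.
#' @param include_laplacian include the Laplacian loss term.
#' @param eps norm floor.
#' @return scalar loss.
#' @export
total_loss <- function(Y, Y_hat, S, alpha = 0.0075, include_laplacian = TRUE,
                       eps = 1e-8) {
  reconstruction_loss(Y, Y_hat, include_laplacian, eps) +
    activity_regularizer(S, alpha, eps)
}
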