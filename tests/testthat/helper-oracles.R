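# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code with the package internals.

# Flood-fill connected-component labelling in plain R.
oracle_label <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  nxt <- 0L
  idx <- which(mask > 0, arr.ind = TRUE)
  inmask <- array(mask > 0, d)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    if (lab[v[1], v[2], v[3]] != 0L) next
    nxt <- nxt + 1L
    stack <- list(v)
    lab[v[1], v[2], v[3]] <- nxt
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        nb <- cur + offs[k, ]
        if (any(nb < 1) || any(nb > d)) next
        if (inmask[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- nxt
          stack[[length(stack) + 1L]] <- nb
        }
      }
    }
  }
  attr(lab, "n") <- nxt
  lab
}

# Per-voxel confusion counting.
oracle_dice <- function(T_mask, P_mask) {
  t <- T_mask > 0; p <- P_mask > 0
  tp <- sum(t & p); fp <- sum(!t & p); fn <- sum(t & !p)
  if (sum(t) == 0 && sum(p) == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

oracle_avd <- function(T_mask, P_mask) abs(sum(T_mask > 0) - sum(P_mask > 0)) / sum(T_mask > 0)

# All-pairs directed distances, plain R.
oracle_h95 <- function(T_mask, P_mask, spacing = c(1, 1, 1)) {
  a <- which(T_mask > 0, arr.ind = TRUE)
  b <- which(P_mask > 0, arr.ind = TRUE)
  if (nrow(a) == 0 || nrow(b) == 0) return(NA_real_)
  A <- sweep(a, 2, spacing, "*"); B <- sweep(b, 2, spacing, "*")
  dmat <- outer(seq_len(nrow(A)), seq_len(nrow(B)), function(i, j)
    sqrt(rowSums((A[i, , drop = FALSE] - B[j, , drop = FALSE])^2)))
  dab <- apply(dmat, 1, min); dba <- apply(dmat, 2, min)
  max(quantile(dab, 0.95, type = 7), quantile(dba, 0.95, type = 7))
}

# Component-overlap counting on oracle labels.
oracle_lesions <- function(T_mask, P_mask, connectivity = 26L) {
  lt <- oracle_label(T_mask, connectivity)
  lp <- oracle_label(P_mask, connectivity)
  nt <- attr(lt, "n")
  det <- 0L
  for (i in seq_len(nt)) if (any(P_mask[lt == i] > 0)) det <- det + 1L
  nf <- 0L
  for (j in seq_len(attr(lp, "n"))) if (!any(T_mask[lp == j] > 0)) nf <- nf + 1L
  list(n_true = nt, n_detected = det, n_false = nf)
}

# Central finite differences of a scalar function at selected indices.
numeric_grad <- function(fn, x, idx, h = 1e-6) {
  vapply(idx, function(i) {
    a <- x; a[i] <- a[i] + h
    b <- x; b[i] <- b[i] - h
    (fn(a) - fn(b)) / (2 * h)
  }, numeric(1))
}

# Random sparse-ish binary mask on a small grid.
random_mask <- function(shape = c(16L, 16L, 16L), density = 0.04) {
  array(as.numeric(stats::runif(prod(shape)) < density), shape)
}
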