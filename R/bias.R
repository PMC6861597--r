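# Iterative pure-tissue inhomogeneity correction: segment, build a
# pure-tissue probability mask, estimate a smooth multiplicative field per
# channel, correct the reconstruction targets, retrain from scratch.

#' Assign material roles from the mixing-weight signature
#'
#' Identifies which Softmax output is which tissue using the recovered
#' mixing weights and the channel contrasts they imply: CSF is bright on
#' T2 and dark on FLAIR/T1; WMH is the FLAIR-brightest of the remaining
#' materials; WM is the T1-brightest of the rest; GM is the remaining
#' material with the largest overall weight; anything left is MENINGES /
#' OTHER. On real data roles can instead be assigned manually.
#'
#' @param w M x C mixing-weight matrix.
#' @param channel_roles character vector naming each channel, a subset of
#'   FLAIR, T1, T2 (default the phantom convention `c("FLAIR","T1","T2")`
#'   truncated to C).
#' @return named list mapping role (CSF, GM, WM, WMH, ...) to material index.
#' @export
assign_material_roles <- function(w, channel_roles = NULL) {
  M <- nrow(w); C <- ncol(w)
  if (is.null(channel_roles)) channel_roles <- c("FLAIR", "T1", "T2")[seq_len(C)]
  stopifnot(length(channel_roles) == C)
  ch <- function(role) {
    i <- match(role, channel_roles)
    if (is.na(i)) NULL else w[, i]
  }
  # normalize each material row so contrasts, not overall gain, decide
  rs <- pmax(rowSums(w), 1e-12)
  wn <- w / rs
  flair <- if (!is.null(ch("FLAIR"))) wn[, match("FLAIR", channel_roles)] else rowMeans(wn)
  t1 <- if (!is.null(ch("T1"))) wn[, match("T1", channel_roles)] else rowMeans(wn)
  t2 <- if (!is.null(ch("T2"))) wn[, match("T2", channel_roles)] else rowMeans(wn)
  left <- seq_len(M)
  roles <- list()
  pick <- function(score) {
    i <- left[which.max(score[left])]
    left <<- setdiff(left, i)
    i
  }
  roles$CSF <- pick(t2 - flair - t1)
  roles$WMH <- pick(flair)
  roles$WM <- pick(t1)
  if (length(left)) roles$GM <- pick(rowSums(w))
  if (length(left)) roles$MENINGES <- pick(rowSums(w))
  if (length(left)) for (k in seq_along(left)) roles[[paste0("OTHER", k)]] <- left[k]
  roles
}

#' Pure-tissue probability mask
#'
#' Sum of the CSF, GM and WM soft maps, clipped to `[0, 1]` and zero
#' outside the brain mask. Voxels dominated by WMH or meninges get low
#' weight, so they contribute minimally to the bias estimation. Under the
#' sum-to-one constraint this equals `1 - S_WMH - S_MENINGES` inside the
#' mask.
#'
#' @param S a `material_maps` object (from [predict_volume]) or a 4D array.
#' @param roles named list with at least `CSF`, `GM`, `WM` indices (see
#'   [assign_material_roles]).
#' @param mask binary 3D array (required when `S` is a bare array).
#' @return probability 3D array in `[0, 1]`.
#' @export
pure_tissue_mask <- function(S, roles, mask = NULL) {
  if (inherits(S, "material_maps")) { mask <- S$mask; S <- S$maps }
  if (is.null(mask)) stop("`mask` is required", call. = FALSE)
  for (r in c("CSF", "GM", "WM"))
    if (is.null(roles[[r]]))
      stop(sprintf("role %s is missing from `roles`", r), call. = FALSE)
  pt <- S[, , , roles$CSF] + S[, , , roles$GM] + S[, , , roles$WM]
  pmin(pmax(pt, 0), 1) * as.numeric(mask > 0)
}

#' Estimate a smooth multiplicative bias field
#'
#' Fits a smooth, strictly positive field to the log-intensities inside
#' the weight mask. With a `reference` volume (a predicted clean
#' reconstruction of the same channel) the field is a weighted Gaussian
#' smoothing of `log(volume / reference)`. Without one, tissue contrast
#' would leak into the field, so the estimator backfits: each iteration
#' clusters the residual log-intensities into tissue classes (k-means with
#' deterministic quantile initialization), flattens them by subtracting
#' the class means, down-weights partial-volume voxels far from their
#' class centre, and adds a weighted smoothing of the flattened residual
#' to the running log-field. The returned field has weighted mean 1 over
#' the mask.
#'
#' @param volume non-negative 3D array.
#' @param weight_mask 3D array in `[0, 1]`, not identically zero (for
#'   example a pure-tissue probability mask).
#' @param smoothness field kernel width in voxels (default 6; small kernels
#'   with several backfitting iterations track the field better than one
#'   wide pass).
#' @param reference optional 3D array of predicted clean intensities.
#' @param n_classes number of intensity clusters for the maskless route.
#' @param n_iter backfitting iterations (maskless route).
#' @return strictly positive 3D bias field, weighted mean 1 over the mask.
#' @export
estimate_bias_field <- function(volume, weight_mask, smoothness = 6,
                                reference = NULL, n_classes = 3L,
                                n_iter = 4L) {
  check_volume3d(volume)
  check_same_grid(volume, weight_mask, "`volume` and `weight_mask`")
  if (any(weight_mask < 0 | weight_mask > 1))
    stop("`weight_mask` must lie in [0, 1]", call. = FALSE)
  w <- weight_mask * (volume > 0)
  if (sum(w) == 0) stop("`weight_mask` is empty on the volume support", call. = FALSE)
  d <- dim(volume)
  sel <- w > 0
  wsmooth <- function(val, wt) {
    num <- gauss_smooth(val * wt, smoothness)
    den <- gauss_smooth(wt, smoothness)
    num / pmax(den, 1e-8)
  }
  if (!is.null(reference)) {
    check_same_grid(volume, reference, "`volume` and `reference`")
    ok <- sel & (reference > 0)
    r <- array(0, d)
    r[ok] <- log(volume[ok] / reference[ok])
    wr <- w * ok
    # backfit: repeated kernel smoothing of the residual counteracts the
    # amplitude shrinkage of a single weighted-smoothing pass
    g <- array(0, d)
    for (it in seq_len(n_iter)) g <- g + wsmooth(r - g, wr)
  } else {
    logv <- array(0, d)
    logv[sel] <- log(volume[sel])
    g <- array(0, d)
    for (it in seq_len(n_iter)) {
      x <- (logv - g)[sel]
      if (stats::sd(x) < 1e-8) break
      ctr <- sort(unique(as.numeric(
        stats::quantile(x, seq(0.5, n_classes - 0.5) / n_classes, type = 7))))
      flat <- if (length(ctr) < 2L) {
        x - mean(x)
      } else {
        km <- stats::kmeans(x, centers = matrix(ctr), iter.max = 50L)
        x - km$centers[km$cluster]
      }
      # partial-volume voxels sit between class centres; give them little say
      s <- max(stats::mad(flat), 1e-3)
      wt <- array(0, d)
      wt[sel] <- w[sel] * exp(-0.5 * (flat / (2.5 * s))^2)
      rfull <- array(0, d)
      rfull[sel] <- flat
      g <- g + wsmooth(rfull, wt)
    }
  }
  field <- exp(g)
  # weighted-mean-1 normalization over the mask
  field / (sum(field * w) / sum(w))
}

#' Divide out a multiplicative bias field
#'
#' Elementwise division inside the volume support; zeros outside are
#' preserved. The field must be strictly positive wherever the volume is
#' non-zero.
#'
#' @param volume 3D array.
#' @param field strictly positive 3D array (same grid).
#' @return corrected 3D array.
#' @export
correct_bias <- function(volume, field) {
  check_same_grid(volume, field, "`volume` and `field`")
  sel <- volume != 0
  if (any(field[sel] <= 0))
    stop("bias field must be strictly positive inside the mask", call. = FALSE)
  out <- volume
  out[sel] <- volume[sel] / field[sel]
  out
}

#' Iterative pure-tissue refinement loop
#'
#' Round 1 trains the autoencoder on the original inputs (targets =
#' inputs). Each later round predicts soft maps with the current network,
#' builds the pure-tissue probability mask, estimates a bias field per
#' channel (using the network's own clean reconstruction as reference),
#' corrects the *targets*, and retrains from a fresh initialization with
#' the original inputs against the corrected targets. The final network
#' thus learns to segment uncorrected images directly.
#'
#' @param volumes 4D array (X, Y, Z, C) of normalized input volumes.
#' @param n_rounds total training rounds (default 2 = one correction pass).
#' @param net_config a [network_config].
#' @param train_cfg a [train_config].
#' @param patch_size,stride patch grid for training and prediction.
#' @param keep_fraction training-patch selection fraction.
#' @param roles optional fixed role assignment; by default roles are
#'   re-derived each round from the recovered mixing weights.
#' @param channel_roles channel names for [assign_material_roles].
#' @param smoothness bias-field kernel width in voxels.
#' @param net_seed seed for each round's fresh initialization.
#' @return list with `network` (final), `corrected_targets` (4D array),
#'   and `rounds` (per round: network, log, targets).
#' @export
iterative_refinement <- function(volumes, n_rounds = 2L, net_config,
                                 train_cfg = train_config(),
                                 patch_size = c(32L, 32L, 32L), stride = 16L,
                                 keep_fraction = 0.5, roles = NULL,
                                 channel_roles = NULL, smoothness = 6,
                                 net_seed = 1L) {
  stopifnot(n_rounds >= 1L)
  d <- dim(volumes); C <- d[4]
  targets <- volumes
  rounds <- vector("list", n_rounds)
  net <- NULL
  for (r in seq_len(n_rounds)) {
    if (r > 1L) {
      S <- predict_volume(net, volumes, patch_size, stride)
      rl <- roles
      if (is.null(rl))
        rl <- assign_material_roles(net$params[["mix.W"]], channel_roles)
      pt <- pure_tissue_mask(S, rl)
      if (sum(pt) < 1)
        stop(sprintf("round %d: degenerate segmentation, pure-tissue mask is empty", r),
             call. = FALSE)
      recon <- array(as_mat(S$maps) %*% net$params[["mix.W"]], d)
      targets <- volumes
      for (ch in seq_len(C)) {
        f <- estimate_bias_field(volumes[, , , ch], pt, smoothness,
                                 reference = recon[, , , ch])
        targets[, , , ch] <- correct_bias(volumes[, , , ch], f)
      }
    }
    in_ps <- extract_patches(volumes, patch_size, stride)
    tg_ps <- extract_patches(targets, patch_size, stride)
    keep <- select_training_patches(in_ps, keep_fraction)
    tg_ps$patches <- tg_ps$patches[keep$kept]
    tg_ps$origins <- tg_ps$origins[keep$kept, , drop = FALSE]
    net0 <- build_network(net_config, seed = net_seed)  # fresh start each round
    fit <- train_segae(net0, keep, tg_ps, train_cfg)
    net <- fit$network
    rounds[[r]] <- list(network = net, log = fit$log, targets = targets)
  }
  list(network = net, corrected_targets = targets, rounds = rounds)
}
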