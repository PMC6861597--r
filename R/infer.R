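# Whole-volume prediction by sliding window with overlap averaging,
# lesion binarization and small-component removal.

#' Predict soft material maps for a whole volume
#'
#' Runs the network over the clamped patch grid (same origin rule as
#' [extract_patches]), averages the Softmax outputs over overlapping
#' voxels, re-applies the brain mask and renormalizes the averaged maps so
#' they sum to one inside the mask. Volumes smaller than the patch size
#' are zero-padded symmetrically and the padding removed afterwards.
#'
#' Batch normalization at prediction time uses per-patch statistics by
#' default (`bn_mode = "batch"`), matching the statistics regime the
#' network was trained under; this measurably outperforms frozen running
#' averages when training used few batch-size-one patches, because the
#' learned features are conditioned on per-patch normalization.
#' `bn_mode = "running"` selects the frozen running averages instead.
#' Prediction should use the same patch size and stride as training.
#'
#' @param network a trained `segae_network` (see [build_network()]).
#' @param volumes 4D array (X, Y, Z, C) of normalized input volumes.
#' @param patch_size length-3 patch dimensions (default 80^3); must be
#'   divisible by `2^(n_scales - 1)`.
#' @param stride sliding-window stride in voxels (default 40).
#' @param bn_mode `"batch"` (default) or `"running"`.
#' @return `material_maps`: list with `maps` (X, Y, Z, M) and `mask`.
#' @export
predict_volume <- function(network, volumes, patch_size = c(80L, 80L, 80L),
                           stride = 40L, bn_mode = c("batch", "running")) {
  bn_mode <- match.arg(bn_mode)
  stopifnot(inherits(network, "segae_network"))
  cfg <- network$config
  d <- dim(volumes)
  if (length(d) == 3L) { dim(volumes) <- c(d, 1L); d <- dim(volumes) }
  if (d[4] != cfg$in_channels)
    stop(sprintf("network expects %d channels, volume has %d",
                 cfg$in_channels, d[4]), call. = FALSE)
  patch_size <- rep_len(as.integer(patch_size), 3L)
  div <- 2L^(cfg$n_scales - 1L)
  if (any(patch_size %% div != 0L))
    stop(sprintf("patch size must be divisible by %d", div), call. = FALSE)
  ps <- extract_patches(volumes, patch_size, stride)
  pd <- ps$source_dim
  M <- cfg$n_materials
  acc <- array(0, c(pd[1:3], M))
  cnt <- array(0, pd[1:3])
  for (i in seq_along(ps$patches)) {
    o <- ps$origins[i, ]
    fw <- segae_forward(network, ps$patches[[i]],
                        training = (bn_mode == "batch"))
    ix <- o[1] + seq_len(patch_size[1]); iy <- o[2] + seq_len(patch_size[2])
    iz <- o[3] + seq_len(patch_size[3])
    acc[ix, iy, iz, ] <- acc[ix, iy, iz, , drop = FALSE] + fw$S
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  for (m in seq_len(M)) acc[, , , m] <- acc[, , , m] / cnt
  # strip padding
  p0 <- ps$pad
  acc <- acc[p0[1] + seq_len(dim(volumes)[1]), p0[2] + seq_len(dim(volumes)[2]),
             p0[3] + seq_len(dim(volumes)[3]), , drop = FALSE]
  mask <- brainmask_from(volumes)
  tot <- array(rowSums(as_mat(acc)), dim(mask))
  maskv <- mask > 0
  for (m in seq_len(M)) {
    mi <- acc[, , , m]
    mi[maskv] <- mi[maskv] / pmax(tot[maskv], 1e-12)
    mi[!maskv] <- 0
    acc[, , , m] <- mi
  }
  structure(list(maps = acc, mask = mask), class = "material_maps")
}

#' Binarize a soft segmentation
#'
#' Strict inequality at the threshold: a voxel is in the mask iff its soft
#' value exceeds the threshold. Reference thresholds: 0.5 (four-sequence
#' model) and 0.87 (two-sequence challenge model).
#'
#' @param S_material 3D soft map.
#' @param threshold scalar in `[0, 1]`.
#' @return binary 3D array with attributes recording the threshold.
#' @export
binarize <- function(S_material, threshold = 0.5) {
  check_volume3d(S_material)
  stopifnot(threshold >= 0, threshold <= 1)
  out <- array(as.numeric(S_material > threshold), dim(S_material))
  attr(out, "threshold") <- threshold
  out
}

#' Remove small connected components
#'
#' Labels the 3D connected components of a binary mask and removes those
#' with fewer than `min_voxels` voxels (a component of exactly
#' `min_voxels` is kept). Idempotent; monotone in `min_voxels`.
#'
#' @param mask binary 3D array.
#' @param min_voxels minimum surviving component size (default 3).
#' @param connectivity 26 (default) or 6 neighbourhood.
#' @return filtered binary 3D array with attribute `min_voxels`.
#' @export
remove_small_components <- function(mask, min_voxels = 3L, connectivity = 26L) {
  check_volume3d(mask)
  stopifnot(min_voxels >= 1L)
  lab <- label_components(mask, connectivity)
  n <- attr(lab, "n")
  if (n == 0) {
    out <- array(0, dim(mask))
  } else {
    sizes <- tabulate(lab[lab > 0], nbins = n)
    keep <- which(sizes >= min_voxels)
    out <- array(as.numeric(lab %in% keep & lab > 0), dim(mask))
  }
  attr(out, "min_voxels") <- as.integer(min_voxels)
  attr(out, "connectivity") <- as.integer(connectivity)
  out
}

#' Save / load a trained network
#'
#' The checkpoint is a single RDS file with the configuration embedded.
#' @param network a `segae_network`.
#' @param path file path.
#' @return `load_network` returns the network.
#' @export
save_network <- function(network, path) {
  stopifnot(inherits(network, "segae_network"))
  saveRDS(network, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "segae_network"))
    stop("not a segae network checkpoint: ", path, call. = FALSE)
  net
}
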