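# Intensity normalisation, PD-based enhancement, cropping, patch
# extraction/selection and training-time augmentation.

#' Normalize a volume by the 99th percentile of its non-zero voxels
#'
#' The percentile uses linear interpolation between order statistics
#' (`stats::quantile` type 7); zeros (background) remain zero.
#'
#' @param volume 3D array with at least one non-zero voxel.
#' @param probs percentile used as the divisor (default 0.99).
#' @return rescaled 3D array.
#' @export
normalize_intensity <- function(volume, probs = 0.99) {
  check_volume3d(volume)
  nz <- volume[volume != 0]
  if (length(nz) == 0L)
    stop("`volume` is all zero: no valid normalizer", call. = FALSE)
  volume / as.numeric(stats::quantile(nz, probs, type = 7))
}

#' Enhance a T1-w or T2-w image with a PD-w image
#'
#' Multiplies the image elementwise with the intensity-inverted PD image,
#' `I_orig * (max(I_pd) - I_pd)`. Where the PD image attains its maximum
#' the output is 0. The operation is linear in `I_orig` and homogeneous of
#' degree 1 in the PD intensity scale.
#'
#' @param I_orig 3D array (T1-w or T2-w).
#' @param I_pd non-negative 3D array (PD-w) on the same grid.
#' @return enhanced 3D array.
#' @export
enhance_with_pd <- function(I_orig, I_pd) {
  check_same_grid(I_orig, I_pd, "`I_orig` and `I_pd`")
  if (any(I_pd < 0)) stop("`I_pd` must be non-negative", call. = FALSE)
  I_orig * (max(I_pd) - I_pd)
}

#' Crop multi-sequence volumes to the smallest cuboid containing the brain
#'
#' @param volumes 4D array (X, Y, Z, C) or 3D array; the brain support is
#'   the union of non-zero voxels across channels.
#' @return list with `volumes` (cropped array of the same rank) and
#'   `offset` (0-based voxel offset of the crop corner in the source grid).
#' @export
crop_to_brain <- function(volumes) {
  d <- dim(volumes)
  was3d <- length(d) == 3L
  if (was3d) { dim(volumes) <- c(d, 1L); d <- dim(volumes) }
  mask <- brainmask_from(volumes)
  if (sum(mask) == 0) stop("empty brain: no non-zero voxels", call. = FALSE)
  idx <- which(mask > 0, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  out <- volumes[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], , drop = FALSE]
  if (was3d) dim(out) <- dim(out)[1:3]
  list(volumes = out, offset = as.integer(lo - 1L))
}

# Patch-grid origins (0-based) along one axis: multiples of the stride with
# a final origin clamped so the last patch touches the boundary.
patch_grid_1d <- function(len, patch, stride) {
  if (stride <= 0L) stop("`stride` must be positive", call. = FALSE)
  if (patch > len) stop("patch size exceeds volume size", call. = FALSE)
  org <- seq.int(0L, len - patch, by = stride)
  if (org[length(org)] != len - patch) org <- c(org, len - patch)
  as.integer(org)
}

# Symmetric zero padding up to at least `target` per axis. Returns padded
# array and the 0-based offset of the original corner inside it.
pad_to <- function(volumes, target) {
  d <- dim(volumes)
  need <- pmax(target - d[1:3], 0L)
  lo <- need %/% 2L
  if (all(need == 0L)) return(list(volumes = volumes, pad = c(0L, 0L, 0L)))
  out <- array(0, c(d[1:3] + need, d[4]))
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3]), ] <-
    volumes
  list(volumes = out, pad = as.integer(lo))
}

#' Extract a regular grid of 3D patches
#'
#' Origins lie at multiples of `stride` per axis with the final origin
#' clamped so the last patch touches the volume boundary (no voxel is left
#' unsampled). Volumes smaller than the patch size are symmetrically
#' zero-padded first; the applied padding is reported so that results can
#' be mapped back.
#'
#' @param volumes 4D array (X, Y, Z, C) or 3D array.
#' @param patch_size length-3 integer patch dimensions.
#' @param stride positive integer stride in voxels (default 40).
#' @return object of class `patch_set`: list with `patches` (list of 4D
#'   arrays), `origins` (N x 3 matrix, 0-based, in the padded grid),
#'   `patch_size`, `stride`, `source_dim` and `pad`.
#' @export
extract_patches <- function(volumes, patch_size, stride = 40L) {
  d <- dim(volumes)
  if (length(d) == 3L) dim(volumes) <- c(d, 1L)
  patch_size <- rep_len(as.integer(patch_size), 3L)
  stride <- as.integer(stride)
  padded <- pad_to(volumes, patch_size)
  volumes <- padded$volumes
  d <- dim(volumes)
  gx <- patch_grid_1d(d[1], patch_size[1], stride)
  gy <- patch_grid_1d(d[2], patch_size[2], stride)
  gz <- patch_grid_1d(d[3], patch_size[3], stride)
  origins <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  patches <- lapply(seq_len(nrow(origins)), function(i) {
    o <- origins[i, ]
    volumes[o[1] + seq_len(patch_size[1]), o[2] + seq_len(patch_size[2]),
            o[3] + seq_len(patch_size[3]), , drop = FALSE]
  })
  structure(list(patches = patches, origins = unname(origins),
                 patch_size = patch_size, stride = stride,
                 source_dim = d, pad = padded$pad),
            class = "patch_set")
}

#' Keep the patches with the fewest background voxels
#'
#' Background is a voxel where all channels are exactly 0. Patches are
#' ranked by ascending background count, ties broken by lexicographic
#' origin order; `ceiling(fraction * N)` patches are kept.
#'
#' @param patchset a [patch_set][extract_patches].
#' @param fraction fraction of patches to keep, in `(0, 1]` (default 0.5).
#' @return a `patch_set` containing the kept patches, plus `kept` (indices
#'   into the input patch list).
#' @export
select_training_patches <- function(patchset, fraction = 0.5) {
  stopifnot(inherits(patchset, "patch_set"))
  n <- length(patchset$patches)
  if (n == 0L) stop("empty patch set", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  bg <- vapply(patchset$patches, function(p) {
    m <- as_mat(p)
    sum(rowSums(m != 0) == 0)
  }, numeric(1))
  o <- patchset$origins
  ord <- order(bg, o[, 1], o[, 2], o[, 3])
  keep <- sort(ord[seq_len(ceiling(fraction * n))])
  out <- patchset
  out$patches <- patchset$patches[keep]
  out$origins <- patchset$origins[keep, , drop = FALSE]
  out$kept <- keep
  out
}

# Augmentation drawing from the current RNG stream (used inside training).
augment_draw <- function(patch, noise_sd = 0.05, scale_sd = 0.5) {
  d <- dim(patch)
  if (noise_sd > 0)
    patch <- patch + array(stats::rnorm(prod(d), 0, noise_sd), d)
  if (scale_sd > 0) {
    sc <- stats::rnorm(d[4], 1, scale_sd)
    patch <- patch * rep(sc, each = prod(d[1:3]))
  }
  patch
}

#' Augment a training patch
#'
#' Adds i.i.d. Gaussian noise (sd `noise_sd`, default 0.05) to every voxel,
#' then multiplies each channel by a scalar drawn from N(1, `scale_sd`^2)
#' (default sd 0.5). Augmentation is applied to the network input only; the
#' reconstruction target stays clean. Channel scalars are not clipped at 0.
#'
#' @param patch 4D array (X, Y, Z, C).
#' @param noise_sd additive noise standard deviation.
#' @param scale_sd channel scaling standard deviation.
#' @param seed integer seed (deterministic augmentation).
#' @return augmented 4D array.
#' @export
augment_patch <- function(patch, noise_sd = 0.05, scale_sd = 0.5, seed = 1L) {
  stopifnot(length(dim(patch)) == 4L, all(is.finite(patch)))
  with_seed(seed, augment_draw(patch, noise_sd, scale_sd))
}
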