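# Lesion evaluation metrics: Dice, absolute volume difference, 95th
# percentile Hausdorff distance, lesion-wise detection counts, and volume
# correlation.

.check_mask_pair <- function(T_mask, P_mask) {
  check_volume3d(T_mask, "T"); check_volume3d(P_mask, "P")
  check_same_grid(T_mask, P_mask, "masks")
  list(t = T_mask > 0, p = P_mask > 0)
}

#' Dice similarity coefficient
#'
#' `2 TP / (2 TP + FP + FN)`, in `[0, 1]`; 1 for a perfect overlap. Both
#' masks empty gives 1 by convention, exactly one empty gives 0. Symmetric
#' in its arguments.
#'
#' @param T_mask,P_mask binary 3D arrays on the same grid (reference and
#'   prediction).
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(T_mask, P_mask) {
  m <- .check_mask_pair(T_mask, P_mask)
  st <- sum(m$t); sp <- sum(m$p)
  if (st == 0 && sp == 0) return(1)
  tp <- sum(m$t & m$p)
  2 * tp / (st + sp)
}

#' Absolute volume difference
#'
#' `|V_T - V_P| / V_T`. Depends only on the two volumes, not on overlap,
#' and is not symmetric (normalized by the reference volume). Reported
#' x100 as a percentage in evaluation tables.
#'
#' @inheritParams dice
#' @param spacing voxel dimensions (cancels in the ratio; accepted for a
#'   uniform interface).
#' @return non-negative scalar (fraction of the true volume).
#' @export
avd <- function(T_mask, P_mask, spacing = c(1, 1, 1)) {
  m <- .check_mask_pair(T_mask, P_mask)
  vt <- sum(m$t)
  if (vt == 0) stop("AVD is undefined for an empty reference mask", call. = FALSE)
  abs(vt - sum(m$p)) / vt
}

#' Modified (95th percentile) Hausdorff distance
#'
#' For voxel sets X (reference) and Y (prediction), the maximum of the
#' 95th percentiles of the two directed nearest-neighbour distance sets,
#' with Euclidean distances in physical units. Computed on full voxel sets;
#' the percentile uses linear interpolation. Less outlier-sensitive than
#' the exact Hausdorff distance, which it never exceeds.
#'
#' @inheritParams dice
#' @param spacing voxel dimensions in mm (default unit voxels).
#' @param percentile percentile of the directed distances (default 0.95;
#'   1 gives the exact Hausdorff distance).
#' @return scalar >= 0, or `NA` if either mask is empty (undefined).
#' @export
hausdorff95 <- function(T_mask, P_mask, spacing = c(1, 1, 1),
                        percentile = 0.95) {
  m <- .check_mask_pair(T_mask, P_mask)
  if (sum(m$t) == 0 || sum(m$p) == 0) return(NA_real_)
  a <- which(m$t, arr.ind = TRUE); b <- which(m$p, arr.ind = TRUE)
  A <- sweep(a, 2, spacing, "*"); B <- sweep(b, 2, spacing, "*")
  dab <- cpp_directed_dists(A, B)
  dba <- cpp_directed_dists(B, A)
  max(as.numeric(stats::quantile(dab, percentile, type = 7)),
      as.numeric(stats::quantile(dba, percentile, type = 7)))
}

#' Label the 3D connected components of a mask
#'
#' @param mask binary 3D array.
#' @param connectivity 26 (default) or 6 neighbourhood.
#' @return integer 3D array of labels (0 = background) with attribute `n`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  check_volume3d(mask)
  stopifnot(connectivity %in% c(6L, 26L))
  lab <- cpp_label_components(as.integer(mask > 0), as.integer(dim(mask)),
                              as.integer(connectivity))
  out <- array(as.integer(lab), dim(mask))
  attr(out, "n") <- attr(lab, "n")
  out
}

#' Lesion-wise detection counts
#'
#' An individual lesion is a 3D connected component. A reference lesion is
#' correctly detected if it overlaps the prediction in at least one voxel
#' (each reference component counts at most once, so `N_P <= N_T`); a
#' predicted component overlapping no reference lesion is a false
#' detection. L-TPR = `N_P / N_T`; L-F1 = `N_P / (N_P + N_F)`.
#'
#' @inheritParams dice
#' @param connectivity component connectivity (26 default, shared with the
#'   post-processing step).
#' @return list with `n_true` (N_T), `n_detected` (N_P), `n_false` (N_F),
#'   `l_tpr` and `l_f1` (`NA` when undefined).
#' @export
lesion_detection <- function(T_mask, P_mask, connectivity = 26L) {
  m <- .check_mask_pair(T_mask, P_mask)
  lt <- label_components(array(as.numeric(m$t), dim(T_mask)), connectivity)
  lp <- label_components(array(as.numeric(m$p), dim(P_mask)), connectivity)
  nt <- attr(lt, "n"); np_all <- attr(lp, "n")
  hit_t <- unique(lt[m$p & lt > 0])
  n_det <- length(hit_t)
  hit_p <- unique(lp[m$t & lp > 0])
  n_false <- np_all - length(hit_p)
  list(n_true = nt, n_detected = n_det, n_false = n_false,
       l_tpr = if (nt > 0) n_det / nt else NA_real_,
       l_f1 = if (n_det + n_false > 0) n_det / (n_det + n_false) else NA_real_)
}

#' Pearson correlation and linear fit of predicted versus true volumes
#'
#' @param true_volumes,predicted_volumes numeric vectors (n >= 3) of
#'   per-subject lesion volumes.
#' @return list with `r`, `slope`, `intercept` (least squares of predicted
#'   on true).
#' @export
volume_correlation <- function(true_volumes, predicted_volumes) {
  stopifnot(length(true_volumes) == length(predicted_volumes),
            length(true_volumes) >= 3L)
  if (stats::sd(true_volumes) == 0 || stats::sd(predicted_volumes) == 0)
    stop("volume correlation is undefined for zero-variance inputs", call. = FALSE)
  fit <- stats::lm(predicted_volumes ~ true_volumes)
  list(r = as.numeric(stats::cor(true_volumes, predicted_volumes)),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Full per-subject lesion evaluation
#'
#' Computes DSC, H95, AVD (as a fraction and x100), L-TPR, L-F1 and the
#' component counts for one predicted mask against a reference mask.
#'
#' @inheritParams dice
#' @param spacing voxel dimensions in mm.
#' @param connectivity lesion connectivity.
#' @return one-row data.frame with columns dsc, h95, avd, avd_pct, l_tpr,
#'   l_f1, n_true, n_detected, n_false.
#' @export
evaluate_lesions <- function(T_mask, P_mask, spacing = c(1, 1, 1),
                             connectivity = 26L) {
  det <- lesion_detection(T_mask, P_mask, connectivity)
  a <- avd(T_mask, P_mask, spacing)
  data.frame(dsc = dice(T_mask, P_mask),
             h95 = hausdorff95(T_mask, P_mask, spacing),
             avd = a, avd_pct = 100 * a,
             l_tpr = det$l_tpr, l_f1 = det$l_f1,
             n_true = det$n_true, n_detected = det$n_detected,
             n_false = det$n_false)
}

#' Match predicted materials to ground truth
#'
#' Finds the material permutation maximizing the mean Dice between the
#' argmax (hard) segmentations of predicted and reference soft maps, by
#' exhaustive search over permutations (M <= 8). Materials with an empty
#' reference map are excluded from the mean.
#'
#' @param S_pred 4D array (X, Y, Z, M) of predicted soft maps.
#' @param S_true 4D array of reference soft maps (same shape).
#' @param mask optional binary 3D array restricting the comparison.
#' @return list with `perm` (index into predicted materials for each truth
#'   material), `dice` (per truth material) and `mean_dice`.
#' @export
match_materials <- function(S_pred, S_true, mask = NULL) {
  stopifnot(identical(dim(S_pred), dim(S_true)))
  d <- dim(S_pred); M <- d[4]
  if (is.null(mask)) mask <- array(1, d[1:3])
  sel <- as.numeric(mask) > 0
  hp <- max.col(as_mat(S_pred)[sel, , drop = FALSE], ties.method = "first")
  ht <- max.col(as_mat(S_true)[sel, , drop = FALSE], ties.method = "first")
  Dm <- matrix(0, M, M)  # Dm[i, j]: Dice of truth material i vs predicted j
  for (i in seq_len(M)) for (j in seq_len(M)) {
    ti <- ht == i; pj <- hp == j
    si <- sum(ti); sj <- sum(pj)
    Dm[i, j] <- if (si + sj == 0) 1 else 2 * sum(ti & pj) / (si + sj)
  }
  nonempty <- vapply(seq_len(M), function(i) sum(ht == i) > 0, logical(1))
  perms <- permutations_of(M)
  best <- NULL; best_val <- -Inf
  for (p in perms) {
    v <- mean(Dm[cbind(seq_len(M), p)][nonempty])
    if (v > best_val) { best_val <- v; best <- p }
  }
  list(perm = best, dice = Dm[cbind(seq_len(M), best)],
       mean_dice = best_val, nonempty = nonempty)
}

# All permutations of 1..n (n <= 8), as a list: insert n into every
# position of every permutation of 1..(n-1).
permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in 0:(n - 1L)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos)
  }
  out
}
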