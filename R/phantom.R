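# Synthetic multi-sequence phantom: known material maps, mixing weights,
# bias fields and noise, so that the whole pipeline is testable without
# real MRI data.

#' Default material names for a phantom with M materials
#'
#' Order is CSF, GM, WM, WMH and, for M = 5, a thin meninges rim.
#' @param n_materials integer number of materials (2..8).
#' @return character vector of material names.
#' @export
phantom_material_names <- function(n_materials) {
  base <- c("CSF", "GM", "WM", "WMH", "MENINGES")
  if (n_materials <= 5L) return(base[seq_len(n_materials)])
  c(base, paste0("OTHER", seq_len(n_materials - 5L)))
}

#' Default non-negative mixing weights for the phantom
#'
#' Rows are materials, columns are channels in the order FLAIR-like,
#' T1-like, T2-like. Values mimic the qualitative MRI contrast of each
#' tissue: CSF dark on FLAIR/T1 and bright on T2, WM brightest on T1, GM
#' brighter than WM on FLAIR, and the lesion material (WMH) FLAIR-dominant
#' and T1-dark, so lesions are identifiable from the weight signature
#' alone. Beyond full rank, the four principal rows (CSF, GM, WM, WMH)
#' are *extreme rays* of their joint non-negative cone (no one of them is
#' a non-negative combination of the other rows, minimum relative
#' residual 0.26): without this property the linear unmixing problem
#' admits exact alternative factorizations and the ground-truth maps are
#' not recoverable even in principle. The meninges row is interior (a dim
#' tissue expressible by the others) — matching its tendency to vanish
#' from trained models.
#'
#' @param n_materials number of materials M (2..8).
#' @param channels number of channels C (1..3).
#' @return M x C non-negative matrix with material/channel dimnames.
#' @export
default_mixing_weights <- function(n_materials = 4L, channels = 3L) {
  stopifnot(n_materials >= 2L, n_materials <= 8L, channels >= 1L, channels <= 3L)
  full <- rbind(
    CSF      = c(0.05, 0.15, 1.00),
    GM       = c(0.75, 0.60, 0.30),
    WM       = c(0.30, 1.00, 0.35),
    WMH      = c(1.00, 0.25, 0.75),
    MENINGES = c(0.30, 0.20, 0.45),
    OTHER1   = c(0.20, 0.80, 0.20),
    OTHER2   = c(0.70, 0.25, 0.40),
    OTHER3   = c(0.10, 0.45, 0.85)
  )
  w <- full[seq_len(n_materials), seq_len(channels), drop = FALSE]
  rownames(w) <- phantom_material_names(n_materials)
  colnames(w) <- c("FLAIR", "T1", "T2")[seq_len(channels)]
  w
}

# Ellipsoidal radial coordinate for a brain-like shape; rho = 1 on the
# brain boundary. Mild per-axis jitter keeps phantoms from being perfectly
# symmetric (drawn from the caller's RNG stream).
.phantom_rho <- function(shape) {
  ctr <- (shape + 1) / 2 + stats::runif(3, -1, 1)
  semi <- shape * stats::runif(3, 0.40, 0.44)
  co <- grid_coords(shape)
  u <- sweep(sweep(co, 2, ctr), 2, semi, "/")
  array(sqrt(rowSums(u^2)), shape)
}

#' Generate soft material maps and a brain mask
#'
#' Builds nested ellipsoidal compartments (central CSF core, white-matter
#' interior, grey-matter shell and, for M >= 5, a thin outer meninges rim)
#' plus randomly placed smoothed lesion blobs inside the white matter.
#' Hard compartment maps are Gaussian-blurred (partial volume) and
#' renormalised so the maps are non-negative and sum to exactly 1 at every
#' voxel of the brain mask, and to 0 outside it.
#'
#' @param shape integer length-3 grid size, each dimension >= 16.
#' @param n_materials integer M in 2..8; order is CSF, GM, WM, WMH, MENINGES.
#' @param lesion_fraction target lesion volume as a fraction of the
#'   white-matter region, in `[0, 1]`. 0 yields an identically zero lesion map.
#' @param softness Gaussian blur sigma in voxels applied to the hard maps
#'   (partial-volume smoothness).
#' @param seed integer seed; identical arguments reproduce identical maps.
#' @return list with `maps` (4D array X x Y x Z x M, material names in the
#'   4th dimnames), `mask` (3D binary array) and `material_names`.
#' @export
make_material_maps <- function(shape, n_materials = 4L, lesion_fraction = 0.05,
                               softness = 1, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("`shape` must have 3 dimensions, each >= 16", call. = FALSE)
  n_materials <- as.integer(n_materials)
  if (n_materials < 2L || n_materials > 8L)
    stop("`n_materials` must be between 2 and 8", call. = FALSE)
  if (lesion_fraction < 0 || lesion_fraction > 1)
    stop("`lesion_fraction` must be in [0, 1]", call. = FALSE)
  mats <- phantom_material_names(n_materials)
  with_seed(seed, {
    rho <- .phantom_rho(shape)
    mask <- array(as.numeric(rho <= 1), shape)
    has_men <- "MENINGES" %in% mats
    # Radial zone boundaries (fractions of the brain radius).
    r_csf <- 0.28
    r_wm  <- 0.70
    r_gm  <- if (has_men) 0.93 else 1.0
    # CSF core is a smaller off-centre ellipsoid (ventricle-like).
    ctr <- (shape + 1) / 2
    co <- grid_coords(shape)
    semi_v <- shape * c(0.13, 0.17, 0.12)
    uv <- sweep(sweep(co, 2, ctr + c(0, -0.05 * shape[2], 0)), 2, semi_v, "/")
    rho_v <- array(sqrt(rowSums(uv^2)), shape)
    hard <- array(0, c(shape, n_materials))
    csf <- (rho_v <= 1) & (mask > 0)
    wm  <- (rho <= r_wm) & !csf & (mask > 0)
    gm  <- (rho > r_wm) & (rho <= r_gm) & (mask > 0)
    men <- if (has_men) (rho > r_gm) & (mask > 0) else array(FALSE, shape)
    # Lesions inside the WM interior, mimicking the clinical pattern:
    # large confluent periventricular caps near the CSF core plus small
    # punctate deep-WM blobs, together reaching the requested fraction of
    # the WM region.
    les <- array(FALSE, shape)
    if (lesion_fraction > 0 && "WMH" %in% mats) {
      target <- lesion_fraction * sum(wm)
      # periventricular caps: centres just outside the ventricle surface
      pv_band <- wm & (rho_v > 1.05) & (rho_v < 1.6)
      cand_pv <- which(pv_band)
      guard <- 0L
      while (sum(les) < 0.6 * target && length(cand_pv) && guard < 50L) {
        guard <- guard + 1L
        cc <- co[cand_pv[sample.int(length(cand_pv), 1L)], ]
        r_hi <- max(2.5, 0.13 * min(shape))
        r <- stats::runif(1, min(3.5, 0.8 * r_hi), r_hi)
        d2 <- (co[, 1] - cc[1])^2 + (co[, 2] - cc[2])^2 + (co[, 3] - cc[3])^2
        les <- les | (array(d2 <= r^2, shape) & wm)
      }
      # punctate deep-WM lesions for the remaining load
      wm_core <- wm & (rho >= 0.33) & (rho <= 0.63) & (rho_v > 1.25)
      cand <- which(wm_core)
      guard <- 0L
      while (sum(les) < target && length(cand) && guard < 400L) {
        guard <- guard + 1L
        cc <- co[cand[sample.int(length(cand), 1L)], ]
        r <- stats::runif(1, 1.6, 3.2)
        d2 <- (co[, 1] - cc[1])^2 + (co[, 2] - cc[2])^2 + (co[, 3] - cc[3])^2
        les <- les | (array(d2 <= r^2, shape) & wm)
      }
    }
    wm_only <- wm & !les
    hard[, , , 1][csf] <- 1
    hard[, , , 2][gm] <- 1
    hard[, , , 3][wm_only] <- 1
    if ("WMH" %in% mats) hard[, , , 4][les] <- 1
    if (has_men) hard[, , , 5][men] <- 1
    soft <- hard
    if (softness > 0)
      for (i in seq_len(n_materials))
        soft[, , , i] <- gauss_smooth(hard[, , , i], softness)
    tot <- array(rowSums(as_mat(soft)), shape)
    maskv <- mask > 0
    for (i in seq_len(n_materials)) {
      mi <- soft[, , , i]
      mi[maskv] <- mi[maskv] / pmax(tot[maskv], 1e-12)
      mi[!maskv] <- 0
      soft[, , , i] <- mi
    }
    dimnames(soft) <- c(rep(list(NULL), 3), list(mats))
    list(maps = soft, mask = mask, material_names = mats)
  })
}

#' Generate a smooth multiplicative bias field
#'
#' Returns `exp(g)` where `g` is Gaussian-smoothed white noise rescaled so
#' that `max(abs(g)) = amplitude`; the field is then renormalised to mean 1
#' over `mask` (the whole volume if no mask is given). The field is strictly
#' positive everywhere.
#'
#' @param shape length-3 grid size.
#' @param amplitude maximum magnitude of the log-field; must be `< 1` and
#'   `>= 0`. 0 yields a field identically 1.
#' @param smoothness correlation length in voxels (Gaussian sigma, >= 4 for
#'   a genuinely low-frequency field).
#' @param seed integer seed.
#' @param mask optional 3D binary array over which the mean is normalised.
#' @return 3D array, strictly positive.
#' @export
make_bias_field <- function(shape, amplitude = 0.3, smoothness = 12,
                            seed = 1L, mask = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L)
  if (amplitude >= 1) stop("`amplitude` must be < 1", call. = FALSE)
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  if (amplitude == 0) return(array(1, shape))
  if (smoothness < 4) stop("`smoothness` must be >= 4 voxels", call. = FALSE)
  with_seed(seed, {
    g <- gauss_smooth(array(stats::rnorm(prod(shape)), shape), smoothness)
    g <- g * (amplitude / max(abs(g)))
    f <- exp(g)
    sel <- if (is.null(mask)) rep(TRUE, length(f)) else mask > 0
    f / mean(f[sel])
  })
}

#' Bundle phantom ground truth
#'
#' @param material_maps 4D array of soft maps (from [make_material_maps]).
#' @param mixing_weights M x C non-negative matrix.
#' @param bias_fields list of C strictly positive 3D arrays (or NULL for unit).
#' @param brain_mask 3D binary array.
#' @param noise_sd non-negative additive noise standard deviation.
#' @param seed integer seed used for the noise draw in [synthesize_volumes].
#' @return object of class `phantom_truth`.
#' @export
phantom_truth <- function(material_maps, mixing_weights, bias_fields = NULL,
                          brain_mask, noise_sd = 0, seed = 1L) {
  M <- dim(material_maps)[4]
  if (nrow(mixing_weights) != M)
    stop("`mixing_weights` must have one row per material", call. = FALSE)
  if (any(mixing_weights < 0))
    stop("`mixing_weights` must be non-negative", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  C <- ncol(mixing_weights)
  if (is.null(bias_fields))
    bias_fields <- rep(list(array(1, dim(brain_mask))), C)
  stopifnot(length(bias_fields) == C)
  structure(list(material_maps = material_maps, mixing_weights = mixing_weights,
                 bias_fields = bias_fields, brain_mask = brain_mask,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_truth")
}

#' Synthesize multi-sequence volumes from phantom ground truth
#'
#' Runs the linear unmixing model generatively: each channel is
#' `bias_c * sum_i w[i,c] * S_i` plus i.i.d. Gaussian noise, clipped at 0
#' and set to exactly 0 outside the brain mask. With zero noise and unit
#' bias the output is the exact linear mixture.
#'
#' @param truth a [phantom_truth] object.
#' @param channels number of channels to synthesize (default: all columns
#'   of the mixing weights).
#' @return 4D array (X, Y, Z, C) with channel dimnames from the weights.
#' @export
synthesize_volumes <- function(truth, channels = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  w <- truth$mixing_weights
  if (is.null(channels)) channels <- ncol(w)
  stopifnot(channels >= 1, channels <= ncol(w))
  d3 <- dim(truth$brain_mask)
  Smat <- as_mat(truth$material_maps)
  mix <- Smat %*% w[, seq_len(channels), drop = FALSE]
  out <- array(0, c(d3, channels))
  maskv <- as.numeric(truth$brain_mask > 0)
  with_seed(truth$seed, {
    for (ch in seq_len(channels)) {
      v <- array(mix[, ch], d3) * truth$bias_fields[[ch]]
      if (truth$noise_sd > 0)
        v <- v + array(stats::rnorm(prod(d3), 0, truth$noise_sd), d3)
      v <- pmax(v, 0) * maskv
      out[, , , ch] <- v
    }
  })
  dimnames(out) <- c(rep(list(NULL), 3), list(colnames(w)[seq_len(channels)]))
  out
}

#' One-stop phantom generator
#'
#' Convenience wrapper producing both the ground truth and the synthesized
#' volumes under a single seed (sub-seeds are derived deterministically).
#'
#' @param shape length-3 grid size (default 48^3).
#' @param channels number of MRI-like channels (default 3: FLAIR, T1, T2).
#' @param n_materials number of materials (default 4: CSF, GM, WM, WMH).
#' @param lesion_fraction lesion volume fraction of the WM region.
#' @param bias_amplitude multiplicative bias log-amplitude (0 = none).
#' @param bias_smoothness bias correlation length in voxels.
#' @param noise_sd additive Gaussian noise sd.
#' @param softness partial-volume blur sigma in voxels.
#' @param seed master seed.
#' @return list with `volumes` (4D array) and `truth` ([phantom_truth]).
#' @export
segae_phantom <- function(shape = c(48L, 48L, 48L), channels = 3L,
                          n_materials = 4L, lesion_fraction = 0.05,
                          bias_amplitude = 0, bias_smoothness = 12,
                          noise_sd = 0, softness = 1, seed = 1L) {
  seed <- as.integer(seed)
  mm <- make_material_maps(shape, n_materials, lesion_fraction,
                           softness = softness, seed = seed)
  w <- default_mixing_weights(n_materials, channels)
  bf <- lapply(seq_len(channels), function(ch) {
    if (bias_amplitude > 0)
      make_bias_field(shape, bias_amplitude, bias_smoothness,
                      seed = seed + 101L * ch, mask = mm$mask)
    else array(1, shape)
  })
  tr <- phantom_truth(mm$maps, w, bf, mm$mask, noise_sd, seed = seed + 7L)
  list(volumes = synthesize_volumes(tr), truth = tr)
}
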