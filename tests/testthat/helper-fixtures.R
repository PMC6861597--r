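# Shared fixtures, generated once per test session.

fixture_env <- new.env(parent = emptyenv())

# Small noiseless phantom used by several module tests.
small_phantom <- function() {
  if (is.null(fixture_env$small)) {
    fixture_env$small <- segae_phantom(c(24L, 24L, 24L), channels = 3L,
                                       n_materials = 4L,
                                       lesion_fraction = 0.05, seed = 11L)
  }
  fixture_env$small
}

# The standard study phantom (48^3, C = 3, M = 4, noiseless, unit bias).
study_phantom <- function() {
  if (is.null(fixture_env$study)) {
    fixture_env$study <- segae_phantom(c(48L, 48L, 48L), channels = 3L,
                                       n_materials = 4L,
                                       lesion_fraction = 0.05, seed = 1L)
  }
  fixture_env$study
}

# The desk-scale training protocol: p99 normalization, brain cropping,
# 16^3 patches with stride 8, 50% least-background selection.
study_patches <- function() {
  if (is.null(fixture_env$patches)) {
    ph <- study_phantom()
    vols <- ph$volumes
    for (ch in seq_len(dim(vols)[4]))
      vols[, , , ch] <- normalize_intensity(vols[, , , ch])
    cr <- crop_to_brain(vols)
    ps <- extract_patches(cr$volumes, c(16L, 16L, 16L), 8L)
    fixture_env$patches <- select_training_patches(ps, 0.5)
    fixture_env$norm_vols <- vols
  }
  fixture_env$patches
}

study_volumes_normalized <- function() {
  study_patches()
  fixture_env$norm_vols
}

# Train the study model once per seed and reuse it across acceptance tests.
study_model <- function(seed = 1L, epochs = 80L) {
  key <- paste0("model", seed)
  if (is.null(fixture_env[[key]])) {
    cfg <- network_config(3L, 4L, base_filters = 8L)
    net <- build_network(cfg, seed = seed)
    tcfg <- train_config(epochs = epochs, seed = seed, alpha = 0.0075)
    keep <- study_patches()
    fixture_env[[key]] <- train_segae(net, keep, keep, tcfg)
  }
  fixture_env[[key]]
}

# Recovery summary for a trained study model: per-channel reconstruction
# cosine, Hungarian-matched Dice, and per-channel mixing-weight correlation.
study_recovery <- function(seed) {
  key <- paste0("recovery", seed)
  if (is.null(fixture_env[[key]])) {
    ph <- study_phantom()
    vols <- study_volumes_normalized()
    net <- study_model(seed)$network
    S <- predict_volume(net, vols, c(16L, 16L, 16L), 8L)
    W <- net$params[["mix.W"]]
    recon <- array(matrix(S$maps, ncol = 4) %*% W, dim(vols))
    cosv <- vapply(1:3, function(cc)
      cosine_proximity(vols[, , , cc], recon[, , , cc]), numeric(1))
    mt <- match_materials(S$maps, ph$truth$material_maps, ph$truth$brain_mask)
    wr <- vapply(1:3, function(cc)
      cor(W[mt$perm, cc], ph$truth$mixing_weights[, cc]), numeric(1))
    fixture_env[[key]] <- list(cos = cosv, match = mt, weight_r = wr,
                               S = S, net = net)
  }
  fixture_env[[key]]
}
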