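# End-to-end plumbing: NIfTI I/O, YAML configuration, and the
# simulate -> train/refine -> predict -> evaluate workflow.

#' Read co-registered single-channel NIfTI volumes into one array
#'
#' @param paths character vector of NIfTI files, one per channel, all on
#'   the same voxel grid.
#' @return 4D array (X, Y, Z, C) with a `spacing` attribute (mm).
#' @export
read_volumes <- function(paths) {
  vols <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
    RNifti::readNifti(p)
  })
  d <- dim(vols[[1]])
  for (v in vols[-1])
    if (!identical(dim(v), d))
      stop("input volumes are not on the same voxel grid", call. = FALSE)
  out <- array(0, c(d, length(vols)))
  for (i in seq_along(vols)) out[, , , i] <- as.array(vols[[i]])
  attr(out, "spacing") <- RNifti::pixdim(vols[[1]])[1:3]
  out
}

#' Write a 3D volume as NIfTI
#'
#' @param volume 3D array.
#' @param path output file (`.nii` or `.nii.gz`).
#' @param spacing voxel dimensions in mm (identity affine scaled by these).
#' @return the path, invisibly.
#' @export
write_volume <- function(volume, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.numeric(volume), dim(volume)[1:3]))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

write_sidecar <- function(path, info) {
  jsonlite::write_json(info, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

config_hash <- function(config) {
  config$out <- NULL  # the output location is not part of the experiment
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Default pipeline configuration
#'
#' All reference defaults pre-filled; any element can be overridden via a
#' nested list or a YAML file with the same structure.
#'
#' @param seed master seed for every stage.
#' @param out output directory.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L, out = "segae_out") {
  list(
    seed = as.integer(seed),
    out = out,
    phantom = list(shape = c(48L, 48L, 48L), channels = 3L, materials = 4L,
                   lesion_fraction = 0.05, bias_amplitude = 0,
                   bias_smoothness = 12, noise_sd = 0, softness = 1),
    model = list(base_filters = 8L, n_scales = 3L, n_blocks = 2L,
                 lrelu_slope = 0.1),
    loss = list(alpha = 0.0075, include_laplacian = TRUE, epsilon = 1e-8),
    train = list(epochs = 80L, learning_rate = 0.001, beta1 = 0.9,
                 beta2 = 0.999, schedule_decay = 0.004, batch_size = 1L,
                 noise_sd = 0.05, scale_sd = 0.5,
                 patch_size = c(16L, 16L, 16L), stride = 8L,
                 keep_fraction = 0.5, rounds = 1L),
    infer = list(threshold = 0.5, min_voxels = 3L, connectivity = 26L,
                 patch_size = c(16L, 16L, 16L), stride = 8L)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  merge_config(default_config(), config)
}

.pipeline_paths <- function(out) {
  list(volumes = function(ch) file.path(out, sprintf("channel%02d.nii.gz", ch)),
       truth_map = function(m) file.path(out, sprintf("truth_%s.nii.gz", m)),
       truth_meta = file.path(out, "truth.json"),
       mask = file.path(out, "brain_mask.nii.gz"),
       checkpoint = file.path(out, "model.rds"),
       train_log = file.path(out, "training_log.csv"),
       soft_map = function(m) file.path(out, sprintf("pred_%s.nii.gz", m)),
       wmh = file.path(out, "pred_wmh_mask.nii.gz"),
       report = file.path(out, "evaluation.json"))
}

#' Run the segmentation pipeline
#'
#' Executes the requested stages in order on artifacts in the configured
#' output directory. `simulate` writes a phantom (volumes, ground-truth
#' maps, weights); `train` trains on the volumes in `out` (with
#' `config$train$rounds` refinement rounds; 1 = plain training); `predict`
#' writes soft maps and the binarized, size-filtered WMH mask; `evaluate`
#' compares the predicted mask with the ground-truth lesion mask and
#' writes a metric report. Every artifact gets a JSON provenance sidecar
#' (config hash, seed, package version). Reruns with identical
#' configuration and seed reproduce identical reports.
#'
#' @param config nested list or YAML path (see [default_config]).
#' @param stages ordered subset of `c("simulate", "train", "predict",
#'   "evaluate")`.
#' @return the evaluation report (if computed), invisibly otherwise.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "train", "predict", "evaluate")) {
  cfg <- load_config(config)
  out <- cfg$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- .pipeline_paths(out)
  prov <- list(config_hash = config_hash(cfg), seed = cfg$seed,
               package = as.character(utils::packageVersion("segae")))
  report <- NULL
  for (stage in stages) {
    if (stage == "simulate") {
      ph <- cfg$phantom
      sim <- segae_phantom(ph$shape, ph$channels, ph$materials,
                           ph$lesion_fraction, ph$bias_amplitude,
                           ph$bias_smoothness, ph$noise_sd, ph$softness,
                           seed = cfg$seed)
      for (ch in seq_len(ph$channels)) {
        write_volume(sim$volumes[, , , ch], paths$volumes(ch))
        write_sidecar(paths$volumes(ch), prov)
      }
      mats <- dimnames(sim$truth$material_maps)[[4]]
      for (m in seq_along(mats))
        write_volume(sim$truth$material_maps[, , , m], paths$truth_map(mats[m]))
      write_volume(sim$truth$brain_mask, paths$mask)
      jsonlite::write_json(
        list(mixing_weights = sim$truth$mixing_weights, materials = mats,
             seed = cfg$seed, parameters = ph),
        paths$truth_meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else if (stage == "train") {
      chfiles <- Sys.glob(file.path(out, "channel*.nii.gz"))
      if (length(chfiles) == 0)
        stop("train: no input volumes found in ", out,
             " (run the simulate stage or place channel*.nii.gz files)",
             call. = FALSE)
      vols <- read_volumes(chfiles)
      for (ch in seq_len(dim(vols)[4]))
        vols[, , , ch] <- normalize_intensity(vols[, , , ch])
      ncfg <- network_config(dim(vols)[4], cfg$phantom$materials,
                             base_filters = cfg$model$base_filters,
                             n_scales = cfg$model$n_scales,
                             n_blocks = cfg$model$n_blocks,
                             lrelu_slope = cfg$model$lrelu_slope)
      tcfg <- train_config(epochs = cfg$train$epochs,
                           learning_rate = cfg$train$learning_rate,
                           beta1 = cfg$train$beta1, beta2 = cfg$train$beta2,
                           schedule_decay = cfg$train$schedule_decay,
                           seed = cfg$seed, alpha = cfg$loss$alpha,
                           noise_sd = cfg$train$noise_sd,
                           scale_sd = cfg$train$scale_sd,
                           include_laplacian = cfg$loss$include_laplacian,
                           eps = cfg$loss$epsilon)
      fit <- iterative_refinement(vols, n_rounds = cfg$train$rounds,
                                  net_config = ncfg, train_cfg = tcfg,
                                  patch_size = cfg$train$patch_size,
                                  stride = cfg$train$stride,
                                  keep_fraction = cfg$train$keep_fraction,
                                  net_seed = cfg$seed)
      save_network(fit$network, paths$checkpoint)
      write_sidecar(paths$checkpoint, prov)
      utils::write.csv(fit$rounds[[length(fit$rounds)]]$log,
                       paths$train_log, row.names = FALSE)
    } else if (stage == "predict") {
      if (!file.exists(paths$checkpoint))
        stop("predict: missing checkpoint ", paths$checkpoint,
             " (run the train stage first)", call. = FALSE)
      chfiles <- Sys.glob(file.path(out, "channel*.nii.gz"))
      vols <- read_volumes(chfiles)
      for (ch in seq_len(dim(vols)[4]))
        vols[, , , ch] <- normalize_intensity(vols[, , , ch])
      net <- load_network(paths$checkpoint)
      S <- predict_volume(net, vols, cfg$infer$patch_size, cfg$infer$stride)
      roles <- assign_material_roles(net$params[["mix.W"]])
      for (r in names(roles)) {
        write_volume(S$maps[, , , roles[[r]]], paths$soft_map(r))
        write_sidecar(paths$soft_map(r), prov)
      }
      wmh <- binarize(S$maps[, , , roles$WMH], cfg$infer$threshold)
      wmh <- remove_small_components(wmh, cfg$infer$min_voxels,
                                     cfg$infer$connectivity)
      write_volume(wmh, paths$wmh)
      write_sidecar(paths$wmh, c(prov, list(threshold = cfg$infer$threshold,
                                            min_voxels = cfg$infer$min_voxels)))
    } else if (stage == "evaluate") {
      if (!file.exists(paths$wmh))
        stop("evaluate: missing predicted mask ", paths$wmh,
             " (run the predict stage first)", call. = FALSE)
      truth_file <- paths$truth_map("WMH")
      if (!file.exists(truth_file))
        stop("evaluate: missing reference lesion map ", truth_file, call. = FALSE)
      pred <- as.array(RNifti::readNifti(paths$wmh))
      tr <- as.array(RNifti::readNifti(truth_file))
      T_mask <- array(as.numeric(tr > 0.5), dim(tr))
      ev <- evaluate_lesions(T_mask, array(pred, dim(pred)[1:3]),
                             connectivity = cfg$infer$connectivity)
      report <- c(as.list(ev),
                  list(threshold = cfg$infer$threshold,
                       min_voxels = cfg$infer$min_voxels,
                       seed = cfg$seed, config_hash = prov$config_hash))
      jsonlite::write_json(report, paths$report, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    } else {
      stop("unknown stage: ", stage, call. = FALSE)
    }
  }
  if (is.null(report)) invisible(NULL) else invisible(report)
}
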