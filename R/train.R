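# Training protocol: Adam with Nesterov momentum (the Nadam update with a
# momentum schedule), seeded shuffling and augmentation, projected
# non-negativity of the mixing weights, per-epoch loss logging.

#' Training configuration
#'
#' Defaults follow the reference optimization protocol: 80 epochs, learning
#' rate 0.001, Adam with Nesterov momentum (beta1 0.9, beta2 0.999,
#' momentum schedule decay 0.004), batch size one, additive input noise
#' sd 0.05 and channel scaling sd 0.5 during augmentation.
#'
#' @param epochs number of passes over the selected patches.
#' @param learning_rate Nadam step size.
#' @param beta1,beta2 Nadam moment decay rates.
#' @param schedule_decay decay of the Nesterov momentum schedule.
#' @param batch_size must be 1 (the protocol trains with single patches).
#' @param seed integer seed controlling shuffling and augmentation.
#' @param alpha activity-regularization coefficient (default 0.0075).
#' @param noise_sd,scale_sd augmentation parameters; set `augment = FALSE`
#'   to disable augmentation entirely.
#' @param augment apply input augmentation each step.
#' @param include_laplacian include the Laplacian loss term.
#' @param eps cosine norm floor.
#' @param adam_eps denominator floor of the Nadam update.
#' @param verbose print the per-epoch loss.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 80L, learning_rate = 0.001, beta1 = 0.9,
                         beta2 = 0.999, schedule_decay = 0.004,
                         batch_size = 1L, seed = 1L, alpha = 0.0075,
                         noise_sd = 0.05, scale_sd = 0.5, augment = TRUE,
                         include_laplacian = TRUE, eps = 1e-8,
                         adam_eps = 1e-8, verbose = FALSE) {
  stopifnot(epochs >= 1L, learning_rate >= 0)
  if (batch_size != 1L)
    stop("only `batch_size = 1` is supported (the training protocol uses single patches)",
         call. = FALSE)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, schedule_decay = schedule_decay,
                 batch_size = 1L, seed = as.integer(seed), alpha = alpha,
                 noise_sd = noise_sd, scale_sd = scale_sd, augment = augment,
                 include_laplacian = include_laplacian, eps = eps,
                 adam_eps = adam_eps, verbose = verbose),
            class = "train_config")
}

nadam_init <- function(params, cfg) {
  list(t = 0L, msched = 1,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       lr = cfg$learning_rate, b1 = cfg$beta1, b2 = cfg$beta2,
       sd = cfg$schedule_decay, eps = cfg$adam_eps)
}

# One Nadam step (Keras-1 formulation with momentum schedule):
#   mu_t   = b1 * (1 - 0.5 * 0.96^(t * sd))
#   m      = b1*m + (1-b1)*g ;  v = b2*v + (1-b2)*g^2
#   mbar   = (1-mu_t) * g/(1-prod(mu_1..t)) + mu_{t+1} * m/(1-prod(mu_1..t+1))
#   p     -= lr * mbar / (sqrt(v/(1-b2^t)) + eps)
nadam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  t <- opt$t
  mu_t <- opt$b1 * (1 - 0.5 * 0.96^(t * opt$sd))
  mu_t1 <- opt$b1 * (1 - 0.5 * 0.96^((t + 1) * opt$sd))
  msched_new <- opt$msched * mu_t
  msched_next <- msched_new * mu_t1
  opt$msched <- msched_new
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$b1 * opt$m[[nm]] + (1 - opt$b1) * g
    opt$v[[nm]] <- opt$b2 * opt$v[[nm]] + (1 - opt$b2) * g * g
    gp <- g / (1 - msched_new)
    mp <- opt$m[[nm]] / (1 - msched_next)
    mbar <- (1 - mu_t) * gp + mu_t1 * mp
    vhat <- opt$v[[nm]] / (1 - opt$b2^t)
    params[[nm]] <- params[[nm]] - opt$lr * mbar / (sqrt(vhat) + opt$eps)
  }
  list(opt = opt, params = params)
}

# Per-term loss of one patch plus all parameter gradients.
train_step_grads <- function(network, input, target, mask, cfg, lap_target) {
  fwd <- segae_forward(network, input, mask = mask, training = TRUE,
                       want_cache = TRUE)
  d3 <- dim(target)[1:3]; C <- dim(target)[4]
  Ym <- as_mat(target); Yh <- as_mat(fwd$reconstruction)
  recon <- 0; lap <- 0
  G <- matrix(0, nrow(Ym), C)
  for (cc in seq_len(C)) {
    recon <- recon - cosine_proximity(Ym[, cc], Yh[, cc], cfg$eps) / C
    g <- cosine_proximity_grad(Ym[, cc], Yh[, cc], cfg$eps)
    if (cfg$include_laplacian) {
      ky <- lap_target[[cc]]
      kh <- laplacian_filter(array(Yh[, cc], d3))
      lap <- lap - cosine_proximity(ky, kh, cfg$eps) / C
      gl <- cosine_proximity_grad(ky, kh, cfg$eps)
      g <- g + as.numeric(laplacian_filter(array(gl, d3)))
    }
    G[, cc] <- -g / C
  }
  Smat <- as_mat(fwd$S)
  reg <- activity_regularizer(Smat, cfg$alpha, cfg$eps)
  dS <- if (cfg$alpha > 0)
    activity_regularizer_grad(Smat, cfg$alpha, cfg$eps) else NULL
  grads <- segae_backward(network, fwd, G, dS)
  list(grads = grads, bn_stats = fwd$bn_stats,
       terms = c(recon = recon, laplace = lap, regularizer = reg,
                 total = recon + lap + reg))
}

#' Train the autoencoder
#'
#' One epoch is a seeded-shuffle pass over the selected patches. Each step
#' augments the input patch (noise, then per-channel scaling), runs the
#' forward/backward pass against the clean target patch, applies one Nadam
#' update, and clips the mixing weights at zero (projected gradient). The
#' brainmask is taken from the clean input patch. Targets may differ from
#' inputs (bias-corrected or enhanced volumes); their patch origins must
#' match the input origins one-to-one.
#'
#' @param network a built `segae_network` (see [build_network()]).
#' @param inputs a [patch_set][extract_patches] of input patches.
#' @param targets a `patch_set` of reconstruction targets (default: the
#'   inputs themselves).
#' @param config a [train_config].
#' @return list with `network` (trained; batch-norm running statistics
#'   updated) and `log` (data.frame: epoch, recon, laplace, regularizer,
#'   total). Deterministic under a fixed seed.
#' @export
train_segae <- function(network, inputs, targets = inputs,
                        config = train_config()) {
  stopifnot(inherits(network, "segae_network"),
            inherits(inputs, "patch_set"), inherits(targets, "patch_set"),
            inherits(config, "train_config"))
  if (!identical(unname(inputs$origins), unname(targets$origins)))
    stop("input and target patch sets are misaligned (origins differ)",
         call. = FALSE)
  n <- length(inputs$patches)
  params <- network$params
  state <- network$state
  opt <- nadam_init(params, config)
  mom <- network$config$bn_momentum
  # Precompute per-patch masks and target Laplacians once.
  masks <- lapply(inputs$patches, brainmask_from)
  lap_targets <- if (config$include_laplacian) {
    lapply(targets$patches, function(p) {
      d3 <- dim(p)[1:3]
      lapply(seq_len(dim(p)[4]), function(cc)
        laplacian_filter(array(p[, , , cc], d3)))
    })
  } else rep(list(NULL), n)
  log_rows <- matrix(NA_real_, config$epochs, 4L)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      terms_acc <- c(recon = 0, laplace = 0, regularizer = 0, total = 0)
      for (i in ord) {
        inp <- inputs$patches[[i]]
        if (config$augment)
          inp <- augment_draw(inp, config$noise_sd, config$scale_sd)
        network$params <- params
        step <- train_step_grads(network, inp, targets$patches[[i]],
                                 masks[[i]], config, lap_targets[[i]])
        if (config$learning_rate > 0) {
          upd <- nadam_step(opt, params, step$grads)
          opt <- upd$opt; params <- upd$params
          params[["mix.W"]] <- pmax(params[["mix.W"]], 0)
        }
        for (nm in names(step$bn_stats)) {
          state[[paste0(nm, ".rmean")]] <-
            mom * state[[paste0(nm, ".rmean")]] + (1 - mom) * step$bn_stats[[nm]]$mu
          state[[paste0(nm, ".rvar")]] <-
            mom * state[[paste0(nm, ".rvar")]] + (1 - mom) * step$bn_stats[[nm]]$vv
        }
        terms_acc <- terms_acc + step$terms
      }
      log_rows[ep, ] <- terms_acc / n
      if (config$verbose)
        message(sprintf("epoch %3d  total %.5f", ep, log_rows[ep, 4]))
    }
  })
  network$params <- params
  network$state <- state
  network$trained <- TRUE
  log <- data.frame(epoch = seq_len(config$epochs),
                    recon = log_rows[, 1], laplace = log_rows[, 2],
                    regularizer = log_rows[, 3], total = log_rows[, 4])
  list(network = network, log = log)
}
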