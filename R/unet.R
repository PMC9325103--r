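## U-net construction and training. The network itself (convolutions,
## pooling, up-convolutions, softmax, backprop, Adam) lives in compiled
## code; this file owns the training protocol: per-step patch sampling,
## augmentation, loss evaluation through the losses module, validation
## tracking and early stopping, and k-fold cross-validation.

#' Training configuration
#'
#' Hyper-parameters of the patch-based training protocol. Defaults follow
#' the reference protocol: Adam at learning rate 1e-4 (beta1 0.9,
#' beta2 0.999), batches of 20 patches drawn from 4 training images,
#' 128 x 128 patches through 4 pooling stages, dropout keep-probability 0.8
#' in the two deepest encoder blocks, at most 100 epochs with early
#' stopping, 10-fold cross-validation.
#'
#' `base_filters` sets the channel width of the first encoder stage
#' (doubling at each stage); 16 is the CPU-scale default. An "epoch" is
#' `steps_per_epoch` optimisation steps; validation Dice is measured once
#' per epoch on held-out patches.
#'
#' @param learning_rate Adam step size
#' @param adam_beta1,adam_beta2 Adam moment decay rates
#' @param batch_patches patches per optimisation step
#' @param images_per_step training volumes drawn (without replacement) per step
#' @param max_epochs epoch cap
#' @param steps_per_epoch optimisation steps per epoch
#' @param early_stop_patience epochs without validation improvement before
#'   stopping
#' @param dropout_keep_p unit keep-probability in `(0, 1]`
#' @param patch_size square patch side; must be divisible by
#'   `2^pooling_stages` and at least 16
#' @param pooling_stages down-/up-sampling stages (fixed architecture: 4)
#' @param base_filters channels of the first stage
#' @param loss_recipe one of `wce`, `dice`, `wce+dice`, `ftl`, `dice+boundary`
#' @param boundary_ramp ramp the boundary member linearly from 0 to 1 over
#'   the epochs (only used by `dice+boundary`)
#' @param rotation_deg_range,scale_range,noise_sd_hu augmentation settings
#' @param epsilon,tversky_alpha,tversky_beta,gamma loss hyper-parameters
#' @param k_folds folds for [crossvalidate()]
#' @param val_fraction fraction of the training cohort held out for the
#'   early-stopping validation set when none is supplied
#' @param seed master RNG seed
#' @return a `train_config` list
#' @export
train_config <- function(learning_rate = 1e-4, adam_beta1 = 0.9, adam_beta2 = 0.999,
                         batch_patches = 20L, images_per_step = 4L,
                         max_epochs = 100L, steps_per_epoch = 20L,
                         early_stop_patience = 10L,
                         dropout_keep_p = 0.8, patch_size = 128L,
                         pooling_stages = 4L, base_filters = 16L,
                         loss_recipe = "wce+dice", boundary_ramp = FALSE,
                         rotation_deg_range = c(-10, 10), scale_range = c(0.9, 1.1),
                         noise_sd_hu = 10,
                         epsilon = 1e-6, tversky_alpha = 0.7, tversky_beta = 0.3,
                         gamma = 4 / 3,
                         k_folds = 10L, val_fraction = 1 / 6, seed = 1L) {
  cfg <- list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
              adam_beta2 = adam_beta2, batch_patches = as.integer(batch_patches),
              images_per_step = as.integer(images_per_step),
              max_epochs = as.integer(max_epochs),
              steps_per_epoch = as.integer(steps_per_epoch),
              early_stop_patience = as.integer(early_stop_patience),
              dropout_keep_p = dropout_keep_p, patch_size = as.integer(patch_size),
              pooling_stages = as.integer(pooling_stages),
              base_filters = as.integer(base_filters),
              loss_recipe = loss_recipe, boundary_ramp = boundary_ramp,
              rotation_deg_range = rotation_deg_range, scale_range = scale_range,
              noise_sd_hu = noise_sd_hu,
              epsilon = epsilon, tversky_alpha = tversky_alpha,
              tversky_beta = tversky_beta, gamma = gamma,
              k_folds = as.integer(k_folds), val_fraction = val_fraction,
              seed = as.integer(seed))
  class(cfg) <- "train_config"
  validate_train_config(cfg)
  cfg
}

#' @rdname train_config
#' @param cfg object to validate
#' @export
validate_train_config <- function(cfg) {
  div <- 2^cfg$pooling_stages
  if (cfg$patch_size %% div != 0)
    stop("patch_size ", cfg$patch_size, " is not divisible by 2^pooling_stages = ",
         div, " (four pooling stages each halve the grid)")
  if (cfg$patch_size < 16L) stop("patch_size must be at least 16, the architectural minimum")
  if (cfg$dropout_keep_p <= 0 || cfg$dropout_keep_p > 1)
    stop("dropout_keep_p must lie in (0, 1]")
  if (!cfg$loss_recipe %in% .loss_recipes)
    stop("unknown loss recipe '", cfg$loss_recipe, "'")
  invisible(cfg)
}

#' Build an (untrained) U-net segmentation model
#'
#' Encoder-decoder with 4 down-sampling and 4 up-sampling stages, skip
#' connections by concatenation, channel width doubling per stage from
#' `base_filters`, and a per-pixel softmax over the 9 classes. Weights are
#' drawn from a truncated Glorot (Xavier) normal,
#' `sd = sqrt(2 / (fan_in + fan_out))`; identical seeds give identical
#' initial weights.
#'
#' @param config a [train_config()]
#' @return a `seg_model`
#' @export
build_unet <- function(config = train_config()) {
  validate_train_config(config)
  ptr <- unet_create(config$base_filters, n_classes(), config$seed)
  structure(list(ptr = ptr, config = config, scheme = class_scheme(),
                 class_weights = rep(1, n_classes()),
                 log = data.frame()),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("seg_model: 2D U-net, base_filters %d, %s parameters, loss '%s'%s\n",
              x$config$base_filters,
              format(unet_n_params(x$ptr), big.mark = ","),
              x$config$loss_recipe,
              if (nrow(x$log)) sprintf(", trained %d epochs (best val Dice %.3f)",
                                       max(x$log$epoch), max(x$log$val_dice))
              else " (untrained)"))
  invisible(x)
}

#' Run the network on a batch of patches
#'
#' @param model a `seg_model`
#' @param patches list of square patch matrices (windowed intensities), or a
#'   single matrix
#' @return array `(H, W, 9, n)` of per-pixel class probabilities
#' @export
predict_patches <- function(model, patches) {
  if (is.matrix(patches)) patches <- list(patches)
  H <- nrow(patches[[1]])
  x <- vapply(patches, as.numeric, numeric(H * H))
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  pr <- unet_forward(model$ptr, x, H, FALSE, 1.0)
  array(pr, c(H, H, n_classes(), length(patches)))
}

## flatten (HW, C, n) probability array to a (HW*n, C) pixel-row matrix and
## back (samples stacked in row blocks)
.probs_to_mat <- function(pr) {
  d <- dim(pr)
  matrix(aperm(pr, c(1, 3, 2)), nrow = d[1] * d[3], ncol = d[2])
}
.mat_to_probs <- function(m, HW, C, n) {
  aperm(array(m, c(HW, n, C)), c(1, 3, 2))
}

.onehot <- function(labels_vec, C) {
  m <- matrix(0, length(labels_vec), C)
  m[cbind(seq_along(labels_vec), as.integer(labels_vec) + 1L)] <- 1
  m
}

## signed distance maps for a label patch, zero-filled for degenerate classes
.phi_patch <- function(lab, C) {
  HW <- length(lab)
  phi <- matrix(0, HW, C)
  for (c in seq_len(C - 1)) {
    mask <- lab == c
    if (any(mask) && !all(mask))
      phi[, c + 1L] <- as.numeric(signed_distance_map(matrix(mask, nrow = sqrt(HW))))
  }
  phi
}

## assemble one training batch (x matrix, onehot, phi) from studies
.draw_batch <- function(studies, cfg, step_seed, need_phi) {
  restore <- .seed_guard(step_seed)
  on.exit(restore())
  n_img <- min(cfg$images_per_step, length(studies))
  picks <- sample.int(length(studies), n_img)
  per <- ceiling(cfg$batch_patches / n_img)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_img)
  patches <- list(); labs <- list()
  for (i in seq_len(n_img)) {
    st <- studies[[picks[i]]]
    ps <- sample_patches(st$vol, st$lab, per, cfg$patch_size, seed = seeds[i])
    ps <- augment(ps, seed = seeds[n_img + i],
                  rotation_deg_range = cfg$rotation_deg_range,
                  scale_range = cfg$scale_range, noise_sd_hu = cfg$noise_sd_hu)
    patches <- c(patches, ps$images)
    labs <- c(labs, ps$labels)
  }
  keep <- seq_len(min(cfg$batch_patches, length(patches)))
  list(images = patches[keep], labels = labs[keep])
}

#' Train a U-net segmentation model
#'
#' Adam optimisation of the configured loss recipe. Each step draws
#' `batch_patches` augmented patches from `images_per_step` training volumes
#' (balanced orbit/non-orbit sampling); class weights for the weighted
#' cross-entropy are the inverse relative class frequencies of the training
#' labels. After each epoch the macro-Dice over muscle classes is measured
#' on a fixed set of validation patches; training stops at `max_epochs` or
#' when validation Dice has not improved for `early_stop_patience` epochs,
#' and the best-epoch weights are restored.
#'
#' @param model a `seg_model` from [build_unet()]
#' @param train_studies list of studies; each a list with `vol` (windowed,
#'   isometrically resampled [ct_volume()]) and `lab` (aligned
#'   [label_volume()]); see [prepare_study()]
#' @param val_studies validation studies in the same form; if `NULL`, a
#'   `val_fraction` share of `train_studies` is held out
#' @param config a [train_config()]; defaults to the model's
#' @param verbose print per-epoch progress
#' @return the trained `seg_model` (training log in `$log`)
#' @export
train <- function(model, train_studies, val_studies = NULL, config = NULL,
                  verbose = interactive()) {
  stopifnot(inherits(model, "seg_model"))
  cfg <- config %||% model$config
  validate_train_config(cfg)
  if (length(train_studies) == 0) stop("empty training set")
  if (is.null(val_studies)) {
    restore <- .seed_guard(cfg$seed + 1L)
    n_val <- max(1L, round(length(train_studies) * cfg$val_fraction))
    vi <- sample.int(length(train_studies), n_val)
    restore()
    val_studies <- train_studies[vi]
    train_studies <- train_studies[-vi]
    if (length(train_studies) == 0) stop("training set too small to hold out validation studies")
  }

  model$class_weights <- class_weights_from_labels(
    lapply(train_studies, function(s) s$lab$labels))

  ## fixed validation patches (orbit-balanced, not augmented)
  restore <- .seed_guard(cfg$seed + 2L)
  vseeds <- sample.int(.Machine$integer.max - 1L, length(val_studies))
  step_seeds <- sample.int(.Machine$integer.max - 1L,
                           cfg$max_epochs * cfg$steps_per_epoch)
  restore()
  vp <- lapply(seq_along(val_studies), function(i)
    sample_patches(val_studies[[i]]$vol, val_studies[[i]]$lab,
                   max(2L, ceiling(cfg$batch_patches / length(val_studies))),
                   cfg$patch_size, seed = vseeds[i]))
  val_imgs <- unlist(lapply(vp, `[[`, "images"), recursive = FALSE)
  val_labs <- unlist(lapply(vp, `[[`, "labels"), recursive = FALSE)

  need_phi <- grepl("boundary", cfg$loss_recipe)
  C <- n_classes(); HW <- cfg$patch_size^2
  best <- list(dice = -Inf, weights = NULL, epoch = 0L)
  log <- NULL
  step_i <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    bw <- if (need_phi && cfg$boundary_ramp) (epoch - 1) / max(1, cfg$max_epochs - 1) else 1
    ep_loss <- c(); ep_members <- NULL
    for (s in seq_len(cfg$steps_per_epoch)) {
      step_i <- step_i + 1L
      b <- .draw_batch(train_studies, cfg, step_seeds[step_i], need_phi)
      n <- length(b$images)
      x <- vapply(b$images, as.numeric, numeric(HW))
      pr <- unet_forward(model$ptr, x, cfg$patch_size, TRUE, cfg$dropout_keep_p)
      lab_vec <- unlist(b$labels, use.names = FALSE)
      onehot <- .onehot(lab_vec, C)
      phi <- if (need_phi) do.call(rbind, lapply(b$labels, .phi_patch, C = C)) else NULL
      batch <- loss_batch(.probs_to_mat(array(pr, c(HW, C, n))), onehot,
                          class_weights = model$class_weights,
                          epsilon = cfg$epsilon, tversky_alpha = cfg$tversky_alpha,
                          tversky_beta = cfg$tversky_beta, gamma = cfg$gamma,
                          phi = phi, validate = FALSE)
      lg <- loss_grad(batch, cfg$loss_recipe, boundary_weight = bw)
      if (!is.finite(lg$loss))
        stop("training aborted: loss diverged to a non-finite value at epoch ",
             epoch, ", step ", s)
      unet_backward(model$ptr, .mat_to_probs(lg$grad, HW, C, n))
      unet_adam_step(model$ptr, cfg$learning_rate, cfg$adam_beta1,
                     cfg$adam_beta2, 1e-8)
      ep_loss <- c(ep_loss, lg$loss)
      ep_members <- rbind(ep_members, lg$members)
    }
    vd <- .patch_macro_dice(model, val_imgs, val_labs)
    mem <- colMeans(ep_members)
    row <- data.frame(epoch = epoch, loss = mean(ep_loss), val_dice = vd)
    for (nm in names(mem)) row[[paste0("loss_", nm)]] <- mem[[nm]]
    log <- rbind(log, row)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val macro-Dice %.4f", epoch, mean(ep_loss), vd))
    if (vd > best$dice + 1e-4) {
      best <- list(dice = vd, weights = unet_get_weights(model$ptr), epoch = epoch)
    } else if (epoch - best$epoch >= cfg$early_stop_patience) {
      break
    }
  }
  if (!is.null(best$weights)) unet_set_weights(model$ptr, best$weights)
  model$log <- log
  model$config <- cfg
  model
}

## hard macro-Dice over muscle classes present in a patch set
.patch_macro_dice <- function(model, imgs, labs) {
  pr <- predict_patches(model, imgs)
  d <- dim(pr)
  pred <- max.col(matrix(aperm(pr, c(1, 2, 4, 3)), ncol = d[3]), "first") - 1L
  dim(pred) <- d[c(1, 2, 4)]
  truth <- simplify2array(labs)
  if (length(dim(pred)) == 2L) dim(pred) <- c(dim(pred), 1L)
  d <- c()
  for (cls in muscle_classes()) {
    g <- truth == cls; p <- pred == cls
    if (!any(g)) next
    d <- c(d, 2 * sum(p & g) / (sum(p) + sum(g)))
  }
  if (length(d)) mean(d) else NA_real_
}

#' Preprocess a CT/label pair for training or inference
#'
#' Isometric resampling to `target_mm`, matched nearest-neighbour label
#' resampling, and display windowing — the preprocessing applied before any
#' patch is drawn.
#'
#' @param ct a [ct_volume()] in HU
#' @param labels aligned [label_volume()] (optional for pure inference)
#' @param target_mm isometric pixel size (default 1 mm)
#' @param level,width display window (defaults 50/250 HU)
#' @return list with `vol` (windowed resampled volume), `lab` (or `NULL`)
#'   and `native` (the original inputs, for later restoration)
#' @export
prepare_study <- function(ct, labels = NULL, target_mm = 1.0, level = 50, width = 250) {
  vol <- window_hu(resample_isometric(ct, target_mm), level, width)
  lab <- if (!is.null(labels)) resample_labels(labels, target_mm) else NULL
  list(vol = vol, lab = lab, native = list(ct = ct, labels = labels))
}

#' Serialise / restore a trained model
#'
#' Checkpoints carry the weights, the training configuration, the class
#' scheme and the training log.
#'
#' @param model a `seg_model`
#' @param path checkpoint file (`.rds`)
#' @return `path` (or the restored `seg_model` for `load_model`)
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "seg_model"))
  saveRDS(list(weights = unet_get_weights(model$ptr), config = model$config,
               scheme = model$scheme, class_weights = model$class_weights,
               log = model$log), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  model <- build_unet(obj$config)
  unet_set_weights(model$ptr, obj$weights)
  model$class_weights <- obj$class_weights
  model$log <- obj$log
  model$scheme <- obj$scheme
  model
}

#' k-fold partition of study indices
#'
#' Partitions `n` studies into `k` folds whose sizes differ by at most one;
#' every study appears in exactly one fold.
#'
#' @param n number of studies
#' @param k number of folds
#' @param seed RNG seed for the shuffle
#' @return list of `k` integer index vectors
#' @export
kfold_split <- function(n, k, seed = 1L) {
  if (n < k) stop("cohort of size ", n, " is smaller than k = ", k)
  restore <- .seed_guard(seed)
  on.exit(restore())
  idx <- sample.int(n)
  # near-equal fold sizes: floor/ceil(n/k)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(idx, rep(seq_len(k), times = sizes))
}

#' k-fold cross-validation
#'
#' Repeats training `k` times on a k-way partition of the cohort, each fold
#' serving exactly once as the validation set; reports per-fold per-class
#' validation Dice and the aggregate mean and standard deviation per class.
#'
#' @param cohort list of studies (as for [train()])
#' @param config a [train_config()]
#' @param verbose print progress
#' @return list with `folds` (per-fold index vectors), `per_fold`
#'   (data.frame of per-fold per-class Dice) and `aggregate` (mean and sd
#'   per class across folds)
#' @export
crossvalidate <- function(cohort, config = train_config(), verbose = interactive()) {
  k <- config$k_folds
  folds <- kfold_split(length(cohort), k, seed = config$seed)
  per_fold <- NULL
  for (fi in seq_len(k)) {
    val_idx <- folds[[fi]]
    model <- build_unet(config)
    model <- train(model, cohort[-val_idx], cohort[val_idx], config,
                   verbose = FALSE)
    for (vi in val_idx) {
      st <- cohort[[vi]]
      pred <- predict_volume(model, st$vol, prepared = TRUE,
                             stride = max(1L, config$patch_size %/% 2L))
      for (cls in muscle_classes()) {
        di <- dice_iou(pred, st$lab, cls)
        per_fold <- rbind(per_fold,
                          data.frame(fold = fi, study = vi, class = cls,
                                     dice = di[1], iou = di[2]))
      }
    }
    if (verbose) message("fold ", fi, "/", k, " done")
  }
  agg <- stats::aggregate(cbind(dice, iou) ~ class, per_fold,
                          function(x) c(mean = mean(x, na.rm = TRUE),
                                        sd = stats::sd(x, na.rm = TRUE)))
  list(folds = folds, per_fold = per_fold, aggregate = agg)
}
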