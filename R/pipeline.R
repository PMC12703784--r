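# The two-phase training protocol. Phase 1 pre-trains the style VAE on
# style vectors pooled from both domains' first-stage features. Phase 2
# freezes the VAE and trains the segmentation backbone on labelled
# laboratory images: each batch's first-stage features are stochastically
# re-styled (latent draw -> decoded statistics -> moment injection), then
# adversarially normalized with learnable statistics that ascend the task
# loss through the gradient reversal contract, and the head is supervised
# with pixel cross-entropy plus the consistency penalty.

#' Training configuration
#'
#' Defaults are the desk-scale profile of the training protocol: the
#' full-scale protocol uses 20,000 segmentation iterations at batch size
#' 64; the desk profile scales iteration counts by 0.1 and the batch to 8
#' so a full run trains in minutes on one CPU. Rates are the protocol's: model learning
#' rate 0.03 (SGD, phase 2), style perturbation rate 0.01 (the
#' adversarial-statistics step size), consistency weight 0.8.
#'
#' @param n_iterations phase-2 iterations.
#' @param model_lr phase-2 SGD learning rate (alpha).
#' @param phi adversarial-statistics update step (beta, the style
#'   perturbation rate).
#' @param lambda_consist consistency-loss weight (applies when the
#'   adversarial module is active).
#' @param batch_size images per phase-2 batch.
#' @param lambda_grl gradient reversal coefficient.
#' @param grl_schedule `"constant"` or `"linear-ramp"`.
#' @param vae_iterations,vae_lr,vae_batch phase-1 (Adam) settings.
#' @param latent_dim,hidden_width style VAE architecture.
#' @param channels backbone stage widths.
#' @param use_rain stochastic style transfer on.
#' @param use_dgb adversarial normalization on.
#' @param use_adain_fixed deterministic style transfer using the statistics
#'   of one randomly paired style image per batch (no VAE); mutually
#'   exclusive with `use_rain`.
#' @param style_source where phase-2 styles come from: `"field"` encodes
#'   the style vectors of randomly drawn style-pool images and samples
#'   their latent posteriors by reparameterization (the default), `"prior"`
#'   decodes standard-normal latent draws.
#' @param dgb_stage backbone stage (1 or 2) whose features the adversarial
#'   shift perturbs; default 1, the same stage the style injection acts on.
#' @param augment training-time augmentation on.
#' @param eps moment stabilizer.
#' @param seed master seed; every random choice in both phases derives
#'   from it.
#' @return An object of class `"seg_config"`.
#' @export
seg_config <- function(n_iterations = 2000L, model_lr = 0.03, phi = 0.01,
                       lambda_consist = 0.8, batch_size = 8L,
                       lambda_grl = 1, grl_schedule = "constant",
                       vae_iterations = 200L, vae_lr = 1e-3,
                       vae_batch = 16L, latent_dim = 64L,
                       hidden_width = 256L, channels = c(16L, 16L, 16L),
                       use_rain = TRUE, use_dgb = TRUE,
                       use_adain_fixed = FALSE,
                       style_source = c("field", "prior"),
                       dgb_stage = 1L, augment = TRUE,
                       eps = 1e-5, seed = 1L) {
  style_source <- match.arg(style_source)
  if (!dgb_stage %in% 1:2)
    stop("`dgb_stage` must be 1 or 2", call. = FALSE)
  if (model_lr <= 0 || phi <= 0 || vae_lr <= 0)
    stop("learning rates must be positive", call. = FALSE)
  if (lambda_consist < 0) stop("`lambda_consist` must be >= 0", call. = FALSE)
  if (use_rain && use_adain_fixed)
    stop("at most one of `use_rain` and `use_adain_fixed` may be active",
         call. = FALSE)
  structure(as.list(environment()), class = "seg_config")
}

# class-presence matrix straight from the masks (foreground classes)
mask_presence <- function(masks, n_classes) {
  N <- dim(masks)[3]
  t(vapply(seq_len(N), function(i) {
    m <- masks[, , i]
    vapply(seq_len(n_classes - 1L), function(k) any(m == k), logical(1))
  }, logical(n_classes - 1L)))
}

# standardized training batch with optional augmentation (raw [0,1] images);
# the augmentation kernel fuses the channel standardization into its final
# pass, so the random draw sequence is identical to augment()'s
assemble_batch <- function(data, idx, do_augment = TRUE) {
  d <- dim(data$images)
  B <- length(idx)
  x <- array(0, c(d[1], d[2], B, 3))
  y <- array(0L, c(d[1], d[2], B))
  for (b in seq_len(B)) {
    img <- data$images[, , , idx[b]]
    msk <- data$masks[, , idx[b]]
    if (do_augment) {
      flip <- stats::runif(1) < 0.5
      ang <- stats::runif(1, -15, 15)
      fb <- stats::runif(1, 0.8, 1.2)
      fc <- stats::runif(1, 0.8, 1.2)
      fs <- stats::runif(1, 0.8, 1.2)
      dh <- stats::runif(1, -0.1, 0.1)
      au <- cpp_augment(img, msk, d[1], d[2], flip, ang * pi / 180,
                        fb, fc, fs, dh, IGNORE_LABEL,
                        IMAGENET_MEAN, IMAGENET_SD)
      x[, , b, ] <- au$image
      y[, , b] <- au$mask
    } else {
      for (ch in 1:3)
        x[, , b, ch] <- (img[, , ch] - IMAGENET_MEAN[ch]) / IMAGENET_SD[ch]
      y[, , b] <- msk
    }
  }
  list(x = x, y = y)
}

#' Phase 1: pre-train the style VAE on pooled domain features
#'
#' Style vectors are the channel statistics of first-stage backbone
#' features from the combined laboratory + field image pool; a subset of
#' laboratory feature maps serves as content for the content/style loss
#' terms. The backbone itself is not trained here.
#'
#' @param vae a [style_vae()].
#' @param model the [seg_backbone()] providing the feature space.
#' @param lab_data,field_data `"seg_dataset"` objects (field labels are
#'   never used -- only the images' style statistics).
#' @param cfg a [seg_config()].
#' @param weights a [rain_weights()] object.
#' @return The trained `"style_vae"` (with its loss `trace`).
#' @export
train_rain_phase <- function(vae, model, lab_data, field_data, cfg,
                             weights = rain_weights()) {
  stopifnot(inherits(vae, "style_vae"), inherits(model, "seg_backbone"))
  if (dim(lab_data$images)[4] < 1L || dim(field_data$images)[4] < 1L)
    stop("both domains must be nonempty", call. = FALSE)
  f_lab <- stage1_features(model, lab_data$images)
  f_field <- stage1_features(model, field_data$images)
  n_lab <- dim(f_lab)[3]; n_field <- dim(f_field)[3]
  all_f <- array(0, c(dim(f_lab)[1], dim(f_lab)[2], n_lab + n_field,
                      dim(f_lab)[4]))
  all_f[, , seq_len(n_lab), ] <- f_lab
  all_f[, , n_lab + seq_len(n_field), ] <- f_field
  st <- cs_fwd(all_f, cfg$eps)
  sv <- cbind(st$mu, st$sigma)
  n_content <- min(64L, n_lab)
  content <- to_bchw(f_lab[, , seq_len(n_content), , drop = FALSE])
  train_style_vae(vae, sv, content, weights,
                  n_iter = cfg$vae_iterations, lr = cfg$vae_lr,
                  batch_size = cfg$vae_batch, seed = cfg$seed + 1L,
                  eps = cfg$eps)
}

#' Phase 2: train the segmentation model inside the full framework
#'
#' Per iteration: a stratified batch of laboratory images is augmented and
#' standardized; first-stage features are stochastically re-styled by the
#' frozen VAE (a latent prior draw decoded to channel statistics and
#' moment-injected); second-stage features pass through the adversarial
#' instance-normalization layer; the model descends
#' `L_task + lambda * L_consist` by SGD while the adversarial statistics
#' ascend the task loss through the gradient reversal contract. The VAE is
#' bit-identical before and after. With every module disabled the loop
#' reduces exactly to plain supervised training.
#'
#' @param model a [seg_backbone()].
#' @param vae frozen [style_vae()] (may be `NULL` when `use_rain` is off).
#' @param adv [adversarial_stats()] (may be `NULL` when `use_dgb` is off).
#' @param lab_data labelled `"seg_dataset"` used for supervision.
#' @param cfg a [seg_config()].
#' @param style_data optional `"seg_dataset"` supplying style images for
#'   the deterministic AdaIN variant.
#' @return List with the trained `model`, final `adv`, and a per-iteration
#'   `trace` data frame (`loss`, `task`, `consist`).
#' @export
train_segmentation_phase <- function(model, vae, adv, lab_data, cfg,
                                     style_data = NULL) {
  stopifnot(inherits(model, "seg_backbone"), inherits(cfg, "seg_config"))
  use_rain <- isTRUE(cfg$use_rain)
  use_dgb <- isTRUE(cfg$use_dgb)
  use_adain <- isTRUE(cfg$use_adain_fixed)
  if (use_rain && is.null(vae)) stop("`vae` required", call. = FALSE)
  if (use_adain && is.null(style_data))
    stop("`style_data` required for the fixed-style variant", call. = FALSE)
  if ((use_rain && identical(cfg$style_source, "field")) || use_adain) {
    if (is.null(style_data))
      stop("`style_data` images are required as the style source",
           call. = FALSE)
  }
  flat <- bb_flat_params(model)
  grl_cfg <- grl_config(cfg$lambda_grl, cfg$phi, cfg$grl_schedule)
  presence <- mask_presence(lab_data$masks, model$n_classes)
  trace <- matrix(NA_real_, cfg$n_iterations, 3,
                  dimnames = list(NULL, c("loss", "task", "consist")))
  n_style <- if (is.null(style_data)) 0L else dim(style_data$images)[4]
  # style statistics of every pool image, extracted once with the frozen
  # phase-1 feature extractor (the stylizer is frozen in phase 2)
  pool_mu <- pool_sigma <- NULL
  if (n_style > 0L && (use_adain ||
                       (use_rain && identical(cfg$style_source, "field")))) {
    fs <- stage1_features(model, style_data$images)
    stp <- cs_fwd(fs, cfg$eps)
    pool_mu <- stp$mu
    pool_sigma <- stp$sigma
  }
  ws <- new.env(parent = emptyenv())
  with_seed(cfg$seed + 2L, function() {
    next_batch <- stratified_batches(presence, cfg$batch_size)
    for (it in seq_len(cfg$n_iterations)) {
      idx <- next_batch()
      ba <- assemble_batch(lab_data, idx, cfg$augment)
      B <- length(idx)
      style_target <- NULL
      if (use_rain) {
        if (identical(cfg$style_source, "field")) {
          si <- sample.int(n_style, B, replace = TRUE)
          dist <- encode_style(vae, cbind(pool_mu[si, , drop = FALSE],
                                          pool_sigma[si, , drop = FALSE]))
          z <- sample_latent(dist)
        } else {
          z <- matrix(stats::rnorm(B * vae$latent_dim), B, vae$latent_dim)
        }
        style_target <- split_style_vector(decode_style(vae, z), cfg$eps)
      } else if (use_adain) {
        si <- sample.int(n_style, 1L)
        style_target <- as_channel_stats(
          matrix(pool_mu[si, ], B, ncol(pool_mu), byrow = TRUE),
          matrix(pool_sigma[si, ], B, ncol(pool_sigma), byrow = TRUE),
          cfg$eps)
      }
      res <- seg_step(flat, model, ba$x, ba$y,
                      style_target = style_target,
                      adv = if (use_dgb) adv else NULL,
                      lambda_consist = if (use_rain || use_dgb || use_adain)
                        cfg$lambda_consist else 0,
                      eps = cfg$eps, dgb_stage = cfg$dgb_stage, ws = ws)
      if (!is.finite(res$loss))
        stop(sprintf("training diverged (non-finite loss) at iteration %d",
                     it), call. = FALSE)
      trace[it, ] <<- c(res$loss, res$task, res$consist)
      flat <<- opt_sgd_step(flat, res$grads, cfg$model_lr)
      if (use_dgb)
        adv <<- dgb_step(adv, res$adv_grad, grl_cfg,
                         lambda_grl = grl_coefficient(grl_cfg, it,
                                                      cfg$n_iterations))
    }
  })
  list(model = bb_set_flat(model, flat), adv = adv,
       trace = as.data.frame(trace))
}

#' Supervised task loss: pixel cross-entropy with an ignore label
#'
#' Softmax cross-entropy of the per-pixel class scores against the true
#' annotation, averaged over pixels whose label is not the ignore value
#' (255). Ignored pixels have no influence on the value or its gradient.
#'
#' @param scores numeric array `(B, K, H, W)` of unnormalized class scores.
#' @param mask integer array `(B, H, W)` of true labels.
#' @return Nonnegative scalar (`log(K)` for uniform scores).
#' @export
task_loss <- function(scores, mask) {
  fm_check(scores, "scores")
  d <- dim(scores)
  if (!identical(dim(mask), d[c(1, 3, 4)]))
    stop("`mask` must be (batch, row, col) matching the score map",
         call. = FALSE)
  # internal layout: scores (H, W, B, K), labels (H, W, B)
  ce_fwd(to_hwbc(scores), aperm(mask, c(2, 3, 1)))$loss
}

#' Combined phase-2 objective
#'
#' `L = L_task + lambda_consist * L_consist`.
#'
#' @param l_task,l_consist finite scalar loss components.
#' @param lambda_consist nonnegative consistency weight (0.8 in the
#'   published protocol).
#' @return Scalar.
#' @export
total_loss <- function(l_task, l_consist, lambda_consist = 0.8) {
  stopifnot(is.finite(l_task), is.finite(l_consist),
            lambda_consist >= 0)
  l_task + lambda_consist * l_consist
}

#' Evaluate a segmentation model on a dataset
#'
#' Predictions are the per-pixel argmax of the score maps; counts accumulate
#' over all images into one confusion matrix. Deterministic given the model
#' and data.
#'
#' @param model a `"seg_backbone"` (or `"weedseg"` fit).
#' @param data a `"seg_dataset"`.
#' @param cmap a [class_map()].
#' @param indices optional subset of image indices to evaluate.
#' @return A `"metrics_report"`.
#' @export
evaluate_model <- function(model, data, cmap, indices = NULL) {
  if (inherits(model, "weedseg")) model <- model$model
  stopifnot(inherits(data, "seg_dataset"))
  if (is.null(indices)) indices <- seq_len(dim(data$images)[4])
  if (!length(indices)) stop("empty evaluation dataset", call. = FALSE)
  K <- model$n_classes
  preds <- predict_masks(model, data$images[, , , indices, drop = FALSE])
  counts <- confusion_counts(preds, data$masks[, , indices, drop = FALSE], K)
  metrics_report(counts, cmap)
}
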