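# User-facing model interface: one fitting function returning a classed
# object with print/summary/predict/plot methods, plus the ablation
# harness and the default synthetic benchmark.

#' Default synthetic two-domain benchmark
#'
#' The study conditions used throughout the package's tests: 64 x 64
#' scenes, 4 classes (background, crop, two weed species), 200 laboratory
#' training images and 100 field images at domain shift delta = 1, the
#' field portion split 10% validation / 90% test. Everything derives
#' deterministically from `seed`.
#'
#' @param seed integer master seed.
#' @param n_lab,n_field images per domain.
#' @param delta field domain shift magnitude.
#' @param image_size square image side (divisible by 4).
#' @param n_classes background + crop + weeds.
#' @return List with `"seg_dataset"`s `lab` and `field`, the field
#'   `test`/`val` index vectors, and the [class_map()].
#' @export
generate_benchmark <- function(seed = 1L, n_lab = 200L, n_field = 100L,
                               delta = 1, image_size = 64L,
                               n_classes = 4L) {
  spec <- scene_spec(image_size = c(image_size, image_size),
                     n_classes = n_classes)
  lab <- samples_to_dataset(generate_samples(spec, lab_domain(), n_lab, seed))
  field_samples <- generate_samples(spec, field_domain(delta), n_field,
                                    seed + 1L)
  field <- samples_to_dataset(field_samples)
  n_val <- max(1L, round(0.1 * n_field))
  val_idx <- with_seed(seed + 2L, function() sample.int(n_field, n_val))
  field$manifest$split <- ifelse(seq_len(n_field) %in% val_idx, "val", "test")
  list(lab = lab, field = field,
       test = setdiff(seq_len(n_field), val_idx), val = sort(val_idx),
       class_map = paddy_class_map(n_classes - 2L))
}

#' Fit a domain-generalized segmentation model
#'
#' Runs the two-phase protocol end to end: phase 1 pre-trains the style VAE
#' on the combined domains' feature statistics (skipped when the stochastic
#' style module is off), phase 2 trains the backbone on the labelled
#' laboratory data with stochastic style transfer and adversarial feature
#' normalization as configured. Field labels are never used for training.
#'
#' @param lab_data labelled `"seg_dataset"` (the training domain).
#' @param field_data `"seg_dataset"` whose *images* provide the style pool
#'   for phase 1 / the fixed-style variant; required when `use_rain` or
#'   `use_adain_fixed` is on.
#' @param cmap a [class_map()]; defaults to background + crop + weeds
#'   inferred from the masks.
#' @param config a [seg_config()].
#' @param vae optionally a pre-trained `"style_vae"` to freeze for phase 2,
#'   skipping phase 1 (it must match the backbone's first-stage width).
#' @return An object of class `"weedseg"`: the trained `model`, the frozen
#'   `vae`, final adversarial statistics `adv`, both phase `trace`s, the
#'   configuration and class map.
#' @examples
#' \donttest{
#' bench <- generate_benchmark(seed = 1, n_lab = 20, n_field = 10)
#' fit <- weedseg_fit(bench$lab, bench$field, bench$class_map,
#'                    seg_config(n_iterations = 50, vae_iterations = 20))
#' print(fit)
#' }
#' @export
weedseg_fit <- function(lab_data, field_data = NULL, cmap = NULL,
                        config = seg_config(), vae = NULL) {
  stopifnot(inherits(lab_data, "seg_dataset"), inherits(config, "seg_config"))
  n_classes <- max(lab_data$masks[lab_data$masks != IGNORE_LABEL]) + 1L
  if (is.null(cmap)) cmap <- paddy_class_map(max(1L, n_classes - 2L))
  n_classes <- max(n_classes, nrow(cmap))
  model <- seg_backbone(n_classes, config$channels, seed = config$seed)
  vae_trace <- NULL
  if (isTRUE(config$use_rain)) {
    if (is.null(field_data))
      stop("`field_data` images are required to learn the style distribution",
           call. = FALSE)
    if (is.null(vae)) {
      vae <- style_vae(model$channels[1], config$latent_dim,
                       config$hidden_width, seed = config$seed + 10L)
      vae <- train_rain_phase(vae, model, lab_data, field_data, config)
    }
    vae_trace <- vae$trace
  } else {
    vae <- NULL
  }
  adv <- if (isTRUE(config$use_dgb))
    adversarial_stats(model$channels[config$dgb_stage]) else NULL
  ph2 <- train_segmentation_phase(model, vae, adv, lab_data, config,
                                  style_data = field_data)
  structure(list(model = ph2$model, vae = vae, adv = ph2$adv,
                 trace = ph2$trace, vae_trace = vae_trace,
                 config = config, class_map = cmap),
            class = "weedseg")
}

#' @export
print.weedseg <- function(x, ...) {
  cfg <- x$config
  variant <- if (cfg$use_rain && cfg$use_dgb) "stochastic style + adversarial"
  else if (cfg$use_rain) "stochastic style only"
  else if (cfg$use_dgb) "adversarial only"
  else if (cfg$use_adain_fixed) "fixed-style transfer"
  else "plain supervised"
  cat(sprintf("Domain-generalized segmentation fit (%s)\n", variant))
  print(x$model)
  cat(sprintf("  %d iterations, final loss %.4f (task %.4f)\n",
              nrow(x$trace), utils::tail(x$trace$loss, 1),
              utils::tail(x$trace$task, 1)))
  invisible(x)
}

#' @export
summary.weedseg <- function(object, ...) {
  print(object)
  tr <- object$trace
  n <- nrow(tr)
  win <- max(1L, n %/% 10L)
  cat(sprintf("  task loss: first-%d mean %.4f, last-%d mean %.4f\n",
              win, mean(tr$task[seq_len(win)]),
              win, mean(tr$task[(n - win + 1L):n])))
  if (!is.null(object$adv))
    print(object$adv)
  invisible(object)
}

#' @param object,newdata a fitted `"weedseg"` model and an image array
#'   `(H, W, 3, N)` in `[0, 1]` or a `"seg_dataset"`.
#' @param ... unused.
#' @return Integer array `(H, W, N)` of predicted class ids.
#' @rdname weedseg_fit
#' @export
predict.weedseg <- function(object, newdata, ...) {
  images <- if (inherits(newdata, "seg_dataset")) newdata$images else newdata
  predict_masks(object$model, images)
}

#' @export
plot.weedseg <- function(x, ...) {
  tr <- x$trace
  graphics::plot(seq_len(nrow(tr)), tr$task, type = "l", col = "grey40",
                 xlab = "iteration", ylab = "loss",
                 main = "Training loss", ...)
  sm <- stats::filter(tr$task, rep(1 / 51, 51), sides = 2)
  graphics::lines(seq_len(nrow(tr)), sm, col = "firebrick", lwd = 2)
  if (any(tr$consist > 0))
    graphics::lines(seq_len(nrow(tr)), tr$consist, col = "steelblue")
  invisible(x)
}

#' Save / load a fitted model
#'
#' Single-file checkpoints holding the backbone, VAE and adversarial
#' statistics.
#'
#' @param object a `"weedseg"` fit (or `"style_vae"`).
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Ablation study over the framework's components
#'
#' Trains the requested variants on the laboratory data, evaluates each on
#' the field test split, and reports per-seed metrics with means and
#' standard deviations. Variants: `baseline` (plain supervised), `adain`
#' (deterministic fixed-style transfer), `rain` (stochastic style only),
#' `dgb` (adversarial only), `full` (stochastic style + adversarial). A
#' variant that errors is recorded and the others continue.
#'
#' @param lab_data,field_data `"seg_dataset"`s; field supplies the style
#'   pool and the evaluation split.
#' @param cmap a [class_map()].
#' @param base_cfg a [seg_config()]; each variant copies it and flips its
#'   module flags, each seed overrides `seed`.
#' @param seeds integer vector (>= 2 values recommended).
#' @param variants subset of the five variant names.
#' @param test_idx field image indices used for evaluation; defaults to
#'   every field image.
#' @param verbose print progress lines.
#' @param keep_fits also return the fitted models (one per variant x seed).
#' @return An object of class `"ablation_report"`: data frame `results`
#'   (one row per variant x seed) and `summary` (mean and sd per variant);
#'   with `keep_fits`, a list `fits` keyed `"<variant>_<seed>"`.
#' @export
run_ablation <- function(lab_data, field_data, cmap, base_cfg = seg_config(),
                         seeds = 1:3,
                         variants = c("baseline", "adain", "rain", "dgb",
                                      "full"),
                         test_idx = NULL, verbose = TRUE,
                         keep_fits = FALSE) {
  variants <- match.arg(variants, several.ok = TRUE)
  flags <- list(
    baseline = c(FALSE, FALSE, FALSE),
    adain = c(FALSE, FALSE, TRUE),
    rain = c(TRUE, FALSE, FALSE),
    dgb = c(FALSE, TRUE, FALSE),
    full = c(TRUE, TRUE, FALSE)
  )
  rows <- list()
  fits <- list()
  # variants sharing a seed share bit-identical phase-1 training; train the
  # style VAE once per seed and freeze it for every variant that needs it
  vae_cache <- list()
  seed_vae <- function(cfg) {
    key <- as.character(cfg$seed)
    if (is.null(vae_cache[[key]])) {
      model <- seg_backbone(nrow(cmap), cfg$channels, seed = cfg$seed)
      v0 <- style_vae(model$channels[1], cfg$latent_dim, cfg$hidden_width,
                      seed = cfg$seed + 10L)
      vae_cache[[key]] <<- train_rain_phase(v0, model, lab_data, field_data,
                                            cfg)
    }
    vae_cache[[key]]
  }
  for (v in variants) for (s in seeds) {
    cfg <- base_cfg
    cfg$use_rain <- flags[[v]][1]
    cfg$use_dgb <- flags[[v]][2]
    cfg$use_adain_fixed <- flags[[v]][3]
    cfg$seed <- as.integer(s)
    res <- tryCatch({
      fit <- weedseg_fit(lab_data, field_data, cmap, cfg,
                         vae = if (cfg$use_rain) seed_vae(cfg) else NULL)
      if (keep_fits) fits[[paste0(v, "_", s)]] <- fit
      rep <- evaluate_model(fit, field_data, cmap, indices = test_idx)
      data.frame(variant = v, seed = s, miou = rep$miou,
                 precision = rep$precision, recall = rep$recall,
                 f1 = rep$f1, weed_iou = rep$weed_iou, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(variant = v, seed = s, miou = NA_real_,
                 precision = NA_real_, recall = NA_real_, f1 = NA_real_,
                 weed_iou = NA_real_, error = conditionMessage(e),
                 stringsAsFactors = FALSE))
    if (verbose)
      message(sprintf("  %-8s seed %d: mIoU %s", v, s,
                      ifelse(is.na(res$miou), paste("failed:", res$error),
                             sprintf("%.2f", res$miou))))
    rows[[length(rows) + 1L]] <- res
  }
  results <- do.call(rbind, rows)
  agg <- function(f) stats::aggregate(
    results[, c("miou", "precision", "recall", "f1", "weed_iou")],
    by = list(variant = results$variant), FUN = f)
  m <- agg(function(x) mean(x, na.rm = TRUE))
  s <- agg(function(x) stats::sd(x, na.rm = TRUE))
  summary_df <- merge(m, s, by = "variant", suffixes = c("_mean", "_sd"))
  summary_df <- summary_df[match(variants, summary_df$variant), ]
  structure(list(results = results, summary = summary_df, seeds = seeds,
                 fits = if (keep_fits) fits),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, digits = 2, ...) {
  cat(sprintf("Ablation over %d seed(s); cross-domain metrics in %%\n",
              length(x$seeds)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-8s mIoU %6.2f +/- %-5.2f  P %6.2f  R %6.2f  F1 %6.2f  WeedIoU %6.2f\n",
                s$variant[i], s$miou_mean[i],
                ifelse(is.na(s$miou_sd[i]), 0, s$miou_sd[i]),
                s$precision_mean[i], s$recall_mean[i], s$f1_mean[i],
                s$weed_iou_mean[i]))
  invisible(x)
}
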