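# Seeded simulator for paired laboratory-like and field-like paddy scenes.
# Realism is not the goal: the generator produces a controllable,
# label-faithful domain gap. Plants are textured superellipse blobs with a
# distinct texture frequency, elongation and hue per class; the field domain
# shifts background reflectance, adds an illumination gradient, specular
# water-glare blobs and background clutter, all scaled by a single shift
# magnitude delta (delta = 0 reproduces the laboratory distribution).

#' Scene specification
#'
#' @param image_size integer `(H, W)`.
#' @param n_classes background + crop + weeds; at least 3.
#' @param plants_per_image integer range `(min, max)` of plant instances.
#' @param instance_size range (pixels) of instance bounding diameters; must
#'   fit inside the image.
#' @param overlap_allowed may plants overlap (later plants occlude earlier
#'   ones; the mask records the top-most class per pixel).
#' @param class_weights sampling weights over the foreground classes
#'   (crop first, then weeds). Default: crop 0.5, weeds sharing 0.5.
#' @return An object of class `"scene_spec"`.
#' @export
scene_spec <- function(image_size = c(64L, 64L), n_classes = 4L,
                       plants_per_image = c(3L, 8L),
                       instance_size = c(8, 24),
                       overlap_allowed = TRUE,
                       class_weights = NULL) {
  if (n_classes < 3L)
    stop("need at least background + crop + one weed class", call. = FALSE)
  if (max(instance_size) > min(image_size))
    stop(sprintf(
      "impossible scene: instance size %g exceeds the image extent %d",
      max(instance_size), min(image_size)), call. = FALSE)
  n_fg <- n_classes - 1L
  if (is.null(class_weights))
    class_weights <- c(0.5, rep(0.5 / (n_fg - 1L), n_fg - 1L))
  if (length(class_weights) != n_fg || any(class_weights < 0))
    stop("`class_weights` must be one nonnegative weight per foreground class",
         call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 n_classes = as.integer(n_classes),
                 plants_per_image = as.integer(plants_per_image),
                 instance_size = as.numeric(instance_size),
                 overlap_allowed = isTRUE(overlap_allowed),
                 class_weights = class_weights / sum(class_weights)),
            class = "scene_spec")
}

#' Domain rendering parameters
#'
#' All departures from the laboratory reference scale linearly with the
#' shift magnitude `delta`; `delta = 0` reproduces the laboratory
#' distribution exactly.
#'
#' @param delta nonnegative shift magnitude.
#' @param name domain tag stored on generated samples; defaults to `"lab"`
#'   when `delta == 0` and `"field"` otherwise.
#' @param base_reflectance laboratory mean background RGB reflectance.
#' @param background_shift RGB shift applied at `delta = 1` (wet, darker,
#'   bluer soil).
#' @param base_sd,sd_gain background reflectance standard deviation at
#'   `delta = 0` and its increase per unit delta.
#' @param illumination_amplitude strength of the linear illumination ramp
#'   per unit delta (relative units).
#' @param specular_rate expected specular glare blobs per image per unit
#'   delta.
#' @param clutter_density expected background distractor objects per image
#'   per unit delta.
#' @return An object of class `"domain_params"`.
#' @export
domain_params <- function(delta = 0, name = NULL,
                          base_reflectance = c(0.44, 0.38, 0.30),
                          background_shift = c(-0.12, -0.05, 0.10),
                          base_sd = 0.02, sd_gain = 0.03,
                          illumination_amplitude = 0.25,
                          specular_rate = 3,
                          clutter_density = 4) {
  if (delta < 0) stop("`delta` must be nonnegative", call. = FALSE)
  if (is.null(name)) name <- if (delta == 0) "lab" else "field"
  structure(list(
    delta = delta, name = name,
    reflectance_mean = base_reflectance + delta * background_shift,
    reflectance_sd = base_sd + delta * sd_gain,
    illumination_amplitude = delta * illumination_amplitude,
    specular_rate = delta * specular_rate,
    clutter_density = delta * clutter_density
  ), class = "domain_params")
}

#' @rdname domain_params
#' @export
lab_domain <- function() domain_params(0, name = "lab")

#' @rdname domain_params
#' @export
field_domain <- function(delta = 1) domain_params(delta, name = "field")

# center-aligned bilinear resize of a matrix
bilinear_resize <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  sy <- (seq_len(H) - 0.5) * h / H + 0.5
  sx <- (seq_len(W) - 0.5) * w / W + 0.5
  y0 <- pmin(pmax(floor(sy), 1L), h); y1 <- pmin(y0 + 1L, h)
  x0 <- pmin(pmax(floor(sx), 1L), w); x1 <- pmin(x0 + 1L, w)
  fy <- pmin(pmax(sy - y0, 0), 1); fx <- pmin(pmax(sx - x0, 0), 1)
  tmp0 <- m[y0, , drop = FALSE] * (1 - fy) + m[y1, , drop = FALSE] * fy
  tmp0[, x0, drop = FALSE] * rep(1 - fx, each = H) +
    tmp0[, x1, drop = FALSE] * rep(fx, each = H)
}

# band-limited noise: white noise at a coarse grid, bilinear-upsampled;
# `scale` is the correlation length in pixels
band_noise <- function(H, W, scale, sd = 1) {
  h <- max(2L, ceiling(H / scale)); w <- max(2L, ceiling(W / scale))
  bilinear_resize(matrix(stats::rnorm(h * w, sd = sd), h, w), H, W)
}

# per-class rendering style; classes beyond the table cycle with jitter
plant_styles <- function(n_fg) {
  base <- list(
    list(color = c(0.36, 0.56, 0.22), aspect = 0.25, exponent = 2.0,
         tex_scale = 2, tex_amp = 0.06, parts = 3L),   # crop: thin blades
    list(color = c(0.16, 0.42, 0.16), aspect = 0.80, exponent = 1.4,
         tex_scale = 5, tex_amp = 0.10, parts = 1L),   # grassy weed, coarse
    list(color = c(0.22, 0.46, 0.36), aspect = 0.65, exponent = 4.0,
         tex_scale = 11, tex_amp = 0.08, parts = 1L),  # broad-leaf weed
    list(color = c(0.30, 0.50, 0.18), aspect = 0.45, exponent = 1.8,
         tex_scale = 8, tex_amp = 0.09, parts = 2L),
    list(color = c(0.18, 0.38, 0.28), aspect = 0.90, exponent = 3.0,
         tex_scale = 3, tex_amp = 0.07, parts = 1L)
  )
  lapply(seq_len(n_fg), function(i) base[[(i - 1L) %% length(base) + 1L]])
}

# pixels inside a rotated superellipse |u/a|^p + |v/b|^p <= 1
superellipse_mask <- function(H, W, cy, cx, a, b, p, angle) {
  yy <- matrix(seq_len(H) - cy, H, W)
  xx <- matrix(rep(seq_len(W) - cx, each = H), H, W)
  u <- cos(angle) * xx + sin(angle) * yy
  v <- -sin(angle) * xx + cos(angle) * yy
  (abs(u / a)^p + abs(v / b)^p) <= 1
}

#' Render one synthetic scene
#'
#' Deterministic given `(spec, dom, seed)`: the background reflectance field
#' and clutter are laid down first, plants are composited back-to-front
#' (mask and instance map record the top-most object per pixel), then the
#' illumination gradient multiplies the whole scene and specular glare
#' saturates background-only pixels toward white.
#'
#' @param spec a [scene_spec()].
#' @param dom a [domain_params()].
#' @param seed integer seed.
#' @return An object of class `"synthetic_sample"`: `image` `(H, W, 3)` in
#'   `[0, 1]`, integer `mask` `(H, W)` (0 background), integer
#'   `instance_ids` `(H, W)`, and the `domain` tag.
#' @export
generate_scene <- function(spec, dom, seed = 1L) {
  stopifnot(inherits(spec, "scene_spec"), inherits(dom, "domain_params"))
  with_seed(seed, function() {
    H <- spec$image_size[1]; W <- spec$image_size[2]
    img <- array(0, c(H, W, 3))
    for (ch in 1:3)
      img[, , ch] <- dom$reflectance_mean[ch] +
        band_noise(H, W, scale = 8, sd = dom$reflectance_sd)

    # background clutter: plant-coloured distractors that stay background
    n_clut <- stats::rpois(1, dom$clutter_density)
    for (i in seq_len(n_clut)) {
      cy <- stats::runif(1, 1, H); cx <- stats::runif(1, 1, W)
      r <- stats::runif(1, 1.5, 4)
      inside <- superellipse_mask(H, W, cy, cx, r, r * stats::runif(1, 0.5, 1),
                                  stats::runif(1, 1.2, 3),
                                  stats::runif(1, 0, pi))
      col <- c(0.26, 0.36, 0.22) + stats::rnorm(3, 0, 0.04)
      for (ch in 1:3) {
        pl <- img[, , ch]; pl[inside] <- col[ch]; img[, , ch] <- pl
      }
    }

    mask <- matrix(0L, H, W)
    inst <- matrix(0L, H, W)
    styles <- plant_styles(spec$n_classes - 1L)
    n_plants <- sample(spec$plants_per_image[1]:spec$plants_per_image[2], 1)
    for (k in seq_len(n_plants)) {
      cls <- sample.int(spec$n_classes - 1L, 1, prob = spec$class_weights)
      sty <- styles[[cls]]
      diam <- stats::runif(1, spec$instance_size[1], spec$instance_size[2])
      a <- diam / 2
      b <- max(1, a * sty$aspect * stats::runif(1, 0.8, 1.2))
      cy <- stats::runif(1, 1 + a / 2, H - a / 2)
      cx <- stats::runif(1, 1 + a / 2, W - a / 2)
      base_angle <- stats::runif(1, 0, pi)
      inside <- matrix(FALSE, H, W)
      for (part in seq_len(sty$parts)) {
        ang <- base_angle + (part - 1) * pi / sty$parts
        inside <- inside | superellipse_mask(H, W, cy, cx, a, b,
                                             sty$exponent, ang)
      }
      if (!spec$overlap_allowed) inside <- inside & (mask == 0L)
      if (!any(inside)) next
      shade <- stats::runif(1, 0.85, 1.15)
      tex <- band_noise(H, W, sty$tex_scale, sd = 1) * sty$tex_amp
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[inside] <- sty$color[ch] * shade + tex[inside]
        img[, , ch] <- pl
      }
      mask[inside] <- cls
      inst[inside] <- k
    }

    # multiplicative illumination ramp across the whole scene
    if (dom$illumination_amplitude > 0) {
      phi <- stats::runif(1, 0, 2 * pi)
      ty <- (seq_len(H) - 0.5) / H - 0.5
      tx <- (seq_len(W) - 0.5) / W - 0.5
      ramp <- 1 + 2 * dom$illumination_amplitude *
        (sin(phi) * matrix(ty, H, W) + cos(phi) * matrix(tx, H, W, byrow = TRUE))
      for (ch in 1:3) img[, , ch] <- img[, , ch] * ramp
    }

    # specular water glare over background pixels only
    n_spec <- stats::rpois(1, dom$specular_rate)
    for (i in seq_len(n_spec)) {
      cy <- stats::runif(1, 1, H); cx <- stats::runif(1, 1, W)
      gl <- superellipse_mask(H, W, cy, cx, stats::runif(1, 2, 6),
                              stats::runif(1, 1, 3), 2,
                              stats::runif(1, 0, pi)) & (mask == 0L)
      for (ch in 1:3) {
        pl <- img[, , ch]; pl[gl] <- pl[gl] + 0.85 * (1 - pl[gl])
        img[, , ch] <- pl
      }
    }

    img[img < 0] <- 0; img[img > 1] <- 1
    structure(list(image = img, mask = mask, instance_ids = inst,
                   domain = dom$name),
              class = "synthetic_sample")
  })
}

# a list of scenes with per-scene seeds derived from one master seed
generate_samples <- function(spec, dom, n, seed) {
  lapply(seq_len(n), function(i)
    generate_scene(spec, dom, seed = (seed + 104729L * i) %% 2147483629L))
}

#' Generate and write a two-domain dataset
#'
#' Writes 8-bit PNG images and single-channel integer PNG label masks plus a
#' tab-separated manifest. Laboratory images form the training split; the
#' field portion is split 10% validation / 90% test.
#'
#' @param spec a [scene_spec()].
#' @param dom_lab,dom_field [domain_params()] for the two domains.
#' @param n_lab,n_field number of images per domain (>= 1).
#' @param seed integer master seed; the run is fully reproducible.
#' @param out_dir output directory (created if needed).
#' @return The manifest data frame (invisibly written to
#'   `<out_dir>/manifest.tsv`): image/mask paths, domain, split, and
#'   per-class instance counts.
#' @export
generate_dataset <- function(spec, dom_lab, dom_field, n_lab, n_field,
                             seed, out_dir) {
  stopifnot(n_lab >= 1L, n_field >= 1L)
  ok <- dir.create(file.path(out_dir, "images"), recursive = TRUE,
                   showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  if (!dir.exists(file.path(out_dir, "images")))
    stop(sprintf("cannot create output directory `%s`", out_dir),
         call. = FALSE)
  lab <- generate_samples(spec, dom_lab, n_lab, seed)
  field <- generate_samples(spec, dom_field, n_field, seed + 1L)
  n_val <- max(1L, round(0.1 * n_field))
  val_idx <- with_seed(seed + 2L, function() sample.int(n_field, n_val))

  rows <- list()
  write_one <- function(smp, tag, i, split) {
    img_path <- file.path("images", sprintf("%s_%04d.png", tag, i))
    msk_path <- file.path("masks", sprintf("%s_%04d_mask.png", tag, i))
    png::writePNG(smp$image, file.path(out_dir, img_path))
    png::writePNG(smp$mask / 255, file.path(out_dir, msk_path))
    counts <- vapply(seq_len(spec$n_classes - 1L), function(k)
      length(unique(smp$instance_ids[smp$mask == k])), integer(1))
    c(list(image = img_path, mask = msk_path, domain = smp$domain,
           split = split), as.list(counts))
  }
  for (i in seq_len(n_lab))
    rows[[length(rows) + 1L]] <- write_one(lab[[i]], "lab", i, "train")
  for (i in seq_len(n_field))
    rows[[length(rows) + 1L]] <- write_one(
      field[[i]], "field", i, if (i %in% val_idx) "val" else "test")

  cls_names <- paste0("n_class_", seq_len(spec$n_classes - 1L))
  man <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(stats::setNames(r, c("image", "mask", "domain", "split",
                                       cls_names)))))
  utils::write.table(man, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  man
}

# per-image channel mean/sd summary used by the gap probe
channel_summary <- function(samples) {
  t(vapply(samples, function(s) {
    im <- if (inherits(s, "synthetic_sample")) s$image else s
    c(apply(im, 3, mean), apply(im, 3, stats::sd))
  }, numeric(6)))
}

#' Energy distance between the channel-statistics of two image sets
#'
#' Each image is summarized by its per-channel mean and standard deviation;
#' the probe returns the energy distance between the two resulting point
#' clouds. Zero for identical datasets, symmetric, and nondecreasing in the
#' domain shift magnitude in expectation.
#'
#' @param dataset_lab,dataset_field nonempty lists of
#'   `"synthetic_sample"` objects (or plain `(H, W, 3)` arrays).
#' @return Nonnegative scalar gap summary.
#' @export
domain_gap_probe <- function(dataset_lab, dataset_field) {
  if (!length(dataset_lab) || !length(dataset_field))
    stop("both datasets must be nonempty", call. = FALSE)
  X <- channel_summary(dataset_lab)
  Y <- channel_summary(dataset_field)
  cross <- mean(sqrt(pmax(outer(rowSums(X^2), rowSums(Y^2), "+") -
                            2 * tcrossprod(X, Y), 0)))
  within <- function(A) {
    if (nrow(A) == 1L) return(0)
    mean(stats::dist(A)) * (nrow(A) - 1) / nrow(A)
  }
  max(0, 2 * cross - within(X) - within(Y))
}
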