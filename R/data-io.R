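# Dataset plumbing: PNG readers/writers, LabelMe polygon import, the
# resize/standardize preprocessing step, training-time augmentation, and
# presence-balanced stratified batch sampling. Masks are 0-based integer
# class ids in single-channel PNGs; 255 marks ignore pixels. Coordinates
# are row-major with the origin at the top-left.

IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_SD <- c(0.229, 0.224, 0.225)
IGNORE_LABEL <- 255L

#' Read one image/mask pair
#'
#' Images come back as float RGB in `[0, 1]`; an alpha channel is dropped
#' with a warning, grayscale is replicated to three channels. Masks are
#' decoded to integer class ids and validated against `n_classes` when
#' given.
#'
#' @param record list or one-row data frame with `image` and `mask` paths.
#' @param base_dir directory the paths are relative to.
#' @param n_classes when non-`NULL`, any mask id outside
#'   `0 .. n_classes - 1` (other than 255) is an error.
#' @return List with `image` `(H, W, 3)` and integer `mask` `(H, W)`.
#' @export
read_sample <- function(record, base_dir = ".", n_classes = NULL) {
  img_path <- file.path(base_dir, record$image)
  msk_path <- file.path(base_dir, record$mask)
  for (p in c(img_path, msk_path))
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  img <- png::readPNG(img_path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4L) {
    warning(sprintf("dropping alpha channel of %s", img_path))
    img <- img[, , 1:3, drop = FALSE]
  }
  msk <- png::readPNG(msk_path)
  if (length(dim(msk)) == 3L) {
    if (dim(msk)[3] > 1L && stats::var(as.vector(msk[, , 1] - msk[, , 2])) > 0)
      stop(sprintf("mask %s is not single-channel", msk_path), call. = FALSE)
    msk <- msk[, , 1]
  }
  mask <- matrix(as.integer(round(msk * 255)), nrow(msk), ncol(msk))
  if (!identical(dim(img)[1:2], dim(mask)))
    stop(sprintf("image/mask dimension mismatch for %s", img_path),
         call. = FALSE)
  if (!is.null(n_classes)) {
    bad <- setdiff(unique(as.vector(mask)),
                   c(0:(n_classes - 1L), IGNORE_LABEL))
    if (length(bad))
      stop(sprintf("mask %s holds unknown label id(s) %s", msk_path,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  list(image = img, mask = mask)
}

#' Write one image/mask pair as PNGs
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param mask integer matrix of class ids (0..254, 255 = ignore).
#' @param img_path,msk_path output file paths.
#' @rdname read_sample
#' @export
write_sample <- function(image, mask, img_path, msk_path) {
  png::writePNG(image, img_path)
  png::writePNG(mask / 255, msk_path)
  invisible(NULL)
}

#' Read a dataset manifest
#'
#' @param path path to a tab-separated manifest with columns `image`,
#'   `mask`, `domain`, `split`.
#' @param base_dir directory the manifest's paths are relative to;
#'   referenced files must exist.
#' @return The manifest data frame.
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("image", "mask", "domain", "split")
  if (!all(need %in% names(man)))
    stop("manifest must have columns image, mask, domain, split",
         call. = FALSE)
  missing <- !file.exists(file.path(base_dir, man$image)) |
    !file.exists(file.path(base_dir, man$mask))
  if (any(missing))
    stop(sprintf("manifest references missing files, e.g. %s",
                 man$image[which(missing)[1]]), call. = FALSE)
  man
}

#' Load a manifest's samples into memory
#'
#' @param manifest manifest data frame (see [read_manifest()]).
#' @param base_dir directory of the referenced files.
#' @param n_classes label validation passed to [read_sample()].
#' @return An object of class `"seg_dataset"`: `images` `(H, W, 3, N)` in
#'   `[0, 1]`, integer `masks` `(H, W, N)`, and the manifest.
#' @export
load_dataset <- function(manifest, base_dir = ".", n_classes = NULL) {
  stopifnot(nrow(manifest) >= 1L)
  first <- read_sample(manifest[1, ], base_dir, n_classes)
  H <- nrow(first$mask); W <- ncol(first$mask)
  N <- nrow(manifest)
  images <- array(0, c(H, W, 3, N))
  masks <- array(0L, c(H, W, N))
  for (i in seq_len(N)) {
    s <- if (i == 1L) first else read_sample(manifest[i, ], base_dir, n_classes)
    images[, , , i] <- s$image
    masks[, , i] <- s$mask
  }
  structure(list(images = images, masks = masks, manifest = manifest),
            class = "seg_dataset")
}

# build a seg_dataset directly from in-memory synthetic samples
samples_to_dataset <- function(samples) {
  H <- nrow(samples[[1]]$mask); W <- ncol(samples[[1]]$mask)
  N <- length(samples)
  images <- array(0, c(H, W, 3, N))
  masks <- array(0L, c(H, W, N))
  for (i in seq_len(N)) {
    images[, , , i] <- samples[[i]]$image
    masks[, , i] <- samples[[i]]$mask
  }
  man <- data.frame(image = sprintf("<memory:%d>", seq_len(N)),
                    mask = sprintf("<memory:%d>", seq_len(N)),
                    domain = vapply(samples, `[[`, "", "domain"),
                    split = "train", stringsAsFactors = FALSE)
  structure(list(images = images, masks = masks, manifest = man),
            class = "seg_dataset")
}

#' @export
print.seg_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("Segmentation dataset: %d images of %d x %d (%s)\n",
              d[4], d[1], d[2],
              paste(sprintf("%s: %d", names(table(x$manifest$domain)),
                            table(x$manifest$domain)), collapse = ", ")))
  invisible(x)
}

## ---- LabelMe polygon import ------------------------------------------------

# even-odd point-in-polygon test for every pixel center of an H x W grid;
# pixel (r, c) has center (x, y) = (c - 0.5, r - 0.5) in LabelMe
# coordinates (x right, y down, origin at the top-left image corner)
rasterize_polygon <- function(points, H, W) {
  px <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  py <- matrix(seq_len(H) - 0.5, H, W)
  inside <- matrix(FALSE, H, W)
  n <- nrow(points)
  j <- n
  for (i in seq_len(n)) {
    xi <- points[i, 1]; yi <- points[i, 2]
    xj <- points[j, 1]; yj <- points[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a LabelMe annotation document to a label mask
#'
#' Polygons are rasterized in their listed order, later polygons overwriting
#' earlier ones on overlaps. A pixel belongs to a polygon when its center
#' lies inside it (even-odd rule), giving half-open rasterization with
#' integer-coordinate polygon edges landing on pixel boundaries.
#'
#' @param json_doc path to a LabelMe JSON file, or the parsed list.
#' @param cmap a [class_map()]; every shape label must appear in it.
#' @param image_size `(H, W)`; defaults to the document's
#'   `imageHeight`/`imageWidth`.
#' @return Integer label mask `(H, W)`.
#' @export
import_labelme <- function(json_doc, cmap, image_size = NULL) {
  stopifnot(inherits(cmap, "class_map"))
  doc <- if (is.character(json_doc))
    jsonlite::fromJSON(json_doc, simplifyVector = FALSE) else json_doc
  if (is.null(image_size))
    image_size <- c(doc$imageHeight, doc$imageWidth)
  H <- image_size[1]; W <- image_size[2]
  mask <- matrix(0L, H, W)
  for (shape in doc$shapes) {
    id <- cmap$id[match(shape$label, cmap$name)]
    if (is.na(id))
      stop(sprintf("unknown class name `%s` in annotation", shape$label),
           call. = FALSE)
    pts <- do.call(rbind, lapply(shape$points, unlist))
    mask[rasterize_polygon(pts, H, W)] <- id
  }
  mask
}

## ---- preprocessing ---------------------------------------------------------

nearest_resize <- function(m, H, W) {
  ri <- pmin(pmax(ceiling((seq_len(H) - 0.5) * nrow(m) / H), 1L), nrow(m))
  ci <- pmin(pmax(ceiling((seq_len(W) - 0.5) * ncol(m) / W), 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Resize and standardize an image/mask pair
#'
#' The image is resized bilinearly and standardized channel-wise with the
#' ImageNet constants (means 0.485/0.456/0.406, sds 0.229/0.224/0.225); the
#' mask is resized with nearest-neighbour interpolation so no non-integer
#' label can appear. A resize to the input's own size leaves it unchanged.
#'
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param mask integer label matrix of matching size.
#' @param size target `(H, W)`; `NULL` keeps the input size.
#' @param normalize apply the ImageNet standardization.
#' @return List with the transformed `image` and `mask`.
#' @export
preprocess <- function(image, mask, size = NULL, normalize = TRUE) {
  if (!is.null(size) && !identical(dim(image)[1:2], as.integer(size))) {
    img2 <- array(0, c(size[1], size[2], 3))
    for (ch in 1:3)
      img2[, , ch] <- bilinear_resize(image[, , ch], size[1], size[2])
    image <- img2
    mask <- nearest_resize(mask, size[1], size[2])
  }
  if (normalize)
    for (ch in 1:3)
      image[, , ch] <- (image[, , ch] - IMAGENET_MEAN[ch]) / IMAGENET_SD[ch]
  list(image = image, mask = mask)
}

## ---- augmentation ----------------------------------------------------------

#' Random training-time augmentation
#'
#' Horizontal flip with probability 0.5, rotation uniform in +/- 15
#' degrees, and color jitter (brightness 0.2, contrast 0.2, saturation 0.2,
#' hue 0.1) applied to the image only. Geometric transforms hit image and
#' mask identically (nearest-neighbour for the mask); pixels exposed by the
#' rotation are filled black in the image and with the ignore label (255)
#' in the mask, so no background label is fabricated. Draws come from R's
#' global RNG; seed the stream for reproducibility.
#'
#' @param image `(H, W, 3)` array in `[0, 1]` (un-standardized).
#' @param mask integer label matrix.
#' @param p_flip,max_rotation,brightness,contrast,saturation,hue
#'   augmentation strengths.
#' @return List with augmented `image` and `mask`.
#' @export
augment <- function(image, mask, p_flip = 0.5, max_rotation = 15,
                    brightness = 0.2, contrast = 0.2, saturation = 0.2,
                    hue = 0.1) {
  flip <- stats::runif(1) < p_flip
  ang <- stats::runif(1, -max_rotation, max_rotation)
  fb <- stats::runif(1, max(0, 1 - brightness), 1 + brightness)
  fc <- stats::runif(1, max(0, 1 - contrast), 1 + contrast)
  fs <- stats::runif(1, max(0, 1 - saturation), 1 + saturation)
  dh <- stats::runif(1, -hue, hue)
  cpp_augment(image, mask, nrow(mask), ncol(mask), flip, ang * pi / 180,
              fb, fc, fs, dh, IGNORE_LABEL)
}

## ---- stratified batch sampling ---------------------------------------------

# logical N x n_fg presence matrix from a generated manifest's instance
# count columns
presence_from_manifest <- function(manifest) {
  cols <- grep("^n_class_", names(manifest), value = TRUE)
  if (!length(cols))
    stop("manifest has no per-class instance count columns", call. = FALSE)
  as.matrix(manifest[, cols, drop = FALSE]) > 0
}

#' Presence-balanced stratified batch iterator
#'
#' Images are drawn with probability proportional to the sum of inverse
#' class frequencies of the foreground classes they contain, which raises
#' the expected per-batch presence of rare classes toward that of common
#' ones. Every image is guaranteed to appear at least once per epoch (an
#' epoch is `2 * ceiling(N / batch_size)` batches): toward the end of an
#' epoch, not-yet-seen images are drained first. A single-class dataset
#' degenerates to uniform sampling. Draws use R's global RNG.
#'
#' @param presence logical `N x K` matrix: does image `i` contain
#'   foreground class `k` (see `presence_from_manifest`), or a manifest
#'   data frame with `n_class_*` columns.
#' @param batch_size images per batch (>= 1).
#' @return A function; each call returns the next batch as an integer
#'   vector of image indices.
#' @export
stratified_batches <- function(presence, batch_size) {
  if (is.data.frame(presence)) presence <- presence_from_manifest(presence)
  presence <- as.matrix(presence)
  N <- nrow(presence)
  if (N < 1L) stop("empty dataset", call. = FALSE)
  if (batch_size < 1L) stop("`batch_size` must be >= 1", call. = FALSE)
  freq <- colSums(presence)
  inv <- ifelse(freq > 0, 1 / freq, 0)
  w <- as.vector(presence %*% inv)
  if (all(w == 0)) w <- rep(1, N)
  w[w == 0] <- min(w[w > 0])
  epoch_len <- 2L * as.integer(ceiling(N / batch_size))
  unseen <- rep(TRUE, N)
  b_in_epoch <- 0L
  function() {
    remaining <- epoch_len - b_in_epoch
    un <- which(unseen)
    idx <- if (length(un) >= (remaining - 1L) * batch_size + 1L) {
      take <- un[sample.int(length(un), min(batch_size, length(un)),
                            prob = w[un])]
      if (length(take) < batch_size)
        take <- c(take, sample.int(N, batch_size - length(take),
                                   replace = TRUE, prob = w))
      take
    } else {
      sample.int(N, batch_size, replace = TRUE, prob = w)
    }
    unseen[idx] <<- FALSE
    b_in_epoch <<- b_in_epoch + 1L
    if (b_in_epoch >= epoch_len) {
      b_in_epoch <<- 0L
      unseen <<- rep(TRUE, N)
    }
    idx
  }
}
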