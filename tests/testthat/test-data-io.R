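write_tmp_pair <- function(image, mask, dir) {
  ip <- file.path(dir, "img.png"); mp <- file.path(dir, "msk.png")
  write_sample(image, mask, ip, mp)
  list(image = "img.png", mask = "msk.png")
}

test_that("image/mask pairs round-trip losslessly through PNG", {
  dir <- withr::local_tempdir()
  set.seed(31)
  img <- array(round(runif(8 * 8 * 3) * 255) / 255, c(8, 8, 3))
  msk <- matrix(sample(c(0:3, 255L), 64, TRUE), 8, 8)
  rec <- write_tmp_pair(img, msk, dir)
  got <- read_sample(rec, base_dir = dir, n_classes = 4)
  expect_identical(got$mask, msk)
  expect_equal(got$image, img, tolerance = 1e-9)
  expect_error(read_sample(list(image = "nope.png", mask = rec$mask), dir),
               "not found")
})

test_that("alpha channels are dropped with a warning and bad ids rejected", {
  dir <- withr::local_tempdir()
  rgba <- array(runif(6 * 6 * 4), c(6, 6, 4))
  png::writePNG(rgba, file.path(dir, "img.png"))
  png::writePNG(matrix(0, 6, 6), file.path(dir, "msk.png"))
  expect_warning(
    got <- read_sample(list(image = "img.png", mask = "msk.png"), dir),
    "alpha")
  expect_identical(dim(got$image)[3], 3L)

  # a mask with an id beyond n_classes - 1 is refused, naming the file
  bad <- matrix(5L, 6, 6)
  png::writePNG(bad / 255, file.path(dir, "badmsk.png"))
  expect_error(
    suppressWarnings(read_sample(list(image = "img.png",
                                      mask = "badmsk.png"),
                                 dir, n_classes = 4)),
    "unknown label")
})

test_that("LabelMe polygons rasterize by pixel centers, later shapes winning", {
  cmap <- paddy_class_map(2)
  doc <- list(imageHeight = 16, imageWidth = 16, shapes = list(
    list(label = "weed_1",
         points = list(list(0, 0), list(10, 0), list(10, 10), list(0, 10)))))
  mask <- import_labelme(doc, cmap)
  expect_equal(sum(mask == 2), 100)            # pixels (0..9, 0..9)
  expect_equal(sum(mask != 0), 100)

  # empty shape list gives an all-background mask
  empty <- import_labelme(list(imageHeight = 8, imageWidth = 8,
                               shapes = list()), cmap)
  expect_true(all(empty == 0))

  # overlapping polygons: the later one wins on the overlap
  doc2 <- list(imageHeight = 16, imageWidth = 16, shapes = list(
    list(label = "crop",
         points = list(list(0, 0), list(12, 0), list(12, 12), list(0, 12))),
    list(label = "weed_2",
         points = list(list(6, 6), list(16, 6), list(16, 16), list(6, 16)))))
  m2 <- import_labelme(doc2, cmap)
  expect_equal(m2[8, 8], 3L)
  expect_equal(m2[2, 2], 1L)

  expect_error(import_labelme(list(imageHeight = 4, imageWidth = 4,
                                   shapes = list(list(label = "thistle",
                                                      points = list(list(0, 0))))),
                              cmap),
               "unknown class")
})

test_that("polygon rasterization agrees with a point-in-polygon loop oracle", {
  set.seed(33)
  cmap <- paddy_class_map(1)
  # an irregular pentagon with non-integer vertices
  pts <- list(list(1.3, 2.1), list(9.7, 0.8), list(11.2, 7.5),
              list(6.1, 11.9), list(0.7, 8.2))
  doc <- list(imageHeight = 14, imageWidth = 14,
              shapes = list(list(label = "crop", points = pts)))
  mask <- import_labelme(doc, cmap)
  poly <- do.call(rbind, lapply(pts, unlist))
  # independent winding-number test per pixel center
  inside_wn <- function(px, py) {
    n <- nrow(poly); wn <- 0
    for (i in seq_len(n)) {
      j <- i %% n + 1
      x1 <- poly[i, 1]; y1 <- poly[i, 2]
      x2 <- poly[j, 1]; y2 <- poly[j, 2]
      if (y1 <= py) {
        if (y2 > py && (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1) > 0)
          wn <- wn + 1
      } else if (y2 <= py &&
                 (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1) < 0) {
        wn <- wn - 1
      }
    }
    wn != 0
  }
  for (r in seq(1, 14, by = 2)) for (cc in seq(1, 14, by = 2))
    expect_identical(mask[r, cc] == 1L, inside_wn(cc - 0.5, r - 0.5),
                     info = sprintf("pixel (%d, %d)", r, cc))
})

test_that("preprocessing resizes cleanly and standardizes with ImageNet constants", {
  set.seed(34)
  img <- array(runif(20 * 24 * 3), c(20, 24, 3))
  msk <- matrix(sample(0:3, 20 * 24, TRUE), 20, 24)
  out <- preprocess(img, msk, size = c(10, 12), normalize = FALSE)
  expect_identical(dim(out$image)[1:2], c(10L, 12L))
  expect_true(all(out$mask %in% 0:3))           # nearest keeps ids intact
  # identity resize leaves the pair untouched
  same <- preprocess(img, msk, size = c(20, 24), normalize = FALSE)
  expect_identical(same$image, img)
  expect_identical(same$mask, msk)
  # the ImageNet-mean colour standardizes to exactly zero
  flat <- array(rep(c(0.485, 0.456, 0.406), each = 12), c(3, 4, 3))
  z <- preprocess(flat, matrix(0L, 3, 4))
  expect_equal(max(abs(z$image)), 0, tolerance = 1e-12)
})

test_that("augmentation flips at the advertised rate", {
  set.seed(35)
  img <- array(runif(4 * 4 * 3), c(4, 4, 3))
  img[1, 1, ] <- 1; img[1, 4, ] <- 0     # asymmetric marker
  msk <- matrix(0L, 4, 4)
  n <- 1e4
  flips <- 0L
  for (i in seq_len(n)) {
    out <- augment(img, msk, max_rotation = 0, brightness = 0, contrast = 0,
                   saturation = 0, hue = 0)
    flips <- flips + (out$image[1, 4, 1] == 1)
  }
  se <- sqrt(0.25 / n)
  expect_lt(abs(flips / n - 0.5), 3 * se)
})

test_that("geometric augmentation is label-safe and flip is an involution", {
  set.seed(36)
  img <- array(runif(12 * 12 * 3), c(12, 12, 3))
  msk <- matrix(sample(0:3, 144, TRUE), 12, 12)
  # forced double flip with no other transform restores the input
  once <- augment(img, msk, p_flip = 1, max_rotation = 0, brightness = 0,
                  contrast = 0, saturation = 0, hue = 0)
  twice <- augment(once$image, once$mask, p_flip = 1, max_rotation = 0,
                   brightness = 0, contrast = 0, saturation = 0, hue = 0)
  expect_equal(twice$image, img, tolerance = 1e-12)
  expect_identical(twice$mask, msk)
  # rotation introduces at most the ignore label, never a new class
  for (i in 1:10) {
    out <- augment(img, msk)
    expect_true(all(out$mask %in% c(unique(as.vector(msk)), 255L)))
    expect_true(all(out$image >= 0 & out$image <= 1))
  }
})

test_that("stratified sampling lifts rare-class presence and covers epochs", {
  # 9:1 presence imbalance between two foreground classes
  set.seed(37)
  N <- 60
  presence <- cbind(rep(TRUE, N), c(rep(TRUE, 6), rep(FALSE, N - 6)))
  nb <- stratified_batches(presence, batch_size = 6)
  seen <- integer(0)
  minority_share <- 0
  n_batches <- 200
  for (i in seq_len(n_batches)) {
    idx <- nb()
    expect_length(idx, 6)
    seen <- union(seen, idx)
    minority_share <- minority_share + mean(presence[idx, 2])
  }
  expect_identical(sort(seen), 1:N)              # epoch coverage
  expect_gt(minority_share / n_batches, 0.1)     # above the raw frequency

  # single-class data degenerates to (near) uniform sampling
  nb1 <- stratified_batches(matrix(TRUE, 30, 1), batch_size = 5)
  draws <- table(factor(unlist(replicate(120, nb1())), levels = 1:30))
  expect_lt(max(draws) / min(draws), 2.5)

  # a fixed seed reproduces the batch sequence exactly
  mk <- function() {
    set.seed(99)
    f <- stratified_batches(presence, 6)
    lapply(1:20, function(i) f())
  }
  expect_identical(mk(), mk())
  expect_error(stratified_batches(matrix(TRUE, 0, 1), 4), "empty")
})
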