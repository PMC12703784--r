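toy_counts <- function() {
  # gt = [1, 1, 2, 2], pred = [1, 2, 2, 2] on a 2x2 mask
  confusion_counts(matrix(c(1, 2, 2, 2), 2), matrix(c(1, 1, 2, 2), 2), 3)
}

test_that("confusion counts enumerate pixels exactly", {
  ct <- toy_counts()
  expect_equal(ct$tp[2:3], c(1, 2))    # class 1: TP 1; class 2: TP 2
  expect_equal(ct$fn[2:3], c(1, 0))
  expect_equal(ct$fp[2:3], c(0, 1))
  expect_equal(sum(ct$tp + ct$fn), 4)  # every evaluated pixel accounted for

  # perfect prediction has no off-diagonal mass
  m <- matrix(sample(0:2, 36, TRUE), 6)
  perfect <- confusion_counts(m, m, 3)
  expect_true(all(perfect$fp == 0) && all(perfect$fn == 0))

  # ignore pixels contribute nothing
  gt <- m; gt[1:3, ] <- 255L
  ct2 <- confusion_counts(m, gt, 3)
  expect_equal(sum(ct2$conf), sum(gt != 255L))
  all_ignore <- confusion_counts(m, matrix(255L, 6, 6), 3)
  expect_equal(sum(all_ignore$conf), 0)

  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3), 2),
               "identical shapes")
  expect_error(confusion_counts(matrix(5, 2, 2), matrix(0, 2, 2), 3),
               "labels outside")
})

test_that("mIoU averages class overlaps over present classes only", {
  expect_equal(miou(toy_counts()), 100 * mean(c(1 / 2, 2 / 3)),
               tolerance = 1e-10)
  m <- matrix(sample(0:2, 25, TRUE), 5)
  expect_equal(miou(confusion_counts(m, m, 3)), 100)
  # disjoint binary masks overlap nowhere
  a <- matrix(c(1, 1, 0, 0), 2); b <- matrix(c(0, 0, 1, 1), 2)
  expect_equal(miou(confusion_counts(a, b, 2)), 0)
  expect_error(miou(confusion_counts(matrix(255L, 2, 2),
                                     matrix(255L, 2, 2), 2)),
               "no class")
})

test_that("micro precision/recall/F1 pool foreground counts", {
  prf <- micro_prf(toy_counts())
  expect_equal(unname(prf), c(75, 75, 75))
  # harmonic identity: P = R forces F1 = P
  expect_equal(prf[["f1"]], prf[["precision"]])
  # no predicted foreground: precision 0 with a warning
  expect_warning(
    p0 <- micro_prf(confusion_counts(matrix(0L, 2, 2),
                                     matrix(c(0L, 1L, 0L, 1L), 2), 2)),
    "precision")
  expect_equal(p0[["precision"]], 0)
})

test_that("weed IoU merges weed species before counting", {
  cmap <- paddy_class_map(2)
  # a weed_1 pixel predicted as weed_2 is a merged true positive
  gt <- matrix(c(2L, 2L, 3L, 0L), 2)
  pred <- matrix(c(3L, 2L, 3L, 0L), 2)
  ct <- confusion_counts(pred, gt, 4)
  expect_equal(weed_iou(ct, cmap), 100)
  # with a single weed class it reduces to that class's IoU
  cm1 <- paddy_class_map(1)
  gt1 <- matrix(c(2L, 2L, 0L, 0L), 2); pr1 <- matrix(c(2L, 0L, 2L, 0L), 2)
  ct1 <- confusion_counts(pr1, gt1, 3)
  expect_equal(weed_iou(ct1, cm1), 100 * 1 / 3)
  expect_error(weed_iou(ct1, class_map(c("background", "crop"),
                                       c("background", "crop"))),
               "weed")
})

test_that("vectorized metrics equal the per-pixel enumeration oracle exactly", {
  set.seed(41)
  cmap <- paddy_class_map(2)
  for (i in 1:30) {
    gt <- matrix(sample(c(0:3, 255L), 32 * 32, TRUE,
                        prob = c(0.5, 0.2, 0.15, 0.1, 0.05)), 32)
    pred <- matrix(sample(0:3, 32 * 32, TRUE), 32)
    ct <- confusion_counts(pred, gt, 4)
    ref <- loop_metrics(pred, gt, 4, weed_ids = 2:3)
    expect_identical(miou(ct), ref$miou)
    prf <- suppressWarnings(micro_prf(ct))
    expect_identical(unname(prf), c(ref$precision, ref$recall, ref$f1))
    expect_identical(weed_iou(ct, cmap), ref$weed_iou)
    # merging can only help: weed IoU >= the worst per-class weed IoU
    rep <- metrics_report(ct, cmap)
    expect_gte(rep$weed_iou, min(rep$per_class_iou[3:4], na.rm = TRUE) - 1e-9)
  }
})

test_that("mIoU is invariant to a class relabelling", {
  set.seed(42)
  gt <- matrix(sample(0:3, 100, TRUE), 10)
  pred <- matrix(sample(0:3, 100, TRUE), 10)
  perm <- c(0L, 3L, 1L, 2L)   # background fixed, foreground permuted
  gt2 <- matrix(perm[gt + 1L], 10)
  pred2 <- matrix(perm[pred + 1L], 10)
  expect_equal(miou(confusion_counts(pred, gt, 4)),
               miou(confusion_counts(pred2, gt2, 4)))
})

test_that("reports accumulate, print and serialize coherently", {
  dir <- withr::local_tempdir()
  cmap <- paddy_class_map(2)
  set.seed(43)
  ct <- confusion_counts(matrix(sample(0:3, 64, TRUE), 8),
                         matrix(sample(0:3, 64, TRUE), 8), 4)
  ct2 <- add_confusion(ct, ct)
  expect_equal(ct2$conf, 2 * ct$conf)
  expect_equal(miou(ct2), miou(ct))    # doubling counts keeps the ratios
  rep <- metrics_report(ct, cmap)
  expect_output(print(rep), "mIoU")
  expect_true(rep$f1 <= max(rep$precision, rep$recall) + 1e-9)
  write_metrics_report(rep, file.path(dir, "m.tsv"), file.path(dir, "m.json"))
  tsv <- read.delim(file.path(dir, "m.tsv"))
  expect_equal(tsv$value[tsv$metric == "miou"], rep$miou)
  js <- jsonlite::fromJSON(file.path(dir, "m.json"))
  expect_equal(js$weed_iou, rep$weed_iou)
})
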