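test_that("scene generation is deterministic and label-faithful", {
  spec <- scene_spec()
  s1 <- generate_scene(spec, lab_domain(), seed = 7)
  s2 <- generate_scene(spec, lab_domain(), seed = 7)
  expect_identical(s1, s2)
  expect_identical(dim(s1$image)[1:2], dim(s1$mask))
  expect_true(all(s1$image >= 0 & s1$image <= 1))
  expect_true(all(s1$mask %in% 0:3))
  # every labelled pixel belongs to exactly one rendered instance
  expect_true(all((s1$mask > 0) == (s1$instance_ids > 0)))
  for (k in setdiff(unique(as.vector(s1$mask)), 0))
    expect_gt(sum(s1$mask == k), 0)
  expect_identical(s1$domain, "lab")
  expect_identical(generate_scene(spec, field_domain(), seed = 1)$domain,
                   "field")
})

test_that("objects are rendered where they are labelled", {
  spec <- scene_spec()
  s <- generate_scene(spec, lab_domain(), seed = 30)
  # plant pixels differ in colour statistics from the background
  fg <- s$mask > 0
  skip_if(sum(fg) < 50)
  bg_red <- mean(s$image[, , 1][!fg])
  fg_green <- mean(s$image[, , 2][fg]) - mean(s$image[, , 1][fg])
  bg_green <- mean(s$image[, , 2][!fg]) - bg_red
  expect_gt(fg_green, bg_green)  # vegetation is greener than soil
})

test_that("an impossible scene specification is rejected", {
  expect_error(scene_spec(image_size = c(32, 32), instance_size = c(8, 40)),
               "impossible")
  expect_error(scene_spec(n_classes = 2), "background")
  expect_error(scene_spec(class_weights = c(1, 2)), "foreground")
  expect_error(domain_params(delta = -1), "nonnegative")
})

test_that("zero domain shift reproduces the laboratory distribution", {
  spec <- scene_spec()
  lab <- generate_samples(spec, lab_domain(), 50, seed = 100)
  fld0 <- generate_samples(spec, domain_params(delta = 0, name = "field"),
                           50, seed = 900)
  # per-image mean background intensity: independent across images, so the
  # KS test's i.i.d. assumption holds (raw pixels are correlated through
  # the smooth reflectance field)
  bg_mean <- function(ss)
    vapply(ss, function(s) mean(s$image[, , 2][s$mask == 0]), numeric(1))
  ks <- suppressWarnings(stats::ks.test(bg_mean(lab), bg_mean(fld0)))
  expect_gt(ks$p.value, 0.01)
  # a genuine shift is detected by the same probe
  fld1 <- generate_samples(spec, field_domain(1), 50, seed = 900)
  ks1 <- suppressWarnings(stats::ks.test(bg_mean(lab), bg_mean(fld1)))
  expect_lt(ks1$p.value, 0.01)
})

test_that("datasets round-trip through disk with a faithful manifest", {
  dir <- withr::local_tempdir()
  spec <- scene_spec()
  man <- generate_dataset(spec, lab_domain(), field_domain(1),
                          n_lab = 6, n_field = 10, seed = 5, out_dir = dir)
  expect_equal(sum(man$domain == "lab"), 6)
  expect_equal(sum(man$domain == "field"), 10)
  expect_equal(sum(man$split == "val"), 1)       # 10% of the field images
  expect_equal(sum(man$split == "test"), 9)
  expect_true(all(file.exists(file.path(dir, man$image))))

  # manifest instance counts equal a recount from the masks on disk
  man2 <- read_manifest(file.path(dir, "manifest.tsv"))
  for (i in c(1, 8)) {
    smp <- read_sample(man2[i, ], base_dir = dir, n_classes = 4)
    for (k in 1:3) {
      n_inst <- man2[[paste0("n_class_", k)]][i]
      expect_identical(sum(smp$mask == k) > 0, n_inst > 0)
    }
  }

  # same seed, second run: identical manifest and pixel data
  dir2 <- withr::local_tempdir()
  manb <- generate_dataset(spec, lab_domain(), field_domain(1),
                           n_lab = 6, n_field = 10, seed = 5, out_dir = dir2)
  expect_identical(man, manb)
  expect_identical(readBin(file.path(dir, man$mask[3]), "raw", 1e5),
                   readBin(file.path(dir2, man$mask[3]), "raw", 1e5))
})

test_that("the domain gap probe is a calibrated distance", {
  spec <- scene_spec()
  lab <- generate_samples(spec, lab_domain(), 12, seed = 40)
  expect_equal(domain_gap_probe(lab, lab), 0, tolerance = 1e-6)
  fld <- generate_samples(spec, field_domain(1), 12, seed = 41)
  expect_equal(domain_gap_probe(lab, fld), domain_gap_probe(fld, lab))
  expect_error(domain_gap_probe(lab, list()), "nonempty")
  # monotone in the shift magnitude over repeated draws
  wins <- 0
  for (s in 1:5) {
    small <- generate_samples(spec, field_domain(0.5), 12, seed = 50 + s)
    large <- generate_samples(spec, field_domain(2), 12, seed = 70 + s)
    wins <- wins + (domain_gap_probe(lab, large) > domain_gap_probe(lab, small))
  }
  expect_gte(wins, 4)
})

test_that("class frequency weights are honoured within binomial error", {
  spec <- scene_spec(class_weights = c(0.6, 0.3, 0.1))
  counts <- c(0, 0, 0)
  for (s in 1:90) {
    smp <- generate_scene(spec, lab_domain(), seed = 200 + s)
    for (k in 1:3)
      counts[k] <- counts[k] + length(unique(smp$instance_ids[smp$mask == k]))
  }
  n <- sum(counts)
  expect_gt(n, 400)
  for (k in 1:3) {
    p <- c(0.6, 0.3, 0.1)[k]
    expect_lt(abs(counts[k] / n - p), 4 * sqrt(p * (1 - p) / n))
  }
})
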