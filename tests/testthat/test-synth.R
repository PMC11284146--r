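# Synthetic data module: generator determinism and composition, fold-plan
# properties, the augmentation policy and file I/O.

test_that("the generator produces the configured dataset deterministically", {
  cfg <- synth_config(n_images = 6, image_size = 64, seed = 7)
  ds1 <- generate_synthetic_dataset(cfg)
  ds2 <- generate_synthetic_dataset(cfg)
  expect_length(ds1, 6)
  expect_identical(ds1[[3]]$image, ds2[[3]]$image)          # bitwise
  expect_identical(ds1[[3]]$mask, ds2[[3]]$mask)
  for (s in ds1) {
    expect_gt(sum(s$mask), 0)                               # non-empty masks
    expect_true(all(s$mask %in% c(0, 1)))
    expect_true(all(s$image >= 0 & s$image <= 1))
    expect_true(s$label %in% c("benign", "malignant"))
  }
  # different seeds give different images
  ds3 <- generate_synthetic_dataset(synth_config(n_images = 6, image_size = 64,
                                                 seed = 8))
  expect_false(identical(ds1[[1]]$image, ds3[[1]]$image))
  expect_error(synth_config(n_images = 4, image_size = 64,
                            node_radius_range = c(10, 40)), "exceeds")
})

test_that("blue-dominant area inside lesions tracks the hardness mix", {
  for (mix in c(0.3, 0.6)) {
    cfg <- synth_config(n_images = 100, image_size = 64, hardness_mix = mix,
                        seed = 21)
    fr <- vapply(generate_synthetic_dataset(cfg),
                 function(s) s$blue_fraction, numeric(1))
    expect_lt(abs(mean(fr) - mix), 0.1)
  }
})

test_that("fold plans partition samples into near-equal folds", {
  plan <- make_fold_plan(263, k = 6, seed = 1)
  sizes <- table(plan$fold_of)
  expect_equal(sort(as.numeric(sizes)), c(43, 44, 44, 44, 44, 44))
  # holding out a 44-sized fold gives the 219/44 protocol split
  f44 <- as.integer(names(sizes)[sizes == 44][1])
  sp <- fold_split(plan, f44)
  expect_length(sp$train, 219)
  expect_length(sp$test, 44)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:263)
  # one sample per fold at n = k
  plan6 <- make_fold_plan(6, k = 6, seed = 2)
  expect_equal(sort(as.numeric(table(plan6$fold_of))), rep(1, 6))
  expect_error(make_fold_plan(5, k = 6), "at least")
  # partition property for random n
  set.seed(10)
  for (n in sample(10:100, 5)) {
    p <- make_fold_plan(n, k = 6, seed = n)
    expect_length(p$fold_of, n)
    expect_lte(diff(range(table(p$fold_of))), 1)
    expect_setequal(unique(p$fold_of), 0:5)
  }
})

test_that("augmentation is identity at p = 0 and an involution for pure flips", {
  s <- tiny_dataset(1, 64)[[1]]
  set.seed(1)
  expect_identical(augment(s, p = 0), s)
  # flip-only (rotation angle 0 is an exact identity of the resampler)
  set.seed(2)
  once <- augment(s, p = 1, angle_choices = 0)
  set.seed(3)
  twice <- augment(once, p = 1, angle_choices = 0)
  expect_equal(twice$image, s$image, tolerance = 1e-12)
  expect_equal(twice$mask, s$mask)
})

test_that("rotation keeps masks binary, nearly area-preserving and aligned", {
  S <- 128
  disk <- disk_mask(S, 50)
  samp <- list(image = array(rep(disk, 3), c(S, S, 3)), mask = disk)
  set.seed(4)
  rot <- augment(samp, p = 1, angle_choices = c(-30, 30))
  expect_true(all(rot$mask %in% c(0, 1)))
  expect_lt(abs(sum(rot$mask) - sum(disk)) / sum(disk), 0.05)
  # image (bilinear) and mask (nearest) stay aligned: IoU > 0.95
  img_blob <- (rot$image[, , 1] > 0.5) * 1
  inter <- sum(img_blob * rot$mask)
  uni <- sum((img_blob + rot$mask) > 0)
  expect_gt(inter / uni, 0.95)
})

test_that("resizing and dataset I/O round-trip through PNG files", {
  ds <- tiny_dataset(3, 64)
  big <- ds[[1]]
  big$image <- array(runif(512 * 512 * 3), c(512, 512, 3))
  big$mask <- disk_mask(512, 100)
  small <- resize_to(big, 256)
  expect_equal(dim(small$image), c(256, 256, 3))
  expect_equal(dim(small$mask), c(256, 256))
  expect_true(all(small$mask %in% c(0, 1)))

  dir <- withr::local_tempdir()
  plan <- make_fold_plan(3, k = 3, seed = 1)
  manifest <- write_dataset(ds, dir, fold_plan = plan)
  expect_equal(nrow(manifest), 3)
  got <- load_dataset(file.path(dir, "images"), file.path(dir, "masks"),
                      size = 64)
  expect_length(got$samples, 3)
  expect_equal(nrow(got$errors), 0)
  expect_equal(got$samples[[1]]$mask,
               ds[[which(sapply(ds, `[[`, "image_id") ==
                           got$samples[[1]]$image_id)]]$mask,
               ignore_attr = TRUE)
  # an image without a mask lands in the error report and is skipped
  png::writePNG(array(0.5, c(8, 8, 3)), file.path(dir, "images", "orphan.png"))
  got2 <- load_dataset(file.path(dir, "images"), file.path(dir, "masks"),
                       size = 64)
  expect_length(got2$samples, 3)
  expect_equal(got2$errors$image, "orphan.png")
  # grayscale inputs are replicated to three channels
  png::writePNG(matrix(runif(64), 8, 8), file.path(dir, "images", "gray.png"))
  png::writePNG(matrix(1, 8, 8), file.path(dir, "masks", "gray.png"))
  got3 <- load_dataset(file.path(dir, "images"), file.path(dir, "masks"),
                       size = 64)
  gray <- got3$samples[[which(sapply(got3$samples, `[[`, "image_id") == "gray")]]
  expect_equal(dim(gray$image), c(64, 64, 3))
})
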