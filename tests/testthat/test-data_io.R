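# NIfTI round-trips, preprocessing geometry, augmentation, metrics export.

test_that("NIfTI volumes round-trip through disk, including gzip", {
  ph <- generate_phantom(phantom_spec(shape = c(6, 16, 16), seed = 3))
  for (ext in c(".nii", ".nii.gz")) {
    f <- tempfile(fileext = ext)
    save_volume(ph$image, f)
    back <- load_volume(f, "image")
    expect_equal(dim(back$voxels), c(6, 16, 16))
    expect_lt(max(abs(back$voxels - ph$image$voxels)), 1e-3) # float32 on disk
    fm <- tempfile(fileext = ext)
    save_volume(ph$mask, fm)
    backm <- load_volume(fm, "mask")
    expect_identical(backm$labels, ph$mask$labels)
  }
})

test_that("NIfTI writer agrees with an independent reader (nibabel)", {
  f <- tempfile(fileext = ".nii.gz")
  vol <- image_volume(array(seq_len(4 * 5 * 6) / 7, c(4, 5, 6)),
                      spacing = c(3, 2, 1))
  save_volume(vol, f)
  script <- paste(
    "import nibabel, sys, numpy as np",
    sprintf("img = nibabel.load('%s')", f),
    "d = np.asanyarray(img.dataobj)",
    "print(d.shape[0], d.shape[1], d.shape[2])",
    "print(float(d.sum()))",
    "print(float(d[1, 2, 3]))",
    "print(*img.header.get_zooms())",
    sep = "; ")
  out <- tryCatch(system2("python", c("-c", shQuote(script)), stdout = TRUE,
                          stderr = FALSE),
                  error = function(e) NULL)
  expect_false(is.null(out))
  vals <- strsplit(paste(out, collapse = " "), "\\s+")[[1]]
  # on-disk order is (x, y, z) = (w, h, d)
  expect_equal(as.numeric(vals[1:3]), c(6, 5, 4))
  expect_equal(as.numeric(vals[4]), sum(vol$voxels), tolerance = 1e-4)
  expect_equal(as.numeric(vals[5]), vol$voxels[4, 3, 2], tolerance = 1e-5)
  expect_equal(as.numeric(vals[6:8]), c(1, 2, 3), tolerance = 1e-6)
})

test_that("mask validation names offending labels and rejects DICOM dirs", {
  bad <- array(0L, c(2, 4, 4))
  bad[1, 1, 1] <- 3L
  expect_error(zone_mask(bad), "\\{3\\}")
  f <- tempfile(fileext = ".nii")
  write_nifti(array(c(0, 1, 2, 5), c(2, 2, 1)), f, datatype = 64L)
  expect_error(load_volume(f, "mask"), "outside \\{0,1,2\\}")
  d <- tempfile(); dir.create(d)
  expect_error(load_volume(d, "image"), "DICOM")
})

test_that("preprocess crops the center window and normalizes to [0, 255]", {
  set.seed(5)
  img <- array(rnorm(4 * 320 * 320, 100, 20), c(4, 320, 320))
  lab <- array(0L, c(4, 320, 320))
  lab[, 150:200, 150:200] <- 1L
  pre <- preprocess(image_volume(img), zone_mask(lab), crop_hw = 128,
                    target = c(4, 128, 128))
  expect_equal(dim(pre$image$voxels), c(4, 128, 128))
  # retained index range is 96..223 (0-based): compare against manual crop
  manual <- img[, 97:224, 97:224]
  manual <- (manual - min(manual)) / (max(manual) - min(manual)) * 255
  expect_lt(max(abs(pre$image$voxels - manual)), 1e-9)
  expect_identical(pre$mask$labels, lab[, 97:224, 97:224])
  expect_gte(min(pre$image$voxels), 0)
  expect_lte(max(pre$image$voxels), 255)
})

test_that("preprocess resamples depth, maps constants to zero, is idempotent", {
  ph <- generate_phantom(phantom_spec(shape = c(13, 160, 160), seed = 9))
  pre <- preprocess(ph$image, ph$mask, crop_hw = 128, target = c(20, 128, 128))
  expect_equal(dim(pre$image$voxels), c(20, 128, 128))
  expect_equal(dim(pre$mask$labels), c(20, 128, 128))
  expect_true(all(pre$mask$labels %in% 0:2))
  # constant image maps to all zeros
  cst <- preprocess(image_volume(array(7, c(4, 130, 130))),
                    zone_mask(array(0L, c(4, 130, 130))),
                    crop_hw = 128, target = c(4, 128, 128))
  expect_true(all(cst$image$voxels == 0))
  # idempotence on already-preprocessed input
  pre2 <- preprocess(pre$image, pre$mask, crop_hw = 128, target = c(20, 128, 128))
  expect_lt(max(abs(pre2$image$voxels - pre$image$voxels)), 1e-6)
  expect_identical(pre2$mask$labels, pre$mask$labels)
  expect_error(preprocess(ph$image, ph$mask, crop_hw = 999), "exceeds")
})

test_that("augmentation is seeded, involutive for flips, label-preserving", {
  ph <- generate_phantom(phantom_spec(shape = c(3, 32, 32), seed = 21))
  a1 <- augment_pair(ph$image, ph$mask, seed = 5)
  a2 <- augment_pair(ph$image, ph$mask, seed = 5)
  expect_identical(a1$image$voxels, a2$image$voxels)
  expect_identical(a1$mask$labels, a2$mask$labels)
  # label multiset preserved under every draw
  for (s in 1:12) {
    a <- augment_pair(ph$image, ph$mask, seed = s)
    expect_equal(table(a$mask$labels), table(ph$mask$labels))
    expect_equal(sort(as.vector(a$image$voxels)), sort(as.vector(ph$image$voxels)))
  }
})

test_that("90-degree rotation maps (r, c) to (c, h-1-r)", {
  # find a seed whose draw is (no flip, one quarter turn) by replaying the
  # documented draw order
  seed <- NULL
  for (s in 1:200) {
    draw <- with_seed(s, list(flip = sample(c("none", "horizontal", "vertical"), 1),
                              turns = sample(0:3, 1)))
    if (draw$flip == "none" && draw$turns == 1) { seed <- s; break }
  }
  expect_false(is.null(seed))
  img <- array(seq_len(2 * 6 * 6), c(2, 6, 6))
  msk <- array(0L, c(2, 6, 6))
  a <- augment_pair(image_volume(img), zone_mask(msk), seed = seed)
  h <- 6
  for (r in 0:(h - 1)) for (c in 0:(h - 1)) {
    expect_equal(a$image$voxels[1, c + 1, h - r], img[1, r + 1, c + 1])
  }
  # flips are involutions: applying the same flip seed twice restores input
  seed_f <- NULL
  for (s in 1:200) {
    draw <- with_seed(s, list(flip = sample(c("none", "horizontal", "vertical"), 1),
                              turns = sample(0:3, 1)))
    if (draw$flip == "horizontal" && draw$turns == 0) { seed_f <- s; break }
  }
  b1 <- augment_pair(image_volume(img), zone_mask(msk), seed = seed_f)
  b2 <- augment_pair(b1$image, b1$mask, seed = seed_f)
  expect_equal(b2$image$voxels, img, ignore_attr = FALSE, tolerance = 0)
})

test_that("augment_dataset doubles the set deterministically", {
  pairs <- lapply(1:3, function(i) {
    generate_phantom(phantom_spec(shape = c(2, 16, 16), seed = i))
  })
  aug1 <- augment_dataset(pairs, seed = 99)
  aug2 <- augment_dataset(pairs, seed = 99)
  expect_length(aug1, 6L)
  expect_identical(aug1[[5]]$image$voxels, aug2[[5]]$image$voxels)
  expect_match(aug1[[4]]$image$subject_id, "_aug$")
})

test_that("export_metrics writes rows plus mean/sd/worst summaries", {
  rec <- data.frame(subject_id = rep(c("a", "b", "c"), each = 2),
                    class = rep(c("TZ", "PZ"), 3),
                    dsc = c(0.8, 0.7, 0.9, 0.8, 1.0, 0.9),
                    iou = c(0.7, 0.6, 0.8, 0.7, 1.0, 0.8),
                    msd = c(1.0, 2.0, 0.5, 1.0, 0.0, 0.5),
                    flags = "", stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".csv")
  out <- export_metrics(rec, f)
  expect_true(file.exists(f))
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_identical(names(back), c("subject_id", "class", "dsc", "iou", "msd", "flags"))
  tz <- back[back$class == "TZ", ]
  expect_equal(tz$dsc[tz$subject_id == "mean"], 0.9)
  expect_equal(tz$dsc[tz$subject_id == "worst_case"], 0.8)
  expect_equal(tz$dsc[tz$subject_id == "sd"], pop_sd(c(0.8, 0.9, 1.0)))
  expect_equal(tz$msd[tz$subject_id == "worst_case"], 1.0)
  expect_error(export_metrics(rec[0, ], f), "no metrics")
})
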