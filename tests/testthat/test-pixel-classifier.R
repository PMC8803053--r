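const_image <- function(rgb, nr = 40, nc = 40, psz = 1) {
  calibrated_image(array(rep(rgb, each = nr * nc), c(nr, nc, 3)), psz)
}

test_that("feature planes behave on degenerate inputs", {
  img <- const_image(c(120, 80, 200))
  f <- extract_features(img)
  cfg <- default_feature_config()
  for (i in seq_len(nrow(cfg))) {
    plane <- f[, , i]
    if (cfg$filter[i] == "gauss") {
      expect_equal(max(abs(plane - img$pixels[1, 1, cfg$channel[i]])), 0,
                   tolerance = 1e-9)
    } else {
      expect_equal(max(abs(plane)), 0, tolerance = 1e-9)
    }
  }
  # sigma = 0 gauss is the identity on the resampled channel
  raw_idx <- which(cfg$filter == "gauss" & cfg$sigma == 0 & cfg$channel == 1)
  img2 <- fixture_tissue()$image
  f2 <- extract_features(img2)
  expect_identical(f2[, , raw_idx], img2$pixels[, , 1])
})

test_that("Gaussian feature on a delta image matches a direct convolution oracle", {
  nr <- 41; nc <- 41
  arr <- array(0, c(nr, nc, 3))
  arr[21, 21, ] <- 255
  img <- calibrated_image(arr, 1)
  cfg <- data.frame(channel = 1, filter = "gauss", sigma = 4,
                    stringsAsFactors = FALSE)
  f <- extract_features(img, cfg)
  k1 <- adipoquant:::.gauss_kernel_1d(4)
  oracle <- conv2_oracle(img$pixels[, , 1], outer(k1, k1))
  expect_equal(f[, , 1], oracle, tolerance = 1e-10)
})

test_that("a feature scale larger than the image is rejected", {
  img <- const_image(c(100, 100, 100), nr = 10, nc = 10)
  cfg <- data.frame(channel = 1, filter = "gauss", sigma = 8,
                    stringsAsFactors = FALSE)
  expect_error(extract_features(img, cfg), "scale")
})

test_that("training reaches high held-out accuracy on a clean render and is deterministic", {
  model <- fixture_model()
  expect_gte(model$holdout_accuracy, 0.98)
  gen <- fixture_tissue()
  labels <- make_labels_from_truth(gen)
  model2 <- train_pixel_classifier(
    list(list(image = gen$image, labels = labels)), seed = 7)
  probe <- gen$image
  m1 <- classify_pixels(model, probe)
  m2 <- classify_pixels(model2, probe)
  expect_identical(m1$mask, m2$mask)
  m3 <- classify_pixels(model, probe)
  expect_identical(m1$mask, m3$mask)
})

test_that("single-class annotations fail with the missing class named", {
  gen <- fixture_tissue()
  labels <- make_labels_from_truth(gen)
  only_fat <- labels; only_fat[only_fat == 2L] <- 0L
  expect_error(train_pixel_classifier(
    list(list(image = gen$image, labels = only_fat)), seed = 1), "tissue")
  only_tissue <- labels; only_tissue[only_tissue == 1L] <- 0L
  expect_error(train_pixel_classifier(
    list(list(image = gen$image, labels = only_tissue)), seed = 1), "fat")
})

test_that("classifying the training image agrees with its labels", {
  gen <- fixture_tissue()
  labels <- make_labels_from_truth(gen)
  mask <- classify_pixels(fixture_model(), gen$image)
  lab_px <- which(labels > 0L)
  agreement <- mean(mask$mask[lab_px] == (labels[lab_px] == 1L))
  expect_gte(agreement, 0.95)
})

test_that("palette probe images classify to the expected single class", {
  model <- fixture_model()
  white <- const_image(c(250, 250, 250))
  membrane <- const_image(c(168, 112, 160))
  expect_true(all(classify_pixels(model, white)$mask))
  expect_false(any(classify_pixels(model, membrane)$mask))
})

test_that("pixels outside the ROI polygon are forced to tissue", {
  gen <- fixture_tissue()
  half <- cbind(c(0, 400, 400, 0), c(0, 0, 600, 600))
  mask <- classify_pixels(fixture_model(), gen$image, roi_polygon = half)
  expect_false(any(mask$mask[, 401:800]))
  expect_true(any(mask$mask[, 1:400]))
})

test_that("fat fraction matches the ground-truth lumen fraction within 3 points", {
  gen <- fixture_tissue()
  mask <- classify_pixels(fixture_model(), gen$image)
  d <- dim(gen$image$pixels)
  lab <- adipoquant:::.rasterize_polygons(
    gen$truth$cell_polygons, d[1], d[2], 1, 0, 0)
  expect_lt(abs(mean(mask$mask) - mean(lab > 0)), 0.03)
})

test_that("swapping training classes complements the mask", {
  gen <- fixture_tissue()
  labels <- make_labels_from_truth(gen)
  swapped <- labels
  swapped[labels == 1L] <- 2L
  swapped[labels == 2L] <- 1L
  m_orig <- classify_pixels(fixture_model(), gen$image)
  model_sw <- train_pixel_classifier(
    list(list(image = gen$image, labels = swapped)), seed = 7)
  m_sw <- classify_pixels(model_sw, gen$image)
  expect_identical(m_sw$mask, !m_orig$mask)
})

test_that("incremental annotation retrains and can fix a biased model", {
  gen <- fixture_tissue()
  labels <- make_labels_from_truth(gen, n_per_class = 300, seed = 2)
  model <- train_pixel_classifier(
    list(list(image = gen$image, labels = labels)), seed = 3)
  more <- make_labels_from_truth(gen, n_per_class = 1500, seed = 4)
  model2 <- add_training_annotations(model, gen$image, more)
  expect_s3_class(model2, "pixel_classifier_model")
  expect_gt(nrow(model2$train_x), nrow(model$train_x))
  expect_gte(model2$holdout_accuracy, 0.98)
})

test_that("model round-trips through its serialized container", {
  model <- fixture_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_pixel_classifier(model, path)
  loaded <- load_pixel_classifier(path)
  gen <- fixture_tissue()
  expect_identical(classify_pixels(loaded, gen$image)$mask,
                   classify_pixels(model, gen$image)$mask)
})

test_that("classification requires a calibrated image", {
  expect_error(classify_pixels(fixture_model(), matrix(1, 4, 4)),
               "calibrated_image")
})
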