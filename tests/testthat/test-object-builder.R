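test_that("hole filling respects the size threshold and border rule", {
  # 10 x 10 um fat square at 1 um/px with a 2 x 2 px hole (4 um^2 < 30)
  m <- matrix(TRUE, 10, 10)
  m[5:6, 5:6] <- FALSE
  filled <- fill_small_holes(toy_mask(m), 30)
  expect_true(all(filled$mask))
  # a 6 x 6 px hole (36 um^2 >= 30) is kept
  m2 <- matrix(TRUE, 10, 10)
  m2[3:8, 3:8] <- FALSE
  kept <- fill_small_holes(toy_mask(m2), 30)
  expect_identical(kept$mask, m2)
  # threshold 0 is the identity
  expect_identical(fill_small_holes(toy_mask(m2), 0)$mask, m2)
  # a gap open to the border is never a hole
  m3 <- matrix(TRUE, 10, 10)
  m3[1:2, 5] <- FALSE
  expect_identical(fill_small_holes(toy_mask(m3), 30)$mask, m3)
  # boundary convention: a hole of exactly the threshold area survives
  m4 <- matrix(TRUE, 20, 20)
  m4[6:11, 6:10] <- FALSE  # 30 px = 30 um^2
  expect_identical(fill_small_holes(toy_mask(m4), 30)$mask, m4)
  m4[6:11, 6:10] <- FALSE
  m5 <- matrix(TRUE, 20, 20)
  m5[6:10, 6:10] <- FALSE  # 25 px < 30 um^2
  expect_true(all(fill_small_holes(toy_mask(m5), 30)$mask))
})

test_that("small-object removal keeps components at the threshold", {
  m <- matrix(FALSE, 12, 12)
  m[2:5, 2:6] <- TRUE  # 20 px = 20 um^2, kept (inclusive bound)
  m[8:11, 8:11] <- TRUE
  m[8, 8] <- FALSE  # 15 px < 20, removed
  out <- remove_small_objects(toy_mask(m), 20)
  expect_true(all(out$mask[2:5, 2:6]))
  expect_false(any(out$mask[8:11, 8:11]))
  # 19 um^2 blob removed, 20 um^2 kept
  m19 <- matrix(FALSE, 10, 10); m19[2:5, 2:6] <- TRUE; m19[5, 6] <- FALSE
  expect_false(any(remove_small_objects(toy_mask(m19), 20)$mask))
  # empty mask passes through
  empty <- toy_mask(matrix(FALSE, 5, 5))
  expect_identical(remove_small_objects(empty, 20)$mask, empty$mask)
})

test_that("mask operations agree with a brute-force flood-fill oracle", {
  set.seed(42)
  for (i in 1:30) {
    m <- matrix(runif(64 * 64) < runif(1, 0.3, 0.7), 64, 64)
    cm <- toy_mask(m)
    expect_identical(fill_small_holes(cm, 30)$mask, fill_holes_oracle(m, 30))
    expect_identical(remove_small_objects(cm, 20)$mask,
                     remove_small_oracle(m, 20))
    lab <- label_components(m, 4)
    oracle <- flood_label_oracle(m, 4)
    expect_identical(attr(lab, "n_labels"), attr(oracle, "n_labels"))
    # label partitions must match up to renumbering
    expect_identical(lab > 0, oracle > 0)
    expect_true(all(tapply(oracle[m], lab[m], function(x) length(unique(x))) == 1))
    lab8 <- label_components(m, 8)
    oracle8 <- flood_label_oracle(m, 8)
    expect_identical(attr(lab8, "n_labels"), attr(oracle8, "n_labels"))
  }
})

test_that("watershed splits a fused disc pair along the neck", {
  # two overlapping discs, radius 40 um, centres 60 um apart
  cm <- disc_mask(100, 160, list(c(50, 50), c(50, 110)), 40)
  lab <- split_touching(cm)
  expect_identical(attr(lab, "n_labels"), 2L)
  expect_true(lab[50, 50] != lab[50, 110])
  expect_true(all(lab[cm$mask] > 0))  # conservation: no pixel dropped
  expect_true(all(lab[!cm$mask] == 0))
  # a single disc passes through unchanged
  one <- disc_mask(100, 100, list(c(50, 50)), 40)
  lab1 <- split_touching(one)
  expect_identical(attr(lab1, "n_labels"), 1L)
  expect_identical(lab1 > 0, one$mask)
})

test_that("split_objects = FALSE leaves fused pairs as one component", {
  cm <- disc_mask(100, 160, list(c(50, 50), c(50, 110)), 40)
  no_split <- object_builder_settings(split_objects = FALSE)
  objs <- mask_to_objects(cm, no_split)
  expect_identical(nrow(objs), 1L)
  objs2 <- mask_to_objects(cm, object_builder_settings())
  expect_identical(nrow(objs2), 2L)
  # conservation through the split
  expect_equal(sum(objs2$pixel_count), sum(cm$mask))
})

test_that("object areas equal pixel counts times pixel area on a toy mask", {
  m <- matrix(FALSE, 32, 32)
  m[2:7, 2:7] <- TRUE              # 36 px
  m[12:19, 5:14] <- TRUE           # 80 px
  m[24:31, 20:31] <- TRUE          # 96 px
  objs <- mask_to_objects(toy_mask(m, pixel_size_um = 0.5),
                          object_builder_settings(min_object_size_um2 = 5))
  expect_identical(nrow(objs), 3L)
  expect_equal(sort(objs$pixel_count), c(36L, 80L, 96L))
  expect_equal(objs$area_um2, objs$pixel_count * 0.25)
  expect_equal(objs$diameter_um, 2 * sqrt(objs$area_um2 / pi))
})

test_that("boundary polygons close around their pixels and match areas", {
  m <- matrix(FALSE, 20, 20)
  m[5:10, 5:12] <- TRUE
  objs <- mask_to_objects(toy_mask(m), object_builder_settings())
  b <- objs$boundary[[1]]
  # rectangle 6 x 8 px -> polygon area 48 um^2, equals pixel-count area
  expect_equal(abs(polygon_area(b)), objs$area_um2[1])
  expect_equal(nrow(b), 4L)
  # centroid inside bounding box of the boundary
  expect_gte(objs$centroid_x_um[1], min(b[, 1]))
  expect_lte(objs$centroid_x_um[1], max(b[, 1]))
})

test_that("raising min object size never increases the object count", {
  set.seed(17)
  m <- matrix(runif(96 * 96) < 0.55, 96, 96)
  cm <- toy_mask(m)
  counts <- vapply(c(0, 5, 10, 20, 40, 80), function(thr) {
    nrow(mask_to_objects(cm, object_builder_settings(
      min_object_size_um2 = thr, split_objects = FALSE)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("areas are resolution-invariant within rasterization tolerance", {
  cm <- disc_mask(64, 64, list(c(32, 32)), 20)        # ~1257 um^2 at 1 um/px
  up <- cm$mask[rep(seq_len(64), each = 2), rep(seq_len(64), each = 2)]
  cm2 <- class_mask(up, 0.5)
  a1 <- mask_to_objects(cm, object_builder_settings())$area_um2
  a2 <- mask_to_objects(cm2, object_builder_settings())$area_um2
  expect_equal(a1, a2, tolerance = 0.02)
})

test_that("an all-tissue mask yields no objects", {
  objs <- mask_to_objects(toy_mask(matrix(FALSE, 30, 30)),
                          object_builder_settings())
  expect_identical(nrow(objs), 0L)
})

test_that("full pipeline on a good render recovers the true cell count", {
  gen <- fixture_tissue()
  mask <- classify_pixels(fixture_model(), gen$image)
  objs <- mask_to_objects(mask, object_builder_settings())
  objs <- filter_by_area(objs, area_filter())
  expect_lt(abs(nrow(objs) - gen$truth$true_count) / gen$truth$true_count,
            0.05)
})
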