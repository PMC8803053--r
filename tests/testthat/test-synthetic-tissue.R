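test_that("generated cell count tracks the target density", {
  spec <- tissue_spec(region_width_um = 2000, region_height_um = 1000,
                      target_density = 150, seed = 7)
  gen <- generate_tissue(spec)
  target <- 150 * 2000 * 1000 / 1e6  # 300 whole cells
  expect_gt(gen$truth$true_count, target * 0.85)
  expect_lt(gen$truth$true_count, target * 1.15)
  expect_equal(gen$truth$true_count, length(gen$truth$cell_polygons))
  expect_true(all(gen$truth$cell_areas_um2 > 0))
})

test_that("generation is deterministic for a fixed seed", {
  spec <- tissue_spec(region_width_um = 500, region_height_um = 400,
                      target_density = 150, seed = 21)
  a <- generate_tissue(spec)
  b <- generate_tissue(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$cell_areas_um2, b$truth$cell_areas_um2)
  expect_identical(a$truth$cell_polygons, b$truth$cell_polygons)
})

test_that("degenerate densities raise an empty-tessellation error", {
  expect_error(generate_tissue(tissue_spec(target_density = 0)),
               "empty tessellation")
  expect_error(
    generate_tissue(tissue_spec(region_width_um = 50, region_height_um = 50,
                                target_density = 1)),
    "empty tessellation")
})

test_that("lumina are near-white and membranes stained in good mode", {
  gen <- fixture_tissue()
  d <- dim(gen$image$pixels)
  lab <- adipoquant:::.rasterize_polygons(
    gen$truth$cell_polygons, d[1], d[2], gen$image$pixel_size_um, 0, 0)
  lumen_mean <- mean(gen$image$pixels[, , 2][lab > 0])
  membrane_mean <- mean(gen$image$pixels[, , 2][lab == 0])
  expect_gte(lumen_mean, 230)
  expect_lt(membrane_mean, 180)
})

test_that("ground-truth polygons are disjoint and fit inside the ROI", {
  gen <- fixture_tissue()
  truth <- gen$truth
  expect_lte(sum(truth$cell_areas_um2),
             truth$region_width_um * truth$region_height_um)
  # rasterize at fine resolution: no pixel may be claimed twice
  lab <- adipoquant:::.rasterize_polygons(
    truth$cell_polygons, 1200, 1600, 0.5, 0, 0)
  expect_identical(attr(lab, "n_overlap"), 0)
  for (p in truth$cell_polygons) {
    expect_true(all(p[, 1] >= 0 & p[, 1] <= truth$region_width_um))
    expect_true(all(p[, 2] >= 0 & p[, 2] <= truth$region_height_um))
  }
})

test_that("areas are geometric: shoelace on the polygons reproduces them", {
  truth <- fixture_tissue()$truth
  shoelace <- vapply(truth$cell_polygons,
                     function(p) abs(polygon_area(p)), numeric(1))
  expect_equal(shoelace, truth$cell_areas_um2, tolerance = 1e-12)
})

test_that("pixel size changes the raster but not the ground truth", {
  base <- tissue_spec(region_width_um = 400, region_height_um = 300,
                      target_density = 150, seed = 9, pixel_size_um = 1)
  fine <- tissue_spec(region_width_um = 400, region_height_um = 300,
                      target_density = 150, seed = 9, pixel_size_um = 0.5)
  a <- generate_tissue(base)
  b <- generate_tissue(fine)
  expect_identical(a$truth$cell_areas_um2, b$truth$cell_areas_um2)
  expect_identical(dim(b$image$pixels)[1:2], 2L * dim(a$image$pixels)[1:2])
})

test_that("spillover tints bands deterministically and darkens lumina", {
  gen <- fixture_tissue()
  sp1 <- apply_spillover(gen$image, gen$truth, fraction = 0.4, seed = 3)
  sp2 <- apply_spillover(gen$image, gen$truth, fraction = 0.4, seed = 3)
  expect_identical(sp1$pixels, sp2$pixels)
  d <- dim(gen$image$pixels)
  lab <- adipoquant:::.rasterize_polygons(
    gen$truth$cell_polygons, d[1], d[2], 1, 0, 0)
  lum <- lab > 0
  expect_lt(mean(sp1$pixels[, , 2][lum]), mean(gen$image$pixels[, , 2][lum]))
  # pixels outside every cell are untouched
  expect_identical(sp1$pixels[, , 1][lab == 0], gen$image$pixels[, , 1][lab == 0])
  expect_error(apply_spillover(gen$image, gen$truth, 0), "fraction")
  expect_error(apply_spillover(gen$image, gen$truth, 1.2), "fraction")
})

test_that("quality grades map to increasing spillover", {
  mk <- function(grade) {
    spec <- tissue_spec(region_width_um = 400, region_height_um = 300,
                        target_density = 150, seed = 13,
                        quality_grade = grade)
    generate_tissue(spec)
  }
  good <- mk("good"); avg <- mk("average"); poor <- mk("poor")
  expect_identical(good$truth$cell_areas_um2, poor$truth$cell_areas_um2)
  g <- mean(good$image$pixels[, , 2])
  a <- mean(avg$image$pixels[, , 2])
  p <- mean(poor$image$pixels[, , 2])
  expect_lt(p, a)
  expect_lt(a, g)
})
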