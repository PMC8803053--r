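#' Specification of a synthetic adipose-tissue region
#'
#' Describes a rectangular region of H&E-like subcutaneous adipose tissue:
#' polygonal fat cells (near-white lumina, the lipid having dissolved during
#' processing) separated by thin stained membranes, rendered at a given
#' physical resolution. `quality_grade` reproduces the visual grading of
#' section/staining quality: `"good"` renders crisp membranes only,
#' `"average"` tints half of `spillover_fraction` of each lumen,
#' `"poor"` tints the full `spillover_fraction` — emulating the artefactual
#' "spilling of staining" adjacent to membranes that corrupts lumen
#' detection.
#'
#' @param region_width_um,region_height_um region size in micrometres.
#' @param target_density target cell density, whole cells per 10^6 um^2.
#' @param membrane_thickness_um thickness of the stained membrane between
#'   neighbouring lumina, micrometres.
#' @param cell_size_cv coefficient of variation of cell areas. The
#'   tessellation's own spread is topped up with lognormal multiplicative
#'   jitter toward this value (realized CV is approximate, see vignette).
#' @param quality_grade `"good"`, `"average"` or `"poor"`.
#' @param spillover_fraction fraction of each lumen area tinted in poor
#'   mode, in \[0, 1\].
#' @param noise_sd Gaussian pixel noise standard deviation, 8-bit units.
#' @param pixel_size_um rendering resolution, micrometres per pixel.
#' @param seed integer seed; fixes the tessellation, jitter and noise.
#' @return An object of class `tissue_spec`.
#' @export
tissue_spec <- function(region_width_um = 2000, region_height_um = 1000,
                        target_density = 150, membrane_thickness_um = 3,
                        cell_size_cv = 0.45,
                        quality_grade = c("good", "average", "poor"),
                        spillover_fraction = 0.4, noise_sd = 4,
                        pixel_size_um = 1, seed = 1L) {
  quality_grade <- match.arg(quality_grade)
  if (region_width_um <= 0 || region_height_um <= 0)
    stop("region dimensions must be positive")
  if (membrane_thickness_um <= 0) stop("membrane_thickness_um must be positive")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (spillover_fraction < 0 || spillover_fraction > 1)
    stop("spillover_fraction must be in [0, 1]")
  if (cell_size_cv < 0) stop("cell_size_cv must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(
    list(region_width_um = region_width_um,
         region_height_um = region_height_um,
         target_density = target_density,
         membrane_thickness_um = membrane_thickness_um,
         cell_size_cv = cell_size_cv,
         quality_grade = quality_grade,
         spillover_fraction = spillover_fraction,
         noise_sd = noise_sd,
         pixel_size_um = pixel_size_um,
         seed = as.integer(seed)),
    class = "tissue_spec")
}

#' @export
print.tissue_spec <- function(x, ...) {
  cat(sprintf(
    "<tissue_spec> %g x %g um, %g cells/1e6 um^2, grade %s, %g um/px, seed %d\n",
    x$region_width_um, x$region_height_um, x$target_density,
    x$quality_grade, x$pixel_size_um, x$seed))
  invisible(x)
}

# H&E-like palette (8-bit RGB)
.membrane_rgb <- c(168, 112, 160)
.lumen_rgb    <- c(245, 243, 246)
# spillover tint: membrane colour, slightly desaturated toward white —
# strong enough that tinted lumen reads as faintly stained tissue
.spill_rgb    <- .membrane_rgb + 0.10 * (255 - .membrane_rgb)

# Poisson-disc style dart throwing: n points in [x0,x1]x[y0,y1] with minimum
# spacing rmin; grid-bucketed; gives up after max_attempts candidates.
.dart_throw <- function(n, x0, x1, y0, y1, rmin) {
  cell <- rmin / sqrt(2)
  gx <- max(1L, ceiling((x1 - x0) / cell))
  gy <- max(1L, ceiling((y1 - y0) / cell))
  grid <- matrix(0L, gy, gx)
  px <- numeric(n); py <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 40L * n
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    cx <- runif(1, x0, x1); cy <- runif(1, y0, y1)
    ix <- min(gx, 1L + floor((cx - x0) / cell))
    iy <- min(gy, 1L + floor((cy - y0) / cell))
    ok <- TRUE
    for (dy in -2:2) {
      for (dx in -2:2) {
        jx <- ix + dx; jy <- iy + dy
        if (jx < 1 || jy < 1 || jx > gx || jy > gy) next
        k <- grid[jy, jx]
        if (k > 0 && (px[k] - cx)^2 + (py[k] - cy)^2 < rmin^2) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) {
      placed <- placed + 1L
      px[placed] <- cx; py[placed] <- cy
      grid[iy, ix] <- placed
    }
  }
  cbind(px[seq_len(placed)], py[seq_len(placed)])
}

# Build the cell geometry for a spec: Voronoi tessellation of min-spacing
# random seeds over a padded region, inward offset by half the membrane
# thickness, lognormal size jitter, border cells dropped. Pure geometry;
# no rasterization, so results are independent of pixel_size_um.
.tessellate <- function(spec) {
  W <- spec$region_width_um; H <- spec$region_height_um
  lambda <- spec$target_density / 1e6
  expected <- lambda * W * H
  if (expected < 1)
    stop("empty tessellation: region too small to hold one cell at the requested density")
  mean_area <- 1 / lambda
  d <- 2 * sqrt(mean_area / pi)  # nominal cell diameter
  if (W <= d || H <= d)
    stop("empty tessellation: region narrower than one cell at the requested density")
  # whole-cell centres must stay ~d/2 from the border; inflate intensity so
  # the number of uncut cells lands on target
  infl <- (W * H) / ((W - d) * (H - d))
  pad <- d
  area_padded <- (W + 2 * pad) * (H + 2 * pad)
  n_seeds <- max(4L, round(lambda * infl * area_padded))
  rmin <- 0.55 / sqrt(lambda * infl)

  set.seed(spec$seed)
  pts <- .dart_throw(n_seeds, -pad, W + pad, -pad, H + pad, rmin)
  if (nrow(pts) < 4) stop("empty tessellation: could not place seed points")
  dd <- deldir::deldir(pts[, 1], pts[, 2],
                       rw = c(-pad, W + pad, -pad, H + pad), suppressMsge = TRUE)
  tl <- deldir::tile.list(dd)

  erode <- spec$membrane_thickness_um / 2
  polys <- vector("list", length(tl))
  for (i in seq_along(tl)) {
    poly <- cbind(tl[[i]]$x, tl[[i]]$y)
    polys[[i]] <- convex_inward_offset(poly, erode)
  }
  keep <- vapply(polys, function(p) {
    nrow(p) >= 3 &&
      all(p[, 1] > 0 & p[, 1] < W & p[, 2] > 0 & p[, 2] < H)
  }, logical(1))
  polys <- polys[keep]
  if (length(polys) == 0)
    stop("empty tessellation: no whole cell fits inside the region")

  areas <- abs(vapply(polys, polygon_area, numeric(1)))
  # top up the tessellation's area CV toward the requested value with
  # multiplicative lognormal jitter, shrink-only so cells never overlap
  cv_v <- sd(areas) / mean(areas)
  if (spec$cell_size_cv > cv_v) {
    sig <- sqrt(log((1 + spec$cell_size_cv^2) / (1 + cv_v^2)))
    tj <- exp(sig * rnorm(length(polys)) - sig^2 / 2)
    s <- sqrt(pmin(tj, 1))
    for (i in seq_along(polys)) {
      if (s[i] < 1) {
        ctr <- polygon_centroid(polys[[i]])
        polys[[i]] <- t(ctr + s[i] * (t(polys[[i]]) - ctr))
      }
    }
    areas <- abs(vapply(polys, polygon_area, numeric(1)))
  }
  centroids <- t(vapply(polys, polygon_centroid, numeric(2)))

  structure(
    list(cell_polygons = polys,
         cell_areas_um2 = areas,
         true_count = length(polys),
         centroids_um = centroids,
         roi_polygon = cbind(c(0, W, W, 0), c(0, 0, H, H)),
         region_width_um = W, region_height_um = H,
         spec = spec),
    class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d cells in %g x %g um; mean area %.0f um^2 (CV %.2f)\n",
    x$true_count, x$region_width_um, x$region_height_um,
    mean(x$cell_areas_um2), sd(x$cell_areas_um2) / mean(x$cell_areas_um2)))
  invisible(x)
}

#' Render a window of a synthetic tissue geometry
#'
#' Rasterizes the lumen polygons of `truth` falling inside `bbox_um` at the
#' spec's pixel size: membrane colour everywhere, lumen colour inside cells,
#' plus Gaussian pixel noise. Noise is seeded per window from the spec seed
#' and the window origin, so a window render is deterministic but windows
#' are rendered independently.
#'
#' @param truth a `ground_truth` from [generate_tissue()].
#' @param bbox_um numeric (xmin, ymin, xmax, ymax) in micrometres; default
#'   the full region.
#' @return A [calibrated_image()] with `origin_um = (xmin, ymin)`.
#' @export
render_tissue_region <- function(truth, bbox_um = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  spec <- truth$spec
  if (is.null(bbox_um))
    bbox_um <- c(0, 0, truth$region_width_um, truth$region_height_um)
  psz <- spec$pixel_size_um
  nc <- max(1L, round((bbox_um[3] - bbox_um[1]) / psz))
  nr <- max(1L, round((bbox_um[4] - bbox_um[2]) / psz))
  lab <- .rasterize_polygons(truth$cell_polygons, nr, nc, psz,
                             bbox_um[1], bbox_um[2])
  lumen <- lab > 0
  pix <- array(0, c(nr, nc, 3))
  # per-window noise stream: derived from the spec seed and window origin
  set.seed((as.numeric(spec$seed) * 7919 +
              (round(bbox_um[1]) %% 10000) * 131 +
              (round(bbox_um[2]) %% 10000)) %% 2147483647)
  for (ch in 1:3) {
    plane <- matrix(.membrane_rgb[ch], nr, nc)
    plane[lumen] <- .lumen_rgb[ch]
    if (spec$noise_sd > 0)
      plane <- plane + rnorm(nr * nc, 0, spec$noise_sd)
    pix[, , ch] <- pmin(255, pmax(0, plane))
  }
  img <- calibrated_image(pix, psz, origin_um = bbox_um[1:2])
  frac <- switch(spec$quality_grade,
                 good = 0, average = spec$spillover_fraction / 2,
                 poor = spec$spillover_fraction)
  if (frac > 0)
    img <- apply_spillover(img, truth, frac, seed = spec$seed + 1L)
  img
}

#' Generate a calibrated synthetic adipose-tissue image with ground truth
#'
#' Builds a Voronoi-like tessellation of whole fat cells (uniform seed
#' points with minimum-spacing rejection), erodes each cell inward by half
#' the membrane thickness so neighbouring lumina are separated by a stained
#' membrane of the requested thickness, applies lognormal cell-size jitter,
#' drops cells cut by the region border, and renders the result as an
#' H&E-like RGB image. Cell polygons and areas are defined geometrically in
#' micrometres, independent of the rendering resolution.
#'
#' @param spec a [tissue_spec()].
#' @return A list with elements `image` (a [calibrated_image()]) and
#'   `truth` (a `ground_truth`: `cell_polygons`, `cell_areas_um2`,
#'   `true_count`, `centroids_um`, `roi_polygon`).
#' @examples
#' ts <- tissue_spec(region_width_um = 600, region_height_um = 400,
#'                   target_density = 150, seed = 3)
#' gt <- generate_tissue(ts)
#' gt$truth$true_count
#' @export
generate_tissue <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  truth <- .tessellate(spec)
  image <- render_tissue_region(truth)
  list(image = image, truth = truth)
}

#' Tint a spillover-staining band inside each lumen
#'
#' Emulates the artefactual "spilling of staining": for every cell, the band
#' of the lumen adjacent to the membrane covering `fraction` of the lumen
#' area is blended toward a desaturated membrane colour. Pixels outside the
#' bands are untouched.
#'
#' @param image a [calibrated_image()] rendered from `truth`.
#' @param truth the `ground_truth` the image was rendered from.
#' @param fraction fraction of each lumen area to tint, in (0, 1\].
#' @param seed integer seed for the per-cell tint strength.
#' @return A new [calibrated_image()].
#' @export
apply_spillover <- function(image, truth, fraction, seed = 1L) {
  stopifnot(inherits(image, "calibrated_image"), inherits(truth, "ground_truth"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be a single number in (0, 1]")
  set.seed(as.integer(seed))
  w <- runif(truth$true_count, 0.65, 0.9)  # per-cell tint strength
  s <- sqrt(1 - fraction)                 # core scale: band area = fraction
  cores <- vector("list", truth$true_count)
  for (i in seq_len(truth$true_count)) {
    ctr <- polygon_centroid(truth$cell_polygons[[i]])
    cores[[i]] <- t(ctr + s * (t(truth$cell_polygons[[i]]) - ctr))
  }
  d <- dim(image$pixels)
  psz <- image$pixel_size_um
  lab_cell <- .rasterize_polygons(truth$cell_polygons, d[1], d[2], psz,
                                  image$origin_um[1], image$origin_um[2])
  lab_core <- .rasterize_polygons(cores, d[1], d[2], psz,
                                  image$origin_um[1], image$origin_um[2])
  band <- lab_cell > 0 & lab_core == 0
  if (!any(band)) return(image)
  wb <- w[lab_cell[band]]
  pix <- image$pixels
  for (ch in 1:3) {
    plane <- pix[, , ch]
    plane[band] <- (1 - wb) * plane[band] + wb * .spill_rgb[ch]
    pix[, , ch] <- plane
  }
  calibrated_image(pix, psz, image$origin_um)
}

#' Sample sparse training annotations from synthetic ground truth
#'
#' Draws labelled pixels for classifier training directly from the
#' generator's geometry: fat pixels from inside the lumen polygons,
#' tissue pixels from the stained remainder. This mimics sparse manual
#' annotation of both tissue components on a training image.
#'
#' @param gen a list with `image` and `truth` as returned by
#'   [generate_tissue()].
#' @param n_per_class labelled pixels per class.
#' @param seed integer seed for the pixel sampling.
#' @return Integer label matrix at the image resolution:
#'   0 = unlabelled, 1 = fat, 2 = tissue.
#' @export
training_labels_from_truth <- function(gen, n_per_class = 1500, seed = 5L) {
  stopifnot(inherits(gen$image, "calibrated_image"),
            inherits(gen$truth, "ground_truth"))
  d <- dim(gen$image$pixels)
  lab <- .rasterize_polygons(gen$truth$cell_polygons, d[1], d[2],
                             gen$image$pixel_size_um,
                             gen$image$origin_um[1], gen$image$origin_um[2])
  labels <- matrix(0L, d[1], d[2])
  set.seed(as.integer(seed))
  fat <- which(lab > 0); tis <- which(lab == 0)
  labels[sample(fat, min(n_per_class, length(fat)))] <- 1L
  labels[sample(tis, min(n_per_class, length(tis)))] <- 2L
  labels
}

#' Generate synthetic tissue geometry without rendering
#'
#' Runs the tessellation stage only and returns the `ground_truth`.
#' Combine with [render_tissue_region()] or [write_tile_map()] to
#' rasterize arbitrarily large regions window by window, so a whole-slide
#' synthetic image never has to exist in memory at once.
#'
#' @param spec a [tissue_spec()].
#' @return A `ground_truth`.
#' @export
generate_tissue_geometry <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  .tessellate(spec)
}
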