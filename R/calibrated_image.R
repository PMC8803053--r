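#' Calibrated RGB image
#'
#' A plain container tying an 8-bit RGB pixel array to its physical pixel
#' size, the bridge between pixel space and every micrometre-denominated
#' threshold in the pipeline. Row index corresponds to the y axis (top to
#' bottom), column index to x. The centre of pixel `(r, c)` sits at
#' `origin_um + (c - 0.5, r - 0.5) * pixel_size_um` in slide coordinates.
#'
#' @param pixels H x W x 3 numeric array, intensities in \[0, 255\].
#' @param pixel_size_um physical size of one pixel in micrometres (> 0).
#' @param origin_um length-2 numeric, (x, y) slide coordinate of the
#'   top-left image corner in micrometres.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size_um, origin_um = c(0, 0)) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  if (length(origin_um) != 2L || any(!is.finite(origin_um)))
    stop("origin_um must be two finite numbers")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         origin_um = as.numeric(origin_um)),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<calibrated_image> %d x %d px at %.4g um/px (%.4g x %.4g um), origin (%.4g, %.4g) um\n",
    d[1], d[2], x$pixel_size_um, d[2] * x$pixel_size_um,
    d[1] * x$pixel_size_um, x$origin_um[1], x$origin_um[2]))
  invisible(x)
}

#' Physical extent of a calibrated image
#'
#' @param img a [calibrated_image()].
#' @return Named numeric: xmin, xmax, ymin, ymax in micrometres.
#' @export
image_extent_um <- function(img) {
  stopifnot(inherits(img, "calibrated_image"))
  d <- dim(img$pixels)
  c(xmin = img$origin_um[1], xmax = img$origin_um[1] + d[2] * img$pixel_size_um,
    ymin = img$origin_um[2], ymax = img$origin_um[2] + d[1] * img$pixel_size_um)
}

#' Resample a calibrated image to a target pixel size
#'
#' Bilinear resampling (via EBImage). Downsampling to the coarser working
#' resolution used for classification; origin is preserved.
#'
#' @param img a [calibrated_image()].
#' @param pixel_size_um target pixel size; must be >= the source pixel size.
#' @return A [calibrated_image()] at the requested resolution.
#' @export
resample_image <- function(img, pixel_size_um) {
  stopifnot(inherits(img, "calibrated_image"))
  if (pixel_size_um < img$pixel_size_um - 1e-9)
    stop("target pixel size must not be finer than the source pixel size")
  if (abs(pixel_size_um - img$pixel_size_um) < 1e-9) return(img)
  d <- dim(img$pixels)
  nh <- max(1L, round(d[1] * img$pixel_size_um / pixel_size_um))
  nw <- max(1L, round(d[2] * img$pixel_size_um / pixel_size_um))
  out <- array(0, c(nh, nw, 3))
  for (ch in 1:3) {
    # EBImage images are x-major; transpose in and out
    e <- EBImage::Image(t(img$pixels[, , ch]) / 255)
    r <- EBImage::resize(e, w = nw, h = nh)
    out[, , ch] <- t(EBImage::imageData(r)) * 255
  }
  calibrated_image(out, pixel_size_um, img$origin_um)
}

# --- geometry helpers (micrometre coordinates) -------------------------------

#' Signed polygon area (shoelace formula)
#'
#' @param poly n x 2 matrix of (x, y) vertices of a closed ring (the last
#'   vertex connects back to the first).
#' @return Signed area; positive when vertices wind counter-clockwise in
#'   standard (y up) orientation.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# centroid of a simple polygon
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# clip polygon by half-plane a*x + b*y <= c (Sutherland-Hodgman step)
clip_halfplane <- function(poly, a, b, cc) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  v <- a * poly[, 1] + b * poly[, 2] - cc
  keep_in <- v <= 1e-12
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (keep_in[i]) out <- rbind(out, poly[i, ])
    if (keep_in[i] != keep_in[j]) {
      t <- v[i] / (v[i] - v[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# inward offset of a convex polygon by distance d (shift every edge inward);
# returns a matrix with 0 rows when the polygon vanishes
convex_inward_offset <- function(poly, d) {
  if (d <= 0) return(poly)
  n <- nrow(poly)
  # orientation: ensure we shift toward the interior
  s <- sign(polygon_area(poly))
  out <- poly
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- poly[j, 1] - poly[i, 1]
    ey <- poly[j, 2] - poly[i, 2]
    len <- sqrt(ex^2 + ey^2)
    if (len < 1e-12) next
    # inward normal for this winding
    nx <- -s * ey / len
    ny <- s * ex / len
    # keep points on the inner side: n . p >= n . v + d  =>  -n . p <= -n.v - d
    cc <- -(nx * poly[i, 1] + ny * poly[i, 2]) - d
    out <- clip_halfplane(out, -nx, -ny, cc)
    if (nrow(out) < 3) return(matrix(numeric(0), ncol = 2))
  }
  out
}

# point-in-polygon (even-odd), vectorized over points
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi <= py) != (yj <= py)) &
      (px < xi + (py - yi) * (xj - xi) / (yj - yi))
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
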