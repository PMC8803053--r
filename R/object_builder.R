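#' Object-creation settings
#'
#' Parameters of the mask-to-objects conversion: minimum object size,
#' minimum retained hole size, and whether touching cells are split by
#' watershed. Defaults match the validated protocol settings
#' (min object 20 um^2, min hole 30 um^2, split on).
#'
#' @param min_object_size_um2 fat components smaller than this are
#'   discarded (kept when area >= threshold).
#' @param min_hole_size_um2 enclosed background holes smaller than this
#'   are filled (a hole is kept when its area >= threshold).
#' @param split_objects split touching cells with marker-based watershed.
#' @param watershed_h depth (pixels, working resolution) below which
#'   distance-transform maxima are merged; the `h` of the h-maxima markers.
#' @return An object of class `object_builder_settings`.
#' @export
object_builder_settings <- function(min_object_size_um2 = 20,
                                    min_hole_size_um2 = 30,
                                    split_objects = TRUE,
                                    watershed_h = 2) {
  if (min_object_size_um2 < 0 || min_hole_size_um2 < 0)
    stop("size thresholds must be non-negative")
  structure(list(min_object_size_um2 = min_object_size_um2,
                 min_hole_size_um2 = min_hole_size_um2,
                 split_objects = isTRUE(split_objects),
                 watershed_h = watershed_h),
            class = "object_builder_settings")
}

#' Connected-component labels of a binary matrix
#'
#' Fat objects are 4-connected; background (and therefore holes) is
#' 8-connected. The duality stops fat leaking diagonally through
#' one-pixel membrane gaps, the main source of falsely conjoined cells.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of labels (0 = background) with attribute
#'   `n_labels`.
#' @export
label_components <- function(mask, connectivity = 4L) {
  .cc_label(mask, as.integer(connectivity))
}

#' Fill enclosed background holes smaller than a threshold
#'
#' Background regions fully enclosed by fat (8-connected, not touching
#' the mask border) with area below `min_hole_size_um2` are set to fat.
#' Holes at or above the threshold, and any background connected to the
#' border, are untouched. Threshold 0 is the identity.
#'
#' @param mask a [class_mask()].
#' @param min_hole_size_um2 threshold in square micrometres.
#' @return A [class_mask()].
#' @export
fill_small_holes <- function(mask, min_hole_size_um2) {
  stopifnot(inherits(mask, "class_mask"))
  if (min_hole_size_um2 <= 0) return(mask)
  bg <- .cc_label(!mask$mask, 8L)
  n <- attr(bg, "n_labels")
  if (n == 0) return(mask)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  px_area <- mask$pixel_size_um^2
  counts <- tabulate(bg[bg > 0], nbins = n)
  fill <- which(counts * px_area < min_hole_size_um2)
  fill <- setdiff(fill, border_labels)
  if (length(fill) == 0) return(mask)
  m <- mask$mask
  m[bg %in% fill] <- TRUE
  class_mask(m, mask$pixel_size_um, mask$origin_um, mask$provenance)
}

#' Remove fat components smaller than a threshold
#'
#' 4-connected fat components with area below `min_object_size_um2` are
#' cleared; components at or above the threshold are untouched
#' (inclusive lower bound: a component of exactly the threshold area is
#' kept).
#'
#' @param mask a [class_mask()].
#' @param min_object_size_um2 threshold in square micrometres.
#' @return A [class_mask()].
#' @export
remove_small_objects <- function(mask, min_object_size_um2) {
  stopifnot(inherits(mask, "class_mask"))
  if (min_object_size_um2 <= 0) return(mask)
  lab <- .cc_label(mask$mask, 4L)
  n <- attr(lab, "n_labels")
  if (n == 0) return(mask)
  px_area <- mask$pixel_size_um^2
  counts <- tabulate(lab[lab > 0], nbins = n)
  drop <- which(counts * px_area < min_object_size_um2)
  if (length(drop) == 0) return(mask)
  m <- mask$mask
  m[lab %in% drop] <- FALSE
  class_mask(m, mask$pixel_size_um, mask$origin_um, mask$provenance)
}

#' Split touching cells by watershed on the distance transform
#'
#' Each fat component is partitioned by watershed on its Euclidean
#' distance transform; maxima closer than `h` in depth are merged before
#' seeding, so convex single cells (one surviving maximum) pass through
#' unchanged. Every fat pixel keeps a label: splitting reassigns pixels,
#' never deletes them.
#'
#' @param mask a [class_mask()].
#' @param h h-maxima depth in working-resolution pixels.
#' @return Integer label matrix with attribute `n_labels`.
#' @export
split_touching <- function(mask, h = 2) {
  stopifnot(inherits(mask, "class_mask"))
  if (!any(mask$mask)) {
    lab <- matrix(0L, nrow(mask$mask), ncol(mask$mask))
    attr(lab, "n_labels") <- 0L
    return(lab)
  }
  dm <- EBImage::distmap(t(mask$mask))  # EBImage is x-major
  # integer distance steps: part of the splitting definition; with h >= 1
  # the surviving maxima are unchanged and flooding is several-fold faster
  ws <- EBImage::watershed(round(dm), tolerance = h, ext = 1)
  lab <- t(EBImage::imageData(ws))
  storage.mode(lab) <- "integer"
  attr(lab, "n_labels") <- max(lab)
  lab
}

#' Convert a class mask into adipocyte objects
#'
#' The create-objects pipeline: fill small holes, remove small
#' components, split touching cells (optional), then measure each label:
#' pixel count, area (pixel count x pixel size^2), circular-equivalent
#' diameter, centroid and traced boundary polygon, all in micrometre
#' slide coordinates.
#'
#' @param mask a [class_mask()].
#' @param settings an [object_builder_settings()].
#' @param tile_id provenance tag recorded per object.
#' @return data.frame with one row per object: `id`, `pixel_count`,
#'   `area_um2`, `diameter_um`, `centroid_x_um`, `centroid_y_um`,
#'   `tile_id`, and a list column `boundary` of n x 2 micrometre polygon
#'   matrices.
#' @export
mask_to_objects <- function(mask, settings = object_builder_settings(),
                            tile_id = NA_character_) {
  stopifnot(inherits(mask, "class_mask"),
            inherits(settings, "object_builder_settings"))
  m <- fill_small_holes(mask, settings$min_hole_size_um2)
  m <- remove_small_objects(m, settings$min_object_size_um2)
  lab <- if (settings$split_objects) {
    split_touching(m, h = settings$watershed_h)
  } else {
    .cc_label(m$mask, 4L)
  }
  objects_from_labels(lab, m$pixel_size_um, m$origin_um, tile_id)
}

#' Measure labelled objects
#'
#' @param lab integer label matrix (0 = background).
#' @param pixel_size_um working resolution.
#' @param origin_um (x, y) of the image's top-left corner, micrometres.
#' @param tile_id provenance tag.
#' @return data.frame as in [mask_to_objects()].
#' @export
objects_from_labels <- function(lab, pixel_size_um, origin_um = c(0, 0),
                                tile_id = NA_character_) {
  n <- max(0L, max(lab))
  if (n == 0) {
    out <- data.frame(id = integer(0), pixel_count = integer(0),
                      area_um2 = numeric(0), diameter_um = numeric(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0),
                      tile_id = character(0), stringsAsFactors = FALSE)
    out$boundary <- list()
    return(out)
  }
  st <- .label_stats(lab, n)
  boundaries <- .trace_boundaries(lab, n)
  px_area <- pixel_size_um^2
  area <- st[, 1] * px_area
  out <- data.frame(
    id = seq_len(n),
    pixel_count = as.integer(st[, 1]),
    area_um2 = area,
    diameter_um = circular_diameter(area),
    # pixel (r, c) centre is origin + (c - 0.5, r - 0.5) * psz
    centroid_x_um = origin_um[1] + (st[, 3] / st[, 1] - 0.5) * pixel_size_um,
    centroid_y_um = origin_um[2] + (st[, 2] / st[, 1] - 0.5) * pixel_size_um,
    tile_id = tile_id, stringsAsFactors = FALSE)
  out$boundary <- lapply(boundaries, function(b) {
    s <- .simplify_ring(b)
    cbind(origin_um[1] + s[, 1] * pixel_size_um,
          origin_um[2] + s[, 2] * pixel_size_um)
  })
  out
}

# drop collinear vertices from a closed ring of axis-aligned unit edges
.simplify_ring <- function(b) {
  n <- nrow(b)
  if (n < 3) return(b)
  prv <- b[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- b[c(2:n, 1), , drop = FALSE]
  turn <- (b[, 1] - prv[, 1]) * (nxt[, 2] - b[, 2]) -
    (b[, 2] - prv[, 2]) * (nxt[, 1] - b[, 1])
  keep <- abs(turn) > 1e-12
  if (!any(keep)) return(b)
  b[keep, , drop = FALSE]
}
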