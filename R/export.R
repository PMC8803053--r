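# GeoJSON / CSV export of detections, ground truth and ROIs.
# Coordinates are micrometre slide coordinates throughout, so exported
# polygons can be overlaid in common slide viewers.

.polygon_feature <- function(poly, properties) {
  ring <- lapply(seq_len(nrow(poly)), function(i) c(poly[i, 1], poly[i, 2]))
  ring[[length(ring) + 1L]] <- ring[[1L]]  # close the ring
  list(type = "Feature",
       geometry = list(type = "Polygon", coordinates = list(ring)),
       properties = properties)
}

#' Export adipocyte objects as a GeoJSON FeatureCollection
#'
#' One polygon feature per object with `id`, `area_um2`, `diameter_um`,
#' centroid and `tile_id` properties, class property `"adipocyte"`.
#'
#' @param objects data.frame from [mask_to_objects()].
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
objects_to_geojson <- function(objects, path) {
  feats <- lapply(seq_len(nrow(objects)), function(i) {
    .polygon_feature(objects$boundary[[i]], list(
      id = objects$id[i],
      class = "adipocyte",
      area_um2 = objects$area_um2[i],
      diameter_um = objects$diameter_um[i],
      centroid_x_um = objects$centroid_x_um[i],
      centroid_y_um = objects$centroid_y_um[i],
      tile_id = objects$tile_id[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 6)
  invisible(path)
}

#' Export adipocyte objects as flat CSV
#'
#' One row per object; the boundary polygon is omitted (use
#' [objects_to_geojson()] for geometry).
#'
#' @param objects data.frame from [mask_to_objects()].
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
objects_to_csv <- function(objects, path) {
  df <- objects[, setdiff(names(objects), "boundary"), drop = FALSE]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write synthetic ground truth to disk
#'
#' Cell polygons as GeoJSON (micrometre coordinates, class property
#' `"adipocyte_truth"`), per-cell areas as CSV, and the generating spec
#' as flat JSON.
#'
#' @param truth a `ground_truth`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  feats <- lapply(seq_len(truth$true_count), function(i) {
    .polygon_feature(truth$cell_polygons[[i]], list(
      id = i, class = "adipocyte_truth",
      area_um2 = truth$cell_areas_um2[i]))
  })
  feats[[length(feats) + 1L]] <-
    .polygon_feature(truth$roi_polygon, list(id = 0, class = "roi"))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file.path(dir, "truth.geojson"),
                       auto_unbox = TRUE, digits = 6)
  write.csv(data.frame(id = seq_len(truth$true_count),
                       area_um2 = truth$cell_areas_um2,
                       centroid_x_um = truth$centroids_um[, 1],
                       centroid_y_um = truth$centroids_um[, 2]),
            file.path(dir, "truth_areas.csv"), row.names = FALSE)
  spec <- truth$spec
  jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read the first polygon from a GeoJSON file
#'
#' Used for region-of-interest polygons. Returns the coordinates of the
#' first `Polygon` feature (outer ring) as an n x 2 matrix; a trailing
#' duplicate of the first vertex is dropped.
#'
#' @param path a `.geojson` file.
#' @return n x 2 numeric matrix of (x, y) micrometre coordinates.
#' @export
read_roi_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  for (f in feats) {
    geom <- if (identical(f$type, "Feature")) f$geometry else f
    if (identical(geom$type, "Polygon")) {
      ring <- geom$coordinates[[1]]
      m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ]))
        m <- m[-nrow(m), , drop = FALSE]
      return(m)
    }
  }
  stop("no Polygon feature found in ", basename(path))
}
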