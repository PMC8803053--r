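#' Plan tiles covering a bounding box
#'
#' Cores partition the box into `tile_size_um` squares (half-open, so
#' every pixel centre belongs to exactly one core); each processing tile
#' is its core expanded by `halo_um` and clipped to the box. Objects that
#' cross a core boundary are re-assembled from the halos, so the halo
#' should be at least half the largest expected cell diameter.
#'
#' @param bbox_um (xmin, ymin, xmax, ymax), micrometres.
#' @param tile_size_um core edge length (default 2000, i.e. cores of
#'   4 x 10^6 um^2 at most).
#' @param halo_um overlap margin (default 150).
#' @param min_recommended_halo_um warn when `halo_um` falls below this
#'   (half a generous adipocyte diameter).
#' @return data.frame of class `tile_plan`: one row per tile with core
#'   and tile bounds in micrometres.
#' @export
tile_plan <- function(bbox_um, tile_size_um = 2000, halo_um = 150,
                      min_recommended_halo_um = 75) {
  stopifnot(length(bbox_um) == 4, bbox_um[3] > bbox_um[1],
            bbox_um[4] > bbox_um[2], tile_size_um > 0, halo_um >= 0)
  if (halo_um < min_recommended_halo_um)
    warning("halo_um = ", halo_um, " um is below the recommended ",
            min_recommended_halo_um,
            " um; cells crossing tile cores may be truncated")
  nx <- max(1L, ceiling((bbox_um[3] - bbox_um[1]) / tile_size_um - 1e-9))
  ny <- max(1L, ceiling((bbox_um[4] - bbox_um[2]) / tile_size_um - 1e-9))
  xs <- bbox_um[1] + tile_size_um * (seq_len(nx) - 1L)
  ys <- bbox_um[2] + tile_size_um * (seq_len(ny) - 1L)
  g <- expand.grid(x0 = xs, y0 = ys)
  out <- data.frame(
    tile_id = sprintf("tile_%03d", seq_len(nrow(g))),
    core_xmin = g$x0, core_ymin = g$y0,
    core_xmax = pmin(g$x0 + tile_size_um, bbox_um[3]),
    core_ymax = pmin(g$y0 + tile_size_um, bbox_um[4]))
  out$tile_xmin <- pmax(out$core_xmin - halo_um, bbox_um[1])
  out$tile_ymin <- pmax(out$core_ymin - halo_um, bbox_um[2])
  out$tile_xmax <- pmin(out$core_xmax + halo_um, bbox_um[3])
  out$tile_ymax <- pmin(out$core_ymax + halo_um, bbox_um[4])
  attr(out, "bbox_um") <- bbox_um
  attr(out, "tile_size_um") <- tile_size_um
  attr(out, "halo_um") <- halo_um
  class(out) <- c("tile_plan", "data.frame")
  out
}

# fat mask -> label matrix honouring the settings
.build_labels <- function(mask, settings) {
  m <- fill_small_holes(mask, settings$min_hole_size_um2)
  m <- remove_small_objects(m, settings$min_object_size_um2)
  if (settings$split_objects) split_touching(m, h = settings$watershed_h)
  else .cc_label(m$mask, 4L)
}

#' Analyse one calibrated image in memory
#'
#' The untiled pipeline: classify pixels, build objects, filter by area,
#' summarise. The region-of-interest polygon limits classification and
#' supplies the density denominator.
#'
#' @param image a [calibrated_image()].
#' @param model a trained `pixel_classifier_model`.
#' @param roi_polygon optional n x 2 micrometre polygon; default the full
#'   image extent.
#' @param settings an [object_builder_settings()].
#' @param filter an [area_filter()].
#' @param density_denominator passed to [summarize_morphometry()].
#' @return List: `objects` (filtered data.frame), `summary`
#'   (`morphometry_summary`), `objects_unfiltered`.
#' @export
analyze_image <- function(image, model, roi_polygon = NULL,
                          settings = object_builder_settings(),
                          filter = area_filter(),
                          density_denominator = "roi") {
  stopifnot(inherits(image, "calibrated_image"))
  if (is.null(roi_polygon)) {
    ext <- image_extent_um(image)
    roi_polygon <- cbind(c(ext["xmin"], ext["xmax"], ext["xmax"], ext["xmin"]),
                         c(ext["ymin"], ext["ymin"], ext["ymax"], ext["ymax"]))
  }
  mask <- classify_pixels(model, image, roi_polygon)
  lab <- .build_labels(mask, settings)
  objects <- objects_from_labels(lab, mask$pixel_size_um, mask$origin_um,
                                 tile_id = "untiled")
  kept <- filter_by_area(objects, filter)
  summary <- summarize_morphometry(
    objects, abs(polygon_area(roi_polygon)), filter,
    density_denominator = density_denominator)
  list(objects = kept, summary = summary, objects_unfiltered = objects)
}

#' Tiled analysis of a large calibrated image
#'
#' Processes the region of interest tile by tile so that no full-region
#' RGB raster is ever held in memory (pair with a tile-map source from
#' [write_tile_map()] for true windowed reads). Objects whose pixels lie
#' strictly inside a tile's core are kept as-is. Objects crossing a core
#' boundary contribute their pixel sets (in global working-grid
#' coordinates) to a merge pool; pooled pixels are unioned across
#' neighbouring tiles' halos, de-duplicated, and re-processed (hole fill,
#' minimum size, split) so each boundary cell is counted exactly once.
#'
#' @param path image file or tile-map directory (see [read_region()]).
#' @param model a trained `pixel_classifier_model`.
#' @param roi_polygon optional n x 2 micrometre polygon; default the full
#'   source extent.
#' @param settings an [object_builder_settings()].
#' @param filter an [area_filter()].
#' @param tile_size_um,halo_um tile geometry, see [tile_plan()].
#' @param mpp optional calibration override for the source.
#' @param density_denominator passed to [summarize_morphometry()].
#' @return List: `objects` (filtered), `summary`, `objects_unfiltered`,
#'   `plan` (the [tile_plan()]), `truncated_objects` (count of merged
#'   objects touching a tile's outer edge, 0 when the halo was
#'   sufficient).
#' @export
tiled_analysis <- function(path, model, roi_polygon = NULL,
                           settings = object_builder_settings(),
                           filter = area_filter(),
                           tile_size_um = 2000, halo_um = 150, mpp = NULL,
                           density_denominator = "roi") {
  # source extent without decoding pixels where possible
  if (dir.exists(path)) {
    idx <- .read_tilemap_index(path)
    psz_src <- if (!is.null(mpp)) mpp else as.numeric(idx$pixel_size_um)
    src_origin <- c(as.numeric(idx$origin_x_um), as.numeric(idx$origin_y_um))
    src_ext <- c(xmin = src_origin[1], xmax = src_origin[1] + as.integer(idx$width_px) * psz_src,
                 ymin = src_origin[2], ymax = src_origin[2] + as.integer(idx$height_px) * psz_src)
  } else {
    probe <- .read_image_file(path, mpp)
    src_ext <- image_extent_um(probe)
    rm(probe)
  }
  if (is.null(roi_polygon))
    roi_polygon <- cbind(c(src_ext["xmin"], src_ext["xmax"], src_ext["xmax"], src_ext["xmin"]),
                         c(src_ext["ymin"], src_ext["ymin"], src_ext["ymax"], src_ext["ymax"]))
  bbox <- c(max(min(roi_polygon[, 1]), src_ext["xmin"]),
            max(min(roi_polygon[, 2]), src_ext["ymin"]),
            min(max(roi_polygon[, 1]), src_ext["xmax"]),
            min(max(roi_polygon[, 2]), src_ext["ymax"]))
  plan <- tile_plan(bbox, tile_size_um, halo_um)

  wpsz <- model$working_pixel_size_um
  nr_global <- max(1L, round((bbox[4] - bbox[2]) / wpsz))
  kept_objects <- list()
  pool_px <- list()   # pooled pixels as global working-grid integer keys
  truncated <- 0L

  for (i in seq_len(nrow(plan))) {
    tl <- plan[i, ]
    img_t <- read_region(path, c(tl$tile_xmin, tl$tile_ymin,
                                 tl$tile_xmax, tl$tile_ymax), mpp = mpp)
    mask <- classify_pixels(model, img_t, roi_polygon)
    lab <- .build_labels(mask, settings)
    n <- max(0L, max(lab))
    if (n == 0L) next
    st <- .label_stats(lab, n)
    # bounds of each label in micrometre slide coordinates (pixel centres)
    ox <- mask$origin_um[1]; oy <- mask$origin_um[2]
    # label_stats columns: count, sum_r, sum_c, rmin, rmax, cmin, cmax
    x_lo <- ox + (st[, 6] - 0.5) * wpsz; x_hi <- ox + (st[, 7] - 0.5) * wpsz
    y_lo <- oy + (st[, 4] - 0.5) * wpsz; y_hi <- oy + (st[, 5] - 0.5) * wpsz
    # half-open core membership of pixel centres
    in_core <- x_lo >= tl$core_xmin & x_hi < tl$core_xmax &
      y_lo >= tl$core_ymin & y_hi < tl$core_ymax
    overlaps_core <- x_hi >= tl$core_xmin & x_lo < tl$core_xmax &
      y_hi >= tl$core_ymin & y_lo < tl$core_ymax
    if (any(in_core)) {
      sub <- lab
      sub[!(lab %in% which(in_core))] <- 0L
      # renumber to 1..m for measurement
      ids <- which(in_core)
      remap <- integer(n); remap[ids] <- seq_along(ids)
      sub[sub > 0L] <- remap[sub[sub > 0L]]
      attr(sub, "n_labels") <- length(ids)
      kept_objects[[length(kept_objects) + 1L]] <-
        objects_from_labels(sub, wpsz, mask$origin_um, tile_id = tl$tile_id)
    }
    cross_ids <- which(overlaps_core & !in_core)
    if (length(cross_ids) > 0) {
      idx_all <- which(lab %in% cross_ids)  # one scan for all crossing labels
      lv <- lab[idx_all]
      r <- (idx_all - 1L) %% nrow(lab) + 1L
      cc <- (idx_all - 1L) %/% nrow(lab) + 1L
      cx <- ox + (cc - 0.5) * wpsz
      cy <- oy + (r - 0.5) * wpsz
      in_core_px <- cx >= tl$core_xmin & cx < tl$core_xmax &
        cy >= tl$core_ymin & cy < tl$core_ymax
      # a tile pools only objects that own at least one of its core pixels
      owned <- cross_ids[cross_ids %in% unique(lv[in_core_px])]
      sel <- lv %in% owned
      if (any(sel)) {
        # touching the tile's outer edge means the halo may have truncated it
        clipped <- tl$tile_xmin > bbox[1] || tl$tile_ymin > bbox[2] ||
          tl$tile_xmax < bbox[3] || tl$tile_ymax < bbox[4]
        if (clipped) {
          at_edge <- r == 1L | r == nrow(lab) | cc == 1L | cc == ncol(lab)
          truncated <- truncated + length(unique(lv[sel & at_edge]))
        }
        # global working-grid indices relative to the plan bbox
        gr <- as.integer(round((cy[sel] - bbox[2]) / wpsz + 0.5))
        gc <- as.integer(round((cx[sel] - bbox[1]) / wpsz + 0.5))
        pool_px[[length(pool_px) + 1L]] <- gr + (gc - 1L) * nr_global
      }
    }
  }

  merged <- NULL
  if (length(pool_px) > 0) {
    keys <- unique(unlist(pool_px))
    gr <- (keys - 1L) %% nr_global + 1L
    gc <- (keys - 1L) %/% nr_global + 1L
    r0 <- min(gr); c0 <- min(gc)
    subm <- matrix(FALSE, max(gr) - r0 + 1L, max(gc) - c0 + 1L)
    subm[cbind(gr - r0 + 1L, gc - c0 + 1L)] <- TRUE
    sub_origin <- c(bbox[1] + (c0 - 1) * wpsz, bbox[2] + (r0 - 1) * wpsz)
    cm <- class_mask(subm, wpsz, sub_origin, provenance = "tile-merge")
    lab <- .build_labels(cm, settings)
    merged <- objects_from_labels(lab, wpsz, sub_origin, tile_id = "merged")
  }
  objects <- do.call(rbind, c(kept_objects, list(merged)))
  if (is.null(objects) || nrow(objects) == 0) {
    objects <- objects_from_labels(structure(matrix(0L, 1, 1), n_labels = 0L),
                                   wpsz, c(0, 0))
  } else {
    objects$id <- seq_len(nrow(objects))
  }
  if (truncated > 0)
    warning(truncated, " merged object(s) touched a tile's outer edge; ",
            "increase halo_um")
  kept <- filter_by_area(objects, filter)
  summary <- summarize_morphometry(objects, abs(polygon_area(roi_polygon)),
                                   filter,
                                   density_denominator = density_denominator)
  list(objects = kept, summary = summary, objects_unfiltered = objects,
       plan = plan, truncated_objects = truncated)
}
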