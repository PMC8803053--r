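#' Circular-equivalent diameter
#'
#' Diameter of the circle with the given area: `2 * sqrt(area / pi)`.
#' Vectorized.
#'
#' @param area_um2 non-negative area(s) in square micrometres.
#' @return Diameter(s) in micrometres.
#' @examples
#' circular_diameter(pi * 50^2)  # 100
#' @export
circular_diameter <- function(area_um2) {
  if (any(!is.finite(area_um2)) || any(area_um2 < 0))
    stop("area_um2 must be non-negative and finite")
  2 * sqrt(area_um2 / pi)
}

#' Area-range filter
#'
#' Inclusive bounds, matching spreadsheet COUNTIFS/AVERAGEIFS range
#' semantics; default 500 to 100,000 um^2, the working range for human
#' adipocytes.
#'
#' @param lower_um2,upper_um2 bounds in square micrometres,
#'   `0 <= lower <= upper`.
#' @return An object of class `area_filter`.
#' @export
area_filter <- function(lower_um2 = 500, upper_um2 = 100000) {
  if (lower_um2 < 0 || lower_um2 > upper_um2)
    stop("need 0 <= lower_um2 <= upper_um2")
  structure(list(lower_um2 = lower_um2, upper_um2 = upper_um2),
            class = "area_filter")
}

#' Keep objects within an area range
#'
#' @param objects data.frame with an `area_um2` column (as returned by
#'   [mask_to_objects()]).
#' @param filter an [area_filter()]. Bounds are inclusive; order is
#'   preserved.
#' @return The filtered data.frame.
#' @export
filter_by_area <- function(objects, filter = area_filter()) {
  stopifnot(inherits(filter, "area_filter"), "area_um2" %in% names(objects))
  objects[objects$area_um2 >= filter$lower_um2 &
            objects$area_um2 <= filter$upper_um2, , drop = FALSE]
}

#' Morphometry summary for one region of interest
#'
#' Applies the area filter, then reports count, mean and sample SD of
#' area, mean and sample SD of the per-object circular-equivalent
#' diameters (the mean of diameters, not the diameter of the mean area),
#' and density per 10^6 um^2 of ROI. With zero surviving objects the
#' means are `NA` and density is 0; with one object the SDs are `NA`.
#'
#' @param objects data.frame with an `area_um2` column.
#' @param roi_area_um2 area of the annotated region of interest (the
#'   density denominator), square micrometres, > 0.
#' @param filter an [area_filter()].
#' @param density_denominator `"roi"` (default) uses `roi_area_um2`;
#'   `"hull"` uses the convex hull area of the filtered objects'
#'   centroids instead.
#' @return An object of class `morphometry_summary` (a one-row list).
#' @export
summarize_morphometry <- function(objects, roi_area_um2,
                                  filter = area_filter(),
                                  density_denominator = c("roi", "hull")) {
  density_denominator <- match.arg(density_denominator)
  if (!is.numeric(roi_area_um2) || length(roi_area_um2) != 1L ||
      is.na(roi_area_um2) || roi_area_um2 <= 0)
    stop("roi_area_um2 must be a single positive number")
  kept <- filter_by_area(objects, filter)
  n <- nrow(kept)
  dia <- circular_diameter(kept$area_um2)
  denom <- roi_area_um2
  if (density_denominator == "hull" && n >= 3) {
    pts <- cbind(kept$centroid_x_um, kept$centroid_y_um)
    hull <- pts[chull(pts), , drop = FALSE]
    denom <- abs(polygon_area(hull))
  }
  structure(
    list(count = n,
         mean_area_um2 = if (n > 0) mean(kept$area_um2) else NA_real_,
         sd_area_um2 = if (n > 1) sd(kept$area_um2) else NA_real_,
         mean_diameter_um = if (n > 0) mean(dia) else NA_real_,
         sd_diameter_um = if (n > 1) sd(dia) else NA_real_,
         density_per_1e6um2 = n / denom * 1e6,
         roi_area_um2 = roi_area_um2,
         filter = filter),
    class = "morphometry_summary")
}

#' @export
print.morphometry_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<morphometry_summary> n = %d | mean area %.1f +/- %.1f um^2 | ",
           "mean diameter %.1f +/- %.1f um | density %.1f /1e6 um^2\n"),
    x$count, x$mean_area_um2, x$sd_area_um2, x$mean_diameter_um,
    x$sd_diameter_um, x$density_per_1e6um2))
  invisible(x)
}

#' One-row data.frame view of a morphometry summary
#'
#' @param x a `morphometry_summary`.
#' @param ... unused.
#' @export
as.data.frame.morphometry_summary <- function(x, ...) {
  data.frame(count = x$count, mean_area_um2 = x$mean_area_um2,
             sd_area_um2 = x$sd_area_um2,
             mean_diameter_um = x$mean_diameter_um,
             sd_diameter_um = x$sd_diameter_um,
             density_per_1e6um2 = x$density_per_1e6um2,
             roi_area_um2 = x$roi_area_um2)
}
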