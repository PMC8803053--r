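#' Write a calibrated image to PNG or TIFF
#'
#' PNG carries the calibration in tEXt chunks (`pixel_size_um`,
#' `origin_x_um`, `origin_y_um`). TIFF (the `tiff` package exposes no
#' resolution tags on write) gets a JSON sidecar `<path>.json` with the
#' same fields. Pixels are quantized to 8 bits.
#'
#' @param img a [calibrated_image()].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_calibrated_image <- function(img, path) {
  stopifnot(inherits(img, "calibrated_image"))
  ext <- tolower(tools::file_ext(path))
  arr <- pmax(pmin(img$pixels / 255, 1), 0)
  if (ext == "png") {
    png::writePNG(arr, path,
                  text = c(pixel_size_um = format(img$pixel_size_um, digits = 15),
                           origin_x_um = format(img$origin_um[1], digits = 15),
                           origin_y_um = format(img$origin_um[2], digits = 15)))
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = 8L)
    jsonlite::write_json(
      list(pixel_size_um = img$pixel_size_um,
           origin_x_um = img$origin_um[1], origin_y_um = img$origin_um[2]),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

# read a whole PNG/TIFF file with its calibration; mpp overrides metadata
.read_image_file <- function(path, mpp = NULL) {
  ext <- tolower(tools::file_ext(path))
  origin <- c(0, 0)
  psz <- mpp
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    txt <- info$text
    if (is.null(psz)) {
      if (!is.null(txt) && "pixel_size_um" %in% names(txt)) {
        psz <- as.numeric(txt[["pixel_size_um"]])
      } else if (!is.null(info$dpi) && all(is.finite(info$dpi))) {
        psz <- 25400 / info$dpi[1]  # dots per inch -> um per pixel
      }
    }
    if (!is.null(txt) && all(c("origin_x_um", "origin_y_um") %in% names(txt)))
      origin <- c(as.numeric(txt[["origin_x_um"]]), as.numeric(txt[["origin_y_um"]]))
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      if (is.null(psz)) psz <- as.numeric(meta$pixel_size_um)
      if (!is.null(meta$origin_x_um))
        origin <- c(as.numeric(meta$origin_x_um), as.numeric(meta$origin_y_um))
    }
    if (is.null(psz)) {
      xres <- attr(arr, "x.resolution")
      unit <- attr(arr, "resolution.unit")
      if (!is.null(xres) && is.finite(xres) && xres > 0) {
        per_um <- switch(ifelse(is.null(unit), "inch", unit),
                         inch = xres / 25400, cm = xres / 10000, NULL)
        if (!is.null(per_um)) psz <- 1 / per_um
      }
    }
  } else stop("unsupported image format: .", ext)
  if (is.null(psz) || !is.finite(psz))
    stop("no pixel-size calibration in ", basename(path),
         " and no --mpp override supplied")
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), c(dim(arr), 3))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  arr <- arr * 255
  attributes(arr) <- list(dim = dim(arr))
  calibrated_image(arr, psz, origin)
}

# pixel-index range covering [lo, hi) in micrometres for a given axis
.px_range <- function(lo, hi, origin, psz, nmax) {
  i_lo <- max(1L, as.integer(ceiling((lo - origin) / psz + 0.5 - 1e-9)))
  i_hi <- min(nmax, as.integer(ceiling((hi - origin) / psz + 0.5 - 1e-9)) - 1L)
  c(i_lo, i_hi)
}

#' Read a calibrated image region
#'
#' `path` may be a PNG or TIFF file (read whole, then cropped) or a tile-map
#' directory written by [write_tile_map()], from which only the tiles
#' overlapping the requested box are decoded — the memory-bounded route for
#' whole-slide sources. Pixel membership uses pixel centres, so adjacent
#' boxes partition an image without overlap.
#'
#' @param path image file or tile-map directory.
#' @param bbox_um optional (xmin, ymin, xmax, ymax) in micrometre slide
#'   coordinates; default the full image.
#' @param mpp optional micrometres-per-pixel override; wins over any file
#'   metadata.
#' @return A [calibrated_image()] with `origin_um` set so exported
#'   coordinates stay in slide coordinates.
#' @export
read_region <- function(path, bbox_um = NULL, mpp = NULL) {
  if (dir.exists(path)) return(.read_tilemap_region(path, bbox_um, mpp))
  img <- .read_image_file(path, mpp)
  if (is.null(bbox_um)) return(img)
  ext <- image_extent_um(img)
  if (bbox_um[1] < ext["xmin"] - 1e-6 || bbox_um[3] > ext["xmax"] + 1e-6 ||
      bbox_um[2] < ext["ymin"] - 1e-6 || bbox_um[4] > ext["ymax"] + 1e-6)
    stop("requested bbox lies outside the image")
  d <- dim(img$pixels)
  cr <- .px_range(bbox_um[1], bbox_um[3], img$origin_um[1], img$pixel_size_um, d[2])
  rr <- .px_range(bbox_um[2], bbox_um[4], img$origin_um[2], img$pixel_size_um, d[1])
  if (cr[2] < cr[1] || rr[2] < rr[1]) stop("requested bbox contains no pixels")
  calibrated_image(
    img$pixels[rr[1]:rr[2], cr[1]:cr[2], , drop = FALSE],
    img$pixel_size_um,
    c(img$origin_um[1] + (cr[1] - 1) * img$pixel_size_um,
      img$origin_um[2] + (rr[1] - 1) * img$pixel_size_um))
}

#' Write a large image as a tile map
#'
#' A tile map is a directory holding an `index.json` plus one calibrated
#' PNG per tile; [read_region()] decodes only the tiles a request
#' overlaps. `source` is either a [calibrated_image()] (split into
#' tiles) or a `ground_truth` (each tile is rendered on demand, so a
#' whole-slide synthetic image never exists in memory at once).
#'
#' @param source a [calibrated_image()] or `ground_truth`.
#' @param dir output directory (created).
#' @param tile_px tile edge length in pixels.
#' @return `dir`, invisibly.
#' @export
write_tile_map <- function(source, dir, tile_px = 2048L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(source, "ground_truth")) {
    spec <- source$spec
    psz <- spec$pixel_size_um
    nc <- max(1L, round(source$region_width_um / psz))
    nr <- max(1L, round(source$region_height_um / psz))
    origin <- c(0, 0)
    getter <- function(r0, c0, nrow_t, ncol_t) {
      bb <- c(origin[1] + c0 * psz, origin[2] + r0 * psz,
              origin[1] + (c0 + ncol_t) * psz, origin[2] + (r0 + nrow_t) * psz)
      render_tissue_region(source, bb)
    }
  } else if (inherits(source, "calibrated_image")) {
    psz <- source$pixel_size_um
    d <- dim(source$pixels)
    nr <- d[1]; nc <- d[2]
    origin <- source$origin_um
    getter <- function(r0, c0, nrow_t, ncol_t) {
      calibrated_image(
        source$pixels[(r0 + 1):(r0 + nrow_t), (c0 + 1):(c0 + ncol_t), ,
                      drop = FALSE],
        psz, c(origin[1] + c0 * psz, origin[2] + r0 * psz))
    }
  } else stop("source must be a calibrated_image or ground_truth")

  tiles <- list()
  k <- 0L
  for (r0 in seq(0L, nr - 1L, by = tile_px)) {
    for (c0 in seq(0L, nc - 1L, by = tile_px)) {
      nrow_t <- min(tile_px, nr - r0)
      ncol_t <- min(tile_px, nc - c0)
      k <- k + 1L
      fn <- sprintf("tile_%05d.png", k)
      img_t <- getter(r0, c0, nrow_t, ncol_t)
      png::writePNG(pmax(pmin(img_t$pixels / 255, 1), 0), file.path(dir, fn))
      tiles[[k]] <- list(row0 = r0, col0 = c0, nrow = nrow_t, ncol = ncol_t,
                         file = fn)
    }
  }
  jsonlite::write_json(
    list(pixel_size_um = psz, origin_x_um = origin[1], origin_y_um = origin[2],
         height_px = nr, width_px = nc, tiles = tiles),
    file.path(dir, "index.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

.read_tilemap_index <- function(dir) {
  jsonlite::read_json(file.path(dir, "index.json"), simplifyVector = FALSE)
}

.read_tilemap_region <- function(dir, bbox_um = NULL, mpp = NULL) {
  idx <- .read_tilemap_index(dir)
  psz <- if (!is.null(mpp)) mpp else as.numeric(idx$pixel_size_um)
  origin <- c(as.numeric(idx$origin_x_um), as.numeric(idx$origin_y_um))
  nr <- as.integer(idx$height_px); nc <- as.integer(idx$width_px)
  if (is.null(bbox_um))
    bbox_um <- c(origin[1], origin[2], origin[1] + nc * psz, origin[2] + nr * psz)
  if (bbox_um[1] < origin[1] - 1e-6 || bbox_um[2] < origin[2] - 1e-6 ||
      bbox_um[3] > origin[1] + nc * psz + 1e-6 ||
      bbox_um[4] > origin[2] + nr * psz + 1e-6)
    stop("requested bbox lies outside the image")
  cr <- .px_range(bbox_um[1], bbox_um[3], origin[1], psz, nc)
  rr <- .px_range(bbox_um[2], bbox_um[4], origin[2], psz, nr)
  if (cr[2] < cr[1] || rr[2] < rr[1]) stop("requested bbox contains no pixels")
  out <- array(0, c(rr[2] - rr[1] + 1L, cr[2] - cr[1] + 1L, 3))
  for (tl in idx$tiles) {
    t_r <- c(tl$row0 + 1L, tl$row0 + tl$nrow)  # 1-based pixel rows
    t_c <- c(tl$col0 + 1L, tl$col0 + tl$ncol)
    if (t_r[2] < rr[1] || t_r[1] > rr[2] || t_c[2] < cr[1] || t_c[1] > cr[2])
      next
    a <- png::readPNG(file.path(dir, tl$file))
    if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
    rs <- max(t_r[1], rr[1]):min(t_r[2], rr[2])
    cs <- max(t_c[1], cr[1]):min(t_c[2], cr[2])
    out[rs - rr[1] + 1L, cs - cr[1] + 1L, ] <-
      a[rs - tl$row0, cs - tl$col0, 1:3] * 255
  }
  calibrated_image(out, psz,
                   c(origin[1] + (cr[1] - 1) * psz,
                     origin[2] + (rr[1] - 1) * psz))
}
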