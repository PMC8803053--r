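#' Default pixel-feature configuration
#'
#' Per-pixel features for the two-class (fat lumen vs stained tissue)
#' classifier: raw R, G, B plus Gaussian-smoothed intensity, gradient
#' magnitude and Laplacian-of-Gaussian per channel at a small set of
#' scales. `sigma = 0` means the raw (resampled) channel.
#'
#' @param sigmas_gauss,sigmas_grad,sigmas_log scales (pixels at working
#'   resolution) for each filter family.
#' @return data.frame with columns `channel` (1 = R, 2 = G, 3 = B),
#'   `filter` (`"gauss"`, `"grad"`, `"log"`), `sigma`.
#' @export
default_feature_config <- function(sigmas_gauss = c(0, 2, 4),
                                   sigmas_grad = 2, sigmas_log = 2) {
  cfg <- rbind(
    expand.grid(channel = 1:3, filter = "gauss", sigma = sigmas_gauss,
                stringsAsFactors = FALSE),
    expand.grid(channel = 1:3, filter = "grad", sigma = sigmas_grad,
                stringsAsFactors = FALSE),
    expand.grid(channel = 1:3, filter = "log", sigma = sigmas_log,
                stringsAsFactors = FALSE))
  cfg[order(cfg$filter, cfg$sigma, cfg$channel), , drop = FALSE]
}

# 1-D Gaussian kernel, radius 3*sigma, normalized
.gauss_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian smoothing with replicated borders (direct convolution)
.smooth2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  .sep_conv2(m, .gauss_kernel_1d(sigma))
}

.conv3 <- function(m, kern) .conv2_small(m, kern)

#' Extract per-pixel classification features
#'
#' Resamples the image to the working resolution, then computes one plane
#' per feature row: Gaussian-smoothed channel, gradient magnitude of the
#' smoothed channel (central differences), or Laplacian of the smoothed
#' channel (3x3 stencil).
#'
#' @param image a [calibrated_image()].
#' @param feature_config data.frame as from [default_feature_config()].
#' @param working_pixel_size_um resolution at which to classify; defaults
#'   to the image's own pixel size.
#' @return H' x W' x F numeric array with attributes `pixel_size_um`,
#'   `origin_um`.
#' @export
extract_features <- function(image, feature_config = default_feature_config(),
                             working_pixel_size_um = NULL) {
  stopifnot(inherits(image, "calibrated_image"))
  if (is.null(working_pixel_size_um))
    working_pixel_size_um <- image$pixel_size_um
  img <- resample_image(image, working_pixel_size_um)
  d <- dim(img$pixels)
  max_sigma <- max(feature_config$sigma)
  if (2 * ceiling(3 * max_sigma) + 1 > min(d[1], d[2]))
    stop("feature scale too large for the image extent")
  nf <- nrow(feature_config)
  feats <- array(0, c(d[1], d[2], nf))
  # smooth each (channel, sigma) once
  key <- paste(feature_config$channel, feature_config$sigma)
  smoothed <- list()
  for (i in seq_len(nf)) {
    k <- key[i]
    if (is.null(smoothed[[k]]))
      smoothed[[k]] <- .smooth2d(img$pixels[, , feature_config$channel[i]],
                                 feature_config$sigma[i])
    base <- smoothed[[k]]
    feats[, , i] <- switch(
      feature_config$filter[i],
      gauss = base,
      grad = {
        gx <- .conv3(base, matrix(c(0.5, 0, -0.5), nrow = 1))
        gy <- .conv3(base, matrix(c(0.5, 0, -0.5), ncol = 1))
        sqrt(gx^2 + gy^2)
      },
      log = .conv3(base, matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)),
      stop("unknown filter: ", feature_config$filter[i]))
  }
  attr(feats, "pixel_size_um") <- working_pixel_size_um
  attr(feats, "origin_um") <- img$origin_um
  feats
}

# nearest-neighbour resampling of a label matrix to a target grid
.resample_labels <- function(labels, src_psz, dst_psz, nr, nc) {
  if (abs(src_psz - dst_psz) < 1e-9 &&
      nrow(labels) == nr && ncol(labels) == nc) return(labels)
  ri <- pmin(nrow(labels), pmax(1L, round((seq_len(nr) - 0.5) * dst_psz / src_psz + 0.5)))
  ci <- pmin(ncol(labels), pmax(1L, round((seq_len(nc) - 0.5) * dst_psz / src_psz + 0.5)))
  labels[ri, ci, drop = FALSE]
}

#' Binary class mask at working resolution
#'
#' @param mask logical matrix, `TRUE` = fat lumen.
#' @param pixel_size_um working resolution, micrometres per pixel.
#' @param origin_um (x, y) slide coordinate of the top-left corner.
#' @param provenance free-form character tag (model/image identifiers).
#' @return An object of class `class_mask`.
#' @export
class_mask <- function(mask, pixel_size_um, origin_um = c(0, 0),
                       provenance = "") {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("mask must be a logical matrix")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be positive")
  structure(list(mask = mask, pixel_size_um = pixel_size_um,
                 origin_um = as.numeric(origin_um), provenance = provenance),
            class = "class_mask")
}

#' @export
print.class_mask <- function(x, ...) {
  cat(sprintf("<class_mask> %d x %d px at %.4g um/px, %.1f%% fat\n",
              nrow(x$mask), ncol(x$mask), x$pixel_size_um,
              100 * mean(x$mask)))
  invisible(x)
}

#' Train the two-class random-forest pixel classifier
#'
#' Pools the labelled pixels of one or more annotated images, extracts
#' features at the working resolution, and fits a random forest
#' (`ranger`). Label masks use 0 = unlabelled, 1 = fat, 2 = tissue, at the
#' source image resolution. A held-out fraction of the labelled pixels is
#' set aside (before fitting) to report a held-out pixel accuracy.
#'
#' @param training list of `list(image = <calibrated_image>, labels =
#'   <integer matrix>)`.
#' @param feature_config see [default_feature_config()].
#' @param working_pixel_size_um classification resolution (>= image pixel
#'   size), micrometres per pixel.
#' @param num_trees number of trees (odd keeps majority votes tie-free).
#' @param max_pixels_per_class cap on pooled training pixels per class.
#' @param holdout_fraction fraction of labelled pixels held out for the
#'   reported accuracy.
#' @param seed integer; fixes subsampling and forest growth.
#' @return A `pixel_classifier_model`.
#' @export
train_pixel_classifier <- function(training,
                                   feature_config = default_feature_config(),
                                   working_pixel_size_um = 1,
                                   num_trees = 51L,
                                   max_pixels_per_class = 5000L,
                                   holdout_fraction = 0.2,
                                   seed = 1L) {
  if (inherits(training, "calibrated_image"))
    stop("training must be a list of list(image=, labels=) pairs")
  pool_x <- NULL; pool_y <- integer(0)
  for (item in training) {
    feats <- extract_features(item$image, feature_config, working_pixel_size_um)
    d <- dim(feats)
    lab <- .resample_labels(item$labels, item$image$pixel_size_um,
                            working_pixel_size_um, d[1], d[2])
    idx <- which(lab == 1L | lab == 2L)
    if (length(idx) == 0) next
    fm <- matrix(feats, d[1] * d[2], d[3])
    pool_x <- rbind(pool_x, fm[idx, , drop = FALSE])
    pool_y <- c(pool_y, lab[idx])
  }
  .fit_pixel_model(pool_x, pool_y, feature_config, working_pixel_size_um,
                   num_trees, max_pixels_per_class, holdout_fraction, seed)
}

# Flatten a grown ranger probability forest into per-tree arrays for the
# fast C++ evaluator: left/right child ids, split variable (0-based),
# split value, and the fat-class probability stored at terminal nodes.
.compile_forest <- function(forest) {
  fat_col <- which(forest$levels[forest$class.values] == "fat")
  ntree <- forest$num.trees
  out <- list(left = vector("list", ntree), right = vector("list", ntree),
              varid = vector("list", ntree), splitval = vector("list", ntree),
              nodeprob = vector("list", ntree))
  for (t in seq_len(ntree)) {
    L <- as.integer(forest$child.nodeIDs[[t]][[1]])
    R <- as.integer(forest$child.nodeIDs[[t]][[2]])
    prob <- numeric(length(L))
    term <- which(L == 0L & R == 0L)
    tcc <- forest$terminal.class.counts[[t]]
    prob[term] <- vapply(tcc[term], function(p) p[fat_col], numeric(1))
    out$left[[t]] <- L
    out$right[[t]] <- R
    out$varid[[t]] <- as.integer(forest$split.varIDs[[t]])
    out$splitval[[t]] <- as.numeric(forest$split.values[[t]])
    out$nodeprob[[t]] <- prob
  }
  out
}

# P(fat) per row of a feature matrix, via the compiled forest
.predict_fat_prob <- function(model, X) {
  cf <- model$compiled
  .forest_prob(cf$left, cf$right, cf$varid, cf$splitval, cf$nodeprob, X)
}

.fit_pixel_model <- function(pool_x, pool_y, feature_config,
                             working_pixel_size_um, num_trees,
                             max_pixels_per_class, holdout_fraction, seed) {
  classes <- c(fat = 1L, tissue = 2L)
  missing <- names(classes)[!classes %in% unique(pool_y)]
  if (length(missing) > 0 || is.null(pool_x))
    stop("training annotations contain no '",
         paste(missing, collapse = "', '"), "' pixels")
  set.seed(as.integer(seed))
  # per-class cap
  keep <- unlist(lapply(classes, function(cl) {
    i <- which(pool_y == cl)
    if (length(i) > max_pixels_per_class) sample(i, max_pixels_per_class) else i
  }), use.names = FALSE)
  x <- pool_x[keep, , drop = FALSE]
  y <- factor(ifelse(pool_y[keep] == 1L, "fat", "tissue"),
              levels = c("fat", "tissue"))
  n <- length(y)
  n_hold <- max(0L, floor(holdout_fraction * n))
  hold <- if (n_hold > 0) sample(n, n_hold) else integer(0)
  tr <- if (length(hold)) setdiff(seq_len(n), hold) else seq_len(n)
  if (length(unique(y[tr])) < 2)
    stop("training annotations contain too few pixels of one class")
  df <- data.frame(x[tr, , drop = FALSE])
  names(df) <- paste0("f", seq_len(ncol(x)))
  df$.class <- y[tr]
  forest <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = num_trees, probability = TRUE,
    mtry = max(1L, floor(sqrt(ncol(x)))),
    seed = as.integer(seed), num.threads = 1)
  compiled <- .compile_forest(forest$forest)
  acc <- NA_real_
  if (length(hold)) {
    hd <- data.frame(x[hold, , drop = FALSE])
    names(hd) <- paste0("f", seq_len(ncol(x)))
    p <- predict(forest, hd, num.threads = 1)$predictions
    acc <- mean((p[, "fat"] >= 0.5) == (y[hold] == "fat"))
  }
  structure(
    list(forest = forest, compiled = compiled,
         feature_config = feature_config,
         working_pixel_size_um = working_pixel_size_um,
         class_labels = c("fat", "tissue"), train_seed = as.integer(seed),
         num_trees = num_trees, max_pixels_per_class = max_pixels_per_class,
         holdout_fraction = holdout_fraction,
         holdout_accuracy = acc,
         train_x = pool_x, train_y = pool_y),
    class = "pixel_classifier_model")
}

#' @export
print.pixel_classifier_model <- function(x, ...) {
  cat(sprintf(
    "<pixel_classifier_model> %d features, %d trees, %.4g um/px working, held-out accuracy %.3f\n",
    nrow(x$feature_config), x$num_trees, x$working_pixel_size_um,
    x$holdout_accuracy))
  invisible(x)
}

#' Append annotations to a trained model and retrain
#'
#' Incremental improvement loop: annotate misclassified regions, fold the
#' new labels into the pooled training pixels, refit with the model's own
#' configuration and seed.
#'
#' @param model a `pixel_classifier_model`.
#' @param image the annotated [calibrated_image()].
#' @param labels integer matrix, 0 = unlabelled, 1 = fat, 2 = tissue.
#' @return A retrained `pixel_classifier_model`.
#' @export
add_training_annotations <- function(model, image, labels) {
  stopifnot(inherits(model, "pixel_classifier_model"))
  feats <- extract_features(image, model$feature_config,
                            model$working_pixel_size_um)
  d <- dim(feats)
  lab <- .resample_labels(labels, image$pixel_size_um,
                          model$working_pixel_size_um, d[1], d[2])
  idx <- which(lab == 1L | lab == 2L)
  fm <- matrix(feats, d[1] * d[2], d[3])
  .fit_pixel_model(rbind(model$train_x, fm[idx, , drop = FALSE]),
                   c(model$train_y, lab[idx]),
                   model$feature_config, model$working_pixel_size_um,
                   model$num_trees, model$max_pixels_per_class,
                   model$holdout_fraction, model$train_seed)
}

#' Classify the pixels of a calibrated image
#'
#' Applies the trained forest at the working resolution; a pixel is fat
#' when its forest probability for the fat class is >= 0.5 (majority
#' vote). Pixels outside the optional region-of-interest polygon are
#' forced to tissue.
#'
#' @param model a `pixel_classifier_model`.
#' @param image a [calibrated_image()].
#' @param roi_polygon optional n x 2 matrix of (x, y) micrometre slide
#'   coordinates.
#' @return A [class_mask()].
#' @export
classify_pixels <- function(model, image, roi_polygon = NULL) {
  stopifnot(inherits(model, "pixel_classifier_model"))
  if (!inherits(image, "calibrated_image"))
    stop("image must be a calibrated_image (pixel size in micrometres is required)")
  feats <- extract_features(image, model$feature_config,
                            model$working_pixel_size_um)
  d <- dim(feats)
  psz <- attr(feats, "pixel_size_um")
  origin <- attr(feats, "origin_um")
  X <- matrix(feats, d[1] * d[2], d[3])
  rm(feats)  # the feature stack dominates memory at slide scale
  p <- .predict_fat_prob(model, X)
  rm(X)
  mask <- matrix(p >= 0.5, d[1], d[2])
  if (!is.null(roi_polygon)) {
    inside <- .rasterize_polygons(list(roi_polygon), d[1], d[2],
                                  psz, origin[1], origin[2]) > 0
    mask <- mask & inside
  }
  class_mask(mask, psz, origin,
             provenance = sprintf("ranger[%d trees] seed %d",
                                  model$num_trees, model$train_seed))
}

#' Save / load a pixel classifier model
#'
#' Serialized as a single RDS container carrying the forest, feature
#' configuration, working resolution and seed.
#'
#' @param model a `pixel_classifier_model`.
#' @param path file path.
#' @return `load_pixel_classifier` returns the model.
#' @export
save_pixel_classifier <- function(model, path) {
  stopifnot(inherits(model, "pixel_classifier_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_pixel_classifier
#' @export
load_pixel_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pixel_classifier_model"))
    stop("file does not contain a pixel_classifier_model")
  model
}
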