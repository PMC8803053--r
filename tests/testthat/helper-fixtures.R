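# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# mid-sized good-quality synthetic region used across modules
fixture_tissue <- function() {
  if (is.null(.fixtures$tissue)) {
    spec <- tissue_spec(region_width_um = 800, region_height_um = 600,
                        target_density = 150, seed = 11)
    .fixtures$tissue <- generate_tissue(spec)
  }
  .fixtures$tissue
}

make_labels_from_truth <- function(gen, n_per_class = 1500, seed = 5) {
  training_labels_from_truth(gen, n_per_class, seed)
}

fixture_model <- function() {
  if (is.null(.fixtures$model)) {
    gen <- fixture_tissue()
    labels <- make_labels_from_truth(gen)
    .fixtures$model <- train_pixel_classifier(
      list(list(image = gen$image, labels = labels)), seed = 7)
  }
  .fixtures$model
}

# toy class_mask from a 0/1 matrix at 1 um/px
toy_mask <- function(m, pixel_size_um = 1) {
  class_mask(matrix(as.logical(m), nrow(m), ncol(m)), pixel_size_um)
}

# filled disc mask (centre in pixel units, radius in pixels)
disc_mask <- function(nr, nc, centres, radius, pixel_size_um = 1) {
  m <- matrix(FALSE, nr, nc)
  for (ct in centres) {
    for (r in 1:nr) {
      dy2 <- (r - ct[1])^2
      cols <- which(dy2 + (seq_len(nc) - ct[2])^2 <= radius^2)
      m[r, cols] <- TRUE
    }
  }
  class_mask(m, pixel_size_um)
}
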