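# Shared fixtures, generated in code.  The trained reference model is
# expensive (a couple of minutes), so it is built once per test run and
# memoized in this environment.

.fixtures <- new.env(parent = emptyenv())

# n patches per class of the default textures, at the standard 224 px
make_texture_set <- function(n_per_class, seed0 = 1L, size = 224L) {
  classes <- patch_classes()
  patches <- vector("list", n_per_class * length(classes))
  labels <- character(length(patches))
  k <- 0L
  for (ci in seq_along(classes)) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      patches[[k]] <- draw_texture(classes[ci], size, size,
                                   seed = seed0 + ci * 10000L + i)
      labels[k] <- classes[ci]
    }
  }
  list(patches = patches, labels = labels)
}

# the separability fixture: 200 patches/class, 20 epochs (held-out set
# of 20/class drawn from a disjoint seed range)
fixture_model <- function() {
  if (is.null(.fixtures$model)) {
    train <- make_texture_set(200, seed0 = 1L)
    .fixtures$model <- train_patch_classifier(train$patches, train$labels,
                                              train_config(seed = 303L))
  }
  .fixtures$model
}

fixture_heldout <- function() {
  if (is.null(.fixtures$heldout))
    .fixtures$heldout <- make_texture_set(20, seed0 = 5e6L)
  .fixtures$heldout
}

# small quick models for ensemble/determinism properties
quick_model <- function(seed, n_per_class = 60L, epochs = 8L) {
  key <- sprintf("quick_%d_%d_%d", seed, n_per_class, epochs)
  if (is.null(.fixtures[[key]])) {
    tr <- make_texture_set(n_per_class, seed0 = 7e6L)
    .fixtures[[key]] <- train_patch_classifier(
      tr$patches, tr$labels, train_config(epochs = epochs, seed = seed))
  }
  .fixtures[[key]]
}

# a small planted slide (5x5 window grid) for inference tests
small_slide <- function(label, villous = 0, ssa = 0, seed = 11L) {
  generate_slide(slide_spec(label, slide_id = paste0("small-", label),
                            size = 1120L, n_roi = 2L, roi_cells = c(2L, 2L),
                            villous_fraction = villous, ssa_fraction = ssa,
                            n_norm_boxes = 3L),
                 seed = seed)
}

# independent brute-force one-vs-rest 2x2 tabulation oracle
brute_force_ovr <- function(pred, truth, class) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(truth)) {
    p <- pred[i] == class; t <- truth[i] == class
    if (p && t) tp <- tp + 1
    else if (p && !t) fp <- fp + 1
    else if (!p && t) fn <- fn + 1
    else tn <- tn + 1
  }
  c(accuracy = 100 * (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

# the printed per-class performance table (worked-example inputs)
performance_table <- function() {
  read.csv(system.file("extdata", "performance_table.csv",
                       package = "polypscope"),
           stringsAsFactors = FALSE)
}
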