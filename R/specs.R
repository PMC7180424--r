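#' Sliding-window patch specification
#'
#' Describes the fixed-size patch grid used for both training-patch
#' extraction and whole-slide inference.  The defaults follow the common
#' digital-pathology setup of non-overlapping 224 x 224-pixel windows.
#'
#' `extraction_downsample` is the integer factor by which the source
#' image is area-averaged before windowing.  Images produced by the
#' synthetic generator are already at extraction resolution, so the
#' default is 1; for a full-resolution 40x scan (0.25 um/px) where a
#' 224-pixel patch should cover 448 um of tissue, use 8.
#'
#' @param patch_size Side of the square patch, in pixels of the
#'   (possibly downsampled) extraction image.
#' @param stride Step between window origins in pixels; defaults to
#'   `patch_size` (non-overlapping tiling).
#' @param extraction_downsample Integer downsample factor >= 1 applied
#'   to images before windowing.
#' @return An object of class `patch_spec`.
#' @examples
#' patch_spec()                    # 224 px non-overlapping windows
#' patch_spec(extraction_downsample = 8)  # for 40x full-resolution scans
#' @export
patch_spec <- function(patch_size = 224L, stride = patch_size,
                       extraction_downsample = 1L) {
  patch_size <- as.integer(patch_size)
  stride <- as.integer(stride)
  extraction_downsample <- as.integer(extraction_downsample)
  if (patch_size < 1L) stopf("patch_size must be >= 1")
  if (stride < 1L) stopf("stride must be >= 1")
  if (extraction_downsample < 1L) stopf("extraction_downsample must be >= 1")
  structure(list(patch_size = patch_size, stride = stride,
                 extraction_downsample = extraction_downsample),
            class = "patch_spec")
}

#' Patch augmentation specification
#'
#' Controls the stochastic augmentations applied to training patches:
#' right-angle rotations, horizontal/vertical flips, and colour jitter on
#' brightness, contrast, saturation and hue.  Jitter offsets are drawn
#' uniformly from `[-half_range, +half_range]`; hue is expressed as a
#' fraction of a full hue circle.  Augmented pixel values are clipped to
#' `[0, 1]`.
#'
#' @param rotations Subset of `c(0, 90, 180, 270)` degrees to draw from.
#' @param hflip,vflip Enable horizontal / vertical flips (each applied
#'   with probability 1/2 when enabled).
#' @param brightness,contrast,saturation,hue Non-negative jitter
#'   half-ranges.
#' @return An object of class `augment_spec`.
#' @examples
#' augment_spec()                               # defaults
#' augment_spec(rotations = 0, hflip = FALSE,
#'              vflip = FALSE, brightness = 0,
#'              contrast = 0, saturation = 0, hue = 0)  # identity
#' @export
augment_spec <- function(rotations = c(0, 90, 180, 270),
                         hflip = TRUE, vflip = TRUE,
                         brightness = 0.1, contrast = 0.1,
                         saturation = 0.1, hue = 0.05) {
  rotations <- as.integer(rotations)
  if (!all(rotations %in% c(0L, 90L, 180L, 270L)))
    stopf("rotations must be a subset of 0, 90, 180, 270")
  if (length(rotations) == 0L) rotations <- 0L
  jit <- c(brightness = brightness, contrast = contrast,
           saturation = saturation, hue = hue)
  if (any(jit < 0)) stopf("jitter half-ranges must be >= 0")
  structure(list(rotations = rotations, hflip = isTRUE(hflip),
                 vflip = isTRUE(vflip), brightness = brightness,
                 contrast = contrast, saturation = saturation, hue = hue),
            class = "augment_spec")
}

#' Training configuration for the patch classifier
#'
#' The learning-rate schedule is exponential decay per epoch:
#' `lr(e) = initial_lr * lr_decay^(e - 1)`, so epoch 1 runs at the
#' initial rate.  The reference schedule used at scale is 200 epochs from
#' 0.001 with decay 0.9 per epoch; the desk-scale default trains for 20
#' epochs, which is sufficient for the synthetic textures.
#'
#' @param epochs Number of training epochs (>= 1).
#' @param initial_lr Initial learning rate.
#' @param lr_decay Multiplicative decay per epoch, in (0, 1].
#' @param batch_size Minibatch size for stochastic gradient descent.
#' @param momentum SGD momentum coefficient in `[0, 1)`.
#' @param seed Integer seed controlling initialization, shuffling and
#'   augmentation; training is deterministic given the seed.
#' @param augment An [augment_spec()] applied to each training patch, or
#'   `NULL` to disable augmentation.
#' @param init Weight initialization: `"he_normal"` (MSRA-style, normal
#'   with variance 2/fan-in) or `"fixed_seed_uniform"` (small uniform).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 20L, initial_lr = 0.001, lr_decay = 0.9,
                         batch_size = 8L, momentum = 0.9, seed = 1L,
                         augment = augment_spec(),
                         init = c("he_normal", "fixed_seed_uniform")) {
  epochs <- as.integer(epochs)
  if (epochs < 1L) stopf("epochs must be >= 1")
  if (!(lr_decay > 0 && lr_decay <= 1)) stopf("lr_decay must be in (0, 1]")
  if (initial_lr <= 0) stopf("initial_lr must be > 0")
  if (!is.null(augment) && !inherits(augment, "augment_spec"))
    stopf("augment must be an augment_spec or NULL")
  structure(list(epochs = epochs, initial_lr = initial_lr,
                 lr_decay = lr_decay, batch_size = as.integer(batch_size),
                 momentum = momentum, seed = as.integer(seed),
                 augment = augment, init = match.arg(init)),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' @param config A [train_config()].
#' @param epochs Epochs at which to evaluate the schedule (default: all
#'   epochs of the configuration).
#' @return Numeric vector of per-epoch learning rates,
#'   `initial_lr * lr_decay^(epoch - 1)`.
#' @examples
#' lr_schedule(train_config(epochs = 3))  # 0.001 0.0009 0.00081
#' @export
lr_schedule <- function(config, epochs = seq_len(config$epochs)) {
  config$initial_lr * config$lr_decay^(epochs - 1)
}

#' Slide-level decision thresholds
#'
#' The hierarchical slide rule first assigns the adenomatous or serrated
#' branch by patch-count majority, then subclassifies within the branch:
#' an adenomatous slide whose villous (TVA-patch) fraction strictly
#' exceeds `villous_threshold` is called TVA, otherwise TA; a serrated
#' slide whose SSA-patch fraction strictly exceeds `ssa_threshold` is
#' called SSA, otherwise HP.  The reference operating point is a villous
#' threshold of 0.30 and an SSA threshold of 0.015, both applied as
#' strict `>`.
#'
#' @param villous_threshold Villous fraction cutoff in `[0, 1]`.
#' @param ssa_threshold SSA fraction cutoff in `[0, 1]`.
#' @param denominator `"branch"` computes each fraction over the patches
#'   of its own branch (TVA over adenomatous patches, SSA over serrated
#'   patches); `"all_polyp_patches"` divides by all non-normal patches.
#' @return An object of class `threshold_config`.
#' @examples
#' threshold_config()  # reference operating point
#' @export
threshold_config <- function(villous_threshold = 0.30, ssa_threshold = 0.015,
                             denominator = c("branch", "all_polyp_patches")) {
  if (villous_threshold < 0 || villous_threshold > 1 ||
      ssa_threshold < 0 || ssa_threshold > 1)
    stopf("thresholds must lie in [0, 1]")
  structure(list(villous_threshold = villous_threshold,
                 ssa_threshold = ssa_threshold,
                 denominator = match.arg(denominator)),
            class = "threshold_config")
}

#' Grid specification for threshold calibration
#'
#' Defines the candidate grid searched by [calibrate_thresholds()].  The
#' SSA grid is finer than the villous grid because the useful operating
#' points for the SSA fraction are small.
#'
#' @param villous_grid Candidate villous thresholds in `[0, 1]`.
#' @param ssa_grid Candidate SSA thresholds in `[0, 1]`.
#' @param objective `"mean_class_accuracy"` (unweighted mean of the four
#'   one-vs-rest class accuracies) or `"overall_accuracy"`.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(villous_grid = seq(0, 1, by = 0.05),
                      ssa_grid = seq(0, 0.10, by = 0.005),
                      objective = c("mean_class_accuracy",
                                    "overall_accuracy")) {
  if (length(villous_grid) == 0L || length(ssa_grid) == 0L)
    stopf("threshold grids must be nonempty")
  if (any(villous_grid < 0 | villous_grid > 1) ||
      any(ssa_grid < 0 | ssa_grid > 1))
    stopf("grid values must lie in [0, 1]")
  structure(list(villous_grid = sort(villous_grid),
                 ssa_grid = sort(ssa_grid),
                 objective = match.arg(objective)),
            class = "grid_spec")
}

#' Heatmap overlay style
#'
#' Colours, the confidence-to-opacity mapping, and the lesion highlight
#' set used by [render_heatmap()] and [render_lesion_mask()].  Opacity is
#' linear in the patch confidence (the maximum class probability):
#' `alpha = alpha_base + alpha_gain * confidence`, clipped to `[0, 1]`,
#' so higher-confidence predictions are tinted more darkly.
#'
#' @param colors Named list/vector of RGB triples (values in `[0, 1]`)
#'   per patch class.
#' @param alpha_base,alpha_gain Intercept and slope of the linear
#'   confidence-to-alpha mapping; `alpha_gain` must be >= 0 so the
#'   mapping is monotone increasing.
#' @param highlight_classes Classes highlighted by
#'   [render_lesion_mask()]; default all four polyp classes.
#' @param highlight_color RGB triple used for the lesion highlight.
#' @return An object of class `overlay_style`.
#' @export
overlay_style <- function(colors = NULL, alpha_base = 0.15,
                          alpha_gain = 0.6,
                          highlight_classes = slide_classes(),
                          highlight_color = c(0.1, 0.8, 0.2)) {
  default_cols <- list(TA   = c(0.20, 0.45, 0.95),
                       TVA  = c(0.95, 0.55, 0.10),
                       HP   = c(0.15, 0.75, 0.65),
                       SSA  = c(0.85, 0.15, 0.25),
                       NORM = c(0.70, 0.70, 0.70))
  if (is.null(colors)) colors <- default_cols
  if (!all(patch_classes() %in% names(colors)))
    stopf("colors must be named for every patch class")
  if (alpha_gain < 0) stopf("alpha_gain must be >= 0 (monotone mapping)")
  highlight_classes <- match_labels(highlight_classes, patch_classes(),
                                    "highlight class")
  structure(list(colors = colors, alpha_base = alpha_base,
                 alpha_gain = alpha_gain,
                 highlight_classes = highlight_classes,
                 highlight_color = highlight_color),
            class = "overlay_style")
}
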