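#' Default texture recipes for synthetic slide classes
#'
#' Each patch class is rendered as a parametric procedural texture: a
#' base colour modulated by a class-specific periodic structure plus
#' Gaussian pixel noise.  The structures loosely mimic the architecture
#' that distinguishes the polyp types -- round tubular lumens (TA),
#' elongated frond-like stripes (TVA), sawtooth serration (HP), large
#' dilated crypts (SSA), and sparse pale stroma (NORM) -- but they are
#' deliberately simple statistical patterns, not histology simulations:
#' the classes are separable by mean colour, gradient energy and
#' dominant spatial period, which a small classifier can learn quickly
#' on a CPU.
#'
#' @return Named list of recipes, one per patch class, each with fields
#'   `base` (RGB triple), `structure` (pattern name), `period` (pixels),
#'   `amplitude` (modulation depth) and `noise_sd`.
#' @export
default_texture_recipes <- function() {
  list(
    TA   = list(base = c(0.88, 0.58, 0.72), structure = "round_tubules",
                period = 28, amplitude = 0.45, noise_sd = 0.02),
    TVA  = list(base = c(0.80, 0.42, 0.58), structure = "elongated_fronds",
                period = 20, amplitude = 0.50, noise_sd = 0.02),
    HP   = list(base = c(0.92, 0.70, 0.82), structure = "sawtooth_serration",
                period = 24, amplitude = 0.35, noise_sd = 0.02),
    SSA  = list(base = c(0.70, 0.50, 0.82), structure = "dilated_boot_crypts",
                period = 56, amplitude = 0.50, noise_sd = 0.02),
    NORM = list(base = c(0.96, 0.88, 0.92), structure = "sparse_stroma",
                period = 48, amplitude = 0.25, noise_sd = 0.02)
  )
}

#' Render a class texture
#'
#' @param class Patch class name.
#' @param width,height Output size in pixels.
#' @param seed Seed for the pixel noise; deterministic given the seed.
#' @param recipes Recipe list, see [default_texture_recipes()].
#' @return `height x width x 3` array in `[0, 1]`.
#' @export
draw_texture <- function(class, width, height, seed = NULL,
                         recipes = default_texture_recipes()) {
  class <- match_labels(class, patch_classes(), "texture class")
  r <- recipes[[class]]
  m <- texture_structure(r, width, height)
  img <- with_seed(seed, {
    noise <- array(stats::rnorm(height * width * 3, sd = r$noise_sd),
                   c(height, width, 3))
    out <- array(0, c(height, width, 3))
    for (ch in 1:3) out[, , ch] <- r$base[ch] * (1 - r$amplitude * m)
    out + noise
  })
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

# deterministic structure pattern, cached by recipe geometry
.texture_cache <- new.env(parent = emptyenv())

texture_structure <- function(r, width, height) {
  key <- paste(r$structure, r$period, width, height, sep = "_")
  if (!is.null(.texture_cache[[key]])) return(.texture_cache[[key]])
  p <- r$period
  x <- matrix(rep(seq_len(width) - 1, each = height), nrow = height)
  y <- matrix(rep(seq_len(height) - 1, times = width), nrow = height)
  m <- switch(r$structure,
    round_tubules = sin(pi * x / p)^2 * sin(pi * y / p)^2,
    elongated_fronds = sin(pi * x / p)^2,
    sawtooth_serration = 2 * abs(((x + y) %% p) / p - 0.5),
    dilated_boot_crypts = sin(pi * x / (2 * p))^2 * sin(pi * y / p)^2,
    sparse_stroma = as.numeric(sin(pi * x / p)^2 * sin(pi * y / p)^2 > 0.9),
    stopf("unknown texture structure '%s'", r$structure))
  .texture_cache[[key]] <- m
  m
}

#' Summary statistics of a texture patch
#'
#' The feature vector that underwrites class separability: per-channel
#' mean intensity, mean gradient energy, and the dominant spatial
#' frequency of the column-mean profile.
#'
#' @param patch `h x w x 3` array.
#' @return Named numeric vector of length 5.
#' @export
texture_statistics <- function(patch) {
  gray <- (patch[, , 1] + patch[, , 2] + patch[, , 3]) / 3
  gx <- gray[, -1] - gray[, -ncol(gray)]
  gy <- gray[-1, ] - gray[-nrow(gray), ]
  cm <- colMeans(gray)
  sp <- Mod(stats::fft(cm - mean(cm)))
  n <- length(cm)
  dom <- which.max(sp[2:(n %/% 2)]) / n
  c(mean_r = mean(patch[, , 1]), mean_g = mean(patch[, , 2]),
    mean_b = mean(patch[, , 3]),
    grad_energy = mean(abs(gx)) + mean(abs(gy)),
    dom_freq = dom)
}

#' Specification of one synthetic slide
#'
#' Synthetic slides are a normal-tissue background with `n_roi`
#' rectangular polyp ROIs whose corners are aligned to the sliding
#' window grid (cells of `cell` pixels), so that every planted texture
#' region coincides exactly with one inference window.  For adenomatous
#' slides a fraction `villous_fraction` of ROI cells (rounded at the
#' slide level) is drawn with TVA texture and the rest with TA texture;
#' for serrated slides `ssa_fraction` of the cells is SSA and the rest
#' HP.
#'
#' @param true_label Slide-level class (`TA`, `TVA`, `HP`, `SSA`).
#' @param slide_id Slide identifier.
#' @param size Slide side in pixels (default 2048, about 81 windows of
#'   224 px at stride 224).
#' @param n_roi Number of polyp ROIs.
#' @param roi_cells Range (min, max) of ROI side length in grid cells.
#' @param villous_fraction Fraction of adenomatous ROI area drawn with
#'   TVA texture (only meaningful for labels TA/TVA).
#' @param ssa_fraction Fraction of serrated ROI area drawn with SSA
#'   texture (only meaningful for labels HP/SSA).
#' @param n_norm_boxes Number of background cells annotated as NORM.
#' @param cell Grid cell side in pixels (the inference patch size).
#' @param recipes Texture recipes, see [default_texture_recipes()].
#' @return An object of class `slide_spec`.
#' @export
slide_spec <- function(true_label, slide_id = "slide-1", size = 2048L,
                       n_roi = 3L, roi_cells = c(3L, 4L),
                       villous_fraction = 0, ssa_fraction = 0,
                       n_norm_boxes = 6L, cell = 224L,
                       recipes = default_texture_recipes()) {
  true_label <- match_labels(true_label, slide_classes(), "slide label")
  if (villous_fraction < 0 || villous_fraction > 1 ||
      ssa_fraction < 0 || ssa_fraction > 1)
    stopf("villous_fraction and ssa_fraction must lie in [0, 1]")
  structure(list(true_label = true_label, slide_id = slide_id,
                 size = as.integer(size), n_roi = as.integer(n_roi),
                 roi_cells = as.integer(roi_cells),
                 villous_fraction = villous_fraction,
                 ssa_fraction = ssa_fraction,
                 n_norm_boxes = as.integer(n_norm_boxes),
                 cell = as.integer(cell), recipes = recipes),
            class = "slide_spec")
}

#' Generate one synthetic slide
#'
#' Deterministic given `(spec, seed)`.  Returns the rendered image, the
#' ROI annotations (one box per grid cell, tiling each planted ROI, plus
#' `n_norm_boxes` normal-tissue boxes), the slide label, and the integer
#' label mask (values index [patch_classes()]) from which planted area
#' fractions and oracle patch labels can be recovered.  Because cell
#' assignment is rounded at the slide level, the realized villous/SSA
#' texture-area fraction is within `0.5 / n_cells` of the requested
#' fraction (at the defaults, within 0.02).
#'
#' @param spec A [slide_spec()].
#' @param seed Integer seed.
#' @return List with elements `image`, `annotations`, `label`, `mask`,
#'   and `cells` (data frame of planted cell labels).
#' @export
generate_slide <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "slide_spec"))
  cell <- spec$cell
  n_grid <- spec$size %/% cell
  if (max(spec$roi_cells) > n_grid)
    stopf("ROI size (%d cells) exceeds the slide grid (%d cells)",
          max(spec$roi_cells), n_grid)
  with_seed(seed, {
    # place non-overlapping ROIs on the cell grid
    occ <- matrix(FALSE, n_grid, n_grid)
    rois <- list()
    for (i in seq_len(spec$n_roi)) {
      side_range <- spec$roi_cells[1]:spec$roi_cells[2]
      for (try in 1:500) {
        w <- side_range[sample.int(length(side_range), 1L)]
        h <- side_range[sample.int(length(side_range), 1L)]
        cx <- sample.int(n_grid - w + 1L, 1L) - 1L
        cy <- sample.int(n_grid - h + 1L, 1L) - 1L
        if (!any(occ[(cy + 1):(cy + h), (cx + 1):(cx + w)])) {
          occ[(cy + 1):(cy + h), (cx + 1):(cx + w)] <- TRUE
          rois[[i]] <- c(cx = cx, cy = cy, w = w, h = h)
          break
        }
      }
      if (length(rois) < i)
        stopf("could not place %d non-overlapping ROIs on the slide",
              spec$n_roi)
    }
    # enumerate ROI cells and assign the minority texture at slide level
    cells <- do.call(rbind, lapply(rois, function(r) {
      expand.grid(cx = r[["cx"]] + 0:(r[["w"]] - 1L),
                  cy = r[["cy"]] + 0:(r[["h"]] - 1L))
    }))
    n_cells <- nrow(cells)
    adeno <- spec$true_label %in% c("TA", "TVA")
    frac <- if (adeno) spec$villous_fraction else spec$ssa_fraction
    minority <- if (adeno) "TVA" else "SSA"
    majority <- if (adeno) "TA" else "HP"
    n_min <- round(frac * n_cells)
    lab <- rep(majority, n_cells)
    if (n_min > 0) lab[sample.int(n_cells, n_min)] <- minority
    cells$label <- lab
    # NORM annotation boxes on unoccupied cells
    free <- which(!occ) - 1L
    n_norm <- min(spec$n_norm_boxes, length(free))
    norm_cells <- if (n_norm > 0) {
      idx <- free[sample.int(length(free), n_norm)]
      data.frame(cx = idx %/% n_grid, cy = idx %% n_grid,
                 label = "NORM", stringsAsFactors = FALSE)
    } else NULL
    # render: NORM background, then one texture tile per planted cell
    image <- draw_texture("NORM", spec$size, spec$size,
                          seed = derive_seed(seed, 0), recipes = spec$recipes)
    mask <- matrix(match("NORM", patch_classes()),
                   nrow = spec$size, ncol = spec$size)
    for (i in seq_len(n_cells)) {
      x0 <- cells$cx[i] * cell; y0 <- cells$cy[i] * cell
      tile <- draw_texture(cells$label[i], cell, cell,
                           seed = derive_seed(seed, i),
                           recipes = spec$recipes)
      image[(y0 + 1):(y0 + cell), (x0 + 1):(x0 + cell), ] <- tile
      mask[(y0 + 1):(y0 + cell), (x0 + 1):(x0 + cell)] <-
        match(cells$label[i], patch_classes())
    }
    all_cells <- rbind(cells, norm_cells)
    annotations <- data.frame(
      slide_id = spec$slide_id,
      x0 = all_cells$cx * cell, y0 = all_cells$cy * cell,
      x1 = (all_cells$cx + 1L) * cell, y1 = (all_cells$cy + 1L) * cell,
      label = all_cells$label, annotator_id = "synthetic",
      stringsAsFactors = FALSE)
    list(image = image, annotations = validate_annotations(annotations),
         label = spec$true_label, mask = mask, cells = all_cells)
  })
}

#' Planted area fraction recovered from a label mask
#'
#' @param mask Integer label mask from [generate_slide()].
#' @param branch `"adenomatous"` (TVA fraction of TA+TVA pixels) or
#'   `"serrated"` (SSA fraction of HP+SSA pixels).
#' @return Realized area fraction, or `NA` if the branch is absent.
#' @export
mask_area_fraction <- function(mask, branch = c("adenomatous", "serrated")) {
  branch <- match.arg(branch)
  counts <- tabulate(mask, nbins = 5L)
  names(counts) <- patch_classes()
  if (branch == "adenomatous") {
    denom <- counts[["TA"]] + counts[["TVA"]]
    if (denom == 0) return(NA_real_)
    counts[["TVA"]] / denom
  } else {
    denom <- counts[["HP"]] + counts[["SSA"]]
    if (denom == 0) return(NA_real_)
    counts[["SSA"]] / denom
  }
}

#' Oracle patch predictions from a generator label mask
#'
#' Produces the prediction table a perfect patch classifier would emit:
#' for every sliding window over the whole slide, a one-hot probability
#' vector on the majority pixel label within the window.
#'
#' @param mask Integer label mask from [generate_slide()].
#' @param slide_id Slide identifier for the prediction rows.
#' @param spec A [patch_spec()].
#' @return Prediction data frame (see [read_predictions()]).
#' @export
oracle_patch_predictions <- function(mask, slide_id = "slide-1",
                                     spec = patch_spec()) {
  d <- dim(mask)
  origins <- sliding_window(c(0, 0, d[2L], d[1L]), spec)
  size <- spec$patch_size
  probs <- matrix(0, nrow(origins), 5L)
  for (i in seq_len(nrow(origins))) {
    win <- mask[(origins$y[i] + 1):(origins$y[i] + size),
                (origins$x[i] + 1):(origins$x[i] + size)]
    probs[i, which.max(tabulate(win, nbins = 5L))] <- 1
  }
  prediction_table(slide_id, origins, probs, size)
}

#' Generate a synthetic slide cohort
#'
#' Generates `n_per_class` slides for each of the four polyp classes,
#' assigns train/validation/internal-test splits deterministically, and
#' writes the full fixture set in the package's exchange formats:
#' slide images (PNG), `manifest.csv`, `annotations.json`, `truth.csv`
#' (slide label plus the planted fractions and per-slide seed) and
#' `oracle_counts.csv` (the planted patch-label histogram over the
#' whole-slide window grid).
#'
#' Planted villous/SSA fractions are drawn uniformly from per-class
#' ranges chosen to straddle the reference decision thresholds (0.30
#' villous, 0.015 SSA) with a margin of at least 0.05: TA slides draw
#' villous fractions in `[0.05, 0.22]`, TVA in `[0.40, 0.80]`, HP slides
#' carry no SSA texture, and SSA slides draw SSA fractions in
#' `[0.10, 0.40]`.
#'
#' @param n_per_class Slides per class (scalar or named vector over
#'   [slide_classes()]), each >= 1.
#' @param split_fractions Named fractions for `train`, `validation`,
#'   `test_internal`; must sum to 1.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param slide_size Slide side in pixels.
#' @param villous_ranges,ssa_ranges Named lists of `c(lo, hi)` fraction
#'   ranges for the adenomatous / serrated classes.
#' @param write_images If `FALSE`, skip the PNG rendering (manifest and
#'   tables only; useful when only counts-level fixtures are needed).
#' @param ... Further arguments passed to [slide_spec()].
#' @return Invisibly, a list with `manifest`, `annotations`, `truth`,
#'   `oracle_counts` and `dir`.
#' @export
generate_cohort <- function(n_per_class = 10L,
                            split_fractions = c(train = 0.6,
                                                validation = 0.2,
                                                test_internal = 0.2),
                            out_dir = tempfile("cohort"), seed = 1L,
                            slide_size = 2048L,
                            villous_ranges = list(TA = c(0.05, 0.22),
                                                  TVA = c(0.40, 0.80)),
                            ssa_ranges = list(HP = c(0, 0),
                                              SSA = c(0.10, 0.40)),
                            write_images = TRUE, ...) {
  if (length(n_per_class) == 1L)
    n_per_class <- stats::setNames(rep(as.integer(n_per_class), 4L),
                                   slide_classes())
  if (any(n_per_class < 1L)) stopf("n_per_class must be >= 1 for every class")
  if (abs(sum(split_fractions) - 1) > 1e-8)
    stopf("split fractions must sum to 1 (got %.4f)", sum(split_fractions))
  splits <- names(split_fractions)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- manifest <- ann <- counts <- list()
  slide_no <- 0L
  for (cl in slide_classes()) {
    n <- n_per_class[[cl]]
    # largest-remainder split allocation, deterministic order given seed
    alloc <- floor(split_fractions * n)
    rem <- n - sum(alloc)
    if (rem > 0) {
      extra <- order(split_fractions * n - alloc, decreasing = TRUE)[seq_len(rem)]
      alloc[extra] <- alloc[extra] + 1L
    }
    split_vec <- with_seed(derive_seed(seed, match(cl, slide_classes())),
                           sample(rep(splits, alloc)))
    for (i in seq_len(n)) {
      slide_no <- slide_no + 1L
      sid <- sprintf("%s-%03d", cl, i)
      slide_seed <- derive_seed(seed, 100L + slide_no)
      fr <- with_seed(derive_seed(seed, 10000L + slide_no), {
        if (cl %in% c("TA", "TVA")) {
          r <- villous_ranges[[cl]]
          c(villous = stats::runif(1, r[1], r[2]), ssa = 0)
        } else {
          r <- ssa_ranges[[cl]]
          c(villous = 0, ssa = stats::runif(1, r[1], r[2]))
        }
      })
      spec <- slide_spec(cl, slide_id = sid, size = slide_size,
                         villous_fraction = fr[["villous"]],
                         ssa_fraction = fr[["ssa"]], ...)
      slide <- generate_slide(spec, seed = slide_seed)
      img_path <- file.path(out_dir, paste0(sid, ".png"))
      if (write_images) write_slide_image(slide$image, img_path)
      manifest[[slide_no]] <- data.frame(
        slide_id = sid, image_path = img_path, microns_per_pixel = 2,
        split = split_vec[i], institution_id = "synthetic",
        stringsAsFactors = FALSE)
      ann[[slide_no]] <- slide$annotations
      # oracle counts: planted cells are windows; remaining windows NORM
      n_windows <- (slide_size %/% spec$cell)^2
      tab <- table(factor(slide$cells$label, levels = patch_classes()))
      tab[["NORM"]] <- tab[["NORM"]] + n_windows - nrow(slide$cells)
      counts[[slide_no]] <- data.frame(slide_id = sid, t(as.integer(tab)),
                                       stringsAsFactors = FALSE)
      truth[[slide_no]] <- data.frame(
        slide_id = sid, label = cl, villous_fraction = fr[["villous"]],
        ssa_fraction = fr[["ssa"]], seed = slide_seed,
        stringsAsFactors = FALSE)
      rm(slide)
    }
  }
  manifest <- do.call(rbind, manifest)
  annotations <- do.call(rbind, ann)
  truth <- do.call(rbind, truth)
  oracle_counts <- do.call(rbind, counts)
  names(oracle_counts) <- c("slide_id", paste0("n_", patch_classes()))
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  write_annotations(annotations, file.path(out_dir, "annotations.json"))
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(oracle_counts, file.path(out_dir, "oracle_counts.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(list(manifest = manifest, annotations = annotations,
                 truth = truth, oracle_counts = oracle_counts,
                 dir = out_dir))
}

#' Annotator panel model
#'
#' Simulated annotators label slides independently; annotator `a` labels
#' a slide of true class `k` by drawing from row `k` of its 4x4
#' row-stochastic confusion matrix.  The default matrix places
#' probability `accuracy` on the true class and spreads the remainder
#' uniformly over the other three classes.  The default accuracy of
#' 0.886 is calibrated so that, for a balanced 4-class cohort, the
#' expected pairwise Cohen kappa of two such annotators is 0.72, the
#' agreement level typical of expert gastrointestinal-pathologist
#' panels on this task.
#'
#' @param accuracy Diagonal probability of the default confusion model.
#' @param n_annotators Panel size.
#' @param confusion Optional list of `n_annotators` 4x4 row-stochastic
#'   matrices (rows/columns in [slide_classes()] order) overriding the
#'   default.
#' @return An object of class `annotator_model`.
#' @export
annotator_model <- function(accuracy = 0.886, n_annotators = 5L,
                            confusion = NULL) {
  if (is.null(confusion)) {
    m <- matrix((1 - accuracy) / 3, 4L, 4L,
                dimnames = list(slide_classes(), slide_classes()))
    diag(m) <- accuracy
    confusion <- rep(list(m), n_annotators)
  }
  if (length(confusion) != n_annotators)
    stopf("need one confusion matrix per annotator")
  for (m in confusion) {
    if (!all(dim(m) == c(4L, 4L))) stopf("confusion matrices must be 4x4")
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8))
      stopf("confusion matrix rows must be nonnegative and sum to 1")
  }
  structure(list(confusion = confusion,
                 n_annotators = as.integer(n_annotators)),
            class = "annotator_model")
}

#' Simulate a multi-annotator label panel
#'
#' Each annotator's label for each slide is drawn independently from the
#' confusion-matrix row of the slide's true class.
#'
#' @param truth Character vector of true slide classes.
#' @param model An [annotator_model()].
#' @param seed Integer seed.
#' @param slide_ids Slide identifiers (default `s1`, `s2`, ...).
#' @return Slide label table (`slide_id`, `annotator_id`, `label`), as
#'   accepted by [read_slide_labels()] and [majority_vote()].
#' @export
simulate_annotator_panel <- function(truth, model = annotator_model(),
                                     seed = 1L,
                                     slide_ids = paste0("s", seq_along(truth))) {
  truth <- match_labels(truth, slide_classes(), "true label")
  ti <- match(truth, slide_classes())
  with_seed(seed, {
    rows <- lapply(seq_len(model$n_annotators), function(a) {
      cm <- model$confusion[[a]]
      lab <- vapply(ti, function(k)
        sample(slide_classes(), 1L, prob = cm[k, ]), character(1))
      data.frame(slide_id = slide_ids, annotator_id = sprintf("A%d", a),
                 label = lab, stringsAsFactors = FALSE)
    })
    validate_slide_labels(do.call(rbind, rows))
  })
}

#' Simulate a counts-level cohort with planted decision thresholds
#'
#' Generates per-slide patch-class counts directly (no images): each
#' slide is adenomatous or serrated with equal probability, its minority
#' fraction (villous or SSA) is drawn uniformly from a range straddling
#' the planted threshold, counts are quantized to `n_patches` polyp
#' patches, and the true label is assigned by the hierarchical rule at
#' the planted thresholds.  With `n_patches = 1000` the fraction
#' resolution (0.001) is much finer than the default calibration grid,
#' so grid search over such a cohort recovers the planted thresholds.
#'
#' @param n_slides Number of slides.
#' @param n_patches Polyp patches per slide (fraction resolution
#'   `1/n_patches`).
#' @param thresholds Planted [threshold_config()].
#' @param villous_range,ssa_range Sampling ranges for the minority
#'   fractions.
#' @param n_norm Normal patches added to every slide's counts.
#' @param seed Integer seed.
#' @return List with `counts` (data frame `slide_id`, `n_TA`, ...,
#'   `n_NORM`) and `labels` (character vector of true classes).
#' @export
simulate_patch_count_cohort <- function(n_slides = 200L, n_patches = 1000L,
                                        thresholds = threshold_config(),
                                        villous_range = c(0, 0.6),
                                        ssa_range = c(0, 0.05),
                                        n_norm = 200L, seed = 1L) {
  with_seed(seed, {
    adeno <- stats::runif(n_slides) < 0.5
    counts <- matrix(0L, n_slides, 5L,
                     dimnames = list(NULL, paste0("n_", patch_classes())))
    for (i in seq_len(n_slides)) {
      if (adeno[i]) {
        f <- stats::runif(1, villous_range[1], villous_range[2])
        counts[i, "n_TVA"] <- as.integer(round(f * n_patches))
        counts[i, "n_TA"] <- n_patches - counts[i, "n_TVA"]
      } else {
        f <- stats::runif(1, ssa_range[1], ssa_range[2])
        counts[i, "n_SSA"] <- as.integer(round(f * n_patches))
        counts[i, "n_HP"] <- n_patches - counts[i, "n_SSA"]
      }
      counts[i, "n_NORM"] <- n_norm
    }
    df <- data.frame(slide_id = sprintf("c%04d", seq_len(n_slides)), counts,
                     stringsAsFactors = FALSE)
    labels <- vapply(seq_len(n_slides), function(i)
      hierarchical_classify(counts[i, ], thresholds), character(1))
    list(counts = df, labels = labels)
  })
}
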