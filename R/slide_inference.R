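#' Tally predicted patch classes for one slide
#'
#' Counts the hard (argmax) labels of a slide's patch predictions.
#' Normal-tissue patches are counted but never enter the branch
#' fractions of the hierarchical rule.
#'
#' @param predictions Prediction data frame (see [read_predictions()]);
#'   all rows must share one `slide_id`.  An empty table yields all-zero
#'   counts.
#' @return An object of class `class_counts`: a named integer vector
#'   `n_TA, n_TVA, n_HP, n_SSA, n_NORM` with a `slide_id` attribute.
#' @export
count_patch_classes <- function(predictions) {
  predictions <- validate_predictions(predictions)
  sid <- unique(predictions$slide_id)
  if (length(sid) > 1L)
    stopf("predictions mix slide_ids: %s", paste(sid, collapse = ", "))
  if (nrow(predictions) == 0L) {
    counts <- stats::setNames(integer(5L), paste0("n_", patch_classes()))
    return(structure(counts, slide_id = NA_character_,
                     class = "class_counts"))
  }
  lab <- hard_labels(as.matrix(predictions[prob_cols()]))
  counts <- table(factor(lab, levels = patch_classes()))
  counts <- stats::setNames(as.integer(counts), paste0("n_", patch_classes()))
  structure(counts, slide_id = sid, class = "class_counts")
}

#' @export
print.class_counts <- function(x, ...) {
  cat("Patch class counts for slide",
      if (is.na(attr(x, "slide_id"))) "<none>" else attr(x, "slide_id"), "\n")
  print(stats::setNames(as.integer(x), names(unclass(x))))
  invisible(x)
}

# accept a class_counts object, a named vector (TA.. or n_TA..), a plain
# length-5 vector in class order, or a one-row data frame
as_count_vector <- function(counts) {
  if (is.data.frame(counts)) counts <- unlist(counts[paste0("n_", patch_classes())])
  counts <- unclass(counts)
  nm <- names(counts)
  want <- patch_classes()
  if (!is.null(nm) && all(paste0("n_", want) %in% nm))
    counts <- counts[paste0("n_", want)]
  else if (!is.null(nm) && all(want %in% nm))
    counts <- counts[want]
  else if (length(counts) != 5L)
    stopf("counts must be a length-5 vector in patch-class order")
  v <- as.numeric(counts)
  if (any(v < 0)) stopf("patch counts must be nonnegative")
  stats::setNames(v, want)
}

#' Hierarchical slide-level diagnosis from patch counts
#'
#' Implements the two-stage heuristic: a slide is first assigned to the
#' adenomatous branch if its adenomatous patch count (`n_TA + n_TVA`) is
#' at least the serrated count (`n_HP + n_SSA`; ties go to the
#' adenomatous branch, the clinically more consequential call), else to
#' the serrated branch.  Within the adenomatous branch, the slide is TVA
#' when its villous fraction strictly exceeds the villous threshold,
#' else TA; within the serrated branch it is SSA when its SSA fraction
#' strictly exceeds the SSA threshold, else HP.  Normal patches are
#' excluded throughout.  A slide with zero polyp patches cannot be
#' diagnosed and raises a "no lesion detected" error.
#'
#' @param counts Patch counts: a [count_patch_classes()] result, a named
#'   vector (`n_TA`... or `TA`...), or a plain length-5 vector in
#'   [patch_classes()] order.
#' @param thresholds A [threshold_config()].
#' @return Slide class, with attributes `villous_fraction`,
#'   `ssa_fraction` and `branch`.
#' @examples
#' hierarchical_classify(c(60, 10, 5, 0, 200))   # villous 10/70 -> TA
#' hierarchical_classify(c(50, 50, 0, 0, 0))     # villous 0.50  -> TVA
#' @export
hierarchical_classify <- function(counts, thresholds = threshold_config()) {
  v <- as_count_vector(counts)
  adeno <- v[["TA"]] + v[["TVA"]]
  serr <- v[["HP"]] + v[["SSA"]]
  if (adeno + serr == 0)
    stopf("no lesion detected: slide has zero polyp patches")
  all_polyp <- adeno + serr
  vf <- if (thresholds$denominator == "branch") {
    if (adeno > 0) v[["TVA"]] / adeno else NA_real_
  } else v[["TVA"]] / all_polyp
  sf <- if (thresholds$denominator == "branch") {
    if (serr > 0) v[["SSA"]] / serr else NA_real_
  } else v[["SSA"]] / all_polyp
  if (adeno >= serr) {
    out <- if (!is.na(vf) && vf > thresholds$villous_threshold) "TVA" else "TA"
    branch <- "adenomatous"
  } else {
    out <- if (!is.na(sf) && sf > thresholds$ssa_threshold) "SSA" else "HP"
    branch <- "serrated"
  }
  structure(out, villous_fraction = vf, ssa_fraction = sf, branch = branch)
}

# strip attributes; vectorised over a counts data frame
classify_counts_table <- function(counts_df, thresholds) {
  vapply(seq_len(nrow(counts_df)), function(i)
    as.character(hierarchical_classify(counts_df[i, ], thresholds)),
    character(1))
}

#' Calibrate the slide-rule thresholds by grid search
#'
#' Evaluates every `(villous, ssa)` grid point against the true slide
#' labels and returns the point maximizing the objective; ties are
#' broken toward the smallest `(villous, ssa)` pair in lexicographic
#' order.  Because each slide's diagnosis depends only on its branch's
#' threshold, the search decomposes by branch and is fast even on fine
#' grids.
#'
#' @param counts Data frame of per-slide counts (`slide_id`, `n_TA`,
#'   ..., `n_NORM`), e.g. rows of [count_patch_classes()] results or the
#'   `oracle_counts` of [generate_cohort()].
#' @param truth Character vector of true slide classes, parallel to
#'   `counts`.
#' @param grid A [grid_spec()].
#' @param denominator Fraction denominator mode, see
#'   [threshold_config()].
#' @return List with `thresholds` (a [threshold_config()] at the best
#'   grid point), `objective` (its objective value) and `surface` (data
#'   frame `villous`, `ssa`, `objective` over the full grid).
#' @export
calibrate_thresholds <- function(counts, truth, grid = grid_spec(),
                                 denominator = "branch") {
  if (nrow(counts) != length(truth))
    stopf("counts and truth differ in length")
  if (nrow(counts) == 0L) stopf("calibration requires at least one slide")
  truth <- match_labels(truth, slide_classes(), "true label")
  # slides without any polyp patch carry no threshold information
  polyp <- rowSums(counts[paste0("n_", slide_classes())]) > 0
  if (!all(polyp)) {
    counts <- counts[polyp, , drop = FALSE]
    truth <- truth[polyp]
    if (nrow(counts) == 0L)
      stopf("calibration requires at least one slide with polyp patches")
  }
  # per-slide branch and within-branch fraction (thresholds do not move
  # slides between branches, so these are computed once)
  base <- threshold_config(denominator = denominator)
  info <- lapply(seq_len(nrow(counts)), function(i) {
    d <- hierarchical_classify(counts[i, ], base)
    list(branch = attr(d, "branch"),
         vf = attr(d, "villous_fraction"), sf = attr(d, "ssa_fraction"))
  })
  branch <- vapply(info, `[[`, character(1), "branch")
  vf <- vapply(info, `[[`, numeric(1), "vf")
  sf <- vapply(info, `[[`, numeric(1), "sf")
  is_a <- branch == "adenomatous"

  objective_value <- function(pred) {
    if (grid$objective == "overall_accuracy") return(mean(pred == truth))
    accs <- vapply(slide_classes(), function(cl)
      mean((pred == cl) == (truth == cl)), numeric(1))
    mean(accs)
  }
  surface <- expand.grid(villous = grid$villous_grid, ssa = grid$ssa_grid,
                         KEEP.OUT.ATTRS = FALSE)
  pred <- character(length(truth))
  obj <- numeric(nrow(surface))
  for (j in seq_len(nrow(surface))) {
    pred[is_a] <- ifelse(!is.na(vf[is_a]) & vf[is_a] > surface$villous[j],
                         "TVA", "TA")
    pred[!is_a] <- ifelse(!is.na(sf[!is_a]) & sf[!is_a] > surface$ssa[j],
                          "SSA", "HP")
    obj[j] <- objective_value(pred)
  }
  surface$objective <- obj
  # maximize; ties -> smallest (villous, ssa) lexicographically
  ord <- order(-surface$objective, surface$villous, surface$ssa)
  best <- surface[ord[1L], ]
  list(thresholds = threshold_config(best$villous, best$ssa,
                                     denominator = denominator),
       objective = best$objective, surface = surface)
}

#' Whole-slide inference
#'
#' Runs the full slide pipeline: sliding-window enumeration over the
#' whole slide, patch classification, patch-vote counting, and the
#' hierarchical diagnosis rule.
#'
#' @param model A `patch_cnn` or `patch_ensemble`.
#' @param image Slide raster, or a path to a PNG/TIFF slide image.
#' @param spec A [patch_spec()]; the patch size must match the model's.
#' @param thresholds A [threshold_config()].
#' @param slide_id Identifier used in the prediction table.
#' @return List with `diagnosis` (slide class, with fraction
#'   attributes), `counts` and `predictions`.
#' @export
infer_slide <- function(model, image, spec = patch_spec(),
                        thresholds = threshold_config(),
                        slide_id = "slide-1") {
  preds <- slide_patch_predictions(model, image, spec, slide_id)
  counts <- count_patch_classes(preds)
  diagnosis <- hierarchical_classify(counts, thresholds)
  list(diagnosis = diagnosis, counts = counts, predictions = preds)
}

#' Patch predictions over a whole slide
#'
#' Enumerates the sliding-window grid over the full slide and classifies
#' every patch; the first two stages of [infer_slide()].
#'
#' @inheritParams infer_slide
#' @return Prediction data frame (see [read_predictions()]).
#' @export
slide_patch_predictions <- function(model, image, spec = patch_spec(),
                                    slide_id = "slide-1") {
  if (is.character(image)) image <- read_slide_image(image)
  if (spec$extraction_downsample > 1L)
    image <- downsample_image(image, spec$extraction_downsample)
  if (spec$patch_size != model$patch_size)
    stopf("patch spec size %d does not match the model's %d",
          spec$patch_size, model$patch_size)
  d <- dim(image)
  origins <- sliding_window(c(0, 0, d[2L], d[1L]), spec)
  patches <- lapply(seq_len(nrow(origins)), function(i)
    extract_patch(image, origins$x[i], origins$y[i], spec$patch_size))
  probs <- predict_probs(model, patches)
  prediction_table(slide_id, origins, probs, spec$patch_size)
}

#' Per-slide diagnosis table
#'
#' Applies the hierarchical rule to a counts table and returns the
#' diagnosis CSV layout: slide id, diagnosis, the five patch counts and
#' the two branch fractions.
#'
#' A slide whose counts contain no polyp patches (for which
#' [hierarchical_classify()] raises its "no lesion detected" error) is
#' recorded with diagnosis `"none"` and missing fractions, so one blank
#' slide does not abort a cohort run; a `"none"` diagnosis is wrong
#' against every slide-level truth label in evaluation.
#'
#' @param counts Data frame of per-slide counts (see
#'   [calibrate_thresholds()]).
#' @param thresholds A [threshold_config()].
#' @return Data frame with one row per slide.
#' @export
diagnose_slides <- function(counts, thresholds = threshold_config()) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    d <- tryCatch(hierarchical_classify(counts[i, ], thresholds),
                  error = function(e) {
                    if (!grepl("no lesion", conditionMessage(e))) stop(e)
                    structure("none", villous_fraction = NA_real_,
                              ssa_fraction = NA_real_)
                  })
    data.frame(slide_id = counts$slide_id[i], diagnosis = as.character(d),
               counts[i, paste0("n_", patch_classes())],
               villous_fraction = attr(d, "villous_fraction"),
               ssa_fraction = attr(d, "ssa_fraction"),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Read and write threshold configuration files
#'
#' Thresholds are exchanged as JSON:
#' `{"villous_threshold": 0.30, "ssa_threshold": 0.015,
#' "denominator": "branch"}`.
#'
#' @param path JSON path.
#' @return `read_thresholds()` returns a [threshold_config()].
#' @export
read_thresholds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  threshold_config(x$villous_threshold, x$ssa_threshold,
                   denominator = x$denominator %||% "branch")
}

#' @rdname read_thresholds
#' @param thresholds A [threshold_config()].
#' @export
write_thresholds <- function(thresholds, path) {
  jsonlite::write_json(unclass(thresholds), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
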