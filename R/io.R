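#' Read and write slide manifests
#'
#' A manifest is a CSV with one row per slide and columns `slide_id`,
#' `image_path`, `microns_per_pixel`, `split`, `institution_id`.
#' `slide_id` must be unique, `microns_per_pixel` positive, and `split`
#' one of `train`, `validation`, `test_internal`, `test_external`.
#'
#' @param path Path to a manifest CSV.
#' @return `read_manifest()` returns a data frame of slide records;
#'   `write_manifest()` writes one and invisibly returns `path`.
#' @examples
#' m <- data.frame(slide_id = c("s1", "s2"), image_path = c("a.png", "b.png"),
#'                 microns_per_pixel = 2, split = "train", institution_id = "I0")
#' f <- tempfile(fileext = ".csv")
#' write_manifest(m, f)
#' read_manifest(f)
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(df)
}

#' @rdname read_manifest
#' @param manifest Data frame of slide records.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_manifest <- function(df) {
  required <- c("slide_id", "image_path", "microns_per_pixel", "split",
                "institution_id")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stopf("manifest is missing column '%s'", missing[[1L]])
  df$slide_id <- as.character(df$slide_id)
  dup <- df$slide_id[duplicated(df$slide_id)]
  if (length(dup) > 0)
    stopf("duplicate slide_id in manifest: '%s'", dup[[1L]])
  if (any(!is.finite(df$microns_per_pixel) | df$microns_per_pixel <= 0))
    stopf("microns_per_pixel must be positive")
  df$split <- match_labels(df$split,
                           c("train", "validation", "test_internal",
                             "test_external"), "split")
  df[required]
}

#' Read and write bounding-box ROI annotations
#'
#' Annotations are stored as a JSON array of objects
#' `{"slide_id": ..., "box": [x0, y0, x1, y1], "label": ...,
#' "annotator_id": ...}` (a minimal RectLabel-style schema).  Boxes are
#' 0-based, half-open pixel rectangles with `x1 > x0`, `y1 > y0`; labels
#' must be one of the five patch classes.
#'
#' @param path Path to an annotation JSON file.
#' @return `read_annotations()` returns a data frame with columns
#'   `slide_id`, `x0`, `y0`, `x1`, `y1`, `label`, `annotator_id`.
#' @export
read_annotations <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(raw) == 0L) return(empty_annotations())
  rows <- lapply(raw, function(a) {
    box <- unlist(a$box)
    if (length(box) != 4L) stopf("annotation box must have 4 coordinates")
    data.frame(slide_id = as.character(a$slide_id),
               x0 = as.integer(box[[1L]]), y0 = as.integer(box[[2L]]),
               x1 = as.integer(box[[3L]]), y1 = as.integer(box[[4L]]),
               label = as.character(a$label),
               annotator_id = as.character(
                 if (is.null(a$annotator_id)) NA else a$annotator_id),
               stringsAsFactors = FALSE)
  })
  validate_annotations(do.call(rbind, rows))
}

#' @rdname read_annotations
#' @param annotations Data frame of annotations (see above).
#' @export
write_annotations <- function(annotations, path) {
  annotations <- validate_annotations(annotations)
  objs <- lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    list(slide_id = a$slide_id,
         box = c(a$x0, a$y0, a$x1, a$y1),
         label = a$label, annotator_id = a$annotator_id)
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

empty_annotations <- function() {
  data.frame(slide_id = character(), x0 = integer(), y0 = integer(),
             x1 = integer(), y1 = integer(), label = character(),
             annotator_id = character(), stringsAsFactors = FALSE)
}

validate_annotations <- function(df) {
  required <- c("slide_id", "x0", "y0", "x1", "y1", "label", "annotator_id")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stopf("annotations are missing column '%s'", missing[[1L]])
  df$label <- match_labels(df$label, patch_classes(), "annotation label")
  bad <- df$x1 <= df$x0 | df$y1 <= df$y0
  if (any(bad))
    stopf("degenerate annotation box for slide '%s': [%d,%d,%d,%d]",
          df$slide_id[bad][[1L]], df$x0[bad][[1L]], df$y0[bad][[1L]],
          df$x1[bad][[1L]], df$y1[bad][[1L]])
  if (any(df$x0 < 0 | df$y0 < 0)) stopf("annotation box origin must be >= 0")
  df[required]
}

#' Read and write patch prediction tables
#'
#' Predictions are stored as a CSV with columns `slide_id`, `x`, `y`,
#' `size` (the patch origin and side, in pixels) and one probability
#' column per patch class: `p_TA`, `p_TVA`, `p_HP`, `p_SSA`, `p_NORM`.
#' Each probability row must sum to 1 within 1e-6; probabilities are
#' written with enough significant digits to round-trip at that
#' tolerance.
#'
#' @param path Path to a predictions CSV.
#' @return `read_predictions()` returns the prediction data frame.
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_predictions(df)
}

#' @rdname read_predictions
#' @param predictions Data frame of patch predictions (see above).
#' @export
write_predictions <- function(predictions, path) {
  predictions <- validate_predictions(predictions)
  out <- predictions
  for (cl in prob_cols()) out[[cl]] <- sprintf("%.8g", predictions[[cl]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

prob_cols <- function() paste0("p_", patch_classes())

validate_predictions <- function(df) {
  required <- c("slide_id", "x", "y", "size", prob_cols())
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stopf("predictions are missing column '%s'", missing[[1L]])
  df$slide_id <- as.character(df$slide_id)
  p <- as.matrix(df[prob_cols()])
  if (nrow(df) > 0) {
    if (any(p < -1e-9)) stopf("probabilities must be nonnegative")
    s <- rowSums(p)
    off <- which(abs(s - 1) > 1e-6)
    if (length(off) > 0)
      stopf("probability row %d sums to %.8f, not 1", off[[1L]], s[[off[[1L]]]])
  }
  df[required]
}

#' Build a prediction table from a probability matrix
#'
#' @param slide_id Slide identifier (recycled).
#' @param origins Data frame with columns `x`, `y` (patch origins).
#' @param probs `n x 5` probability matrix in patch-class order.
#' @param size Patch side in pixels.
#' @return A prediction data frame as accepted by [write_predictions()].
#' @export
prediction_table <- function(slide_id, origins, probs, size) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 5L) stopf("probs must have 5 columns")
  df <- data.frame(slide_id = rep_len(as.character(slide_id), nrow(probs)),
                   x = origins$x, y = origins$y,
                   size = rep_len(as.integer(size), nrow(probs)),
                   stringsAsFactors = FALSE)
  colnames(probs) <- prob_cols()
  validate_predictions(cbind(df, as.data.frame(probs)))
}

#' Read and write slide label tables
#'
#' A slide label table records one diagnosis per (slide, annotator) pair
#' as a CSV with columns `slide_id`, `annotator_id`, `label`; labels are
#' restricted to the four slide-level polyp classes.
#'
#' @param path Path to a label CSV.
#' @return `read_slide_labels()` returns the label data frame.
#' @export
read_slide_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_slide_labels(df)
}

#' @rdname read_slide_labels
#' @param labels Data frame of slide labels.
#' @export
write_slide_labels <- function(labels, path) {
  labels <- validate_slide_labels(labels)
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_slide_labels <- function(df) {
  required <- c("slide_id", "annotator_id", "label")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stopf("slide labels are missing column '%s'", missing[[1L]])
  df$slide_id <- as.character(df$slide_id)
  df$annotator_id <- as.character(df$annotator_id)
  df$label <- match_labels(df$label, slide_classes(), "slide label")
  key <- paste(df$slide_id, df$annotator_id)
  dup <- key[duplicated(key)]
  if (length(dup) > 0)
    stopf("duplicate (slide_id, annotator_id) pair: %s", dup[[1L]])
  df[required]
}

#' Read and write slide images
#'
#' Slide rasters are exchanged as PNG or plain (non-pyramidal) TIFF.  In
#' memory an image is a numeric array `[row, column, channel]` with
#' values in `[0, 1]`; grayscale files are expanded to 3 channels and an
#' alpha channel, if present, is dropped.
#'
#' @param path Image path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @return `read_slide_image()` returns an `h x w x 3` array.
#' @export
read_slide_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stopf("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stopf("unsupported image format '.%s' (use PNG or TIFF)", ext))
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3L] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname read_slide_image
#' @param image `h x w x 3` numeric array in `[0, 1]`.
#' @export
write_slide_image <- function(image, path) {
  image[image < 0] <- 0
  image[image > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stopf("writing TIFF requires the 'tiff' package")
      tiff::writeTIFF(image, path)
    },
    stopf("unsupported image format '.%s' (use PNG or TIFF)", ext))
  invisible(path)
}
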