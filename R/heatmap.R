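#' Render a class-confidence heatmap over a slide
#'
#' Tints each predicted patch region with its argmax class colour at an
#' opacity that increases linearly with the prediction confidence (the
#' maximum class probability), so higher-confidence predictions appear
#' darker.  Pixels outside any predicted patch are returned unchanged;
#' with an empty prediction table the output is bit-identical to the
#' input.
#'
#' @param image Slide raster (`h x w x 3` array).
#' @param predictions Prediction data frame (see [read_predictions()]);
#'   every patch box must lie within the image.
#' @param style An [overlay_style()].
#' @return Tinted `h x w x 3` array.
#' @export
render_heatmap <- function(image, predictions, style = overlay_style()) {
  predictions <- validate_predictions(predictions)
  d <- dim(image)
  out <- image
  if (nrow(predictions) == 0L) return(out)
  probs <- as.matrix(predictions[prob_cols()])
  labels <- hard_labels(probs)
  conf <- apply(probs, 1L, max)
  alpha <- pmin(1, pmax(0, style$alpha_base + style$alpha_gain * conf))
  for (i in seq_len(nrow(predictions))) {
    x <- predictions$x[i]; y <- predictions$y[i]; s <- predictions$size[i]
    if (x < 0 || y < 0 || x + s > d[2L] || y + s > d[1L])
      stopf("patch [%d,%d,%d,%d) outside the %dx%d image",
            x, y, x + s, y + s, d[2L], d[1L])
    col <- style$colors[[labels[i]]]
    rows <- (y + 1):(y + s); cols <- (x + 1):(x + s)
    for (ch in 1:3)
      out[rows, cols, ch] <- (1 - alpha[i]) * out[rows, cols, ch] +
        alpha[i] * col[ch]
  }
  out
}

#' Render a binary lesion highlight
#'
#' Highlights every patch whose argmax class belongs to the style's
#' highlight set (by default the four polyp classes, i.e. precancerous
#' or lesional tissue); normal-tissue patches and pixels outside any
#' patch are left untouched.
#'
#' @inheritParams render_heatmap
#' @return Highlighted `h x w x 3` array.
#' @export
render_lesion_mask <- function(image, predictions, style = overlay_style()) {
  predictions <- validate_predictions(predictions)
  d <- dim(image)
  out <- image
  if (nrow(predictions) == 0L) return(out)
  labels <- hard_labels(as.matrix(predictions[prob_cols()]))
  alpha <- 0.5
  for (i in seq_len(nrow(predictions))) {
    if (!(labels[i] %in% style$highlight_classes)) next
    x <- predictions$x[i]; y <- predictions$y[i]; s <- predictions$size[i]
    if (x < 0 || y < 0 || x + s > d[2L] || y + s > d[1L])
      stopf("patch [%d,%d,%d,%d) outside the %dx%d image",
            x, y, x + s, y + s, d[2L], d[1L])
    rows <- (y + 1):(y + s); cols <- (x + 1):(x + s)
    for (ch in 1:3)
      out[rows, cols, ch] <- (1 - alpha) * out[rows, cols, ch] +
        alpha * style$highlight_color[ch]
  }
  out
}
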