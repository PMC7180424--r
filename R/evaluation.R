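#' Majority-vote ground truth from an annotator panel
#'
#' Assigns each slide the strict plurality label of its panel.  When two
#' or more classes tie for the plurality, the tie is resolved by the
#' designated reference annotator's label if it is among the tied
#' classes (otherwise the tied class earliest in [slide_classes()]
#' order), and the slide is flagged.
#'
#' @param panel Slide label table (`slide_id`, `annotator_id`, `label`);
#'   every slide must be labeled by every annotator.
#' @param reference Annotator id whose vote resolves ties (default: the
#'   first annotator in sorted order).
#' @return Data frame with columns `slide_id`, `label`, `tie`.
#' @export
majority_vote <- function(panel, reference = NULL) {
  panel <- validate_slide_labels(panel)
  annotators <- sort(unique(panel$annotator_id))
  if (is.null(reference)) reference <- annotators[[1L]]
  slides <- unique(panel$slide_id)
  rows <- lapply(slides, function(sid) {
    sub <- panel[panel$slide_id == sid, ]
    missing <- setdiff(annotators, sub$annotator_id)
    if (length(missing) > 0)
      stopf("slide '%s' is missing a label from annotator '%s'",
            sid, missing[[1L]])
    tab <- table(factor(sub$label, levels = slide_classes()))
    top <- names(tab)[tab == max(tab)]
    tie <- length(top) > 1L
    label <- if (!tie) top else {
      ref_label <- sub$label[sub$annotator_id == reference]
      if (length(ref_label) == 1L && ref_label %in% top) ref_label
      else top[[1L]]
    }
    data.frame(slide_id = sid, label = label, tie = tie,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-vs-rest metrics for a single class
#'
#' Treats `class` as positive and all other labels as negative:
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/n`.  A metric whose denominator is empty (class absent from
#' the truth, or no negatives) is reported as `NA`, not 0.
#'
#' @param predicted,truth Equal-length label vectors.
#' @param class The positive class.
#' @param percent Report metrics on the 0-100 scale (default) rather
#'   than as proportions.
#' @return Named numeric vector `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
per_class_metrics <- function(predicted, truth, class, percent = TRUE) {
  if (length(predicted) != length(truth))
    stopf("predicted and truth differ in length")
  pos_t <- truth == class
  pos_p <- predicted == class
  tp <- sum(pos_t & pos_p); fn <- sum(pos_t & !pos_p)
  fp <- sum(!pos_t & pos_p); tn <- sum(!pos_t & !pos_p)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / length(truth)
  out <- c(accuracy = acc, sensitivity = sens, specificity = spec)
  if (percent) out * 100 else out
}

#' Unweighted mean of per-class metric values
#'
#' The mean row of the evaluation report is the unweighted arithmetic
#' mean of the four per-class values; it is computed before any
#' rounding, and reported missing if any class value is missing.
#'
#' @param values Numeric vector of the four per-class values.
#' @return The mean, or `NA` if any input is missing.
#' @examples
#' mean_metrics(c(93.0, 95.5, 92.4, 93.0))  # 93.475, printed as 93.5
#' @export
mean_metrics <- function(values) {
  if (length(values) != 4L)
    stopf("mean_metrics expects the four per-class values")
  if (any(is.na(values))) return(NA_real_)
  mean(values)
}

#' Round half away from zero
#'
#' The rounding used for all reported percentages (base `round()` uses
#' round-half-even, which disagrees with how diagnostic tables are
#' conventionally printed).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @examples
#' round_half_up(93.45, 1)  # 93.5
#' @export
round_half_up <- function(x, digits = 1L) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Wald binomial confidence interval
#'
#' Normal-approximation interval `p +/- z * sqrt(p(1-p)/n)`, reported in
#' percent and clipped to `[0, 100]`.
#'
#' @param p Proportion in `[0, 1]`.
#' @param n Sample size (>= 1).
#' @param z Normal quantile (1.96 for 95% coverage).
#' @return Named vector `lo`, `hi` in percent.
#' @examples
#' wald_ci(0.935, 157)  # about (89.6, 97.4)
#' @export
wald_ci <- function(p, n, z = 1.96) {
  if (n < 1) stopf("n must be >= 1")
  if (p < 0 || p > 1) stopf("p must lie in [0, 1]")
  half <- z * sqrt(p * (1 - p) / n)
  c(lo = max(0, (p - half)) * 100, hi = min(1, (p + half)) * 100)
}

#' Multiclass Cohen kappa
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` over the
#' four slide classes, with expected agreement `p_e` from the product of
#' the two raters' marginal label distributions.  When both raters are
#' constant and identical (`p_e = 1` with perfect observed agreement)
#' kappa is defined as 1.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @param classes Label vocabulary.
#' @return Kappa in `[-1, 1]`.
#' @export
multiclass_kappa <- function(labels_a, labels_b, classes = slide_classes()) {
  if (length(labels_a) != length(labels_b))
    stopf("label vectors differ in length")
  n <- length(labels_a)
  if (n == 0L) stopf("kappa requires at least one rating")
  a <- factor(labels_a, levels = classes)
  b <- factor(labels_b, levels = classes)
  tab <- table(a, b) / n
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (abs(1 - p_e) < 1e-12) return(if (p_o >= 1 - 1e-12) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' Mean pairwise kappa of an annotator panel
#'
#' Computes [multiclass_kappa()] for every pair of annotators and
#' summarizes the panel as the mean pairwise kappa with a
#' normal-approximation 95% interval on the mean.
#'
#' @param panel Slide label table (`slide_id`, `annotator_id`,
#'   `label`); every slide must be labeled by every annotator.
#' @param z Normal quantile for the interval.
#' @return An object of class `kappa_result`: list with `pairs` (data
#'   frame `annotator_a`, `annotator_b`, `kappa`), `mean_kappa` and
#'   `ci` (`lo`, `hi`).
#' @export
mean_pairwise_kappa <- function(panel, z = 1.96) {
  panel <- validate_slide_labels(panel)
  annotators <- sort(unique(panel$annotator_id))
  if (length(annotators) < 2L) stopf("need at least two annotators")
  slides <- unique(panel$slide_id)
  wide <- matrix(NA_character_, length(slides), length(annotators),
                 dimnames = list(slides, annotators))
  wide[cbind(match(panel$slide_id, slides),
             match(panel$annotator_id, annotators))] <- panel$label
  if (any(is.na(wide))) {
    miss <- which(is.na(wide), arr.ind = TRUE)[1L, ]
    stopf("slide '%s' is missing a label from annotator '%s'",
          slides[miss[1L]], annotators[miss[2L]])
  }
  pairs <- utils::combn(annotators, 2L)
  ks <- apply(pairs, 2L, function(p)
    multiclass_kappa(wide[, p[1L]], wide[, p[2L]]))
  m <- mean(ks)
  se <- if (length(ks) > 1L) stats::sd(ks) / sqrt(length(ks)) else 0
  structure(list(pairs = data.frame(annotator_a = pairs[1L, ],
                                    annotator_b = pairs[2L, ], kappa = ks,
                                    stringsAsFactors = FALSE),
                 mean_kappa = m,
                 ci = c(lo = m - z * se, hi = m + z * se)),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Mean pairwise multiclass Cohen kappa: %.2f (95%% CI, %.2f-%.2f) over %d pairs\n",
              x$mean_kappa, x$ci[["lo"]], x$ci[["hi"]], nrow(x$pairs)))
  invisible(x)
}

#' Two-proportion z-test
#'
#' Large-sample test comparing two proportions.  The pooled form (the
#' standard "t test for proportions") uses
#' `z = (p1 - p2) / sqrt(phat (1 - phat) (1/n1 + 1/n2))` with `phat` the
#' pooled proportion; the two-sided p-value comes from the normal
#' distribution.  When the pooled proportion is degenerate (0 or 1) the
#' proportions are necessarily equal and `p = 1`.
#'
#' @param p1,p2 Proportions in `[0, 1]`.
#' @param n1,n2 Sample sizes (>= 1).
#' @param pooled Use the pooled variance estimate (default); otherwise
#'   the unpooled Wald variant.
#' @return List with `z` and `p_value`.
#' @examples
#' two_proportion_test(0.866, 238, 0.870, 238)$p_value  # about 0.90
#' @export
two_proportion_test <- function(p1, n1, p2, n2, pooled = TRUE) {
  if (min(n1, n2) < 1) stopf("sample sizes must be >= 1")
  if (min(p1, p2) < 0 || max(p1, p2) > 1) stopf("proportions must lie in [0, 1]")
  if (pooled) {
    phat <- (p1 * n1 + p2 * n2) / (n1 + n2)
    v <- phat * (1 - phat) * (1 / n1 + 1 / n2)
  } else {
    v <- p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2
  }
  if (v <= 0) {
    z <- if (p1 == p2) 0 else sign(p1 - p2) * Inf
  } else {
    z <- (p1 - p2) / sqrt(v)
  }
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Confusion matrix with row-normalized agreement ratios
#'
#' Counts are indexed `(truth row, predicted column)`; the ratio view
#' divides each row by its sum, so each cell is the agreement ratio
#' between the ground-truth class and the predicted class.
#'
#' @param predicted,truth Equal-length, nonempty label vectors.
#' @param classes Label vocabulary.
#' @return An object of class `polyp_confusion`: list with `counts` and
#'   `ratio` matrices.
#' @export
confusion_matrix <- function(predicted, truth, classes = slide_classes()) {
  if (length(truth) == 0L) stopf("confusion matrix requires observations")
  if (length(predicted) != length(truth))
    stopf("predicted and truth differ in length")
  counts <- table(truth = factor(truth, levels = classes),
                  predicted = factor(predicted, levels = classes))
  counts <- unclass(counts)
  rs <- rowSums(counts)
  ratio <- counts / ifelse(rs == 0, 1, rs)
  structure(list(counts = counts, ratio = ratio), class = "polyp_confusion")
}

#' @export
print.polyp_confusion <- function(x, digits = 3, ...) {
  cat("Confusion matrix (rows = ground truth, columns = predicted)\n")
  cat("Counts:\n"); print(x$counts)
  cat("Agreement ratios:\n"); print(round(x$ratio, digits))
  invisible(x)
}

#' Full evaluation report
#'
#' The per-class and mean diagnostic metrics in the layout of a
#' per-class comparison table: one row per polyp class with one-vs-rest
#' accuracy, sensitivity and specificity (percent), a mean row that is
#' the unweighted mean of the four per-class values, and Wald 95%
#' intervals for the mean row treating each mean percentage as a
#' binomial proportion over the `n` evaluated slides.
#'
#' @param predicted,truth Equal-length slide label vectors.
#' @return An object of class `polyp_eval`: list with `table` (data
#'   frame of unrounded per-class + Mean rows), `ci` (data frame of
#'   `lo`/`hi` per mean metric), `confusion` (a [confusion_matrix()])
#'   and `n`.
#' @export
eval_report <- function(predicted, truth) {
  n <- length(truth)
  per <- t(vapply(slide_classes(), function(cl)
    per_class_metrics(predicted, truth, cl), numeric(3)))
  means <- apply(per, 2L, function(col) mean_metrics(col))
  tab <- data.frame(class = c(slide_classes(), "Mean"),
                    rbind(per, Mean = means), row.names = NULL)
  ci <- t(vapply(names(means), function(m) {
    if (is.na(means[[m]])) c(lo = NA_real_, hi = NA_real_)
    else wald_ci(means[[m]] / 100, n)
  }, numeric(2)))
  structure(list(table = tab,
                 ci = data.frame(metric = rownames(ci), ci, row.names = NULL),
                 confusion = confusion_matrix(predicted, truth), n = n),
            class = "polyp_eval")
}

#' @export
print.polyp_eval <- function(x, ...) {
  cat("Slide-level evaluation on", x$n, "slides\n\n")
  tab <- x$table
  for (m in c("accuracy", "sensitivity", "specificity"))
    tab[[m]] <- round_half_up(tab[[m]], 1)
  print(tab, row.names = FALSE)
  m <- x$table[x$table$class == "Mean", ]
  ci <- x$ci
  cat(sprintf("\nMean accuracy %.1f%% (95%% CI, %.1f%%-%.1f%%)\n",
              round_half_up(m$accuracy, 1),
              round_half_up(ci$lo[ci$metric == "accuracy"], 1),
              round_half_up(ci$hi[ci$metric == "accuracy"], 1)))
  invisible(x)
}

#' Write an evaluation report
#'
#' Writes the rounded per-class table as CSV (mirroring the printed
#' table layout) and the unrounded values, intervals and confusion
#' matrix as JSON.
#'
#' @param report A [eval_report()].
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_eval_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    tab <- report$table
    for (m in c("accuracy", "sensitivity", "specificity"))
      tab[[m]] <- round_half_up(tab[[m]], 1)
    utils::write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(table = report$table, ci = report$ci, n = report$n,
           confusion_counts = as.data.frame(report$confusion$counts),
           confusion_ratio = as.data.frame(report$confusion$ratio)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
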