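panel_df <- function(labels_by_annotator, slide_ids = NULL) {
  n <- length(labels_by_annotator[[1]])
  if (is.null(slide_ids)) slide_ids <- paste0("s", seq_len(n))
  do.call(rbind, lapply(names(labels_by_annotator), function(a)
    data.frame(slide_id = slide_ids, annotator_id = a,
               label = labels_by_annotator[[a]], stringsAsFactors = FALSE)))
}

test_that("majority vote takes the plurality and flags resolved ties", {
  p <- panel_df(list(A1 = "TA", A2 = "TA", A3 = "TA", A4 = "HP",
                     A5 = "SSA"))
  mv <- majority_vote(p)
  expect_equal(mv$label, "TA")
  expect_false(mv$tie)

  # 2-2-1 tie resolved by the reference annotator (A1 by default)
  p2 <- panel_df(list(A1 = "HP", A2 = "TA", A3 = "TA", A4 = "HP",
                      A5 = "SSA"))
  mv2 <- majority_vote(p2)
  expect_equal(mv2$label, "HP")
  expect_true(mv2$tie)
  # a different reference annotator can flip the resolution
  mv2b <- majority_vote(p2, reference = "A2")
  expect_equal(mv2b$label, "TA")

  # unanimous panels equal any annotator's column
  p3 <- panel_df(list(A1 = c("TVA", "SSA"), A2 = c("TVA", "SSA"),
                      A3 = c("TVA", "SSA"), A4 = c("TVA", "SSA"),
                      A5 = c("TVA", "SSA")))
  expect_equal(majority_vote(p3)$label, c("TVA", "SSA"))

  p4 <- p3[p3$annotator_id != "A5" | p3$slide_id != "s1", ]
  expect_error(majority_vote(p4), "missing a label.*A5")
})

test_that("one-vs-rest metrics match hand counts and degenerate rules", {
  perfect <- per_class_metrics(c("TA", "HP"), c("TA", "HP"), "TA")
  expect_equal(unname(perfect), c(100, 100, 100))

  m <- per_class_metrics(c("TA", "HP", "HP", "HP"),
                         c("TA", "TA", "HP", "HP"), "TA")
  expect_equal(m[["accuracy"]], 75)
  expect_equal(m[["sensitivity"]], 50)
  expect_equal(m[["specificity"]], 100)

  # class absent from truth: sensitivity undefined, not zero
  absent <- per_class_metrics(c("TA", "TA"), c("TA", "TA"), "SSA")
  expect_true(is.na(absent[["sensitivity"]]))
  # no negatives: specificity undefined
  allpos <- per_class_metrics(c("TA", "TA"), c("TA", "TA"), "TA")
  expect_true(is.na(allpos[["specificity"]]))
})

test_that("one-vs-rest metrics agree with a brute-force 2x2 oracle", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    truth <- sample(slide_classes(), n, replace = TRUE)
    pred <- sample(slide_classes(), n, replace = TRUE)
    for (cl in slide_classes()) {
      got <- per_class_metrics(pred, truth, cl)
      want <- brute_force_ovr(pred, truth, cl)
      expect_equal(got, want)
    }
  }
})

test_that("mean metrics reproduce the printed per-class table means", {
  expect_equal(round_half_up(mean_metrics(c(93.0, 95.5, 92.4, 93.0)), 1),
               93.5)
  expect_equal(round_half_up(mean_metrics(c(84.5, 89.5, 85.3, 88.7)), 1),
               87.0)
  expect_equal(mean_metrics(c(91, 91, 91, 91)), 91)
  expect_true(is.na(mean_metrics(c(91, NA, 91, 91))))
  expect_error(mean_metrics(c(1, 2, 3)), "four per-class")
})

test_that("Wald intervals reproduce the published mean-accuracy intervals", {
  ci1 <- wald_ci(0.935, 157)
  expect_equal(round_half_up(ci1[["lo"]], 1), 89.6)
  expect_equal(round_half_up(ci1[["hi"]], 1), 97.4)
  ci2 <- wald_ci(0.870, 238)
  expect_equal(round_half_up(ci2[["lo"]], 1), 82.7)
  expect_equal(round_half_up(ci2[["hi"]], 1), 91.3)
  # degenerate proportions give a zero-width interval at the boundary
  expect_equal(unname(wald_ci(0, 50)), c(0, 0))
  expect_equal(unname(wald_ci(1, 50)), c(100, 100))
  expect_error(wald_ci(0.5, 0), "n must be")
})

test_that("multiclass kappa matches hand computations and an oracle", {
  expect_equal(multiclass_kappa(c("TA", "HP", "SSA"), c("TA", "HP", "SSA")),
               1)
  # hand example: p_o = 0.5, p_e = 0.5 -> kappa = 0
  expect_equal(multiclass_kappa(c("TA", "TA", "HP", "HP"),
                                c("TA", "HP", "TA", "HP")), 0)
  # constant identical raters: defined as 1
  expect_equal(multiclass_kappa(rep("TA", 5), rep("TA", 5)), 1)

  # independent oracle on random vectors
  skip_if_not_installed("e1071")
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(10:80, 1)
    a <- sample(slide_classes(), n, replace = TRUE)
    b <- sample(slide_classes(), n, replace = TRUE)
    tab <- table(factor(a, levels = slide_classes()),
                 factor(b, levels = slide_classes()))
    expect_equal(multiclass_kappa(a, b),
                 e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  }
})

test_that("binary-collapsed multiclass kappa equals classical 2-class kappa", {
  set.seed(12)
  a <- sample(c("TA", "HP"), 60, replace = TRUE)
  b <- sample(c("TA", "HP"), 60, replace = TRUE)
  two_class <- function(x, y) {
    p_o <- mean(x == y)
    p_yes <- mean(x == "TA") * mean(y == "TA")
    p_no <- mean(x == "HP") * mean(y == "HP")
    (p_o - (p_yes + p_no)) / (1 - (p_yes + p_no))
  }
  expect_equal(multiclass_kappa(a, b), two_class(a, b))
})

test_that("panel kappa recovers the analytic value of its annotator model", {
  # uniform-error model with diagonal a over a balanced 4-class truth:
  # p_o = a^2 + (1-a)^2/3, p_e = 1/4, kappa = (p_o - 1/4)/(3/4)
  a <- 0.9
  truth <- rep(slide_classes(), each = 500)
  panel <- simulate_annotator_panel(truth, annotator_model(accuracy = a),
                                    seed = 13)
  expected <- ((a^2 + (1 - a)^2 / 3) - 0.25) / 0.75
  got <- mean_pairwise_kappa(panel)
  expect_equal(got$mean_kappa, expected, tolerance = 0.03)
  expect_equal(nrow(got$pairs), 10L)
  expect_true(got$ci[["lo"]] <= got$mean_kappa &&
              got$mean_kappa <= got$ci[["hi"]])
})

test_that("the two-proportion z-test matches the published comparison", {
  eq <- two_proportion_test(0.4, 100, 0.4, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)

  # external-accuracy comparison: 86.6% vs 87.0% over 238 slides
  res <- two_proportion_test(0.866, 238, 0.870, 238)
  expect_equal(round(res$p_value, 2), 0.90)

  # p-value approaches 1 continuously as the difference vanishes
  ps <- vapply(c(1e-2, 1e-3, 1e-4), function(eps)
    two_proportion_test(0.5, 200, 0.5 + eps, 200)$p_value, numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_gt(ps[3], 0.995)

  # degenerate pooled proportion with equal inputs
  expect_equal(two_proportion_test(0, 50, 0, 50)$p_value, 1)
  expect_equal(two_proportion_test(1, 50, 1, 50)$p_value, 1)

  # the unpooled variant differs but agrees at equality
  expect_lt(abs(two_proportion_test(0.6, 100, 0.4, 100, pooled = FALSE)$z -
                two_proportion_test(0.6, 100, 0.4, 100)$z), 0.2)
})

test_that("confusion matrices count and row-normalize correctly", {
  perfect <- confusion_matrix(c("TA", "TVA", "HP", "SSA"),
                              c("TA", "TVA", "HP", "SSA"))
  expect_equal(unname(diag(perfect$ratio)), rep(1, 4))

  half <- confusion_matrix(c("TA", "TA", "TVA", "TVA"), rep("TA", 4))
  expect_equal(unname(half$ratio["TA", ]), c(0.5, 0.5, 0, 0))

  set.seed(14)
  pred <- sample(slide_classes(), 40, replace = TRUE)
  truth <- sample(slide_classes(), 40, replace = TRUE)
  cm <- confusion_matrix(pred, truth)
  present <- rowSums(cm$counts) > 0
  expect_equal(unname(rowSums(cm$ratio)[present]),
               rep(1, sum(present)))
  expect_equal(sum(cm$counts), 40)
  expect_error(confusion_matrix(character(0), character(0)), "requires")
})

test_that("the evaluation report assembles per-class rows, means and CIs", {
  set.seed(15)
  truth <- rep(slide_classes(), each = 10)
  pred <- truth
  pred[c(1, 12, 23)] <- c("TVA", "TA", "SSA")  # three errors
  rep_ <- eval_report(pred, truth)
  expect_equal(nrow(rep_$table), 5L)
  expect_equal(rep_$table$class[5], "Mean")
  mean_acc <- rep_$table$accuracy[5]
  expect_equal(mean_acc, mean(rep_$table$accuracy[1:4]))
  ci <- rep_$ci[rep_$ci$metric == "accuracy", ]
  manual <- wald_ci(mean_acc / 100, 40)
  expect_equal(ci$lo, manual[["lo"]])
  expect_equal(ci$hi, manual[["hi"]])
  expect_output(print(rep_), "Mean accuracy")
})
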