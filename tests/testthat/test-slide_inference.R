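test_that("patch counts tally argmax labels and reject mixed slides", {
  probs <- rbind(c(0.6, 0.1, 0.1, 0.1, 0.1),
                 c(0.5, 0.2, 0.1, 0.1, 0.1),
                 c(0.1, 0.1, 0.7, 0.05, 0.05))
  p <- prediction_table("s1", data.frame(x = c(0L, 224L, 448L), y = 0L),
                        probs, 224L)
  cc <- count_patch_classes(p)
  expect_equal(as.integer(cc), c(2L, 0L, 1L, 0L, 0L))
  expect_equal(attr(cc, "slide_id"), "s1")

  empty <- p[0, ]
  cc0 <- count_patch_classes(empty)
  expect_equal(as.integer(cc0), rep(0L, 5L))

  mixed <- p
  mixed$slide_id[2] <- "s2"
  expect_error(count_patch_classes(mixed), "mix slide_ids")
})

test_that("oracle counts from a planted slide equal its cell histogram", {
  s <- small_slide("TVA", villous = 0.5, seed = 21)
  preds <- oracle_patch_predictions(s$mask, "small-TVA",
                                    patch_spec(224L, 224L))
  cc <- count_patch_classes(preds)
  planted <- table(factor(s$cells$label, levels = patch_classes()))
  n_windows <- (1120L %/% 224L)^2
  expected <- as.integer(planted)
  expected[5] <- expected[5] + n_windows - nrow(s$cells)
  expect_equal(as.integer(cc), expected)
})

test_that("the hierarchical rule follows the branch-and-threshold contract", {
  thr <- threshold_config()  # villous 0.30, ssa 0.015, strict >
  d1 <- hierarchical_classify(c(60, 10, 5, 0, 200), thr)
  expect_equal(as.character(d1), "TA")
  expect_equal(attr(d1, "villous_fraction"), 10 / 70)

  expect_equal(as.character(hierarchical_classify(c(50, 50, 0, 0, 0), thr)),
               "TVA")

  # strict inequality at the SSA boundary: 3/200 = 0.015 is not > 0.015
  expect_equal(as.character(hierarchical_classify(c(0, 0, 197, 3, 0), thr)),
               "HP")
  expect_equal(as.character(hierarchical_classify(c(0, 0, 196, 4, 0), thr)),
               "SSA")
  # and at the villous boundary: 30/100 is not > 0.30
  expect_equal(as.character(hierarchical_classify(c(70, 30, 0, 0, 0), thr)),
               "TA")
  expect_equal(as.character(hierarchical_classify(c(69, 31, 0, 0, 0), thr)),
               "TVA")

  # adenomatous/serrated tie goes to the adenomatous branch
  tie <- hierarchical_classify(c(5, 0, 5, 0, 10), thr)
  expect_equal(attr(tie, "branch"), "adenomatous")
  expect_equal(as.character(tie), "TA")

  # normal patches never enter the fractions
  expect_equal(as.character(hierarchical_classify(c(1, 0, 0, 0, 1000), thr)),
               "TA")
  expect_error(hierarchical_classify(c(0, 0, 0, 0, 81), thr), "no lesion")

  # the all-polyp denominator mode changes the fraction base
  thr_all <- threshold_config(denominator = "all_polyp_patches")
  # villous fraction 40/(60+40+30) = 0.31 > 0.30 -> TVA under all-polyp,
  # but 40/100 = 0.40 under branch too; distinguishing case:
  # counts (30, 35, 25, 0, 0): branch 35/65 = 0.54 -> TVA;
  # all-polyp 35/90 = 0.389 -> TVA; boundary case (62, 28, 10, 0, 0):
  # branch 28/90 = 0.311 -> TVA, all-polyp 28/100 = 0.28 -> TA
  expect_equal(as.character(hierarchical_classify(c(62, 28, 10, 0, 0), thr)),
               "TVA")
  expect_equal(as.character(hierarchical_classify(c(62, 28, 10, 0, 0),
                                                  thr_all)), "TA")
})

test_that("raising a threshold only ever demotes the minority diagnosis", {
  set.seed(99)
  n <- 10000L
  counts <- cbind(TA = rpois(n, 20), TVA = rpois(n, 8),
                  HP = rpois(n, 15), SSA = rpois(n, 2),
                  NORM = rpois(n, 40))
  counts <- counts[rowSums(counts[, 1:4]) > 0, ]
  lo <- threshold_config(0.2, 0.01)
  hi <- threshold_config(0.5, 0.05)
  d_lo <- vapply(seq_len(nrow(counts)), function(i)
    as.character(hierarchical_classify(counts[i, ], lo)), character(1))
  d_hi <- vapply(seq_len(nrow(counts)), function(i)
    as.character(hierarchical_classify(counts[i, ], hi)), character(1))
  # permissible transitions when thresholds rise: TVA->TA and SSA->HP only
  expect_true(all(d_hi[d_lo == "TA"] == "TA"))
  expect_true(all(d_hi[d_lo == "HP"] == "HP"))
  expect_true(all(d_hi[d_lo == "TVA"] %in% c("TVA", "TA")))
  expect_true(all(d_hi[d_lo == "SSA"] %in% c("SSA", "HP")))
  # and the branch assignment never moves
  expect_true(all((d_lo %in% c("TA", "TVA")) == (d_hi %in% c("TA", "TVA"))))
})

test_that("grid search recovers planted thresholds within one grid step", {
  cc <- simulate_patch_count_cohort(n_slides = 200, seed = 5)
  cal <- calibrate_thresholds(cc$counts, cc$labels)
  expect_lte(abs(cal$thresholds$villous_threshold - 0.30), 0.05)
  expect_lte(abs(cal$thresholds$ssa_threshold - 0.015), 0.005)
  expect_equal(cal$objective, 1)
  # the surface covers the full grid
  expect_equal(nrow(cal$surface), 21L * 21L)
})

test_that("degenerate calibration inputs follow the tie contract", {
  # single-point grid returns that point
  cc <- simulate_patch_count_cohort(n_slides = 20, seed = 6)
  g1 <- grid_spec(villous_grid = 0.4, ssa_grid = 0.02)
  cal1 <- calibrate_thresholds(cc$counts, cc$labels, g1)
  expect_equal(cal1$thresholds$villous_threshold, 0.4)
  expect_equal(cal1$thresholds$ssa_threshold, 0.02)

  # all slides one class: every threshold optimal, smallest pair returned
  counts <- data.frame(slide_id = c("a", "b"), n_TA = c(10L, 20L),
                       n_TVA = 0L, n_HP = 0L, n_SSA = 0L, n_NORM = 5L)
  cal2 <- calibrate_thresholds(counts, c("TA", "TA"))
  expect_equal(cal2$thresholds$villous_threshold, 0)
  expect_equal(cal2$thresholds$ssa_threshold, 0)

  expect_error(grid_spec(villous_grid = numeric(0)), "nonempty")
  expect_error(calibrate_thresholds(counts[0, ], character(0)),
               "at least one slide")
})

test_that("whole-slide inference composes the pipeline stages", {
  m <- fixture_model()
  sTA <- small_slide("TA", villous = 0.1, seed = 31)
  res <- infer_slide(m, sTA$image, patch_spec(), slide_id = "x")
  expect_equal(as.character(res$diagnosis), "TA")
  expect_equal(sum(as.integer(res$counts)), 25L)
  expect_equal(nrow(res$predictions), 25L)

  sSSA <- small_slide("SSA", ssa = 0.3, seed = 32)
  resS <- infer_slide(m, sSSA$image, patch_spec(), slide_id = "y")
  expect_equal(as.character(resS$diagnosis), "SSA")

  # an all-normal slide has no polyp patches to diagnose
  blank <- oracle_patch_predictions(
    matrix(match("NORM", patch_classes()), 448, 448), "z")
  expect_error(hierarchical_classify(count_patch_classes(blank)),
               "no lesion")
})

test_that("threshold configs round-trip through JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  thr <- threshold_config(0.25, 0.02, denominator = "all_polyp_patches")
  write_thresholds(thr, f)
  back <- read_thresholds(f)
  expect_equal(back$villous_threshold, 0.25)
  expect_equal(back$ssa_threshold, 0.02)
  expect_equal(back$denominator, "all_polyp_patches")
  expect_error(threshold_config(1.2, 0), "\\[0, 1\\]")
})
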