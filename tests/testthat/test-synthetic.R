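test_that("slide generation is deterministic and seed-sensitive", {
  spec <- slide_spec("TA", size = 1120L, n_roi = 2L, roi_cells = c(2L, 2L),
                     villous_fraction = 0.1)
  a <- generate_slide(spec, seed = 5)
  b <- generate_slide(spec, seed = 5)
  expect_identical(a$image, b$image)
  expect_identical(a$annotations, b$annotations)
  c <- generate_slide(spec, seed = 6)
  expect_false(identical(a$image, c$image))
})

test_that("planted texture-area fractions are recovered from the mask", {
  s0 <- small_slide("TA", villous = 0)
  # no TVA texture anywhere when the villous fraction is zero
  expect_equal(sum(s0$mask == match("TVA", patch_classes())), 0)
  expect_equal(mask_area_fraction(s0$mask, "adenomatous"), 0)

  s5 <- generate_slide(slide_spec("TVA", villous_fraction = 0.5,
                                  size = 2048L), seed = 3)
  f <- mask_area_fraction(s5$mask, "adenomatous")
  expect_gte(f, 0.48); expect_lte(f, 0.52)

  sS <- generate_slide(slide_spec("SSA", ssa_fraction = 0.3, size = 2048L),
                       seed = 4)
  fS <- mask_area_fraction(sS$mask, "serrated")
  expect_gte(fS, 0.28); expect_lte(fS, 0.32)
})

test_that("ROIs larger than the slide are rejected", {
  expect_error(generate_slide(slide_spec("TA", size = 448L,
                                         roi_cells = c(3L, 3L)), 1),
               "exceeds the slide grid")
})

test_that("texture recipes are statistically separable", {
  classes <- patch_classes()
  n_rep <- 8L
  stats <- lapply(classes, function(cl)
    t(vapply(seq_len(n_rep), function(i)
      texture_statistics(draw_texture(cl, 224, 224, seed = 100 * i)),
      numeric(5))))
  centers <- t(vapply(stats, colMeans, numeric(5)))
  # pooled intra-class spread of the statistic vector
  intra <- mean(vapply(stats, function(s) mean(apply(s, 2L, sd)), numeric(1)))
  d <- as.matrix(dist(centers))
  inter <- mean(d[upper.tri(d)])
  expect_gt(inter, 3 * intra)
})

test_that("cohort generation honors counts, splits and determinism", {
  coh <- generate_cohort(n_per_class = 5,
                         split_fractions = c(train = 0.6, validation = 0.2,
                                             test_internal = 0.2),
                         out_dir = withr::local_tempdir(), seed = 2,
                         slide_size = 1120L, n_roi = 2L,
                         roi_cells = c(2L, 2L), write_images = FALSE)
  expect_equal(nrow(coh$manifest), 20L)
  expect_equal(as.vector(table(coh$truth$label)), rep(5L, 4L))
  expect_equal(sum(coh$manifest$split == "train"), 12L)
  expect_equal(sum(coh$manifest$split == "validation"), 4L)
  expect_equal(sum(coh$manifest$split == "test_internal"), 4L)
  # oracle counts cover the full window grid
  expect_true(all(rowSums(coh$oracle_counts[, -1]) == 25L))

  coh2 <- generate_cohort(n_per_class = 5, out_dir = withr::local_tempdir(),
                          seed = 3, slide_size = 1120L, n_roi = 2L,
                          roi_cells = c(2L, 2L), write_images = FALSE)
  expect_false(identical(coh$annotations, coh2$annotations))
  expect_equal(as.vector(table(coh2$truth$label)), rep(5L, 4L))

  expect_error(generate_cohort(5, split_fractions = c(train = 0.5,
                                                      validation = 0.2,
                                                      test_internal = 0.2)),
               "sum to 1")
})

test_that("planted fractions in the default cohort respect the rule margins", {
  coh <- generate_cohort(n_per_class = 8, out_dir = withr::local_tempdir(),
                         seed = 7, slide_size = 1120L, n_roi = 2L,
                         roi_cells = c(2L, 2L), write_images = FALSE)
  # oracle counts + reference thresholds reproduce every planted label
  pred <- vapply(seq_len(nrow(coh$oracle_counts)), function(i)
    as.character(hierarchical_classify(coh$oracle_counts[i, ])), character(1))
  expect_equal(pred, coh$truth$label)
})

test_that("annotator panels follow their confusion model", {
  truth <- rep(slide_classes(), each = 500)

  ident <- annotator_model(accuracy = 1)
  panel <- simulate_annotator_panel(truth, ident, seed = 1)
  expect_equal(mean_pairwise_kappa(panel)$mean_kappa, 1)

  unif <- annotator_model(confusion = rep(list(matrix(0.25, 4, 4)), 5))
  panel_u <- simulate_annotator_panel(truth, unif, seed = 2)
  expect_lt(abs(mean_pairwise_kappa(panel_u)$mean_kappa), 0.05)

  m90 <- annotator_model(accuracy = 0.9)
  panel_90 <- simulate_annotator_panel(truth, m90, seed = 3)
  acc <- vapply(paste0("A", 1:5), function(a) {
    sub <- panel_90[panel_90$annotator_id == a, ]
    mean(sub$label[match(paste0("s", seq_along(truth)), sub$slide_id)] == truth)
  }, numeric(1))
  expect_true(all(abs(acc - 0.9) <= 0.02))

  bad <- matrix(0.3, 4, 4)
  expect_error(annotator_model(confusion = rep(list(bad), 5)), "sum to 1")
})
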