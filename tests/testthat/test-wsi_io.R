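test_that("manifest round-trips and enforces its invariants", {
  m <- data.frame(slide_id = c("s1", "s2"),
                  image_path = c("a.png", "b.png"),
                  microns_per_pixel = c(0.25, 2),
                  split = c("train", "test_internal"),
                  institution_id = c("I0", "I1"),
                  stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  write_manifest(m, f)
  expect_identical(read_manifest(f), m)

  dup <- m; dup$slide_id <- c("s1", "s1")
  expect_error(write_manifest(dup, f), "duplicate slide_id.*s1")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(m[, -3], f2, row.names = FALSE)
  expect_error(read_manifest(f2), "missing column 'microns_per_pixel'")
  bad <- m; bad$microns_per_pixel[1] <- 0
  expect_error(write_manifest(bad, f), "microns_per_pixel")
  bad <- m; bad$split[1] <- "holdout"
  expect_error(write_manifest(bad, f), "train, validation")
})

test_that("annotation JSON parses, validates labels and boxes, round-trips", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('[{"slide_id":"s1","box":[0,0,224,224],',
                    '"label":"TA","annotator_id":"A1"}]'), f)
  a <- read_annotations(f)
  expect_equal(nrow(a), 1L)
  expect_equal((a$x1 - a$x0) * (a$y1 - a$y0), 224 * 224)

  writeLines(paste0('[{"slide_id":"s1","box":[0,0,10,10],',
                    '"label":"polyp","annotator_id":"A1"}]'), f)
  expect_error(read_annotations(f), "TA, TVA, HP, SSA, NORM")
  writeLines(paste0('[{"slide_id":"s1","box":[50,0,50,10],',
                    '"label":"TA","annotator_id":"A1"}]'), f)
  expect_error(read_annotations(f), "degenerate")

  ann <- data.frame(slide_id = "s9", x0 = 10L, y0 = 20L, x1 = 234L,
                    y1 = 244L, label = "SSA", annotator_id = "A2",
                    stringsAsFactors = FALSE)
  write_annotations(ann, f)
  expect_identical(read_annotations(f), ann)
})

test_that("a large generated annotation set is read back in full", {
  n <- 3848L
  set.seed(1)
  x0 <- sample.int(4000L, n, replace = TRUE) - 1L
  y0 <- sample.int(4000L, n, replace = TRUE) - 1L
  ann <- data.frame(slide_id = sprintf("s%03d", sample.int(157L, n, TRUE)),
                    x0 = x0, y0 = y0,
                    x1 = x0 + sample(224:999, n, TRUE),
                    y1 = y0 + sample(224:999, n, TRUE),
                    label = sample(patch_classes()[1:4], n, TRUE),
                    annotator_id = sample(c("A1", "A2"), n, TRUE),
                    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".json")
  write_annotations(ann, f)
  expect_equal(nrow(read_annotations(f)), n)
})

test_that("prediction tables validate probabilities and round-trip to 1e-6", {
  f <- withr::local_tempfile(fileext = ".csv")
  p <- prediction_table("s1", data.frame(x = 0L, y = 0L),
                        matrix(rep(0.2, 5), 1), 224L)
  write_predictions(p, f)
  expect_equal(nrow(read_predictions(f)), 1L)

  set.seed(2)
  pm <- matrix(rexp(50), 10)
  pm <- pm / rowSums(pm)
  p <- prediction_table("s1", data.frame(x = 224L * (0:9), y = 0L), pm, 224L)
  write_predictions(p, f)
  back <- read_predictions(f)
  expect_equal(as.matrix(back[paste0("p_", patch_classes())]),
               as.matrix(p[paste0("p_", patch_classes())]),
               tolerance = 1e-6, ignore_attr = TRUE)

  bad <- p
  for (cl in paste0("p_", patch_classes())) bad[[cl]] <- bad[[cl]] * 0.9
  expect_error(write_predictions(bad, f), "sums to")
})

test_that("slide label tables enforce one label per slide and annotator", {
  lab <- data.frame(slide_id = c("s1", "s1"), annotator_id = c("A1", "A2"),
                    label = c("TA", "HP"), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  write_slide_labels(lab, f)
  expect_identical(read_slide_labels(f), lab)
  dup <- rbind(lab, lab[1, ])
  expect_error(write_slide_labels(dup, f), "duplicate")
  bad <- lab; bad$label[1] <- "NORM"
  expect_error(write_slide_labels(bad, f), "slide label")
})

test_that("coordinates are 0-based half-open with origin top-left", {
  img <- array(0, c(8, 8, 3))
  img[1:3, 1:3, 1] <- 1  # top-left 3x3 block marked in channel 1
  p <- extract_patch(img, 0, 0, 3)
  expect_equal(p[, , 1], matrix(1, 3, 3))
  # box [0,0,s) x [0,0,s) is exactly the top-left s x s pixels
  expect_equal(extract_patch(img, 0, 0, 4)[4, 4, 1], 0)
  expect_error(extract_patch(img, 6, 6, 3), "outside")
})

test_that("slide images round-trip through PNG (and TIFF when available)", {
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  f <- withr::local_tempfile(fileext = ".png")
  write_slide_image(img, f)
  expect_equal(read_slide_image(f), img, tolerance = 1 / 255)
  if (requireNamespace("tiff", quietly = TRUE)) {
    ft <- withr::local_tempfile(fileext = ".tif")
    write_slide_image(img, ft)
    expect_equal(read_slide_image(ft), img, tolerance = 2 / 255)
  }
  expect_error(read_slide_image("x.svs"), "unsupported")
})
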