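#' Enumerate sliding-window patch origins within a box
#'
#' Windows are placed at `(x0 + i*stride, y0 + j*stride)` for all
#' `i, j >= 0` such that the full `patch_size` window lies inside the
#' half-open box `[x0, x1) x [y0, y1)`; windows that would extend past
#' the box are dropped, so a box smaller than the patch in either
#' dimension yields an empty grid.  Origins are returned in row-major
#' order (scanning x fastest within each y row).  The number of origins
#' equals `prod(floor((L - size)/stride) + 1)` over the two dimensions
#' whenever each extent `L >= size`.
#'
#' @param box Numeric vector `c(x0, y0, x1, y1)`, 0-based half-open.
#' @param spec A [patch_spec()].
#' @return Data frame with integer columns `x`, `y` of window origins.
#' @examples
#' nrow(sliding_window(c(0, 0, 448, 448), patch_spec()))  # 4
#' nrow(sliding_window(c(0, 0, 200, 448), patch_spec()))  # 0
#' @export
sliding_window <- function(box, spec = patch_spec()) {
  box <- as.integer(box)
  if (length(box) != 4L || box[3L] <= box[1L] || box[4L] <= box[2L])
    stopf("box must be c(x0, y0, x1, y1) with x1 > x0, y1 > y0")
  size <- spec$patch_size; stride <- spec$stride
  w <- box[3L] - box[1L]; h <- box[4L] - box[2L]
  if (w < size || h < size)
    return(data.frame(x = integer(), y = integer()))
  xs <- box[1L] + seq.int(0L, w - size, by = stride)
  ys <- box[2L] + seq.int(0L, h - size, by = stride)
  data.frame(x = rep(xs, times = length(ys)),
             y = rep(ys, each = length(xs)))
}

#' Extract a square patch from an image
#'
#' @param image `h x w x c` array.
#' @param x,y 0-based origin (column, row) of the patch.
#' @param size Patch side in pixels.
#' @return `size x size x c` array.
#' @export
extract_patch <- function(image, x, y, size) {
  d <- dim(image)
  if (x < 0 || y < 0 || x + size > d[2L] || y + size > d[1L])
    stopf("patch [%d,%d,%d,%d) lies outside the %dx%d image",
          x, y, x + size, y + size, d[2L], d[1L])
  image[(y + 1L):(y + size), (x + 1L):(x + size), , drop = FALSE]
}

#' Area-average downsampling by an integer factor
#'
#' Each output pixel is the mean of the corresponding `factor x factor`
#' block; image dimensions must be divisible by the factor.
#'
#' @param image `h x w x c` array.
#' @param factor Integer downsample factor >= 1.
#' @return `h/factor x w/factor x c` array.
#' @export
downsample_image <- function(image, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  d <- dim(image)
  if (d[1L] %% factor != 0L || d[2L] %% factor != 0L)
    stopf("image dimensions %dx%d not divisible by factor %d",
          d[1L], d[2L], factor)
  h2 <- d[1L] %/% factor; w2 <- d[2L] %/% factor
  # average rows then columns per channel via reshaping
  out <- array(0, c(h2, w2, d[3L]))
  for (ch in seq_len(d[3L])) {
    m <- image[, , ch]
    m <- matrix(colMeans(matrix(m, nrow = factor)), nrow = h2, ncol = d[2L])
    m <- t(matrix(colMeans(matrix(t(m), nrow = factor)), nrow = w2, ncol = h2))
    out[, , ch] <- m
  }
  out
}

#' Extract labeled training patches from annotated ROIs
#'
#' Tiles every annotation box with the sliding-window grid and extracts
#' each fully contained window, labeling it with its ROI's class.  A
#' window that falls inside two overlapping ROIs with conflicting labels
#' is skipped and counted.  When `balance_to` is given, every class
#' present is down-/up-sampled (with replacement where needed, seeded)
#' to exactly that count.
#'
#' @param image Slide raster (`h x w x 3` array) at extraction
#'   resolution; if `spec$extraction_downsample > 1` the image is
#'   area-averaged by that factor first (annotation coordinates are then
#'   interpreted at the downsampled scale).
#' @param annotations Annotation data frame (see [read_annotations()])
#'   for this slide.
#' @param spec A [patch_spec()].
#' @param balance_to Target patch count per class, or `NULL` for no
#'   balancing.
#' @param seed Seed for balancing resamples.
#' @return List with `patches` (list of `size x size x 3` arrays),
#'   `labels` (character vector), `origins` (data frame `x`, `y`), and
#'   `n_skipped` (windows dropped for conflicting ROI labels).
#' @export
extract_training_patches <- function(image, annotations, spec = patch_spec(),
                                     balance_to = NULL, seed = NULL) {
  if (spec$extraction_downsample > 1L)
    image <- downsample_image(image, spec$extraction_downsample)
  size <- spec$patch_size
  grids <- lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    g <- sliding_window(c(a$x0, a$y0, a$x1, a$y1), spec)
    if (nrow(g) > 0) g$label <- a$label
    g
  })
  grid <- do.call(rbind, c(grids, list(data.frame(x = integer(),
                                                  y = integer(),
                                                  label = character()))))
  n_skipped <- 0L
  if (nrow(grid) > 0) {
    # windows inside >1 ROI: identical labels collapse, conflicts skip
    key <- paste(grid$x, grid$y)
    conflicted <- tapply(grid$label, key, function(l) length(unique(l)) > 1L)
    keep <- !duplicated(key) & !conflicted[key]
    n_skipped <- sum(conflicted)
    grid <- grid[keep, , drop = FALSE]
  }
  if (!is.null(balance_to) && nrow(grid) > 0) {
    grid <- with_seed(seed, {
      parts <- lapply(split(seq_len(nrow(grid)), grid$label), function(idx) {
        if (length(idx) >= balance_to) sample(idx, balance_to)
        else c(idx, sample(idx, balance_to - length(idx), replace = TRUE))
      })
      grid[unlist(parts, use.names = FALSE), , drop = FALSE]
    })
  }
  patches <- lapply(seq_len(nrow(grid)), function(i)
    extract_patch(image, grid$x[i], grid$y[i], size))
  list(patches = patches, labels = grid$label,
       origins = grid[, c("x", "y"), drop = FALSE],
       n_skipped = as.integer(n_skipped))
}

#' Apply stochastic augmentation to a patch
#'
#' Draws a rotation from the enabled set, flips (probability 1/2 each
#' when enabled), and jitter offsets uniform within the configured
#' half-ranges, then applies: rotation/flips; additive brightness;
#' contrast scaling about mid-gray; saturation scaling and hue rotation
#' in HSV space.  Output values are clipped to `[0, 1]`.  Deterministic
#' given `seed`; with all augmentations disabled the patch is returned
#' unchanged.
#'
#' @param patch Square `s x s x 3` array.
#' @param spec An [augment_spec()].
#' @param seed Integer seed.
#' @return Augmented `s x s x 3` array.
#' @export
augment <- function(patch, spec = augment_spec(), seed = NULL) {
  d <- dim(patch)
  if (length(d) != 3L || d[1L] != d[2L]) stopf("patch must be square h x w x 3")
  with_seed(seed, {
    rot <- if (length(spec$rotations) > 1L)
      sample(spec$rotations, 1L) else spec$rotations
    do_h <- spec$hflip && stats::runif(1) < 0.5
    do_v <- spec$vflip && stats::runif(1) < 0.5
    jb <- if (spec$brightness > 0)
      stats::runif(1, -spec$brightness, spec$brightness) else 0
    jc <- if (spec$contrast > 0)
      stats::runif(1, -spec$contrast, spec$contrast) else 0
    js <- if (spec$saturation > 0)
      stats::runif(1, -spec$saturation, spec$saturation) else 0
    jh <- if (spec$hue > 0) stats::runif(1, -spec$hue, spec$hue) else 0
    out <- rotate_patch(patch, rot)
    if (do_h) out <- out[, rev(seq_len(ncol(out))), , drop = FALSE]
    if (do_v) out <- out[rev(seq_len(nrow(out))), , , drop = FALSE]
    if (jb != 0) out <- out + jb
    if (jc != 0) out <- (out - 0.5) * (1 + jc) + 0.5
    if (js != 0 || jh != 0) {
      out[out < 0] <- 0
      out[out > 1] <- 1
      out <- jitter_hsv(out, js, jh)
    }
    out[out < 0] <- 0
    out[out > 1] <- 1
    out
  })
}

# counter-clockwise right-angle rotation of an h x w x c array
rotate_patch <- function(patch, degrees) {
  k <- (as.integer(degrees) %/% 90L) %% 4L
  if (k == 0L) return(patch)
  d <- dim(patch)
  out <- patch
  for (i in seq_len(k)) {
    dd <- dim(out)
    out <- aperm(out, c(2L, 1L, 3L))[rev(seq_len(dd[2L])), , , drop = FALSE]
  }
  out
}

# saturation scale (1 + js) and hue shift jh (fraction of the circle)
jitter_hsv <- function(patch, js, jh) {
  d <- dim(patch)
  rgb <- t(matrix(patch, ncol = 3L))  # 3 x n, rows r,g,b in [0,1]
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  hsv[1L, ] <- (hsv[1L, ] + jh) %% 1
  hsv[2L, ] <- pmin(1, pmax(0, hsv[2L, ] * (1 + js)))
  out <- hsv_to_rgb(hsv)
  array(t(out), d)
}

# vectorised HSV -> RGB (h,s,v rows in [0,1]); inverse of rgb2hsv
hsv_to_rgb <- function(hsv) {
  h <- hsv[1L, ] * 6; s <- hsv[2L, ]; v <- hsv[3L, ]
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  rbind(r, g, b)
}
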