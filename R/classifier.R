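#' Train the reference convolutional patch classifier
#'
#' Fits a small two-convolutional-block network (conv 5x5/8 filters,
#' ReLU, 2x2 max-pool; conv 3x3/16 filters, ReLU, 2x2 max-pool; dense
#' softmax over the five patch classes) by minibatch stochastic gradient
#' descent with momentum on the cross-entropy loss.  The learning rate
#' follows exponential decay, `initial_lr * lr_decay^(epoch - 1)`
#' (0.001 with decay 0.9 per epoch by default), and weights use
#' MSRA/He-normal initialization.  Patches are area-averaged to the
#' network's 32x32 working resolution, so the patch side must be a
#' multiple of 32 (224 = 7 x 32 at the defaults).  Training is
#' deterministic given `config$seed`.
#'
#' The architecture is intentionally small enough to train on one CPU in
#' minutes; the classifier interface (`predict` returning an `n x 5`
#' probability matrix in [patch_classes()] order) is the contract, and a
#' larger backbone such as a ResNet can be slotted in behind the same
#' interface.
#'
#' @param patches List of `s x s x 3` arrays (or a single such array),
#'   all the same size.
#' @param labels Character vector of patch classes, one per patch; at
#'   least two distinct classes must be present.
#' @param config A [train_config()].
#' @param validation Optional list with elements `patches` and `labels`
#'   scored after every epoch and recorded in the training log.
#' @return An object of class `patch_cnn` with components `params`
#'   (weights), `classes`, `patch_size`, `input_size`, `config` and
#'   `log` (data frame: epoch, lr, loss, and validation accuracy when
#'   requested).
#' @seealso [predict.patch_cnn()], [ensemble_predict()], [lr_schedule()]
#' @export
train_patch_classifier <- function(patches, labels, config = train_config(),
                                   validation = NULL) {
  if (is.array(patches)) patches <- list(patches)
  n <- length(patches)
  if (n != length(labels)) stopf("patches and labels differ in length")
  labels <- match_labels(labels, patch_classes(), "patch label")
  if (length(unique(labels)) < 2L)
    stopf("training requires at least 2 classes (got %d)",
          length(unique(labels)))
  sizes <- vapply(patches, function(p) dim(p)[1L], integer(1))
  widths <- vapply(patches, function(p) dim(p)[2L], integer(1))
  if (length(unique(c(sizes, widths))) != 1L)
    stopf("all training patches must be square and of uniform size")
  patch_size <- sizes[[1L]]
  input_size <- 32L
  if (patch_size %% input_size != 0L)
    stopf("patch size %d is not a multiple of the %d-pixel input",
          patch_size, input_size)

  y <- match(labels, patch_classes())
  params <- with_seed(config$seed, cnn_init(config$init))
  vel <- lapply(params, function(p) p * 0)
  log_rows <- vector("list", config$epochs)
  val_X <- if (!is.null(validation))
    patches_to_input(validation$patches, input_size) else NULL

  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(config, epoch)
    ep_seed <- derive_seed(config$seed, epoch)
    loss_sum <- 0; loss_n <- 0L
    with_seed(ep_seed, {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (b in batches) {
        Xb <- batch_input(patches[b], input_size, config$augment)
        yb <- y[b]
        fb <- cnn_forward(params, Xb, keep = TRUE)
        loss <- -mean(log(pmax(fb$probs[cbind(seq_along(yb), yb)], 1e-12)))
        loss_sum <- loss_sum + loss * length(b); loss_n <- loss_n + length(b)
        grads <- cnn_backward(params, fb, yb)
        for (k in names(params)) {
          vel[[k]] <- config$momentum * vel[[k]] - lr * grads[[k]]
          params[[k]] <- params[[k]] + vel[[k]]
        }
      }
    })
    row <- data.frame(epoch = epoch, lr = lr, loss = loss_sum / loss_n)
    if (!is.null(val_X)) {
      vp <- cnn_forward(params, val_X)$probs
      pred <- patch_classes()[apply(vp, 1L, which.max)]
      row$val_accuracy <- mean(pred == validation$labels)
    }
    log_rows[[epoch]] <- row
  }
  structure(list(params = params, classes = patch_classes(),
                 patch_size = patch_size, input_size = input_size,
                 config = config, log = do.call(rbind, log_rows)),
            class = "patch_cnn")
}

#' @export
print.patch_cnn <- function(x, ...) {
  cat("Patch classifier: 2-block conv net (", x$input_size, "x",
      x$input_size, " input)\n", sep = "")
  cat("  classes:    ", paste(x$classes, collapse = ", "), "\n", sep = "")
  cat("  patch size: ", x$patch_size, " px\n", sep = "")
  cat("  trained:    ", x$config$epochs, " epochs, initial lr ",
      format(x$config$initial_lr), ", decay ", format(x$config$lr_decay),
      "/epoch, seed ", x$config$seed, "\n", sep = "")
  cat("  final loss: ", format(utils::tail(x$log$loss, 1), digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.patch_cnn <- function(object, ...) {
  print(object)
  cat("\nTraining log (last 5 epochs):\n")
  print(utils::tail(object$log, 5), row.names = FALSE)
  invisible(object$log)
}

#' Predict patch class probabilities
#'
#' @param object A trained [train_patch_classifier()] model.
#' @param patches List of patches (or single array) of the model's
#'   patch size.
#' @param type `"prob"` for the `n x 5` probability matrix (columns in
#'   [patch_classes()] order, rows summing to 1), `"class"` for hard
#'   labels (argmax, ties broken toward the earliest class in the fixed
#'   class order).
#' @param ... Unused.
#' @return Probability matrix or character vector of labels.
#' @export
predict.patch_cnn <- function(object, patches, type = c("prob", "class"),
                              ...) {
  type <- match.arg(type)
  if (is.array(patches)) patches <- list(patches)
  sizes <- vapply(patches, function(p) dim(p)[1L], integer(1))
  if (any(sizes != object$patch_size))
    stopf("patch size %d does not match the model's %d",
          sizes[which(sizes != object$patch_size)][1L], object$patch_size)
  X <- patches_to_input(patches, object$input_size)
  probs <- cnn_forward(object$params, X)$probs
  colnames(probs) <- object$classes
  if (type == "prob") probs else hard_labels(probs)
}

#' @rdname predict.patch_cnn
#' @param model A `patch_cnn` or `patch_ensemble`.
#' @export
predict_probs <- function(model, patches) predict(model, patches, "prob")

#' Hard labels from a probability matrix
#'
#' Argmax per row with ties broken toward the earliest class in the
#' fixed class order (so an exact five-way tie yields `TA`).
#'
#' @param probs `n x 5` probability matrix in [patch_classes()] order.
#' @return Character vector of patch classes.
#' @export
hard_labels <- function(probs) {
  probs <- as.matrix(probs)
  patch_classes()[apply(probs, 1L, which.max)]
}

#' Softmax-averaging classifier ensemble
#'
#' Combines several trained patch classifiers by unweighted averaging of
#' their per-patch probability vectors (renormalized only against
#' numerical drift).  All members must share the class order.
#'
#' @param models List of `patch_cnn` models (>= 1).
#' @return An object of class `patch_ensemble`.
#' @export
patch_ensemble <- function(models) {
  if (inherits(models, "patch_cnn")) models <- list(models)
  if (length(models) < 1L) stopf("ensemble needs at least one member")
  cls <- lapply(models, `[[`, "classes")
  if (!all(vapply(cls, identical, logical(1), cls[[1L]])))
    stopf("ensemble members disagree on class order")
  ps <- vapply(models, `[[`, integer(1), "patch_size")
  if (length(unique(ps)) != 1L)
    stopf("ensemble members disagree on patch size")
  structure(list(models = models, classes = cls[[1L]],
                 patch_size = ps[[1L]]), class = "patch_ensemble")
}

#' @export
print.patch_ensemble <- function(x, ...) {
  cat("Softmax-averaging ensemble of", length(x$models),
      "patch classifiers\n")
  invisible(x)
}

#' @rdname patch_ensemble
#' @param object A `patch_ensemble`.
#' @param patches,type,... As in [predict.patch_cnn()].
#' @export
predict.patch_ensemble <- function(object, patches,
                                   type = c("prob", "class"), ...) {
  type <- match.arg(type)
  probs <- Reduce(`+`, lapply(object$models, predict_probs,
                              patches = patches)) / length(object$models)
  probs <- probs / rowSums(probs)
  if (type == "prob") probs else hard_labels(probs)
}

#' @rdname patch_ensemble
#' @param models List of trained models.
#' @export
ensemble_predict <- function(models, patches)
  predict(patch_ensemble(models), patches, "prob")

#' Save and load a classifier checkpoint
#'
#' Weights are serialized to `path` with a JSON sidecar
#' (`<path>.json`) recording the class order, patch size and training
#' configuration.
#'
#' @param model A `patch_cnn`.
#' @param path Checkpoint path.
#' @return `save_patch_cnn()` invisibly returns `path`;
#'   `load_patch_cnn()` returns the model.
#' @export
save_patch_cnn <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(classes = model$classes, patch_size = model$patch_size,
                  input_size = model$input_size,
                  config = model$config[c("epochs", "initial_lr", "lr_decay",
                                          "batch_size", "momentum", "seed",
                                          "init")])
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_patch_cnn
#' @export
load_patch_cnn <- function(path) readRDS(path)

## ---- internal network machinery ------------------------------------------
## Fixed geometry: 32 -> conv 5x5x8 -> 28 -> pool2 -> 14 -> conv 3x3x16
## -> 12 -> pool2 -> 6 -> dense 576 x 5.

cnn_init <- function(scheme = "he_normal") {
  shp <- list(W1 = c(75, 8), b1 = 8, W2 = c(72, 16), b2 = 16,
              W3 = c(576, 5), b3 = 5)
  fan <- list(W1 = 75, b1 = 1, W2 = 72, b2 = 1, W3 = 576, b3 = 1)
  params <- lapply(names(shp), function(k) {
    d <- shp[[k]]
    nvals <- prod(d)
    v <- if (grepl("^b", k)) rep(0, nvals)
    else if (scheme == "he_normal")
      stats::rnorm(nvals, sd = sqrt(2 / fan[[k]]))
    else stats::runif(nvals, -0.05, 0.05)
    if (length(d) == 2L) matrix(v, d[1L], d[2L]) else v
  })
  names(params) <- names(shp)
  params
}

# cached im2col index matrices and pooling indices per geometry
.cnn_cache <- new.env(parent = emptyenv())

im2col_idx <- function(h, w, c, k) {
  key <- paste("i", h, w, c, k, sep = "_")
  if (!is.null(.cnn_cache[[key]])) return(.cnn_cache[[key]])
  oh <- h - k + 1L; ow <- w - k + 1L
  # linear index of pixel (row, col, ch) in column-major h x w x c layout
  lin <- function(row, col, ch) row + (col - 1L) * h + (ch - 1L) * h * w
  # output positions enumerated column-major (row fastest), matching the
  # layout convention used for every feature map
  pos <- expand.grid(row = seq_len(oh), col = seq_len(ow))
  offs <- expand.grid(dr = 0:(k - 1L), dc = 0:(k - 1L), ch = seq_len(c))
  idx <- matrix(0L, nrow(pos), nrow(offs))
  for (j in seq_len(nrow(offs)))
    idx[, j] <- lin(pos$row + offs$dr[j], pos$col + offs$dc[j], offs$ch[j])
  .cnn_cache[[key]] <- idx
  idx
}

pool_idx <- function(oh, ow) {
  key <- paste("p", oh, ow, sep = "_")
  if (!is.null(.cnn_cache[[key]])) return(.cnn_cache[[key]])
  # 2x2 max-pool over positions in column-major (row fastest) order
  ph <- oh %/% 2L; pw <- ow %/% 2L
  pos <- function(row, col) row + (col - 1L) * oh
  out <- expand.grid(row = seq_len(ph), col = seq_len(pw))
  members <- cbind(pos(2L * out$row - 1L, 2L * out$col - 1L),
                   pos(2L * out$row, 2L * out$col - 1L),
                   pos(2L * out$row - 1L, 2L * out$col),
                   pos(2L * out$row, 2L * out$col))
  .cnn_cache[[key]] <- members
  members
}

# stack a list of patches into an n x (32*32*3) design matrix
patches_to_input <- function(patches, input_size) {
  if (is.array(patches)) patches <- list(patches)
  rows <- vapply(patches, function(p) {
    f <- dim(p)[1L] %/% input_size
    as.vector(downsample_image(p, f)) - 0.5
  }, numeric(input_size * input_size * 3L))
  t(rows)
}

batch_input <- function(patches, input_size, aug) {
  if (is.null(aug)) return(patches_to_input(patches, input_size))
  rows <- vapply(patches, function(p) {
    f <- dim(p)[1L] %/% input_size
    small <- downsample_image(p, f)
    as.vector(augment(small, aug, seed = NULL)) - 0.5
  }, numeric(input_size * input_size * 3L))
  t(rows)
}

# forward pass; X is n x 3072. keep=TRUE retains intermediates for backprop
cnn_forward <- function(params, X, keep = FALSE) {
  n <- nrow(X)
  i1 <- im2col_idx(32L, 32L, 3L, 5L)          # 784 x 75
  P1 <- nrow(i1)
  M1 <- matrix(X[, as.vector(i1)], n * P1, ncol(i1))
  Z1 <- M1 %*% params$W1
  Z1 <- sweep(Z1, 2L, params$b1, `+`)
  A1 <- pmax(Z1, 0)
  pm1 <- pool_idx(28L, 28L)                   # 196 x 4 over positions
  p1 <- pool_forward(A1, pm1, n, P1, 8L)      # n*196 x 8 (+ argmax attr)
  i2 <- im2col_idx(14L, 14L, 8L, 3L)          # 144 x 72
  P2 <- nrow(i2)
  X2 <- pooled_to_rowvec(p1$out, n, 196L, 8L) # n x (14*14*8) array layout
  M2 <- matrix(X2[, as.vector(i2)], n * P2, ncol(i2))
  Z2 <- M2 %*% params$W2
  Z2 <- sweep(Z2, 2L, params$b2, `+`)
  A2 <- pmax(Z2, 0)
  pm2 <- pool_idx(12L, 12L)                   # 36 x 4
  p2 <- pool_forward(A2, pm2, n, P2, 16L)     # n*36 x 16
  F3 <- pooled_to_rowvec(p2$out, n, 36L, 16L)
  S <- F3 %*% params$W3
  S <- sweep(S, 2L, params$b3, `+`)
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  probs <- E / rowSums(E)
  out <- list(probs = probs)
  if (keep)
    out <- c(out, list(X = X, M1 = M1, Z1 = Z1, p1 = p1, M2 = M2, Z2 = Z2,
                       p2 = p2, F3 = F3, n = n, i1 = i1, i2 = i2,
                       pm1 = pm1, pm2 = pm2))
  out
}

# A: (n*P) x F activations at P positions; members: Q x 4 position groups.
# Returns list(out = (n*Q) x F pooled maxima, arg = winning member index).
pool_forward <- function(A, members, n, P, F) {
  Q <- nrow(members)
  idx <- function(m) rep((members[, m] - 1L) * n, each = n) + seq_len(n)
  i1 <- idx(1L); i2 <- idx(2L); i3 <- idx(3L); i4 <- idx(4L)
  v1 <- A[i1, , drop = FALSE]; v2 <- A[i2, , drop = FALSE]
  v3 <- A[i3, , drop = FALSE]; v4 <- A[i4, , drop = FALSE]
  out <- pmax(v1, v2, v3, v4)
  # first member attaining the max wins (deterministic tie-break)
  arg <- ifelse(v1 >= out, 1L, ifelse(v2 >= out, 2L,
                                      ifelse(v3 >= out, 3L, 4L)))
  list(out = out, arg = arg, idx = cbind(i1, i2, i3, i4))
}

# reorder (n*Q) x F pooled matrix into n x (Q*F) row vectors (array layout:
# position index fastest, then channel) matching im2col's linear indexing
# of a Q-position, F-channel feature map stored position-major
pooled_to_rowvec <- function(pooled, n, Q, F) {
  matrix(array(pooled, c(n, Q, F)), n, Q * F)
}

cnn_backward <- function(params, f, y) {
  n <- f$n
  dS <- f$probs
  dS[cbind(seq_len(n), y)] <- dS[cbind(seq_len(n), y)] - 1
  dS <- dS / n
  gW3 <- crossprod(f$F3, dS)
  gb3 <- colSums(dS)
  dF3 <- dS %*% t(params$W3)                    # n x 576
  dP2 <- matrix(array(dF3, c(n, 36L, 16L)), n * 36L, 16L)
  dA2 <- pool_backward(dP2, f$p2, n, 144L, 16L)
  dZ2 <- dA2 * (f$Z2 > 0)
  gW2 <- crossprod(f$M2, dZ2)
  gb2 <- colSums(dZ2)
  dM2 <- dZ2 %*% t(params$W2)                   # (n*144) x 72
  dX2 <- col2im(dM2, f$i2, n, 14L * 14L * 8L)   # n x 1568
  dP1 <- matrix(dX2, n * 196L, 8L)
  dA1 <- pool_backward(dP1, f$p1, n, 784L, 8L)
  dZ1 <- dA1 * (f$Z1 > 0)
  gW1 <- crossprod(f$M1, dZ1)
  gb1 <- colSums(dZ1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

# scatter pooled gradients back to the winning pre-pool positions
pool_backward <- function(dP, pool, n, P, F) {
  dA <- matrix(0, n * P, F)
  for (m in 1:4) {
    sel <- pool$arg == m
    if (!any(sel)) next
    rows <- pool$idx[, m]
    for (ch in seq_len(F)) {
      s <- sel[, ch]
      if (any(s)) dA[rows[s], ch] <- dA[rows[s], ch] + dP[s, ch]
    }
  }
  dA
}

# accumulate im2col gradients back into the input layout
col2im <- function(dM, idx, n, width) {
  dX <- matrix(0, n, width)
  P <- nrow(idx)
  for (k in seq_len(ncol(idx))) {
    block <- matrix(dM[, k], n, P)
    cols <- idx[, k]
    dX[, cols] <- dX[, cols] + block
  }
  dX
}
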