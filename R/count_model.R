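#' Model configuration for the counting regressor
#'
#' The counting network maps a grayscale trap image directly to a scalar
#' insect count (counting by regression — no localization or species
#' identification). The architecture is a stack of 3x3 convolution + ReLU +
#' 2x2 max-pool blocks, global average pooling, and a single linear output
#' unit; it is fully convolutional, so the same weights apply at any input
#' resolution. Training minimizes mean squared error with Adam, mirroring
#' the deployed recipe: learning rate 0.001, beta1 0.9, beta2 0.999, batch
#' size 32, up to 240 epochs with validation-regulated early stopping, and
#' augmentation by random horizontal/vertical flips (p = 0.5 each), random
#' rotation (p = 0.5) and random zoom (p = 0.2).
#'
#' @param input_size `c(height, width)` of model inputs, pixels; default
#'   `c(240, 240)` grayscale.
#' @param channels convolution channel counts, one per conv-pool block.
#' @param kernel convolution kernel side (odd).
#' @param lr,beta1,beta2 Adam hyper-parameters.
#' @param batch_size mini-batch size.
#' @param max_epochs training epoch cap.
#' @param patience epochs without validation improvement before stopping.
#' @param aug augmentation policy: probabilities `flip_h`, `flip_v`, `rot`,
#'   `zoom`, plus `rot_range` (degrees, +/-) and `zoom_range` (scale factor
#'   interval). Magnitudes default to +/-20 degrees and `[0.8, 1.2]`.
#' @return A list of class `trap_model_config`.
#' @export
model_config <- function(input_size = c(240, 240),
                         channels = c(16, 32, 64, 64), kernel = 3,
                         lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 32, max_epochs = 240, patience = 20,
                         aug = list(flip_h = 0.5, flip_v = 0.5, rot = 0.5,
                                    rot_range = 20, zoom = 0.2,
                                    zoom_range = c(0.8, 1.2))) {
  stopifnot(kernel %% 2 == 1, length(channels) >= 1, all(channels >= 1))
  structure(list(input_size = as.integer(input_size), channels = as.integer(channels),
                 kernel = as.integer(kernel), lr = lr, beta1 = beta1,
                 beta2 = beta2, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 aug = aug),
            class = "trap_model_config")
}

#' Preprocess an image into a model input
#'
#' Converts to grayscale (ITU-R 601 luma for color inputs), resizes to the
#' configured input size with bilinear interpolation, and scales to `[0, 1]`.
#' Already-conforming inputs pass through unchanged.
#'
#' @param raster matrix or 3-channel array; 8-bit integer (0-255) or float.
#' @param input_size target `c(height, width)`.
#' @return `input_size` matrix with values in `[0, 1]`.
#' @export
preprocess_image <- function(raster, input_size = c(240, 240)) {
  if (length(raster) == 0) stop("empty image")
  img <- to_gray(raster)
  if (is.integer(raster) || max(img) > 1 + 1e-9) img <- img / 255
  img <- clamp01(img)
  if (!identical(dim(img), as.integer(input_size))) {
    img <- EBImage::imageData(EBImage::resize(EBImage::Image(img),
                                              w = input_size[1], h = input_size[2]))
  }
  img
}

#' Augment a model input
#'
#' Applies, independently: horizontal flip, vertical flip, rotation
#' (expand-canvas then resize back, so no content leaves the frame and the
#' count label is preserved), and zoom (crop-or-pad about the centre). Each
#' transform fires with its configured probability; all randomness comes
#' from the current RNG state, so a fixed seed reproduces the output.
#'
#' @param img input matrix in `[0, 1]`.
#' @param aug augmentation policy (see [model_config()]).
#' @return Augmented matrix, same shape as `img`.
#' @export
augment_image <- function(img, aug = model_config()$aug) {
  H <- nrow(img); W <- ncol(img)
  if (runif(1) < aug$flip_h) img <- img[, W:1, drop = FALSE]
  if (runif(1) < aug$flip_v) img <- img[H:1, , drop = FALSE]
  if (aug$rot > 0 && runif(1) < aug$rot) {
    ang <- runif(1, -aug$rot_range, aug$rot_range)
    img <- rotate_image_expand(img, ang)
  }
  if (aug$zoom > 0 && runif(1) < aug$zoom) {
    z <- runif(1, aug$zoom_range[1], aug$zoom_range[2])
    img <- zoom_image(img, z)
  }
  img
}

# Rotate about the centre with canvas expansion, fill with the border
# median, then resize back to the original shape (a rotation composed with
# a slight zoom-out: keeps all content in frame).
rotate_image_expand <- function(img, angle_deg) {
  th <- angle_deg * pi / 180
  H <- nrow(img); W <- ncol(img)
  fill <- median(c(img[1, ], img[H, ], img[, 1], img[, W]))
  Ho <- ceiling(abs(H * cos(th)) + abs(W * sin(th)))
  Wo <- ceiling(abs(H * sin(th)) + abs(W * cos(th)))
  ic <- c((H - 1) / 2, (W - 1) / 2); oc <- c((Ho - 1) / 2, (Wo - 1) / 2)
  inv <- matrix(c(cos(th), -sin(th), ic[1] - cos(th) * oc[1] + sin(th) * oc[2],
                  sin(th),  cos(th), ic[2] - sin(th) * oc[1] - cos(th) * oc[2]),
                2, 3, byrow = TRUE)
  big <- .warp_affine(img, Ho, Wo, inv, fill)
  EBImage::imageData(EBImage::resize(EBImage::Image(big), w = H, h = W))
}

# Zoom about the centre: z > 1 magnifies (crops), z < 1 shrinks (pads with
# the border median).
zoom_image <- function(img, z) {
  H <- nrow(img); W <- ncol(img)
  fill <- median(c(img[1, ], img[H, ], img[, 1], img[, W]))
  ic <- c((H - 1) / 2, (W - 1) / 2)
  inv <- matrix(c(1 / z, 0, ic[1] * (1 - 1 / z),
                  0, 1 / z, ic[2] * (1 - 1 / z)), 2, 3, byrow = TRUE)
  .warp_affine(img, H, W, inv, fill)
}

#' Build an untrained counting regressor
#'
#' He-initialized weights for the conv stack and a zero-initialized linear
#' head. The final layer emits one unbounded scalar; converting it to a
#' count (rounding, clipping at zero) is the evaluator's job, which keeps
#' MSE gradients unconstrained.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `trap_count_regressor` with fields `weights`,
#'   `config`, `n_params`, `trained`, `history`.
#' @export
build_count_regressor <- function(config = model_config(), seed = 0) {
  with_seed(seed, {
    k <- config$kernel
    cins <- c(1L, config$channels[-length(config$channels)])
    weights <- list()
    for (i in seq_along(config$channels)) {
      fan_in <- k * k * cins[i]
      weights[[paste0("convW", i)]] <-
        matrix(rnorm(fan_in * config$channels[i], sd = sqrt(2 / fan_in)),
               fan_in, config$channels[i])
      weights[[paste0("convb", i)]] <- numeric(config$channels[i])
    }
    cl <- config$channels[length(config$channels)]
    weights$denseW <- matrix(rnorm(cl, sd = sqrt(1 / cl)), cl, 1)
    weights$denseb <- 0
    n_params <- sum(vapply(weights, length, 1L))
    structure(list(weights = weights, config = config, n_params = n_params,
                   trained = FALSE, history = NULL, seed = as.integer(seed)),
              class = "trap_count_regressor")
  })
}

#' @export
print.trap_count_regressor <- function(x, ...) {
  cat(sprintf("<trap_count_regressor: %d conv blocks (%s), %d params, %s>\n",
              length(x$config$channels),
              paste(x$config$channels, collapse = "-"), x$n_params,
              if (x$trained) sprintf("trained (%d epochs)", nrow(x$history))
              else "untrained"))
  invisible(x)
}

# Forward pass on a batch. x: array (H, W, 1, N). Returns predictions and,
# if keep = TRUE, the per-layer caches needed for backprop.
forward_batch <- function(weights, config, x, keep = FALSE,
                          act_hook = NULL) {
  nb <- length(config$channels)
  dims <- dim(x)
  caches <- if (keep) vector("list", nb)
  for (i in seq_len(nb)) {
    z <- .conv2d_fw(x, weights[[paste0("convW", i)]],
                    weights[[paste0("convb", i)]], as.integer(dims))
    a <- pmax(z, 0)
    if (!is.null(act_hook)) a <- act_hook(a, i)
    pl <- .maxpool2_fw(a, as.integer(dim(a)))
    if (keep) caches[[i]] <- list(x = x, dims = dims, relu = z > 0,
                                  a_dims = dim(a), argmax = pl$argmax)
    x <- pl$out
    dims <- dim(x)
  }
  # global average pooling -> (N, C)
  feat <- apply(x, c(3, 4), mean)           # (C, N)
  yhat <- drop(crossprod(feat, weights$denseW)) + weights$denseb
  if (keep) list(yhat = yhat, feat = feat, gap_dims = dims, caches = caches)
  else yhat
}

# Backward pass; returns gradient list matching the weight list.
backward_batch <- function(weights, config, fw, dy) {
  nb <- length(config$channels)
  grads <- list()
  N <- length(dy)
  grads$denseW <- fw$feat %*% matrix(dy, N, 1)
  grads$denseb <- sum(dy)
  # gradient through GAP: spread dy * w over spatial positions
  d <- fw$gap_dims
  per_px <- 1 / (d[1] * d[2])
  dfeat <- weights$denseW %*% matrix(dy, 1, N)   # (C, N)
  dpool <- array(0, d)
  for (n in seq_len(N)) {
    dpool[, , , n] <- rep(dfeat[, n] * per_px, each = d[1] * d[2])
  }
  for (i in rev(seq_len(nb))) {
    cache <- fw$caches[[i]]
    da <- .maxpool2_bw(dpool, cache$argmax, as.integer(cache$a_dims))
    dz <- da * cache$relu
    bw <- .conv2d_bw(cache$x, weights[[paste0("convW", i)]], dz,
                     as.integer(cache$dims))
    grads[[paste0("convW", i)]] <- bw$dW
    grads[[paste0("convb", i)]] <- bw$db
    dpool <- bw$dx
  }
  grads
}

#' Train the counting regressor
#'
#' Minimizes MSE between the scalar prediction and the true count with Adam
#' on shuffled mini-batches, applying the augmentation policy to training
#' images. After each epoch the mean counting accuracy (alpha, predictions
#' rounded) on the validation split is computed; training stops at
#' `max_epochs` or when validation alpha fails to improve for `patience`
#' epochs, and the best-validation weights are restored.
#'
#' @param model an untrained (or trained) `trap_count_regressor`.
#' @param manifest a `trap_manifest` with non-empty `train` and `val` splits.
#' @param bank the sprite bank (needed only if images must be re-rendered).
#' @param seed integer seed governing shuffling and augmentation.
#' @param verbose print one line per epoch.
#' @return The trained model; `$history` holds per-epoch train loss,
#'   validation loss and validation alpha, `$stopped_epoch` the stop point.
#' @export
train_regressor <- function(model, manifest, bank = NULL, seed = 0,
                            verbose = FALSE) {
  config <- model$config
  recs <- manifest$records
  tr <- which(recs$split == "train"); va <- which(recs$split == "val")
  if (length(tr) == 0 || length(va) == 0) stop("missing split: need train and val")
  xtr <- load_images(manifest, tr, bank, config$input_size)
  ytr <- recs$count[tr]
  xva <- load_images(manifest, va, bank, config$input_size)
  yva <- recs$count[va]
  W <- model$weights
  m <- lapply(W, function(w) w * 0); v <- m; t_step <- 0
  best <- list(alpha = -Inf, weights = W, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_alpha = numeric())
  H <- config$input_size[1]; Wd <- config$input_size[2]
  for (epoch in seq_len(config$max_epochs)) {
    ep_seed <- derive_seed(seed, 404L, epoch)
    losses <- with_seed(ep_seed, {
      ord <- sample.int(length(tr))
      batch_losses <- numeric()
      for (b0 in seq(1, length(ord), by = config$batch_size)) {
        bi <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
        nB <- length(bi)
        xb <- array(0, c(H, Wd, 1, nB))
        for (j in seq_len(nB)) {
          xb[, , 1, j] <- augment_image(xtr[, , bi[j]], config$aug)
        }
        fw <- forward_batch(W, config, xb, keep = TRUE)
        err <- fw$yhat - ytr[bi]
        loss <- mean(err^2)
        if (!is.finite(loss)) stop("NaN loss at epoch ", epoch,
                                   "; check learning rate and data scaling")
        dy <- 2 * err / nB
        grads <- backward_batch(W, config, fw, dy)
        t_step <- t_step + 1
        for (nm in names(W)) {
          g <- grads[[nm]]
          m[[nm]] <- config$beta1 * m[[nm]] + (1 - config$beta1) * g
          v[[nm]] <- config$beta2 * v[[nm]] + (1 - config$beta2) * g^2
          mh <- m[[nm]] / (1 - config$beta1^t_step)
          vh <- v[[nm]] / (1 - config$beta2^t_step)
          W[[nm]] <- W[[nm]] - config$lr * mh / (sqrt(vh) + 1e-8)
        }
        batch_losses <- c(batch_losses, loss)
      }
      batch_losses
    })
    pv <- predict_batch(W, config, xva)
    val_loss <- mean((pv - yva)^2)
    val_alpha <- mean(count_accuracy(yva, round_prediction(pv)))
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_loss = val_loss,
                                         val_alpha = val_alpha))
    if (verbose) {
      message(sprintf("epoch %3d  train MSE %.4f  val MSE %.4f  val alpha %.4f",
                      epoch, mean(losses), val_loss, val_alpha))
    }
    if (val_alpha > best$alpha + 1e-9) {
      best <- list(alpha = val_alpha, weights = W, epoch = epoch)
    } else if (epoch - best$epoch >= config$patience) {
      break
    }
  }
  model$weights <- best$weights
  model$trained <- TRUE
  model$history <- history
  model$stopped_epoch <- nrow(history)
  model$best_epoch <- best$epoch
  model$val_alpha <- best$alpha
  model
}

# Load all images of the given record rows into an (H, W, n) array.
load_images <- function(manifest, rows, bank, input_size) {
  n <- length(rows)
  out <- array(0, c(input_size[1], input_size[2], n))
  for (j in seq_len(n)) {
    out[, , j] <- preprocess_image(render_record(manifest, rows[j], bank),
                                   input_size)
  }
  out
}

# Predict on an (H, W, n) array in chunks.
predict_batch <- function(weights, config, x, chunk = 64L, act_hook = NULL) {
  n <- dim(x)[3]
  out <- numeric(n)
  for (b0 in seq(1, n, by = chunk)) {
    bi <- b0:min(b0 + chunk - 1L, n)
    xb <- array(x[, , bi], c(dim(x)[1], dim(x)[2], 1, length(bi)))
    out[bi] <- forward_batch(weights, config, xb, act_hook = act_hook)
  }
  out
}

#' Predict a raw (unrounded) insect count
#'
#' @param model a `trap_count_regressor` or `trap_quantized_regressor`.
#' @param raster one image (matrix/array), a list of images, or an
#'   `(H, W, n)` array of preprocessed inputs.
#' @return Numeric vector of raw scalar predictions, one per image. Use
#'   [round_prediction()] to convert to integer counts.
#' @export
predict_count <- function(model, raster) {
  UseMethod("predict_count")
}

#' @export
predict_count.trap_count_regressor <- function(model, raster) {
  if (!isTRUE(model$trained)) {
    warning("model not trained; predictions are from initial weights")
  }
  x <- as_input_array(raster, model$config$input_size)
  predict_batch(model$weights, model$config, x)
}

as_input_array <- function(raster, input_size) {
  if (is.list(raster)) {
    x <- array(0, c(input_size, length(raster)))
    for (j in seq_along(raster)) x[, , j] <- preprocess_image(raster[[j]], input_size)
    x
  } else if (length(dim(raster)) == 3 && dim(raster)[1] == input_size[1] &&
             dim(raster)[2] == input_size[2]) {
    raster
  } else {
    array(preprocess_image(raster, input_size), c(input_size, 1))
  }
}

#' Serialize a float regressor as a portable flat graph
#'
#' Writes a self-describing binary artifact: a JSON header (architecture,
#' tensor shapes) followed by float32 weight data. This is the "portable
#' graph" whose on-disk size is compared against its 8-bit quantized
#' counterpart.
#'
#' @param model a `trap_count_regressor`.
#' @param path output file path.
#' @return Invisibly, the file size in bytes.
#' @export
serialize_regressor <- function(model, path) {
  header <- jsonlite::toJSON(list(
    format = "trapcount-float32", channels = model$config$channels,
    kernel = model$config$kernel, input_size = model$config$input_size,
    tensors = lapply(model$weights, function(w) dim(w) %||% length(w))),
    auto_unbox = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  hraw <- charToRaw(as.character(header))
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  for (w in model$weights) {
    writeBin(as.numeric(w), con, size = 4L, endian = "little")
  }
  flush(con)
  invisible(file.size(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
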