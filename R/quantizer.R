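#' Post-training 8-bit quantization of a counting regressor
#'
#' Converts the trained float model to 8-bit integer weights so the graph
#' fits microcontroller memory. Convolution and dense weights are quantized
#' symmetrically per output channel to int8; activation ranges are
#' calibrated on a representative set of training images and each ReLU
#' output is quantized affinely to uint8 during inference (input and output
#' tensors stay float32). Inference with the quantized model reproduces the
#' integer arithmetic's rounding, so accuracy can be compared against the
#' float model honestly.
#'
#' @param model a trained `trap_count_regressor`.
#' @param calibration_images list of images, or an `(H, W, n)` array, drawn
#'   from the training split.
#' @param n_cal number of calibration images to use (>= 16; default 128).
#' @param path optional path for the serialized 8-bit artifact; a tempfile
#'   is used when omitted.
#' @return A `trap_quantized_regressor`: int8 weight tensors with per-channel
#'   scales, per-layer activation scales, `size_bytes`, `path`, and the float
#'   `config`.
#' @export
quantize_model <- function(model, calibration_images, n_cal = 128,
                           path = tempfile(fileext = ".tq8")) {
  if (missing(calibration_images) || length(calibration_images) == 0) {
    stop("calibration set required")
  }
  x <- as_input_array(calibration_images, model$config$input_size)
  n_avail <- dim(x)[3]
  if (n_avail < 16) stop("calibration set required: need >= 16 images, got ", n_avail)
  n_cal <- min(n_cal, n_avail)
  x <- x[, , seq_len(n_cal), drop = FALSE]
  config <- model$config
  nb <- length(config$channels)
  # calibrate activation ranges (post-ReLU maxima) on the representative set
  act_max <- numeric(nb)
  hook <- function(a, i) { act_max[i] <<- max(act_max[i], max(a)); a }
  invisible(predict_batch(model$weights, config, x, act_hook = hook))
  act_max[act_max <= 0] <- 1e-6
  qw <- list()
  for (i in seq_len(nb)) {
    qw[[paste0("convW", i)]] <- quantize_per_channel(model$weights[[paste0("convW", i)]])
    qw[[paste0("convb", i)]] <- model$weights[[paste0("convb", i)]]  # float32 bias
  }
  qw$denseW <- quantize_per_channel(model$weights$denseW)
  qw$denseb <- model$weights$denseb
  q <- structure(list(qweights = qw, act_scale = act_max / 255,
                      config = config, n_cal = n_cal,
                      calibration_spec = sprintf("%d training images", n_cal)),
                 class = "trap_quantized_regressor")
  q$path <- path
  q$size_bytes <- serialize_quantized(q, path)
  q
}

#' Draw a representative calibration sample from a manifest
#'
#' Quantization calibrates activation ranges on the calibration images, so
#' the sample must span the count classes: ranges measured on empty scenes
#' clip the activations that multi-insect scenes produce. This helper draws
#' a class-stratified, seeded sample from the training split.
#'
#' @param manifest a `trap_manifest`.
#' @param bank sprite bank, if images must be re-rendered.
#' @param n number of images (default 128).
#' @param seed integer seed.
#' @return List of image matrices.
#' @export
calibration_sample <- function(manifest, bank = NULL, n = 128, seed = 0) {
  recs <- manifest$records
  tr <- which(recs$split == "train")
  if (length(tr) == 0) stop("manifest has no train split")
  classes <- sort(unique(recs$count[tr]))
  per <- ceiling(n / length(classes))
  rows <- with_seed(seed, {
    unlist(lapply(classes, function(k) {
      rk <- tr[recs$count[tr] == k]
      rk[sample.int(length(rk), min(per, length(rk)))]
    }))
  })
  rows <- rows[seq_len(min(n, length(rows)))]
  lapply(rows, function(i) render_record(manifest, i, bank))
}

# Symmetric per-output-channel int8 quantization of a (fan_in x cout) matrix.
quantize_per_channel <- function(W) {
  scale <- apply(abs(W), 2, max) / 127
  scale[scale == 0] <- 1e-12
  qi <- round(sweep(W, 2, scale, "/"))
  storage.mode(qi) <- "integer"
  list(q = qi, scale = scale)
}

dequantize <- function(qt) sweep(qt$q, 2, qt$scale, "*")

#' @export
print.trap_quantized_regressor <- function(x, ...) {
  cat(sprintf("<trap_quantized_regressor: int8 weights, %.3f MB on disk, calibration: %s>\n",
              x$size_bytes / 2^20, x$calibration_spec))
  invisible(x)
}

#' @rdname predict_count
#' @export
predict_count.trap_quantized_regressor <- function(model, raster) {
  x <- as_input_array(raster, model$config$input_size)
  W <- list()
  nb <- length(model$config$channels)
  for (i in seq_len(nb)) {
    W[[paste0("convW", i)]] <- dequantize(model$qweights[[paste0("convW", i)]])
    W[[paste0("convb", i)]] <- model$qweights[[paste0("convb", i)]]
  }
  W$denseW <- dequantize(model$qweights$denseW)
  W$denseb <- model$qweights$denseb
  scales <- model$act_scale
  # simulate uint8 activation quantization after each ReLU
  hook <- function(a, i) {
    s <- scales[i]
    pmin(round(a / s), 255) * s
  }
  # input quantized to uint8 (scale 1/255)
  x <- round(x * 255) / 255
  predict_batch(W, model$config, x, act_hook = hook)
}

# Serialized layout: 4-byte header length, JSON header (arch, scales),
# then int8 weight bytes and float32 biases. Returns file size in bytes.
serialize_quantized <- function(q, path) {
  nb <- length(q$config$channels)
  header <- jsonlite::toJSON(list(
    format = "trapcount-int8", channels = q$config$channels,
    kernel = q$config$kernel, input_size = q$config$input_size,
    act_scale = q$act_scale,
    w_scales = lapply(q$qweights[grep("W", names(q$qweights))],
                      function(t) round(t$scale, 10))),
    auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  hraw <- charToRaw(as.character(header))
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  for (nm in names(q$qweights)) {
    t <- q$qweights[[nm]]
    if (is.list(t)) {
      writeBin(as.raw(as.integer(t$q) %% 256), con)        # int8 bytes
    } else {
      writeBin(as.numeric(t), con, size = 4L, endian = "little")
    }
  }
  flush(con)
  file.size(path)
}

#' Compare float and quantized models on a test set
#'
#' @param float_model a trained `trap_count_regressor`.
#' @param quant_model its `trap_quantized_regressor`.
#' @param test_manifest manifest with a test split.
#' @param bank sprite bank for re-rendering, if needed.
#' @param float_path optional path at which the float portable graph is
#'   serialized for the size comparison (tempfile by default).
#' @return A list: `alpha_float`, `alpha_quant`, `delta` (absolute
#'   difference), `size_float_bytes`, `size_quant_bytes`, and the two
#'   evaluation reports.
#' @export
compare_models <- function(float_model, quant_model, test_manifest,
                           bank = NULL, float_path = tempfile(fileext = ".tf32")) {
  if (!identical(float_model$config$input_size, quant_model$config$input_size)) {
    stop("incompatible models: input sizes differ")
  }
  ev_f <- evaluate_dataset(float_model, test_manifest, bank)
  ev_q <- evaluate_dataset(quant_model, test_manifest, bank)
  size_f <- serialize_regressor(float_model, float_path)
  list(alpha_float = ev_f$mean_alpha, alpha_quant = ev_q$mean_alpha,
       delta = abs(ev_f$mean_alpha - ev_q$mean_alpha),
       size_float_bytes = as.numeric(size_f),
       size_quant_bytes = as.numeric(quant_model$size_bytes),
       report_float = ev_f, report_quant = ev_q)
}
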