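test_that("preprocessing converts, resizes and rescales arbitrary rasters", {
  rgb <- array(runif(60 * 80 * 3), c(60, 80, 3))
  out <- preprocess_image(rgb, c(48, 48))
  expect_identical(dim(out), c(48L, 48L))
  expect_true(all(out >= 0 & out <= 1))
  # constant gray stays constant at the same level
  const <- matrix(0.37, 33, 57)
  expect_equal(range(preprocess_image(const, c(48, 48))), c(0.37, 0.37))
  # already-conforming inputs are a fixed point
  x <- matrix(runif(48 * 48), 48, 48)
  expect_identical(preprocess_image(x, c(48, 48)), x)
  # 8-bit integer input is rescaled to [0, 1]
  x8 <- matrix(as.integer(round(x * 255)), 48, 48)
  expect_equal(max(abs(preprocess_image(x8, c(48, 48)) - x)), 0, tolerance = 1 / 255)
  expect_error(preprocess_image(matrix(numeric(0), 0, 0)), "empty image")
})

test_that("augmentation is identity at zero probability, involutive for flips, seeded", {
  x <- matrix(runif(64 * 64), 64, 64)
  off <- list(flip_h = 0, flip_v = 0, rot = 0, rot_range = 20,
              zoom = 0, zoom_range = c(0.8, 1.2))
  expect_identical(augment_image(x, off), x)
  fh <- with_seed_(1, augment_image(x, list(flip_h = 1, flip_v = 0, rot = 0,
                                            rot_range = 0, zoom = 0,
                                            zoom_range = c(1, 1))))
  expect_identical(fh[, ncol(fh):1], x)
  aug <- model_config()$aug
  a1 <- with_seed_(99, augment_image(x, aug))
  a2 <- with_seed_(99, augment_image(x, aug))
  expect_identical(a1, a2)
})

test_that("augmentation preserves the insect count of composed scenes", {
  cfg <- scene_config(img_size = 64, jitter = FALSE)
  bank <- small_bank()
  bgs <- make_backgrounds(cfg, 17)
  aug_rot <- list(flip_h = 0.5, flip_v = 0.5, rot = 1, rot_range = 20,
                  zoom = 0, zoom_range = c(1, 1))
  set.seed(42)
  for (i in 1:25) {
    k <- (i - 1L) %% 7L
    sc <- compose_scene(bgs, bank, k, seed = 7000 + i, config = cfg)
    a <- augment_image(sc$image, aug_rot)
    # the rotated-and-shrunk scene keeps all insects in frame; count them
    # against the identically transformed background
    bg_a <- abs(a - median(a))
    got <- component_count_oracle(a, matrix(median(sc$image), 64, 64),
                                  threshold = 0.12)
    expect_equal(got, k, info = sprintf("scene %d", i))
  }
})

test_that("the regressor head emits one scalar per image and fits the size budget", {
  cfg <- model_config(input_size = c(64, 64))
  m <- build_count_regressor(cfg, seed = 1)
  x <- array(runif(64 * 64 * 4), c(64, 64, 4))
  y <- suppressWarnings(predict_count(m, x))
  expect_length(y, 4)
  expect_true(all(is.finite(y)))
  # int8 serialization of the default architecture fits the deployment budget
  expect_lte(m$n_params * 1 + 4096, 0.55 * 2^20)
  m2 <- build_count_regressor(cfg, seed = 1)
  expect_identical(m$weights, m2$weights)
  m3 <- build_count_regressor(cfg, seed = 2)
  expect_false(identical(m$weights, m3$weights))
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- model_config(input_size = c(8, 8), channels = c(2, 3))
  m <- build_count_regressor(cfg, seed = 3)
  set.seed(4)
  # jitter the zero-initialized biases: finite differences straddle the
  # ReLU kink at exactly z = 0 (dead patches), where only a subgradient
  # is defined
  for (nm in grep("b", names(m$weights), value = TRUE)) {
    m$weights[[nm]] <- m$weights[[nm]] + rnorm(length(m$weights[[nm]]), sd = 0.05)
  }
  x <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  y <- c(1, 3)
  loss_at <- function(W) mean((trapcount:::forward_batch(W, cfg, x) - y)^2)
  fw <- trapcount:::forward_batch(m$weights, cfg, x, keep = TRUE)
  gr <- trapcount:::backward_batch(m$weights, cfg, fw, 2 * (fw$yhat - y) / 2)
  eps <- 1e-6
  for (nm in names(m$weights)) {
    idx <- sample(length(m$weights[[nm]]), min(8, length(m$weights[[nm]])))
    for (i in idx) {
      Wp <- m$weights; Wp[[nm]][i] <- Wp[[nm]][i] + eps
      Wm <- m$weights; Wm[[nm]][i] <- Wm[[nm]][i] - eps
      num <- (loss_at(Wp) - loss_at(Wm)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   info = sprintf("%s[%d]", nm, i))
    }
  }
})

test_that("training reduces the loss on an easy dataset and records history", {
  cfg <- model_config(input_size = c(64, 64), channels = c(4, 8, 8),
                      max_epochs = 5, patience = 5)
  m <- train_regressor(build_count_regressor(cfg, seed = 5), small_manifest(),
                       small_bank(), seed = 5)
  expect_true(m$trained)
  expect_equal(nrow(m$history), 5L)
  drops <- diff(m$history$train_loss) < 0
  expect_gte(sum(drops), 4L)   # non-increasing in >= 4 of 5 transitions
  expect_true(all(is.finite(m$history$val_alpha)))
})

test_that("a model trained only on empty scenes predicts near zero", {
  cfg <- scene_config(img_size = 64, train_per_class = 12, test_per_class = 4,
                      max_count = 0)
  man0 <- build_dataset(cfg, small_bank(), seed = 31, keep_images = TRUE)
  mcfg <- model_config(input_size = c(64, 64), channels = c(4, 8),
                       max_epochs = 4, patience = 4)
  m <- train_regressor(build_count_regressor(mcfg, seed = 6), man0,
                       small_bank(), seed = 6)
  test_rows <- which(man0$records$split == "test")
  imgs <- lapply(test_rows, function(i) render_record(man0, i, small_bank()))
  expect_true(all(predict_count(m, imgs) < 0.5))
})

test_that("batch prediction equals per-image prediction", {
  m <- tiny_trained_model()
  man <- small_manifest()
  rows <- which(man$records$split == "test")[1:6]
  imgs <- lapply(rows, function(i) render_record(man, i, small_bank()))
  batch <- predict_count(m, imgs)
  single <- vapply(imgs, function(im) predict_count(m, im), 1.0)
  expect_equal(batch, single, tolerance = 1e-12)
  expect_warning(predict_count(build_count_regressor(m$config, 1), imgs[[1]]),
                 "not trained")
})

test_that("float serialization is a self-describing flat graph of the right size", {
  m <- tiny_trained_model()
  f <- withr::local_tempfile(fileext = ".tf32")
  sz <- serialize_regressor(m, f)
  expect_equal(sz, file.size(f))
  # header + 4 bytes per parameter
  con <- file(f, "rb"); on.exit(close(con))
  hlen <- readBin(con, "integer", 1, size = 4, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  expect_equal(header$format, "trapcount-float32")
  expect_equal(sz, 4 + hlen + 4 * m$n_params)
})
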