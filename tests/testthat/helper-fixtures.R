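# Shared fixtures, built once per test run and memoised. All sizes here are
# deliberately small: sprites and scenes scale with resolution, so the
# contracts they exercise are resolution-independent.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 30 procedural sprites at 64 px scene scale, partitioned 70/30.
small_bank <- function() {
  memo("small_bank", {
    partition_sprites(
      procedural_sprite_bank(30, seed = 1, params = sprite_params(scale = 64 / 240)),
      train_fraction = 0.7, seed = 1)
  })
}

small_config <- function(jitter = TRUE) {
  scene_config(img_size = 64, train_per_class = 10, test_per_class = 4,
               jitter = jitter)
}

# A small balanced dataset kept in memory: 10/class train pool, 4/class test.
small_manifest <- function() {
  memo("small_manifest", {
    build_dataset(small_config(), small_bank(), seed = 7, keep_images = TRUE)
  })
}

# A quickly trained model on an easy tiny task (used by unit tests that need
# *a* trained model, not an accurate one).
tiny_trained_model <- function() {
  memo("tiny_trained_model", {
    cfg <- model_config(input_size = c(64, 64), channels = c(4, 8, 8),
                        max_epochs = 3, patience = 3)
    train_regressor(build_count_regressor(cfg, seed = 2), small_manifest(),
                    small_bank(), seed = 2)
  })
}

n_components_test <- function(m) {
  max(EBImage::bwlabel(EBImage::Image(matrix(as.numeric(m > 0), nrow(m)))))
}

with_seed_ <- function(seed, code) { set.seed(seed); force(code) }

# Oracle: count insects as connected components of the difference from the
# scene's own background (valid when jitter is off).
component_count_oracle <- function(image, background, threshold = 0.05) {
  d <- abs(image - background) > threshold
  if (!any(d)) return(0L)
  max(EBImage::bwlabel(EBImage::Image(matrix(as.numeric(d), nrow(d)))))
}
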