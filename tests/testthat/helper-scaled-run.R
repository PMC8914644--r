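# The desk-scale replication run shared by the accuracy and quantization
# tests: procedural sprites, 64 px scenes, 300 scenes/class train pool
# (split 70/30), 50 scenes/class test, training capped at 30 epochs with a
# pinned seed. Built once per test session.
scaled_run <- function() {
  memo("scaled_run", {
    seed <- 0
    bank <- partition_sprites(
      procedural_sprite_bank(100, seed = seed,
                             params = sprite_params(scale = 64 / 240)),
      train_fraction = 0.7, seed = seed)
    cfg <- scene_config(img_size = 64, train_per_class = 300,
                        test_per_class = 50)
    man <- build_dataset(cfg, bank, seed = seed, keep_images = TRUE)
    mcfg <- model_config(input_size = c(64, 64), max_epochs = 30,
                         patience = 20)
    model <- train_regressor(build_count_regressor(mcfg, seed = seed),
                             man, bank, seed = seed)
    list(bank = bank, manifest = man, model = model,
         eval = evaluate_dataset(model, man, bank))
  })
}
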