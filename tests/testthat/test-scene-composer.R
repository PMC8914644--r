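test_that("a zero-count scene is bit-identical to its background when jitter is off", {
  cfg <- small_config(jitter = FALSE)
  bgs <- make_backgrounds(cfg, 3)
  sc <- compose_scene(bgs, small_bank(), 0, seed = 21, config = cfg)
  expect_identical(sc$image, bgs[[sc$background_id]])
  expect_equal(nrow(sc$placements), 0L)
})

test_that("composition places the exact count with pairwise-disjoint, in-bounds masks", {
  cfg <- small_config(jitter = FALSE)
  bgs <- make_backgrounds(cfg, 3)
  sc <- compose_scene(bgs, small_bank(), 3, seed = 33, config = cfg)
  expect_equal(sc$count, 3L)
  expect_equal(nrow(sc$placements), 3L)
  expect_match(sc$filename, "count3")
  # rebuild each placed mask and check pairwise-empty intersections
  bg <- bgs[[sc$background_id]]
  full <- matrix(0L, cfg$img_size, cfg$img_size)
  for (i in seq_len(3)) {
    p <- sc$placements[i, ]
    rs <- rotate_sprite(small_bank()$sprites[[p$sprite_index]], p$rotation_deg)
    m <- rs$alpha >= 0.5
    rr <- (p$row + 1):(p$row + nrow(m)); cc <- (p$col + 1):(p$col + ncol(m))
    expect_true(min(rr) >= 1 && max(rr) <= cfg$img_size &&
                  min(cc) >= 1 && max(cc) <= cfg$img_size)
    full[rr, cc] <- full[rr, cc] + m
  }
  expect_lte(max(full), 1L)
  # the image differs from its background exactly inside the placed masks
  expect_setequal(which(abs(sc$image - bg) > 1e-12), which(full == 1L))
})

test_that("scene composition is bit-for-bit reproducible from its seed", {
  cfg <- small_config()
  bgs <- make_backgrounds(cfg, 3)
  a <- compose_scene(bgs, small_bank(), 4, seed = 55, config = cfg)
  b <- compose_scene(bgs, small_bank(), 4, seed = 55, config = cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$placements, b$placements)
  d <- compose_scene(bgs, small_bank(), 4, seed = 56, config = cfg)
  expect_false(identical(a$image, d$image))
})

test_that("recounting connected components recovers the true label (jitter off)", {
  cfg <- scene_config(img_size = 48, jitter = FALSE)
  bank <- partition_sprites(
    procedural_sprite_bank(20, seed = 9, params = sprite_params(scale = 48 / 240)),
    0.7, seed = 9)
  bgs <- make_backgrounds(cfg, 13)
  counts <- rep(0:6, length.out = 300)
  for (i in seq_along(counts)) {
    sc <- compose_scene(bgs, bank, counts[i], seed = 1000 + i, config = cfg)
    got <- component_count_oracle(sc$image, bgs[[sc$background_id]])
    expect_equal(got, counts[i], info = sprintf("scene %d", i))
  }
})

test_that("build_dataset honours class balance, split sizes, and sprite isolation", {
  man <- small_manifest()
  cfg <- small_config()
  classes <- 0:cfg$max_count
  n_train <- floor(cfg$train_per_class * cfg$trainval_split + 0.5)
  for (k in classes) {
    expect_equal(sum(man$records$split == "train" & man$records$count == k), n_train)
    expect_equal(sum(man$records$split == "val" & man$records$count == k),
                 cfg$train_per_class - n_train)
    expect_equal(sum(man$records$split == "test" & man$records$count == k),
                 cfg$test_per_class)
  }
  expect_equal(sum(man$per_class_counts), nrow(man$records))
  # test scenes draw exclusively from the test partition of the sprite bank
  test_rows <- which(man$records$split == "test" & man$records$count > 0)
  bgs <- make_backgrounds(cfg, man$seed)
  test_idx <- which(small_bank()$partition == "test")
  for (i in head(test_rows, 8)) {
    sc <- compose_scene(bgs, small_bank(), man$records$count[i],
                        man$records$seed[i], split = "test", config = cfg)
    expect_true(all(sc$placements$sprite_index %in% test_idx))
    expect_identical(sc$image, man$images[[man$records$filename[i]]])
  }
})

test_that("whole-dataset generation is reproducible from (config, seed)", {
  cfg <- scene_config(img_size = 48, train_per_class = 4, test_per_class = 2)
  bank <- partition_sprites(
    procedural_sprite_bank(24, seed = 2, params = sprite_params(scale = 48 / 240)),
    0.7, seed = 2)
  m1 <- build_dataset(cfg, bank, seed = 3, keep_images = TRUE)
  m2 <- build_dataset(cfg, bank, seed = 3, keep_images = TRUE)
  expect_identical(m1$records, m2$records)
  expect_identical(m1$images, m2$images)
})

test_that("manifests roundtrip through CSV + JSON and detect tampering", {
  dir <- withr::local_tempdir()
  man <- small_manifest()
  base <- file.path(dir, "manifest")
  write_manifest(man, base)
  back <- read_manifest(base)
  expect_identical(back$records$filename, man$records$filename)
  expect_identical(back$records$count, man$records$count)
  expect_identical(back$seed, man$seed)
  expect_equal(back$config$img_size, man$config$img_size)
  expect_equal(as.vector(back$per_class_counts), as.vector(man$per_class_counts))
  # tamper with the stored per-class counts
  js <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  js$per_class_counts$Freq[1] <- js$per_class_counts$Freq[1] + 1
  jsonlite::write_json(js, paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  expect_error(read_manifest(base), "validation failed")
  # missing image file is named in the error
  dir2 <- withr::local_tempdir()
  cfg <- scene_config(img_size = 48, train_per_class = 2, test_per_class = 1)
  bank <- partition_sprites(
    procedural_sprite_bank(24, seed = 2, params = sprite_params(scale = 48 / 240)),
    0.7, seed = 2)
  m3 <- build_dataset(cfg, bank, seed = 4, out_dir = file.path(dir2, "img"))
  write_manifest(m3, file.path(dir2, "manifest"))
  victim <- m3$records$filename[5]
  unlink(file.path(dir2, "img", victim))
  expect_error(read_manifest(file.path(dir2, "manifest")), victim, fixed = TRUE)
})
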