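test_that("procedural sprites are seed-deterministic and pairwise distinct", {
  p <- sprite_params(scale = 64 / 240)
  a <- synthesize_procedural_sprite(7, p)
  b <- synthesize_procedural_sprite(7, p)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$alpha, b$alpha)
  masks <- lapply(0:99, function(s) synthesize_procedural_sprite(s, p)$alpha)
  keys <- vapply(masks, function(m) paste(dim(m)[1], dim(m)[2], sum(m),
                                          sum(which(m >= 0.5))), "")
  expect_equal(length(unique(keys)), 100L)
})

test_that("procedural masks are connected, nonempty, and border-trimmed over many seeds", {
  p <- sprite_params(scale = 48 / 240)
  for (s in seq_len(500)) {
    sp <- synthesize_procedural_sprite(s, p)
    m <- sp$alpha >= 0.5
    expect_true(any(m))
    expect_identical(dim(sp$pixels), dim(sp$alpha))
    # trimmed: mask touches every raster border
    expect_true(any(m[1, ]) && any(m[nrow(m), ]) && any(m[, 1]) && any(m[, ncol(m)]))
    if (s <= 100) expect_equal(n_components_test(m), 1L)
  }
})

test_that("a sprite with exactly 6 appendages shows 6 protruding limbs", {
  p <- sprite_params(n_appendage_range = c(6L, 6L), wing_prob = 0)
  hits <- 0L
  for (s in 1:10) {
    sp <- synthesize_procedural_sprite(s, p)
    g <- attr(sp, "geom")
    expect_equal(g$n_appendages, 6L)
    # subtract the recorded body (ellipse + head disc, slightly padded):
    # what protrudes is one connected component per limb
    m <- sp$alpha >= 0.5
    body <- trapcount:::ellipse_mask(nrow(m), ncol(m), g$center[1], g$center[2],
                                     g$semi_axes[1] + 1.5, g$semi_axes[2] + 1.5, 0) |
      trapcount:::ellipse_mask(nrow(m), ncol(m),
                               g$center[1] + g$semi_axes[1] * 0.95, g$center[2],
                               g$head_r + 1.5, g$head_r + 1.5, 0)
    limbs <- m & !body
    k <- n_components_test(limbs)
    if (abs(k - 6L) <= 1L) hits <- hits + 1L
  }
  expect_gte(hits, 8L)   # limbs may cross and merge occasionally
})

test_that("degenerate morphology parameters are rejected", {
  expect_error(sprite_params(body_len_range = c(0, 0)), "invalid morphology")
  expect_error(sprite(matrix(0.5, 4, 4), matrix(0, 4, 4)), "empty")
  expect_error(sprite(matrix(0.5, 4, 4), matrix(1, 3, 3)), "identical shapes")
})

test_that("partition covers the bank, is disjoint, reproducible, and splits 100 as 70/30", {
  bank <- procedural_sprite_bank(100, seed = 3,
                                 params = sprite_params(scale = 48 / 240))
  b1 <- partition_sprites(bank, 0.7, seed = 5)
  expect_equal(sum(b1$partition == "train"), 70L)
  expect_equal(sum(b1$partition == "test"), 30L)
  expect_setequal(union(which(b1$partition == "train"),
                        which(b1$partition == "test")), seq_len(100))
  b2 <- partition_sprites(bank, 0.7, seed = 5)
  expect_identical(b1$partition, b2$partition)
  for (frac in c(0.3, 0.5, 0.77)) {
    bp <- partition_sprites(bank, frac, seed = 11)
    expect_equal(sum(bp$partition == "train"), floor(100 * frac + 0.5))
    expect_length(intersect(which(bp$partition == "train"),
                            which(bp$partition == "test")), 0)
  }
  one <- procedural_sprite_bank(1, seed = 3, params = sprite_params(scale = 48 / 240))
  expect_error(partition_sprites(one, 0.7, seed = 1), "degenerate partition")
})

test_that("sprite banks roundtrip through RGBA PNG with deterministic order", {
  dir <- withr::local_tempdir()
  bank <- procedural_sprite_bank(5, seed = 4, params = sprite_params(scale = 48 / 240))
  write_sprite_images(bank, dir)
  r1 <- load_sprite_images(dir)
  r2 <- load_sprite_images(dir)
  expect_equal(length(r1), 5L)
  expect_identical(vapply(r1$sprites, `[[`, "", "species_tag"),
                   vapply(r2$sprites, `[[`, "", "species_tag"))
  for (i in 1:5) {
    expect_identical(dim(r1$sprites[[i]]$alpha), dim(bank$sprites[[i]]$alpha))
    expect_equal(r1$sprites[[i]]$alpha >= 0.5, bank$sprites[[i]]$alpha >= 0.5)
    expect_identical(r1$sprites[[i]]$pixels, r2$sprites[[i]]$pixels)
  }
  expect_error(load_sprite_images(withr::local_tempdir()), "no sprites found")
})

test_that("extract_cutout recovers a composited sprite mask and its pixels", {
  cfg <- scene_config(img_size = 240, jitter = FALSE)
  bg <- make_backgrounds(cfg, 5)[[1]]
  # a representative mid-size insect (the documented use of the extractor)
  sp <- synthesize_procedural_sprite(3, sprite_params(body_len_range = c(40, 60)))
  m <- sp$alpha >= 0.5
  photo <- bg
  r0 <- 60L; c0 <- 60L
  h <- nrow(m); w <- ncol(m)
  tile <- photo[r0:(r0 + h - 1), c0:(c0 + w - 1)]
  tile[m] <- sp$pixels[m]
  photo[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- tile
  cut <- extract_cutout(photo, bg)
  true_mask <- matrix(FALSE, nrow(bg), ncol(bg))
  true_mask[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- m
  anchor <- attr(cut, "anchor")
  rm <- cut$alpha >= 0.5
  rec_mask <- matrix(FALSE, nrow(bg), ncol(bg))
  rec_mask[anchor["row"]:(anchor["row"] + nrow(rm) - 1),
           anchor["col"]:(anchor["col"] + ncol(rm) - 1)] <- rm
  iou <- sum(rec_mask & true_mask) / sum(rec_mask | true_mask)
  expect_gte(iou, 0.90)
  # roundtrip: recomposite the recovered sprite at its anchor
  recon <- bg
  tile <- recon[anchor["row"]:(anchor["row"] + nrow(rm) - 1),
                anchor["col"]:(anchor["col"] + ncol(rm) - 1)]
  tile[rm] <- cut$pixels[rm]
  recon[anchor["row"]:(anchor["row"] + nrow(rm) - 1),
        anchor["col"]:(anchor["col"] + ncol(rm) - 1)] <- tile
  inside <- rec_mask & true_mask
  expect_lte(max(abs(recon[inside] - photo[inside])), 2 / 255)
  expect_error(extract_cutout(bg, bg), "no foreground detected")
})
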