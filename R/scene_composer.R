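#' Scene generator configuration
#'
#' Bundles every knob of the labeled-scene generator. The defaults reproduce
#' the reference database design: balanced classes 0-6 with 2,000 train-pool
#' scenes per class (split 70/30 into train/validation at the image level,
#' i.e. 9,800/4,200) and 200 test scenes per class (1,400 total), composed at
#' 240 x 240 grayscale. Backgrounds are a procedurally generated trap-floor
#' texture family that "differ slightly": `n_backgrounds` low-frequency noise
#' variants plus optional per-scene brightness jitter (+/-5%) and faint
#' smooth noise.
#'
#' @param img_size scene side length in pixels (square scenes).
#' @param max_count maximum insects per scene; classes are `0:max_count`.
#' @param train_per_class train-pool scenes per class.
#' @param test_per_class test scenes per class.
#' @param trainval_split fraction of the train pool used for training (the
#'   rest is validation); applied per class, ties toward train.
#' @param n_backgrounds number of distinct background variants.
#' @param base_gray mean background luminance in `[0, 1]`.
#' @param jitter apply per-scene brightness jitter and faint noise.
#' @param max_attempts placement attempts per sprite before declaring the
#'   scene overcrowded.
#' @param sprite_params morphology ranges for procedural sprites, from
#'   [sprite_params()]; defaults scale with `img_size` so sprites keep the
#'   same proportion of the scene at any resolution.
#' @return A list of class `trap_scene_config`.
#' @export
scene_config <- function(img_size = 240, max_count = 6,
                         train_per_class = 2000, test_per_class = 200,
                         trainval_split = 0.7, n_backgrounds = 8,
                         base_gray = 0.82, jitter = TRUE, max_attempts = 200,
                         sprite_params = NULL) {
  stopifnot(img_size >= 32, max_count >= 0, trainval_split > 0, trainval_split < 1)
  if (is.null(sprite_params)) {
    sprite_params <- trapcount::sprite_params(scale = img_size / 240)
  }
  structure(list(img_size = as.integer(img_size), max_count = as.integer(max_count),
                 train_per_class = as.integer(train_per_class),
                 test_per_class = as.integer(test_per_class),
                 trainval_split = trainval_split,
                 n_backgrounds = as.integer(n_backgrounds),
                 base_gray = base_gray, jitter = jitter,
                 max_attempts = as.integer(max_attempts),
                 sprite_params = sprite_params),
            class = "trap_scene_config")
}

# Mark a placed mask into the occupancy grid with a 2-px dilation halo:
# distinct insects stay at least 3 px apart, so each placed mask remains its
# own connected component even after the mild resampling blur of rotation
# or zoom augmentation (a 1-px gap can bridge under bilinear warping).
mark_occupied <- function(occupied, m, r0, c0) {
  h <- nrow(m); w <- ncol(m); S <- nrow(occupied)
  p <- 2L
  pad <- matrix(FALSE, h + 2L * p, w + 2L * p)
  pad[(p + 1L):(h + p), (p + 1L):(w + p)] <- m
  dil <- pad
  idx_r <- row(pad)[pad]; idx_c <- col(pad)[pad]
  for (dr in -p:p) for (dc in -p:p) {
    if ((dr == 0 && dc == 0) || dr * dr + dc * dc > p * p + 1L) next
    dil[pmin(pmax(idx_r + dr, 1L), h + 2L * p) +
          (h + 2L * p) * (pmin(pmax(idx_c + dc, 1L), w + 2L * p) - 1L)] <- TRUE
  }
  rr <- (r0 - p):(r0 + h + p - 1L); cc <- (c0 - p):(c0 + w + p - 1L)
  keep_r <- rr >= 1L & rr <= S; keep_c <- cc >= 1L & cc <= S
  occupied[rr[keep_r], cc[keep_c]] <-
    occupied[rr[keep_r], cc[keep_c]] | dil[keep_r, keep_c]
  occupied
}

# Smooth low-frequency texture: coarse uniform grid upsampled bilinearly.
smooth_noise <- function(size, coarse, amplitude) {
  g <- matrix(runif(coarse * coarse, -1, 1), coarse, coarse)
  up <- EBImage::resize(EBImage::Image(g), w = size, h = size)
  amplitude * EBImage::imageData(up)
}

#' Generate the background set
#'
#' @param config a [scene_config()].
#' @param seed integer seed.
#' @return List of `config$n_backgrounds` grayscale matrices in `[0, 1]`.
#' @export
make_backgrounds <- function(config, seed = 0) {
  lapply(seq_len(config$n_backgrounds), function(i) {
    with_seed(derive_seed(seed, 202L, i), {
      bg <- config$base_gray + smooth_noise(config$img_size, 6L, 0.04) +
        smooth_noise(config$img_size, 20L, 0.015)
      clamp01(bg)
    })
  })
}

#' Compose one labeled trap scene
#'
#' Picks a background uniformly, draws `count` distinct sprites from the
#' requested partition split, rotates each uniformly in `[0, 360)` degrees,
#' and places them by rejection sampling so that the binary alpha masks are
#' pairwise disjoint and fully inside the frame. The true count is exact by
#' construction. Identical inputs and seed give a bit-identical scene.
#'
#' @param backgrounds list of background matrices from [make_backgrounds()].
#' @param bank a partitioned (or unpartitioned) `trap_sprite_bank`.
#' @param count number of insects to place, `0 <= count <= max_count`.
#' @param seed integer seed.
#' @param split which sprite partition to draw from (`"train"` or `"test"`).
#' @param config a [scene_config()].
#' @return A list of class `trap_scene`: `image` (matrix in `[0,1]`),
#'   `count`, `placements` (data.frame: sprite_index, rotation_deg, row, col;
#'   0-based top-left anchors), `background_id`, `split`, `filename`, `seed`.
#' @export
compose_scene <- function(backgrounds, bank, count, seed,
                          split = "train", config = scene_config()) {
  stopifnot(count >= 0, count <= config$max_count)
  pool <- bank_split(bank, split)
  if (count > 0 && length(pool) < count) {
    stop("sprite split '", split, "' has fewer than ", count, " sprites")
  }
  with_seed(seed, {
    bg_id <- sample.int(length(backgrounds), 1L)
    img <- backgrounds[[bg_id]]
    if (config$jitter) {
      img <- clamp01(img * runif(1, 0.95, 1.05) +
                       smooth_noise(config$img_size, 12L, 0.01))
    }
    S <- config$img_size
    occupied <- matrix(FALSE, S, S)
    placements <- data.frame(sprite_index = integer(), rotation_deg = numeric(),
                             row = integer(), col = integer())
    if (count > 0) {
      idx <- pool[sample.int(length(pool), count)]   # without replacement
      for (si in idx) {
        ang <- runif(1, 0, 360)
        rs <- rotate_sprite(bank$sprites[[si]], ang)
        m <- rs$alpha >= 0.5
        h <- nrow(m); w <- ncol(m)
        if (h > S || w > S) stop("scene overcrowded: sprite larger than scene")
        placed <- FALSE
        for (attempt in seq_len(config$max_attempts)) {
          r0 <- sample.int(S - h + 1L, 1L)
          c0 <- sample.int(S - w + 1L, 1L)
          sub <- occupied[r0:(r0 + h - 1L), c0:(c0 + w - 1L)]
          if (!any(sub & m)) {
            occupied <- mark_occupied(occupied, m, r0, c0)
            tile <- img[r0:(r0 + h - 1L), c0:(c0 + w - 1L)]
            tile[m] <- rs$pixels[m]
            img[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- tile
            placements <- rbind(placements, data.frame(
              sprite_index = si, rotation_deg = ang,
              row = r0 - 1L, col = c0 - 1L))
            placed <- TRUE
            break
          }
        }
        if (!placed) stop("scene overcrowded: placement failed after ",
                          config$max_attempts, " attempts")
      }
    }
    structure(list(image = img, count = as.integer(count),
                   placements = placements, background_id = bg_id,
                   split = split,
                   filename = sprintf("%s_%09d_count%d.png", split,
                                      seed %% 1000000000L, count),
                   seed = as.integer(seed)),
              class = "trap_scene")
  })
}

#' Build the full labeled dataset
#'
#' Repeats scene composition until the configured class balance is reached:
#' by default 2,000 train-pool scenes per class 0-6 (14,000, split 9,800
#' train / 4,200 validation at the image level) and 200 test scenes per class
#' (1,400), test scenes drawing exclusively from test-partition sprites.
#' Scenes that fail placement are regenerated with a fresh derived seed,
#' never mislabeled.
#'
#' @param config a [scene_config()].
#' @param bank a partitioned `trap_sprite_bank`.
#' @param seed integer master seed; every scene seed derives from it.
#' @param out_dir if non-`NULL`, scenes are written there as 8-bit grayscale
#'   PNGs named `{split}_{id}_count{Mc}.png`.
#' @param keep_images if `TRUE`, composed images are kept in memory in the
#'   manifest (`$images`, named by filename). For the default 240 px, 15,400
#'   scene configuration prefer `out_dir`.
#' @return A `trap_manifest`: `records` data.frame (filename, split, count,
#'   background_id, seed), `per_class_counts` (train pool and test, by
#'   class), `seed`, `config`, and optionally `images`.
#' @export
build_dataset <- function(config = scene_config(), bank, seed = 0,
                          out_dir = NULL, keep_images = FALSE) {
  backgrounds <- make_backgrounds(config, seed)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  classes <- 0:config$max_count
  records <- list(); images <- list()
  scene_id <- 0L
  add_scene <- function(count, split, sprite_split, k) {
    # regenerate on overcrowding with a fresh derived seed
    for (try in 0:24) {
      s <- derive_seed(seed, 303L, match(split, c("train", "val", "test")),
                       count, k, try)
      sc <- tryCatch(compose_scene(backgrounds, bank, count, s,
                                   split = sprite_split, config = config),
                     error = function(e) {
                       if (grepl("overcrowded", conditionMessage(e))) NULL else stop(e)
                     })
      if (!is.null(sc)) {
        sc$split <- split
        sc$filename <- sprintf("%s_%06d_count%d.png", split, scene_id, count)
        return(sc)
      }
    }
    stop("scene overcrowded: could not place ", count,
         " sprites after repeated regeneration")
  }
  for (cls in classes) {
    n_train <- floor(config$train_per_class * config$trainval_split + 0.5)
    n_val <- config$train_per_class - n_train
    plan <- c(rep("train", n_train), rep("val", n_val),
              rep("test", config$test_per_class))
    for (k in seq_along(plan)) {
      split <- plan[k]
      sprite_split <- if (split == "test") "test" else "train"
      sc <- add_scene(cls, split, sprite_split, k)
      scene_id <- scene_id + 1L
      sc$filename <- sprintf("%s_%06d_count%d.png", split, scene_id, cls)
      records[[length(records) + 1L]] <- data.frame(
        filename = sc$filename, split = split, count = cls,
        background_id = sc$background_id, seed = sc$seed)
      if (!is.null(out_dir)) {
        EBImage::writeImage(EBImage::Image(sc$image),
                            file.path(out_dir, sc$filename))
      }
      if (keep_images) images[[sc$filename]] <- sc$image
    }
  }
  records <- do.call(rbind, records)
  stopifnot(!anyDuplicated(records$filename))
  manifest <- structure(list(records = records,
                             per_class_counts = table(factor(records$count, levels = classes),
                                                      records$split),
                             seed = as.integer(seed), config = config,
                             out_dir = out_dir),
                        class = "trap_manifest")
  if (keep_images) manifest$images <- images
  manifest
}

#' @export
print.trap_manifest <- function(x, ...) {
  cat(sprintf("<trap_manifest: %d scenes (%s), classes 0-%d, seed %d>\n",
              nrow(x$records),
              paste(sprintf("%s %d", names(table(x$records$split)),
                            as.integer(table(x$records$split))), collapse = ", "),
              x$config$max_count, x$seed))
  invisible(x)
}

#' Re-render a scene recorded in a manifest
#'
#' Scenes are deterministic in their recorded seed, so a manifest plus the
#' sprite bank regenerates any image bit-for-bit without storing pixels.
#'
#' @param manifest a `trap_manifest`.
#' @param i record row index.
#' @param bank the sprite bank used to build the dataset.
#' @return The scene image matrix.
#' @export
render_record <- function(manifest, i, bank) {
  rec <- manifest$records[i, ]
  if (!is.null(manifest$images)) return(manifest$images[[rec$filename]])
  if (!is.null(manifest$out_dir) &&
      file.exists(file.path(manifest$out_dir, rec$filename))) {
    return(EBImage::imageData(EBImage::readImage(
      file.path(manifest$out_dir, rec$filename))))
  }
  backgrounds <- make_backgrounds(manifest$config, manifest$seed)
  sprite_split <- if (rec$split == "test") "test" else "train"
  compose_scene(backgrounds, bank, rec$count, rec$seed,
                split = sprite_split, config = manifest$config)$image
}

#' Write a manifest to disk
#'
#' One CSV row per scene plus a JSON sidecar holding the generator
#' configuration, master seed and per-class counts.
#'
#' @param manifest a `trap_manifest`.
#' @param path basename for `<path>.csv` and `<path>.json`.
#' @return Invisibly, the two file paths.
#' @export
write_manifest <- function(manifest, path) {
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  write.csv(manifest$records, csv, row.names = FALSE)
  cfg <- manifest$config
  side <- list(seed = manifest$seed,
               per_class_counts = as.data.frame(manifest$per_class_counts),
               config = unclass(cfg), out_dir = manifest$out_dir)
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv, js))
}

#' Read a manifest from disk
#'
#' Validates the stored per-class counts against the scene records and, when
#' the dataset was written with images, that every referenced image file
#' exists.
#'
#' @param path basename used in [write_manifest()].
#' @param check_images verify referenced PNG files exist.
#' @return A `trap_manifest`.
#' @export
read_manifest <- function(path, check_images = TRUE) {
  records <- read.csv(paste0(path, ".csv"), stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- side$config
  config <- scene_config(img_size = cfg$img_size, max_count = cfg$max_count,
                         train_per_class = cfg$train_per_class,
                         test_per_class = cfg$test_per_class,
                         trainval_split = cfg$trainval_split,
                         n_backgrounds = cfg$n_backgrounds,
                         base_gray = cfg$base_gray, jitter = cfg$jitter,
                         max_attempts = cfg$max_attempts,
                         sprite_params = lapply(cfg$sprite_params, unlist))
  classes <- 0:config$max_count
  got <- table(factor(records$count, levels = classes), records$split)
  stored <- side$per_class_counts
  if (nrow(stored) > 0) {
    for (r in seq_len(nrow(stored))) {
      if (got[as.character(stored$Var1[r]), as.character(stored$Var2[r])] !=
          stored$Freq[r]) {
        stop("manifest validation failed: per-class counts do not match records")
      }
    }
    if (sum(stored$Freq) != nrow(records)) {
      stop("manifest validation failed: per-class counts do not sum to records")
    }
  }
  out_dir <- side$out_dir
  if (check_images && !is.null(out_dir) && !is.na(out_dir)) {
    missing <- !file.exists(file.path(out_dir, records$filename))
    if (any(missing)) {
      stop("missing image file: ", records$filename[which(missing)[1]])
    }
  }
  structure(list(records = records, per_class_counts = got,
                 seed = as.integer(side$seed), config = config,
                 out_dir = if (is.null(out_dir) || length(out_dir) == 0) NULL else out_dir),
            class = "trap_manifest")
}
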