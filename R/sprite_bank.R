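#' Insect sprites and sprite banks
#'
#' A *sprite* is a single insect cutout: a luminance raster in `[0, 1]`
#' together with a transparency mask, trimmed to the tight bounding box of
#' the mask. Sprites are the unit of composition: the scene composer pastes
#' them onto trap backgrounds to synthesize labeled images. A *sprite bank*
#' is an ordered collection of sprites with a disjoint train/test partition,
#' mirroring the reference database design in which 100 insect cutouts are
#' split 70/30 so that no insect photographed for training ever appears in a
#' test scene.
#'
#' @param pixels numeric matrix in `[0, 1]`, the sprite luminance.
#' @param alpha numeric matrix, same shape as `pixels`; values `>= 0.5` are
#'   treated as foreground when compositing.
#' @param species_tag free-text identifier.
#' @param origin `"real_cutout"` or `"procedural"`.
#' @return An object of class `trap_sprite`.
#' @export
sprite <- function(pixels, alpha, species_tag = "unknown",
                   origin = c("procedural", "real_cutout")) {
  origin <- match.arg(origin)
  if (!identical(dim(pixels), dim(alpha))) {
    stop("pixels and alpha must have identical shapes")
  }
  if (!any(alpha >= 0.5)) stop("sprite alpha mask is empty")
  bb <- mask_bbox(alpha >= 0.5)
  pixels <- pixels[bb["r0"]:bb["r1"], bb["c0"]:bb["c1"], drop = FALSE]
  alpha <- alpha[bb["r0"]:bb["r1"], bb["c0"]:bb["c1"], drop = FALSE]
  structure(list(pixels = clamp01(pixels), alpha = clamp01(alpha),
                 species_tag = species_tag, origin = origin),
            class = "trap_sprite")
}

#' @export
print.trap_sprite <- function(x, ...) {
  cat(sprintf("<trap_sprite '%s' (%s), %d x %d px, %d mask px>\n",
              x$species_tag, x$origin, nrow(x$alpha), ncol(x$alpha),
              sum(x$alpha >= 0.5)))
  invisible(x)
}

new_sprite_bank <- function(sprites, partition = NULL, seed = NA_integer_) {
  structure(list(sprites = sprites, partition = partition, seed = seed),
            class = "trap_sprite_bank")
}

#' @export
print.trap_sprite_bank <- function(x, ...) {
  cat(sprintf("<trap_sprite_bank: %d sprites", length(x$sprites)))
  if (!is.null(x$partition)) {
    cat(sprintf(", %d train / %d test", sum(x$partition == "train"),
                sum(x$partition == "test")))
  }
  cat(">\n")
  invisible(x)
}

#' @export
length.trap_sprite_bank <- function(x) length(x$sprites)

# Sprites belonging to one side of the partition (all sprites if unpartitioned).
bank_split <- function(bank, split) {
  if (is.null(bank$partition)) return(seq_along(bank$sprites))
  which(bank$partition == split)
}

#' Load sprite images from a directory
#'
#' Reads every raster image (PNG/JPEG/TIFF) in `directory_path` in
#' lexicographic filename order. Images with an alpha channel use it as the
#' cutout mask; images without one get a full (all-opaque) mask and are
#' flagged `cutout_pending` — run [extract_cutout()] with a background shot
#' to recover a proper mask for those.
#'
#' @param directory_path directory of image files.
#' @param species_from_filename if `TRUE` (default) the species tag is the
#'   filename without extension.
#' @return A `trap_sprite_bank` (unpartitioned).
#' @export
load_sprite_images <- function(directory_path, species_from_filename = TRUE) {
  files <- sort(list.files(directory_path, full.names = TRUE,
                           pattern = "\\.(png|jpe?g|tiff?)$", ignore.case = TRUE))
  if (length(files) == 0L) stop("no sprites found in ", directory_path)
  sprites <- lapply(files, function(f) {
    img <- tryCatch(EBImage::readImage(f),
                    error = function(e) stop("failed to read sprite file '",
                                             basename(f), "': ",
                                             conditionMessage(e), call. = FALSE))
    a <- EBImage::imageData(img)
    tag <- if (species_from_filename) tools::file_path_sans_ext(basename(f)) else "unknown"
    d <- dim(a)
    if (length(d) == 3L && d[3] == 4L) {
      s <- sprite(to_gray(a[, , 1:3, drop = FALSE]), a[, , 4],
                  species_tag = tag, origin = "real_cutout")
    } else if (length(d) == 3L && d[3] == 2L) {
      s <- sprite(a[, , 1], a[, , 2], species_tag = tag, origin = "real_cutout")
    } else {
      px <- to_gray(a)
      s <- sprite(px, matrix(1, nrow(px), ncol(px)),
                  species_tag = tag, origin = "real_cutout")
      attr(s, "cutout_pending") <- TRUE
    }
    s
  })
  new_sprite_bank(sprites)
}

#' Write a sprite bank to RGBA PNG files
#'
#' @param bank a `trap_sprite_bank`.
#' @param directory output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_sprite_images <- function(bank, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(bank$sprites))
  for (i in seq_along(bank$sprites)) {
    s <- bank$sprites[[i]]
    rgba <- array(0, dim = c(dim(s$pixels), 4L))
    rgba[, , 1] <- s$pixels; rgba[, , 2] <- s$pixels; rgba[, , 3] <- s$pixels
    rgba[, , 4] <- s$alpha
    paths[i] <- file.path(directory, sprintf("%03d_%s.png", i, s$species_tag))
    EBImage::writeImage(EBImage::Image(rgba, colormode = "Color"), paths[i])
  }
  invisible(paths)
}

#' Default morphology ranges for procedural sprites
#'
#' Units are pixels at the stated scene scale. Defaults emulate the diversity
#' of dried insect cutouts — elongated dark bodies over a roughly fivefold
#' length range, thin legs/antennae, occasional paler wing lobes — at the
#' reference 240 px scene resolution; pass `scale` to shrink everything
#' proportionally for smaller scenes.
#'
#' @param scale multiplier applied to all length ranges (1 = 240 px scenes).
#' @param body_len_range body major-axis length range, px.
#' @param aspect_range body length/width ratio range.
#' @param n_appendage_range number of thin appendages (legs + antennae).
#' @param appendage_len_range appendage length as a fraction of body length.
#' @param darkness_range body luminance range (0 = black).
#' @param wing_prob probability of a pair of paler wing lobes.
#' @return A list of morphology parameters.
#' @export
sprite_params <- function(scale = 1,
                          body_len_range = c(12, 60) * scale,
                          aspect_range = c(2, 5),
                          n_appendage_range = c(0L, 8L),
                          appendage_len_range = c(0.25, 0.6),
                          darkness_range = c(0.05, 0.35),
                          wing_prob = 0.4) {
  if (body_len_range[1] <= 0 || diff(body_len_range) < 0) {
    stop("invalid morphology parameters: degenerate body length range")
  }
  if (aspect_range[1] < 1) stop("invalid morphology parameters: aspect < 1")
  list(body_len_range = body_len_range, aspect_range = aspect_range,
       n_appendage_range = as.integer(n_appendage_range),
       appendage_len_range = appendage_len_range,
       darkness_range = darkness_range, wing_prob = wing_prob)
}

# Rasterize a filled ellipse on an existing matrix; returns logical mask.
ellipse_mask <- function(H, W, cr, cc, a, b, theta) {
  r <- matrix(seq_len(H), H, W) - cr
  c <- matrix(seq_len(W), H, W, byrow = TRUE) - cc
  u <- r * cos(theta) + c * sin(theta)
  v <- -r * sin(theta) + c * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# Draw a polyline of unit-width by stamping pixels along it.
draw_polyline <- function(mask, pts, width = 1) {
  H <- nrow(mask); W <- ncol(mask)
  for (i in seq_len(nrow(pts) - 1L)) {
    p0 <- pts[i, ]; p1 <- pts[i + 1L, ]
    n <- max(2L, ceiling(2 * sqrt(sum((p1 - p0)^2))))
    t <- seq(0, 1, length.out = n)
    rr <- round(p0[1] + t * (p1[1] - p0[1]))
    cc <- round(p0[2] + t * (p1[2] - p0[2]))
    for (dr in seq_len(width) - 1L) for (dc in seq_len(width) - 1L) {
      r <- pmin(pmax(rr + dr, 1L), H); c <- pmin(pmax(cc + dc, 1L), W)
      mask[cbind(r, c)] <- TRUE
    }
  }
  mask
}

#' Synthesize a procedural insect sprite
#'
#' Generates a dark articulated shape — an elliptical body, a small head,
#' 0–8 thin polyline appendages and optional paler wing lobes — whose mask
#' is a single connected component. Identical `seed` and `params` give a
#' bit-identical sprite. These procedural sprites stand in for photographed
#' cutouts so the full pipeline runs with no external data.
#'
#' @param seed integer seed.
#' @param params morphology ranges from [sprite_params()].
#' @return A `trap_sprite` with origin `"procedural"`. The attribute `geom`
#'   records the body ellipse and appendage count for morphological checks.
#' @export
synthesize_procedural_sprite <- function(seed, params = sprite_params()) {
  with_seed(seed, {
    L <- runif(1, params$body_len_range[1], params$body_len_range[2])
    asp <- runif(1, params$aspect_range[1], params$aspect_range[2])
    a <- L / 2                       # semi-major (along body axis)
    b <- max(1, L / (2 * asp))       # semi-minor
    n_app <- if (params$n_appendage_range[1] == params$n_appendage_range[2]) {
      params$n_appendage_range[1]
    } else {
      sample(params$n_appendage_range[1]:params$n_appendage_range[2], 1L)
    }
    app_len <- runif(n_app, params$appendage_len_range[1],
                     params$appendage_len_range[2]) * L
    dark <- runif(1, params$darkness_range[1], params$darkness_range[2])
    wings <- runif(1) < params$wing_prob
    pad <- ceiling(max(app_len, 0) + a * 0.6) + 2
    S <- ceiling(2 * a) + 2 * pad
    cr <- cc <- (S + 1) / 2
    body <- ellipse_mask(S, S, cr, cc, a, b, 0)
    # head: small disc at one end of the major axis
    head_r <- max(1.2, b * 0.7)
    body <- body | ellipse_mask(S, S, cr + a * 0.95, cc, head_r, head_r, 0)
    mask <- body
    # appendages: 2-segment polylines rooted just inside the body outline,
    # base angles spread evenly with jitter so limbs rarely merge
    if (n_app > 0) {
      base_ang <- seq(0, 2 * pi, length.out = n_app + 1L)[-(n_app + 1L)] +
        runif(n_app, -0.25, 0.25)
      for (j in seq_len(n_app)) {
        th <- base_ang[j]
        # root on the ellipse at 90% radius (guarantees connectivity)
        den <- sqrt((cos(th) / a)^2 + (sin(th) / b)^2)
        r0 <- cr + 0.9 * cos(th) / den
        c0 <- cc + 0.9 * sin(th) / den
        bend <- th + runif(1, -0.5, 0.5)
        mid <- c(r0 + 0.55 * app_len[j] * cos(th), c0 + 0.55 * app_len[j] * sin(th))
        tip <- c(mid[1] + 0.45 * app_len[j] * cos(bend),
                 mid[2] + 0.45 * app_len[j] * sin(bend))
        mask <- draw_polyline(mask, rbind(c(r0, c0), mid, tip),
                              width = if (L > 30) 2L else 1L)
      }
    }
    px <- matrix(0, S, S)
    if (wings) {
      for (sgn in c(-1, 1)) {
        wing <- ellipse_mask(S, S, cr - a * 0.25, cc + sgn * b * 1.1,
                             a * 0.6, b * 0.9, sgn * 0.35)
        wing <- wing & !body
        # wings touch the body flank, keeping the mask connected
        mask <- mask | wing
        # wings are paler than the body but stay well below background
        # luminance, so composited insects never fade into the backdrop
        px[wing] <- pmin(dark + 0.25, 0.6)
      }
    }
    px[body] <- dark
    legs <- mask & px == 0
    px[legs] <- dark * 0.8
    # light per-pixel texture on the body
    px[body] <- clamp01(px[body] + runif(sum(body), -0.03, 0.03))
    # at very small scales a rasterized appendage or wing can miss the thin
    # body by a pixel; keep the largest connected component so the mask is
    # always a single blob
    labs <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(matrix(as.numeric(mask), S))))
    if (max(labs) > 1) {
      counts <- tabulate(labs[labs > 0])
      mask <- matrix(labs == which.max(counts), S, S)
    }
    bb <- mask_bbox(mask)
    s <- sprite(px, matrix(as.numeric(mask), S, S),
                species_tag = sprintf("procedural_%d", seed),
                origin = "procedural")
    # body geometry in trimmed-raster coordinates, for morphological checks
    attr(s, "geom") <- list(body_len = L, semi_axes = c(a, b),
                            center = c(cr - bb[["r0"]] + 1, cc - bb[["c0"]] + 1),
                            head_r = head_r,
                            n_appendages = n_app, has_wings = wings,
                            darkness = dark)
    s
  })
}

#' Generate a bank of procedural sprites
#'
#' @param n number of sprites; sprite `i` uses seed `derive(seed, i)`.
#' @param seed base seed.
#' @param params morphology ranges from [sprite_params()].
#' @return An unpartitioned `trap_sprite_bank`.
#' @export
procedural_sprite_bank <- function(n = 100, seed = 0, params = sprite_params()) {
  sprites <- lapply(seq_len(n), function(i) {
    synthesize_procedural_sprite(derive_seed(seed, 101L, i), params)
  })
  new_sprite_bank(sprites, seed = as.integer(seed))
}

#' Partition a sprite bank into train and test sprites
#'
#' Assigns `round(n * train_fraction)` sprites (ties toward train) to the
#' training side and the rest to test, by a seeded shuffle. Train and test
#' sets are disjoint and cover the bank, so no insect used to compose
#' training scenes ever appears in a test scene.
#'
#' @param bank a `trap_sprite_bank`.
#' @param train_fraction proportion in (0, 1); default 0.7.
#' @param seed integer seed.
#' @return The bank with its `partition` field filled.
#' @export
partition_sprites <- function(bank, train_fraction = 0.7, seed = 0) {
  n <- length(bank$sprites)
  if (n == 0L) stop("empty sprite bank")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  n_train <- floor(n * train_fraction + 0.5)   # ties toward train
  if (n_train == 0L || n_train == n) {
    stop("degenerate partition: one side would be empty")
  }
  ord <- with_seed(seed, sample.int(n))
  partition <- rep("test", n)
  partition[ord[seq_len(n_train)]] <- "train"
  bank$partition <- partition
  bank$seed <- as.integer(seed)
  bank
}

#' Extract an insect cutout from a photo/background pair
#'
#' Background subtraction: the mask is the largest connected component of
#' `|photo - background| > threshold` after a 3x3 morphological closing,
#' trimmed to its tight bounding box. Used to turn a photograph of a single
#' insect inside the trap into a compositing sprite.
#'
#' @param photo,background grayscale matrices (or color arrays) of identical
#'   size, values in `[0, 1]`; the photo contains exactly one insect.
#' @param threshold absolute luminance difference in `[0, 1]`; default 0.08.
#' @param border_warn_frac warn if more than this fraction of mask pixels lie
#'   on the image border (likely clipped insect); default 0.05.
#' @param species_tag tag for the resulting sprite.
#' @return A `trap_sprite` with origin `"real_cutout"`.
#' @export
extract_cutout <- function(photo, background, threshold = 0.08,
                           border_warn_frac = 0.05, species_tag = "cutout") {
  photo <- to_gray(photo); background <- to_gray(background)
  if (!identical(dim(photo), dim(background))) {
    stop("photo and background must have identical dimensions")
  }
  diffmask <- abs(photo - background) > threshold
  if (!any(diffmask)) stop("no foreground detected")
  closed <- EBImage::closing(EBImage::Image(matrix(as.numeric(diffmask), nrow(photo))),
                             EBImage::makeBrush(3, shape = "box"))
  lab <- EBImage::bwlabel(closed)
  labs <- EBImage::imageData(lab)
  counts <- tabulate(labs[labs > 0])
  keep <- which.max(counts)
  mask <- matrix(labs == keep, nrow(photo))
  on_border <- sum(mask[1, ]) + sum(mask[nrow(mask), ]) +
    sum(mask[, 1]) + sum(mask[, ncol(mask)])
  if (on_border > border_warn_frac * sum(mask)) {
    warning("foreground touches the image border; insect may be clipped")
  }
  s <- sprite(photo, matrix(as.numeric(mask), nrow(mask)),
              species_tag = species_tag, origin = "real_cutout")
  # where the cutout sits in the source photo (1-based top-left corner)
  bb <- mask_bbox(mask)
  attr(s, "anchor") <- c(row = unname(bb["r0"]), col = unname(bb["c0"]))
  s
}

#' Rotate a sprite
#'
#' Bilinear rotation with canvas expansion; the alpha mask is re-binarized
#' at 0.5 and the result trimmed to the tight bounding box, so composited
#' overlap tests stay exact.
#'
#' @param s a `trap_sprite`.
#' @param angle_deg rotation angle, degrees counter-clockwise.
#' @return The rotated `trap_sprite`.
#' @export
rotate_sprite <- function(s, angle_deg) {
  th <- angle_deg * pi / 180
  H <- nrow(s$pixels); W <- ncol(s$pixels)
  Ho <- ceiling(abs(H * cos(th)) + abs(W * sin(th)))
  Wo <- ceiling(abs(H * sin(th)) + abs(W * cos(th)))
  # inverse map: output pixel -> input pixel, rotating about the centre
  ic <- c((H - 1) / 2, (W - 1) / 2); oc <- c((Ho - 1) / 2, (Wo - 1) / 2)
  inv <- matrix(c(cos(th), -sin(th), ic[1] - cos(th) * oc[1] + sin(th) * oc[2],
                  sin(th),  cos(th), ic[2] - sin(th) * oc[1] - cos(th) * oc[2]),
                2, 3, byrow = TRUE)
  px <- .warp_affine(s$pixels, Ho, Wo, inv, 0)
  al <- .warp_affine(s$alpha, Ho, Wo, inv, 0)
  al <- matrix(as.numeric(al >= 0.5), Ho, Wo)
  if (!any(al > 0)) return(s)   # degenerate tiny sprite; keep original
  # thin appendages can shear into fragments under bilinear resampling;
  # keep the largest connected component so a rotated sprite is still one
  # insect (fragments would corrupt the ground-truth count)
  labs <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(al)))
  if (max(labs) > 1) {
    counts <- tabulate(labs[labs > 0])
    al <- matrix(as.numeric(labs == which.max(counts)), Ho, Wo)
  }
  out <- sprite(px, al, species_tag = s$species_tag, origin = s$origin)
  attr(out, "geom") <- attr(s, "geom")
  out
}
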