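#' Consumption profile for duty-cycle energy accounting
#'
#' Per-phase average current and duration for one wake cycle, plus the deep
#' sleep current and battery capacity. The shipped fixtures (see
#' [load_profile()]) carry the measured figures for the four deployed
#' configurations; the ESP32 profile is: sleep 6 mA; capture-with-flash
#' 180 mA x 2 s; inference 85 mA x 51 s; store + WiFi upload 150 mA x 3.5 s;
#' other functions 70 mA x 6.5 s; two 3,350 mAh cells (6,700 mAh at 3.7 V).
#'
#' @param sleep_current_mA deep-sleep current, mA.
#' @param phases data.frame with columns `name`, `current_mA`, `duration_s`.
#' @param battery_capacity_mAh battery capacity, mAh.
#' @param cycles_per_day wake cycles per day (default 1: one photo per day).
#' @param device free-text device label.
#' @return A list of class `trap_consumption_profile`.
#' @export
consumption_profile <- function(sleep_current_mA, phases, battery_capacity_mAh,
                                cycles_per_day = 1, device = "unknown") {
  stopifnot(is.data.frame(phases),
            all(c("name", "current_mA", "duration_s") %in% names(phases)))
  if (sleep_current_mA < 0 || any(phases$current_mA < 0) ||
      any(phases$duration_s < 0) || battery_capacity_mAh <= 0 ||
      cycles_per_day < 0) {
    stop("currents and durations must be >= 0 and capacity > 0")
  }
  structure(list(sleep_current_mA = sleep_current_mA, phases = phases,
                 battery_capacity_mAh = battery_capacity_mAh,
                 cycles_per_day = cycles_per_day, device = device),
            class = "trap_consumption_profile")
}

#' @export
print.trap_consumption_profile <- function(x, ...) {
  cat(sprintf("<trap_consumption_profile '%s': sleep %.3g mA, %d phases (%.1f s active), %g mAh>\n",
              x$device, x$sleep_current_mA, nrow(x$phases),
              sum(x$phases$duration_s), x$battery_capacity_mAh))
  invisible(x)
}

#' Load a consumption profile from YAML
#'
#' Fixture profiles for the four measured device configurations ship with
#' the package: `esp32`, `rpi4`, `coral`, `coral_tpu` under
#' `system.file("extdata", "profiles", package = "trapcount")`.
#'
#' @param path YAML file path, or one of the fixture names above.
#' @return A `trap_consumption_profile`.
#' @export
load_profile <- function(path) {
  if (!file.exists(path)) {
    builtin <- system.file("extdata", "profiles", paste0(path, ".yaml"),
                           package = "trapcount")
    if (builtin == "") stop("profile not found: ", path)
    path <- builtin
  }
  y <- yaml::read_yaml(path)
  consumption_profile(
    sleep_current_mA = y$sleep_current_mA,
    phases = do.call(rbind, lapply(y$phases, function(p) {
      data.frame(name = p$name, current_mA = p$current_mA,
                 duration_s = p$duration_s)
    })),
    battery_capacity_mAh = y$battery_capacity_mAh,
    cycles_per_day = y$cycles_per_day %||% 1,
    device = y$device %||% tools::file_path_sans_ext(basename(path)))
}

#' Estimate battery life in days
#'
#' Energy accounting: per day the device spends
#' `86,400 - cycles_per_day * active_s` seconds asleep and runs the phase
#' chain `cycles_per_day` times, so
#' `daily_mAh = (sleep_mA * (86,400 - cycles * active_s) +
#' cycles * sum(current * duration)) / 3600` and
#' `days = capacity / daily_mAh`.
#'
#' @param profile a `trap_consumption_profile`.
#' @return Battery life in days (`Inf`, with a message, if daily consumption
#'   is zero).
#' @export
estimate_battery_life <- function(profile) {
  active_s <- sum(profile$phases$duration_s)
  active_mAs <- sum(profile$phases$current_mA * profile$phases$duration_s)
  sleep_s <- 86400 - profile$cycles_per_day * active_s
  if (sleep_s < 0) stop("active time exceeds one day")
  daily_mAh <- (profile$sleep_current_mA * sleep_s +
                  profile$cycles_per_day * active_mAs) / 3600
  if (daily_mAh == 0) {
    message("infinite lifetime: zero daily consumption")
    return(Inf)
  }
  profile$battery_capacity_mAh / daily_mAh
}

# mAh consumed by one day of operation (sleep + cycles).
daily_consumption_mAh <- function(profile) {
  active_s <- sum(profile$phases$duration_s)
  (profile$sleep_current_mA * (86400 - profile$cycles_per_day * active_s) +
     profile$cycles_per_day *
     sum(profile$phases$current_mA * profile$phases$duration_s)) / 3600
}

#' Upload trigger
#'
#' The trap uploads its image iff the inferred count differs from the
#' previous day's count; the first observation (no previous count) always
#' uploads.
#'
#' @param prev_count previous day's integer count, or `NULL`/`NA` if none.
#' @param new_count today's integer count (>= 0).
#' @return `TRUE` if the image should be uploaded.
#' @export
should_upload <- function(prev_count, new_count) {
  if (new_count < 0) stop("count must be >= 0")
  is.null(prev_count) || is.na(prev_count) || new_count != prev_count
}

#' Initialize trap state
#'
#' @return A `trap_state` with no previous observation.
#' @export
trap_state <- function() {
  structure(list(day_index = 0L, last_count = NA_integer_,
                 last_image_ref = NA_character_,
                 upload_log = data.frame(day = integer(), count = integer(),
                                         uploaded = logical())),
            class = "trap_state")
}

# Default transport: records HTTP-POST-shaped payloads in memory (and
# optionally on disk); the real WiFi/HTTP stack is firmware, out of scope.
mock_transport <- function(dir = NULL) {
  sent <- list()
  env <- environment()
  function(payload = NULL) {
    if (is.null(payload)) return(env$sent)
    env$sent[[length(env$sent) + 1L]] <- payload[setdiff(names(payload), "image")]
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(payload[setdiff(names(payload), "image")],
                           file.path(dir, sprintf("upload_day%04d.json", payload$day)),
                           auto_unbox = TRUE, digits = NA)
      if (!is.null(payload$image)) {
        EBImage::writeImage(EBImage::Image(payload$image),
                            file.path(dir, sprintf("upload_day%04d.png", payload$day)))
      }
    }
    invisible(TRUE)
  }
}

#' Run one daily trap cycle
#'
#' Executes the deployed chain of tasks: (a) model loaded, (b) image
#' acquired, (c) count inferred, (d) image uploaded iff the count changed
#' since the previous day, (e) last picture stored, (f) sleep until the next
#' cycle. If inference fails the cycle is logged as failed and the state is
#' unchanged except for the day index.
#'
#' @param state a `trap_state`.
#' @param image today's scene (matrix).
#' @param model a counting model (anything [predict_count()] accepts), or a
#'   function `(image) -> numeric` used as the counter.
#' @param transport upload callback taking a payload list; default records
#'   payloads in memory.
#' @return List with the updated `state`, the `upload` decision, and the
#'   inferred `count`.
#' @export
run_daily_cycle <- function(state, image, model, transport = mock_transport()) {
  day <- state$day_index + 1L
  count <- tryCatch({
    y <- if (is.function(model)) model(image) else predict_count(model, image)
    round_prediction(y)[1]
  }, error = function(e) NA_integer_)
  state$day_index <- day
  if (is.na(count)) {
    state$upload_log <- rbind(state$upload_log,
                              data.frame(day = day, count = NA_integer_,
                                         uploaded = FALSE))
    return(list(state = state, upload = FALSE, count = NA_integer_))
  }
  upload <- should_upload(state$last_count, count)
  if (upload) {
    transport(list(day = day, count = count, image = image,
                   device = "trapcount-sim"))
  }
  state$last_count <- count
  state$last_image_ref <- sprintf("day%04d.png", day)
  state$upload_log <- rbind(state$upload_log,
                            data.frame(day = day, count = count,
                                       uploaded = upload))
  list(state = state, upload = upload, count = count)
}

#' Simulate a full trap deployment
#'
#' Renders one scene per day from a per-day schedule of true counts
#' (insects stay stuck on the sticky trap, so placements persist and new
#' insects are added as the scheduled count rises; a drop in the schedule is
#' treated as a serviced/cleaned trap and the scene restarts), runs the
#' daily cycle with the supplied counting model, and accumulates the upload
#' log and energy use.
#'
#' @param arrival_schedule integer vector, true insect count for each day.
#' @param model counting model or counter function; pass
#'   `oracle_counter(arrival_schedule)` for a perfect counter.
#' @param bank sprite bank used to render daily scenes.
#' @param config a [scene_config()].
#' @param profile a `trap_consumption_profile` for energy accounting.
#' @param seed integer seed.
#' @param transport upload callback; default in-memory mock.
#' @return A `trap_deployment` list: `log` data.frame (day, true_count,
#'   inferred_count, uploaded, cum_mAh), `n_uploads`, `total_mAh`,
#'   `battery_life_days`, `final_state`.
#' @export
simulate_deployment <- function(arrival_schedule, model, bank,
                                config = scene_config(img_size = 64),
                                profile = load_profile("esp32"), seed = 0,
                                transport = mock_transport()) {
  if (any(arrival_schedule > config$max_count)) {
    stop("schedule contains counts above max_count")
  }
  if (any(arrival_schedule < 0)) stop("schedule counts must be >= 0")
  backgrounds <- make_backgrounds(config, seed)
  state <- trap_state()
  daily_mAh <- daily_consumption_mAh(profile)
  log <- NULL
  scene <- NULL   # persistent scene: background + stuck insects
  prev_true <- 0L
  for (d in seq_along(arrival_schedule)) {
    n_true <- arrival_schedule[d]
    if (is.null(scene) || n_true < prev_true) {
      scene <- persistent_scene(backgrounds, config, seed = derive_seed(seed, 505L, d))
    }
    while (scene$count < n_true) {
      scene <- add_insect(scene, bank, config,
                          seed = derive_seed(seed, 606L, d, scene$count))
    }
    prev_true <- n_true
    res <- run_daily_cycle(state, scene$image, model, transport)
    state <- res$state
    log <- rbind(log, data.frame(day = d, true_count = n_true,
                                 inferred_count = res$count,
                                 uploaded = res$upload,
                                 cum_mAh = d * daily_mAh))
  }
  structure(list(log = log, n_uploads = sum(log$uploaded),
                 total_mAh = nrow(log) * daily_mAh,
                 battery_life_days = estimate_battery_life(profile),
                 final_state = state),
            class = "trap_deployment")
}

#' @export
print.trap_deployment <- function(x, ...) {
  cat(sprintf("<trap_deployment: %d days, %d uploads, %.1f mAh used (battery lasts %.1f days)>\n",
              nrow(x$log), x$n_uploads, x$total_mAh, x$battery_life_days))
  invisible(x)
}

#' A perfect counter for a known schedule
#'
#' @param arrival_schedule the true per-day counts.
#' @return A counter function returning the true count for each successive
#'   day; useful as an oracle when testing the trigger logic.
#' @export
oracle_counter <- function(arrival_schedule) {
  day <- 0L
  env <- environment()
  function(image) {
    env$day <- env$day + 1L
    arrival_schedule[env$day]
  }
}

# Mutable scene for sticky-trap persistence: insects accumulate.
persistent_scene <- function(backgrounds, config, seed) {
  with_seed(seed, {
    bg_id <- sample.int(length(backgrounds), 1L)
    img <- backgrounds[[bg_id]]
    if (config$jitter) img <- clamp01(img * runif(1, 0.95, 1.05))
    list(image = img, occupied = matrix(FALSE, config$img_size, config$img_size),
         count = 0L)
  })
}

add_insect <- function(scene, bank, config, seed) {
  with_seed(seed, {
    pool <- bank_split(bank, "test")
    si <- pool[sample.int(length(pool), 1L)]
    rs <- rotate_sprite(bank$sprites[[si]], runif(1, 0, 360))
    m <- rs$alpha >= 0.5
    h <- nrow(m); w <- ncol(m); S <- config$img_size
    for (attempt in seq_len(config$max_attempts)) {
      r0 <- sample.int(S - h + 1L, 1L)
      c0 <- sample.int(S - w + 1L, 1L)
      sub <- scene$occupied[r0:(r0 + h - 1L), c0:(c0 + w - 1L)]
      if (!any(sub & m)) {
        scene$occupied <- mark_occupied(scene$occupied, m, r0, c0)
        tile <- scene$image[r0:(r0 + h - 1L), c0:(c0 + w - 1L)]
        tile[m] <- rs$pixels[m]
        scene$image[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- tile
        scene$count <- scene$count + 1L
        return(scene)
      }
    }
    stop("scene overcrowded: could not add insect")
  })
}
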