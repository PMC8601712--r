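# Shared fixture builders and independent brute-force oracles.

t_origin <- as.POSIXct("2018-04-14 21:00:00", tz = "UTC")

# Altitude series on the 5-min grid starting at t0.
mk_series <- function(alt, t0 = t_origin, provenance = "raw") {
  altitude_series(t0 + 300 * (seq_along(alt) - 1), alt,
                  provenance = provenance)
}

# Activity data frame on the 5-min grid.
mk_activity <- function(scores, scale_max = 10, t0 = t_origin,
                        bird = "b1") {
  data.frame(bird_id = bird, timestamp = t0 + 300 * (seq_along(scores) - 1),
             score = as.integer(scores), scale_max = as.integer(scale_max),
             stringsAsFactors = FALSE)
}

# Minimal flight-episode stub for the events/dynamics modules.
mk_episode <- function(alt, duration_s = NULL, scores = NULL,
                       scale_max = 10, t0 = t_origin, id = "ep1",
                       season = "spring", region = "Sahara") {
  n <- length(alt)
  ser <- mk_series(alt, t0)
  if (is.null(scores)) scores <- rep(round(0.95 * scale_max), n)
  structure(list(
    id = id, bird_id = "b1",
    start = t0, end = t0 + 300 * (n - 1),
    duration_s = duration_s %||% (300 * (n - 1)),
    core_hours = t0, n_pre = 0L, n_post = 0L,
    class = if ((duration_s %||% (300 * (n - 1))) > 10800) "migratory"
            else "short",
    region = region, season = season, latitude = 20,
    activity = mk_activity(scores, scale_max, t0),
    altitude = ser), class = "flight_episode")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force tortuosity: explicit zero-carry directions, literal recount.
brute_tortuosity <- function(z) {
  dz <- diff(z)
  dirs <- sign(dz)
  last <- 0
  for (i in seq_along(dirs)) {
    if (dirs[i] == 0) dirs[i] <- last else last <- dirs[i]
  }
  first_nz <- which(dirs != 0)[1]
  if (is.na(first_nz)) return(0)
  dirs[seq_len(first_nz)] <- dirs[first_nz]
  shifts <- 0
  for (i in seq_along(dirs)[-1]) {
    if (dirs[i] != dirs[i - 1]) shifts <- shifts + 1
  }
  shifts / (length(z) - 1)
}

# Brute-force windowed maximum ascent: every ordered pair fitting inside
# one window, literally enumerated.
brute_max_ascent <- function(t, z, window_s) {
  best <- NA_real_
  for (i in seq_along(t)) {
    for (j in seq_along(t)) {
      if (t[j] > t[i] && t[j] - t[i] <= window_s) {
        r <- (z[j] - z[i]) / window_s
        if (is.na(best) || r > best) best <- r
      }
    }
  }
  best
}

# A random valid logger dataset for round-trip property tests.
random_dataset <- function(n_birds = 2, n = 20) {
  acts <- list(); pres <- list(); lats <- list()
  for (b in seq_len(n_birds)) {
    id <- sprintf("bird%02d", b)
    t0 <- t_origin + b * 86400
    keep_a <- sort(sample(n, max(2, n - sample(0:3, 1))))
    keep_p <- sort(sample(n, max(2, n - sample(0:3, 1))))
    scale <- sample(c(5L, 10L), 1)
    acts[[b]] <- data.frame(
      bird_id = id, timestamp = t0 + 300 * keep_a,
      score = sample(0:scale, length(keep_a), replace = TRUE),
      scale_max = scale, stringsAsFactors = FALSE)
    pres[[b]] <- data.frame(
      bird_id = id, timestamp = t0 + 300 * keep_p,
      pressure_hpa = round(runif(length(keep_p), 540, 1030), 3),
      stringsAsFactors = FALSE)
    lats[[b]] <- data.frame(
      bird_id = id, date = as.Date(t0) + 0:2,
      latitude = c(round(runif(2, -30, 60), 2), NA),
      stringsAsFactors = FALSE)
  }
  logger_dataset(activity = do.call(rbind, acts),
                 pressure = do.call(rbind, pres),
                 latitude = do.call(rbind, lats))
}

expect_dataset_equal <- function(d1, d2) {
  expect_equal(d1$activity, d2$activity)
  expect_equal(d1$pressure, d2$pressure, tolerance = 1e-12)
  lat1 <- d1$latitude[!is.na(d1$latitude$latitude), ]
  lat2 <- d2$latitude[!is.na(d2$latitude$latitude), ]
  rownames(lat1) <- rownames(lat2) <- NULL
  expect_equal(lat1, lat2, tolerance = 1e-12)
}

# Scenario with plain migratory night flights (climb, cruise wiggle,
# descend) for several birds over both seasons and regions.
demo_scenario <- function(n_birds = 3, noise = 0.5, seed = 1) {
  plan <- phases(
    displacement_m = c(1500, 60, -60, 80, -80, 60, -60, -1500),
    duration_s = c(3600, 1800, 1800, 1800, 1800, 1800, 1800, 3600),
    duty = 0.95)
  birds <- lapply(seq_len(n_birds), function(b) {
    bird_spec(sprintf("bird%02d", b),
              nights = list(
                night_plan(as.Date("2018-04-14"), plan),
                night_plan(as.Date("2018-10-15"), plan)),
              scale_max = if (b %% 2) 10 else 5,
              latitude = if (b == 1) 45 else if (b == 2) 20 else 5)
  })
  scenario_spec(birds, pressure_noise_sd = noise, seed = seed)
}
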