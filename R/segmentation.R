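#' Is a 5-min activity sample at flight level?
#'
#' A sample indicates sustained flapping when its duty cycle
#' `score / scale_max` reaches the threshold (default 0.6). On the 0-10
#' loggers this is a score of 6 or above; on the 0-5 loggers, 3 or above.
#'
#' @param score integer activity score(s).
#' @param scale_max 5 or 10, the logger's maximum score.
#' @param duty_threshold duty-cycle fraction, default 0.6.
#' @return Logical vector.
#' @export
is_flight_level <- function(score, scale_max, duty_threshold = 0.6) {
  score / scale_max >= duty_threshold
}

#' Find core flight hours in an activity stream
#'
#' A UTC clock-hour is a core hour when at least `core_hour_min_count`
#' (default 7) of its (at most 12) 5-min samples are at flight level.
#' Consecutive core hours merge into the core period of one flight episode.
#'
#' @param activity data frame with `timestamp`, `score`, `scale_max`
#'   (one bird).
#' @param config a [pipeline_config()].
#' @return `POSIXct` vector of core hour starts (sorted).
#' @export
find_core_hours <- function(activity, config = pipeline_config()) {
  if (!nrow(activity)) return(as.POSIXct(character(0), tz = "UTC"))
  fl <- is_flight_level(activity$score, activity$scale_max,
                        config$activity_duty_threshold)
  hr <- floor_hour(activity$timestamp)
  counts <- tapply(fl, as.numeric(hr), sum)
  core <- as.numeric(names(counts))[counts >= config$core_hour_min_count]
  as.POSIXct(sort(core), origin = "1970-01-01", tz = "UTC")
}

#' Assign a latitude band
#'
#' Latitude bands of the migration corridor: north of the upper break
#' (default 38 deg N) is Europe; between the breaks (inclusive) the
#' Mediterranean/Sahara passage; south of the lower break (default 8 deg N)
#' sub-Saharan Africa.
#'
#' @param latitude degrees North (may be `NA`).
#' @param breaks ascending pair of latitude breaks, default `c(8, 38)`.
#' @return Character vector: `"Europe"`, `"Sahara"`, `"subSaharan"` or
#'   `"unknown"` for missing latitude.
#' @export
assign_region <- function(latitude, breaks = c(8, 38)) {
  stopifnot(length(breaks) == 2, breaks[1] < breaks[2])
  out <- ifelse(is.na(latitude), "unknown",
         ifelse(latitude > breaks[2], "Europe",
         ifelse(latitude >= breaks[1], "Sahara", "subSaharan")))
  bad <- !is.na(latitude) & (latitude < -90 | latitude > 90)
  if (any(bad)) stopf("latitude outside [-90, 90]")
  out
}

#' Assign a migration season
#'
#' Default calendar rule: July-December is autumn (southbound half-year),
#' January-June spring. The alternative `"latitude"` rule looks at the net
#' latitudinal displacement over the week around the date and labels
#' southbound movement autumn and northbound spring, falling back to the
#' calendar rule when positions are missing or the bird is stationary.
#'
#' @param date `Date` (episode start date).
#' @param lat_track optional data frame `date`, `latitude` for the bird.
#' @param rule `"calendar"` or `"latitude"`.
#' @return Character vector `"autumn"`/`"spring"`, with attribute
#'   `"season_rule"` recording the rule that was applied.
#' @export
assign_season <- function(date, lat_track = NULL,
                          rule = c("calendar", "latitude")) {
  rule <- match.arg(rule)
  calendar <- ifelse(as.integer(format(date, "%m")) >= 7, "autumn", "spring")
  if (rule == "calendar" || is.null(lat_track) || !nrow(lat_track))
    return(structure(calendar, season_rule = "calendar"))
  out <- calendar
  for (i in seq_along(date)) {
    win <- lat_track[lat_track$date >= date[i] - 3 &
                     lat_track$date <= date[i] + 3 &
                     !is.na(lat_track$latitude), , drop = FALSE]
    if (nrow(win) >= 2) {
      slope <- win$latitude[which.max(win$date)] - win$latitude[which.min(win$date)]
      if (slope < 0) out[i] <- "autumn" else if (slope > 0) out[i] <- "spring"
    }
  }
  structure(out, season_rule = rule)
}

#' Extract flight episodes from a logger dataset
#'
#' Two-step extraction: (1) maximal runs of consecutive core hours (see
#' [find_core_hours()]) form the core period of an episode; (2) the episode
#' is extended by 300 s for every flight-level 5-min sample in the single
#' hour immediately before (pre-core) and after (post-core) the core
#' period. Episodes strictly longer than `min_flight_duration_s` (default
#' 3 h) are classed `"migratory"`; the rest are kept as `"short"` flights,
#' which downstream exploratory-flight scanning needs. Pressure samples
#' inside the episode are converted to altitude and attached.
#'
#' @param dataset a [logger_dataset()].
#' @param config a [pipeline_config()].
#' @param constants an [atmosphere_constants()] object.
#' @return List of `"flight_episode"` objects; see [episode_table()] for a
#'   tabular summary.
#' @export
extract_flight_episodes <- function(dataset, config = pipeline_config(),
                                    constants = atmosphere_constants()) {
  stopifnot(inherits(dataset, "logger_dataset"))
  episodes <- list()
  for (b in unique(dataset$activity$bird_id)) {
    act <- dataset$activity[dataset$activity$bird_id == b, , drop = FALSE]
    pre <- dataset$pressure[dataset$pressure$bird_id == b, , drop = FALSE]
    lat <- dataset$latitude[dataset$latitude$bird_id == b, , drop = FALSE]
    core <- find_core_hours(act, config)
    if (!length(core)) next
    run_id <- cumsum(c(1, diff(as.numeric(core)) != 3600))
    fl <- is_flight_level(act$score, act$scale_max,
                          config$activity_duty_threshold)
    k <- 0
    for (r in split(core, run_id)) {
      k <- k + 1
      core_start <- r[1]
      core_end <- r[length(r)] + 3600
      n_pre <- count_adjacent(act, fl, core_start - 3600, core_start,
                              config$contiguous_precore, from_end = TRUE)
      n_post <- count_adjacent(act, fl, core_end, core_end + 3600,
                               config$contiguous_precore, from_end = FALSE)
      start <- core_start - 300 * n_pre
      end <- core_end + 300 * n_post
      duration <- as.numeric(end) - as.numeric(start)
      sel <- pre$timestamp >= start & pre$timestamp <= end
      alt <- if (any(sel)) {
        altitude_series(pre$timestamp[sel],
                        pressure_to_altitude(pre$pressure_hpa[sel], constants))
      } else NULL
      asel <- act$timestamp >= start & act$timestamp <= end
      mid <- start + duration / 2
      lat_mid <- nearest_latitude(lat, as.Date(mid))
      ep <- structure(list(
        id = sprintf("%s_%03d", b, k),
        bird_id = b,
        start = start, end = end,
        duration_s = duration,
        core_hours = r,
        n_pre = n_pre, n_post = n_post,
        class = if (duration > config$min_flight_duration_s) "migratory"
                else "short",
        region = assign_region(lat_mid, config$region_lat_breaks_degN),
        season = as.character(
          assign_season(as.Date(start), lat, rule = config$season_rule)),
        latitude = lat_mid,
        activity = act[asel, c("timestamp", "score", "scale_max"),
                       drop = FALSE],
        altitude = alt), class = "flight_episode")
      episodes[[length(episodes) + 1]] <- ep
    }
  }
  episodes
}

# Count qualifying 5-min samples in the single adjacent hour [from, to).
# With contiguous = TRUE only the run touching the core period counts.
count_adjacent <- function(act, fl, from, to, contiguous, from_end) {
  sel <- act$timestamp >= from & act$timestamp < to
  q <- fl[sel]
  if (!length(q)) return(0L)
  if (!contiguous) return(sum(q))
  if (from_end) q <- rev(q)  # pre-core hour: walk backwards from the core
  run <- cumprod(q)
  sum(run)
}

nearest_latitude <- function(lat, date) {
  lat <- lat[!is.na(lat$latitude), , drop = FALSE]
  if (!nrow(lat)) return(NA_real_)
  lat$latitude[which.min(abs(as.numeric(lat$date - date)))]
}

#' @export
print.flight_episode <- function(x, ...) {
  cat(sprintf("<flight_episode %s> %s  %s -> %s (%.1f h, %s, %s/%s)\n",
              x$id, x$class, format_utc(x$start), format_utc(x$end),
              x$duration_s / 3600, paste0(length(x$core_hours), " core h"),
              x$season, x$region))
  invisible(x)
}

#' Summarise flight episodes as a data frame
#'
#' @param episodes list of episodes from [extract_flight_episodes()].
#' @return One row per episode: id, bird, start/end, duration, core-hour
#'   count, pre/post extensions, class, region, season, and altitude sample
#'   count.
#' @export
episode_table <- function(episodes) {
  if (!length(episodes)) {
    return(data.frame(id = character(0), bird_id = character(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"),
                      duration_s = numeric(0), n_core_hours = integer(0),
                      n_pre = integer(0), n_post = integer(0),
                      class = character(0), region = character(0),
                      season = character(0), n_altitude = integer(0)))
  }
  do.call(rbind, lapply(episodes, function(e) data.frame(
    id = e$id, bird_id = e$bird_id, start = e$start, end = e$end,
    duration_s = e$duration_s, n_core_hours = length(e$core_hours),
    n_pre = e$n_pre, n_post = e$n_post, class = e$class,
    region = e$region, season = e$season,
    n_altitude = if (is.null(e$altitude)) 0L else nrow(e$altitude),
    stringsAsFactors = FALSE)))
}
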