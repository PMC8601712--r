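episode_dz_series <- function(e, config) {
  if (is.null(e$altitude) || nrow(e$altitude) < 3) return(NULL)
  if (config$dz_basis == "smoothed") rolling_mean3(e$altitude) else e$altitude
}

event_row <- function(e, kind, runs, i, j) {
  leg <- function(r) c(direction = r$direction, displacement = r$displacement,
                       duration = r$duration, rate = abs(r$rate))
  l1 <- runs[i, ]; l2 <- runs[j, ]
  data.frame(
    episode_id = e$id, bird_id = e$bird_id, kind = kind,
    season = e$season, region = e$region,
    start = e$altitude$timestamp[l1$i0], end = e$altitude$timestamp[l2$i1],
    descent_first = l1$direction < 0,
    leg1_displacement = l1$displacement, leg1_duration = l1$duration,
    leg1_rate = abs(l1$rate),
    leg2_displacement = l2$displacement, leg2_duration = l2$duration,
    leg2_rate = abs(l2$rate),
    stringsAsFactors = FALSE)
}

empty_events <- function() data.frame(
  episode_id = character(0), bird_id = character(0), kind = character(0),
  season = character(0), region = character(0),
  start = as.POSIXct(character(0), tz = "UTC"),
  end = as.POSIXct(character(0), tz = "UTC"),
  descent_first = logical(0),
  leg1_displacement = numeric(0), leg1_duration = numeric(0),
  leg1_rate = numeric(0), leg2_displacement = numeric(0),
  leg2_duration = numeric(0), leg2_rate = numeric(0))

#' Detect terminated exploratory flights
#'
#' A terminated exploratory movement is a short flight whose whole profile
#' is a single climb directly followed by a single descent, after which the
#' flight ends: the bird climbs to sample conditions aloft, finds them
#' wanting, and lands. The smoothed profile must decompose into exactly one
#' ascent run and one descent run, the climb must reach the displacement
#' minimum (default 500 m; `terminated_leg_rule = "either"` accepts either
#' leg), and the flight-wide mean absolute vertical rate must exceed
#' `exploratory_min_rate_ms` (default 0.1 m/s).
#'
#' @param episodes episodes from [extract_flight_episodes()]; only flights
#'   not exceeding the migratory duration threshold are scanned.
#' @param config a [pipeline_config()].
#' @return data frame of events (possibly zero rows); episodes without
#'   altitude data are skipped with a warning.
#' @export
detect_terminated_exploratory <- function(episodes,
                                          config = pipeline_config()) {
  out <- empty_events()
  for (e in episodes) {
    if (e$duration_s > config$min_flight_duration_s) next
    if (is.null(e$altitude) || nrow(e$altitude) < 3) {
      warnf("episode %s has no usable altitude data; skipped", e$id)
      next
    }
    ser <- episode_dz_series(e, config)
    runs <- altitude_runs(ser)
    if (nrow(runs) != 2 || runs$direction[1] != 1 || runs$direction[2] != -1)
      next
    ok_disp <- if (config$terminated_leg_rule == "ascent") {
      runs$displacement[1] >= config$exploratory_min_displacement_m
    } else {
      max(abs(runs$displacement)) >= config$exploratory_min_displacement_m
    }
    if (!ok_disp) next
    if (mean_vertical_speed(ser) <= config$exploratory_min_rate_ms) next
    out <- rbind(out, event_row(e, "terminated", runs, 1, 2))
  }
  rownames(out) <- NULL
  out
}

#' Detect mid-flight exploratory movements
#'
#' Scans migratory flights for two consecutive opposite-direction vertical
#' displacements of at least 500 m each -- an ascent followed by a descent
#' or vice versa -- embedded in the cruising part of the flight. Each leg
#' must sustain a mean absolute rate above `exploratory_min_rate_ms`. The
#' episode's first and last runs are excluded (they are the ordinary
#' initial climb and final descent), and overlapping candidates are
#' resolved greedily left to right.
#'
#' @param episodes episodes from [extract_flight_episodes()]; only
#'   migratory flights (longer than the duration threshold) are scanned.
#' @param config a [pipeline_config()].
#' @return data frame of events with `descent_first` indicating profiles
#'   that begin with the descending leg.
#' @export
detect_midflight_exploratory <- function(episodes,
                                         config = pipeline_config()) {
  out <- empty_events()
  for (e in episodes) {
    if (e$duration_s <= config$min_flight_duration_s) next
    ser <- episode_dz_series(e, config)
    if (is.null(ser)) {
      warnf("episode %s has no usable altitude data; skipped", e$id)
      next
    }
    runs <- altitude_runs(ser)
    if (nrow(runs) < 2) next
    # The ordinary profile's edges never form event legs: the initial climb
    # (the ascending run holding the first non-level interval) and the
    # landing descent (the descending run holding the last one).
    is_initial_climb <- runs$direction == 1 & seq_len(nrow(runs)) == 1L
    is_landing <- runs$direction == -1 & seq_len(nrow(runs)) == nrow(runs)
    i <- 1L
    while (i <= nrow(runs) - 1L) {
      r1 <- runs[i, ]; r2 <- runs[i + 1L, ]
      if (!is_initial_climb[i] && !is_landing[i + 1L] &&
          abs(r1$displacement) >= config$exploratory_min_displacement_m &&
          abs(r2$displacement) >= config$exploratory_min_displacement_m &&
          abs(r1$rate) > config$exploratory_min_rate_ms &&
          abs(r2$rate) > config$exploratory_min_rate_ms &&
          r1$direction == -r2$direction) {
        out <- rbind(out, event_row(e, "midflight", runs, i, i + 1L))
        i <- i + 2L   # greedy: legs cannot be reused
      } else {
        i <- i + 1L
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Windowed maximum ascent rate
#'
#' The largest net altitude gain achieved inside any single window of the
#' given length, divided by the window length, for windows of 5 and 20 min
#' (defaults): the maximum over sample pairs no further apart than the
#' window of their altitude difference over `window_s`. Also reports the
#' flight's total climb (sum of positive 5-min displacements) and whether
#' the episode passes the total-climb inclusion filter: the total climb
#' must exceed the altitude a bird climbing at the theoretical maximum
#' rate would cover in one window, otherwise short flights could never
#' express a high rate and would bias the comparison.
#'
#' @param series an [altitude_series()] (raw, per episode).
#' @param window_s window length, a positive multiple of 300 s.
#' @param benchmark_ms theoretical maximum climb rate for the filter
#'   (default 1.16 m/s).
#' @return One-row data frame: `window_s`, `max_rate` (m/s; `NA` when
#'   fewer than 2 samples exist), `total_climb` (m), and `passes_filter`.
#' @export
max_ascent_rate <- function(series, window_s, benchmark_ms = 1.16) {
  stopifnot(inherits(series, "altitude_series"))
  if (window_s <= 0 || window_s %% 300 != 0)
    stopf("window_s must be a positive multiple of 300 s")
  t <- as.numeric(series$timestamp)
  z <- series$altitude
  n <- length(z)
  total_climb <- if (n >= 2) sum(pmax(diff(z), 0)) else 0
  max_rate <- NA_real_
  for (i in seq_len(max(n - 1, 0))) {
    j <- which(t > t[i] & t - t[i] <= window_s)
    if (length(j)) {
      r <- (max(z[j]) - z[i]) / window_s
      if (is.na(max_rate) || r > max_rate) max_rate <- r
    }
  }
  data.frame(window_s = window_s, max_rate = max_rate,
             total_climb = total_climb,
             passes_filter = !is.na(max_rate) &&
               total_climb > benchmark_ms * window_s)
}

#' Ascent maxima for a set of episodes
#'
#' @param episodes episodes from [extract_flight_episodes()].
#' @param config a [pipeline_config()]; windows taken from
#'   `ascent_windows_s`, the filter benchmark from
#'   `max_climb_benchmark_ms`.
#' @return data frame, one row per episode x window.
#' @export
ascent_table <- function(episodes, config = pipeline_config()) {
  rows <- list()
  for (e in episodes) {
    if (is.null(e$altitude) || nrow(e$altitude) < 2) next
    for (w in config$ascent_windows_s) {
      r <- max_ascent_rate(e$altitude, w, config$max_climb_benchmark_ms)
      r <- cbind(data.frame(episode_id = e$id, bird_id = e$bird_id,
                            class = e$class, season = e$season,
                            region = e$region, stringsAsFactors = FALSE), r)
      rows[[length(rows) + 1]] <- r
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract descents of at least 10 minutes
#'
#' Works on the three-point smoothed altitude series so that brief
#' updraft-driven upticks do not split a descent. A descent is a maximal
#' run of non-increasing smoothed altitude with net altitude loss that
#' follows flight-level activity. Runs lasting at least
#' `descent_min_duration_s` are kept; the first and last record of each run
#' are dropped before the rate is computed (they can include time when the
#' bird was still cruising or had already landed), which requires at least
#' 4 samples per run. The descent is classed `"glide"` when the mean
#' activity duty cycle over the run is below the flight-level threshold,
#' otherwise `"active"`.
#'
#' @param episodes episodes from [extract_flight_episodes()].
#' @param config a [pipeline_config()]; `descent_monotone = "strict"`
#'   disallows level intervals inside a run.
#' @return data frame, one row per descent: times, duration of the run,
#'   trimmed-endpoint rate (negative, m/s), mode and mean duty.
#' @export
extract_descents <- function(episodes, config = pipeline_config()) {
  rows <- list()
  for (e in episodes) {
    if (is.null(e$altitude) || nrow(e$altitude) < 4) next
    sm <- rolling_mean3(e$altitude)
    dz <- diff(sm$altitude)
    down <- if (config$descent_monotone == "strict") dz < 0 else dz <= 0
    grp <- cumsum(c(1, diff(down) != 0))
    for (idx in split(seq_along(dz), grp)) {
      if (!down[idx[1]]) next
      # strip level cruise intervals at the run edges; they are not descent
      while (length(idx) && dz[idx[1]] == 0) idx <- idx[-1]
      while (length(idx) && dz[idx[length(idx)]] == 0)
        idx <- idx[-length(idx)]
      if (!length(idx)) next
      i0 <- idx[1]; i1 <- idx[length(idx)] + 1L
      if (sm$altitude[i1] >= sm$altitude[i0]) next       # no net loss
      if (!follows_flight(e, sm$timestamp[i0], config)) next
      dur <- as.numeric(sm$timestamp[i1]) - as.numeric(sm$timestamp[i0])
      if (dur < config$descent_min_duration_s) next
      if (i1 - i0 + 1L < 4) next                          # trimmed rate needs 2 pts
      j0 <- i0 + 1L; j1 <- i1 - 1L
      rate <- (sm$altitude[j1] - sm$altitude[j0]) /
        (as.numeric(sm$timestamp[j1]) - as.numeric(sm$timestamp[j0]))
      duty <- mean_duty(e, sm$timestamp[i0], sm$timestamp[i1])
      rows[[length(rows) + 1]] <- data.frame(
        episode_id = e$id, bird_id = e$bird_id, season = e$season,
        region = e$region, start = sm$timestamp[i0], end = sm$timestamp[i1],
        duration_s = dur, rate = rate,
        mode = if (!is.na(duty) && duty < config$activity_duty_threshold)
          "glide" else "active",
        mean_duty = duty, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(episode_id = character(0), bird_id = character(0),
                      season = character(0), region = character(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"),
                      duration_s = numeric(0), rate = numeric(0),
                      mode = character(0), mean_duty = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# The sample immediately before the run start (or at it, for a run opening
# the episode) must indicate flight-level activity.
follows_flight <- function(e, t0, config) {
  act <- e$activity
  if (is.null(act) || !nrow(act)) return(TRUE)
  before <- act[act$timestamp <= t0, , drop = FALSE]
  if (!nrow(before)) return(TRUE)
  s <- before[nrow(before), ]
  is_flight_level(s$score, s$scale_max, config$activity_duty_threshold)
}

mean_duty <- function(e, t0, t1) {
  act <- e$activity
  if (is.null(act) || !nrow(act)) return(NA_real_)
  sel <- act$timestamp >= t0 & act$timestamp <= t1
  if (!any(sel)) return(NA_real_)
  mean(act$score[sel] / act$scale_max[sel])
}
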