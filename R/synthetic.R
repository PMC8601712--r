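#' Flight-plan phases
#'
#' A phase is a constant-rate leg of a planned night flight: a signed
#' vertical displacement covered over a duration at a given activity duty
#' cycle. Zero displacement is level cruising.
#'
#' @param displacement_m signed vertical displacement (m).
#' @param duration_s phase duration (s), positive.
#' @param duty activity duty cycle in `[0, 1]` during the phase (fraction
#'   of accelerometer sub-measurements registering activity).
#' @return data frame with one row per phase.
#' @export
phases <- function(displacement_m, duration_s, duty = 0.95) {
  df <- data.frame(displacement_m = displacement_m,
                   duration_s = duration_s, duty = duty)
  if (any(df$duration_s <= 0)) stopf("phase durations must be positive")
  if (any(df$duty < 0 | df$duty > 1)) stopf("duty must be in [0, 1]")
  rate <- abs(df$displacement_m) / df$duration_s
  if (any(rate > 2))
    stopf("planted vertical rate %.2f m/s exceeds the 2 m/s ceiling",
          max(rate))
  df
}

#' One planned night flight
#'
#' @param date `Date` (or string) of the evening the flight starts.
#' @param plan a [phases()] data frame.
#' @param start_hour UTC hour of flight start (may be fractional).
#' @return Named list describing the night.
#' @export
night_plan <- function(date, plan, start_hour = 21) {
  list(date = as.Date(date), plan = plan, start_hour = start_hour)
}

#' One simulated bird
#'
#' @param bird_id identifier (no spaces or commas).
#' @param nights list of [night_plan()]s.
#' @param scale_max activity scale of the logger generation: 10 (pre-2018)
#'   or 5 (2018/2019).
#' @param latitude either a single latitude (degrees N) held for the whole
#'   record or a data frame `date`, `latitude`; `NULL` for no positions.
#' @return Named list describing the bird.
#' @export
bird_spec <- function(bird_id, nights, scale_max = 10, latitude = NULL) {
  if (!scale_max %in% c(5, 10)) stopf("scale_max must be 5 or 10")
  list(bird_id = as.character(bird_id), nights = nights,
       scale_max = as.integer(scale_max), latitude = latitude)
}

#' Synthetic logger scenario
#'
#' Describes a complete simulated deployment: birds, their planned night
#' flights, and the instrument model. The defaults mirror the study's
#' instrument: 5-min sampling of both streams, pressure noise well inside
#' the sensor's +/-1 hPa absolute accuracy, near-zero activity at daytime
#' rest.
#'
#' @param birds list of [bird_spec()]s.
#' @param pressure_noise_sd s.d. of Gaussian pressure noise (hPa); the
#'   default 0.5 treats the +/-1 hPa accuracy bound as a ~2 s.d. envelope.
#' @param ground_elevation_m flat terrain elevation (masl); flights start
#'   and end here.
#' @param rest_duty duty cycle while roosting.
#' @param activity_dropout fraction of activity samples forced to score 0,
#'   emulating sensor dropout.
#' @param seed default RNG seed used by [generate_dataset()].
#' @return Object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(birds, pressure_noise_sd = 0.5,
                          ground_elevation_m = 0, rest_duty = 0.02,
                          activity_dropout = 0, seed = 1L) {
  if (pressure_noise_sd < 0 || activity_dropout < 0 || activity_dropout > 1)
    stopf("invalid noise or dropout setting")
  structure(list(birds = birds, pressure_noise_sd = pressure_noise_sd,
                 ground_elevation_m = ground_elevation_m,
                 rest_duty = rest_duty, activity_dropout = activity_dropout,
                 seed = seed),
            class = "scenario_spec")
}

local_seed <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Generate a logger dataset with known ground truth
#'
#' Builds each bird's true altitude path as a piecewise-linear function of
#' time from its flight plans (constant-rate phases, flat ground
#' otherwise), samples it on the 5-min grid, converts it to pressure
#' through the inverse hypsometric formula and adds Gaussian sensor noise.
#' Activity scores are Binomial(`scale_max`, duty) draws per 5-min sample.
#' Output is deterministic for a fixed spec and seed.
#'
#' @param spec a [scenario_spec()].
#' @param seed RNG seed; defaults to the spec's.
#' @param constants an [atmosphere_constants()] object.
#' @return List with `dataset` (a [logger_dataset()]) and `truth`, a list
#'   with per-flight tables: `flights` (true boundaries and the metrics of
#'   the noiseless sampled path), `phase_table` (planted phases with
#'   absolute times) and `series` (noiseless altitude series per flight).
#' @export
generate_dataset <- function(spec, seed = spec$seed,
                             constants = atmosphere_constants()) {
  stopifnot(inherits(spec, "scenario_spec"))
  restore <- local_seed(seed)
  on.exit(restore())

  act_all <- list(); pre_all <- list(); lat_all <- list()
  flights <- list(); phase_rows <- list(); series <- list()

  for (bird in spec$birds) {
    nights <- bird$nights
    if (!length(nights)) next
    dates <- as.Date(vapply(nights, function(n) as.character(n$date), ""))
    # one rest-to-rest window per night (noon before to noon two days
    # after); windows of close nights merge, distant nights leave gaps
    wins <- lapply(sort(unique(dates)), function(d) {
      seq(as.POSIXct(paste(d, "12:00:00"), tz = "UTC"),
          as.POSIXct(paste(d + 2, "12:00:00"), tz = "UTC"), by = 300)
    })
    grid <- sort(unique(do.call(c, wins)))
    attr(grid, "tzone") <- "UTC"
    t_to <- grid[length(grid)]
    alt <- rep(spec$ground_elevation_m, length(grid))
    duty <- rep(spec$rest_duty, length(grid))
    in_flight <- logical(length(grid))

    fk <- 0
    for (night in nights) {
      fk <- fk + 1
      t0 <- as.POSIXct(paste(night$date, "00:00:00"), tz = "UTC") +
        night$start_hour * 3600
      plan <- night$plan
      ends <- as.numeric(t0) + cumsum(plan$duration_s)
      brk_t <- c(as.numeric(t0), ends)
      brk_z <- spec$ground_elevation_m + cumsum(c(0, plan$displacement_m))
      if (any(brk_z < spec$ground_elevation_m - 1e-9))
        stopf("infeasible plan for bird '%s', night %s: altitude below ground",
              bird$bird_id, night$date)
      t1 <- ends[length(ends)]
      if (t1 > as.numeric(t_to))
        stopf("plan for bird '%s', night %s runs past the simulated range",
              bird$bird_id, night$date)
      inside <- as.numeric(grid) >= as.numeric(t0) & as.numeric(grid) <= t1
      if (any(in_flight[inside]))
        stopf("overlapping flight plans for bird '%s' on night %s",
              bird$bird_id, night$date)
      in_flight[inside] <- TRUE
      alt[inside] <- stats::approx(brk_t, brk_z,
                                   xout = as.numeric(grid)[inside])$y
      ph_i <- findInterval(as.numeric(grid)[inside], brk_t,
                           rightmost.closed = TRUE)
      duty[inside] <- plan$duty[pmin(ph_i, nrow(plan))]

      fid <- sprintf("%s_n%02d", bird$bird_id, fk)
      tt <- grid[inside]
      zz <- alt[inside]
      ser <- altitude_series(tt, zz)
      lf <- if (length(zz) >= 2)
        classify_level_intervals(ser)$level_fraction else NA_real_
      tort <- if (length(zz) >= 3)
        vertical_tortuosity(rolling_mean3(ser)) else NA_real_
      mvz <- if (length(zz) >= 2)
        mean_vertical_speed(rolling_mean3(ser)) else NA_real_
      flights[[fid]] <- data.frame(
        flight_id = fid, bird_id = bird$bird_id, date = night$date,
        start = as.POSIXct(as.numeric(t0), origin = "1970-01-01", tz = "UTC"),
        end = as.POSIXct(t1, origin = "1970-01-01", tz = "UTC"),
        duration_s = t1 - as.numeric(t0),
        level_fraction = lf, tortuosity = tort, mean_vz = mvz,
        stringsAsFactors = FALSE)
      phase_rows[[fid]] <- cbind(flight_id = fid,
                                 t_start = utils::head(brk_t, -1),
                                 t_end = brk_t[-1], plan)
      series[[fid]] <- ser
    }

    score <- stats::rbinom(length(grid), bird$scale_max, duty)
    if (spec$activity_dropout > 0) {
      drop <- stats::runif(length(grid)) < spec$activity_dropout
      score[drop] <- 0L
    }
    press <- altitude_to_pressure(alt, constants) +
      if (spec$pressure_noise_sd > 0)
        stats::rnorm(length(grid), 0, spec$pressure_noise_sd) else 0

    act_all[[bird$bird_id]] <- data.frame(
      bird_id = bird$bird_id, timestamp = grid, score = as.integer(score),
      scale_max = bird$scale_max, stringsAsFactors = FALSE)
    pre_all[[bird$bird_id]] <- data.frame(
      bird_id = bird$bird_id, timestamp = grid, pressure_hpa = press,
      stringsAsFactors = FALSE)
    if (!is.null(bird$latitude)) {
      days <- sort(unique(do.call(c, lapply(unique(dates),
                                            function(d) d + 0:2))))
      lat <- if (is.data.frame(bird$latitude)) {
        data.frame(bird_id = bird$bird_id,
                   date = as.Date(bird$latitude$date),
                   latitude = bird$latitude$latitude,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(bird_id = bird$bird_id, date = days,
                   latitude = bird$latitude, stringsAsFactors = FALSE)
      }
      lat_all[[bird$bird_id]] <- lat
    }
  }

  dataset <- logger_dataset(
    activity = if (length(act_all)) do.call(rbind, act_all),
    pressure = if (length(pre_all)) do.call(rbind, pre_all),
    latitude = if (length(lat_all)) do.call(rbind, lat_all))
  truth <- list(
    flights = if (length(flights)) {
      out <- do.call(rbind, flights); rownames(out) <- NULL; out
    } else NULL,
    phase_table = if (length(phase_rows)) {
      out <- do.call(rbind, phase_rows); rownames(out) <- NULL; out
    } else NULL,
    series = series)
  list(dataset = dataset, truth = truth)
}

#' Plan a cruise with a planted near-level fraction
#'
#' Builds a deterministic phase table of 5-min constant-rate intervals in
#' which a fraction `level_fraction` of intervals move `|dz|` = 12 m
#' (level, comfortably under the 30 m bound even after sensor noise) and
#' the rest 90 m (intermediate), alternating sign so the profile stays near
#' its starting altitude. Used for parameter-recovery checks.
#'
#' @param level_fraction target fraction of near-level intervals.
#' @param n_intervals number of 5-min intervals.
#' @param duty activity duty cycle.
#' @param level_step,big_step interval displacements (m).
#' @return A [phases()] data frame.
#' @export
plan_level_profile <- function(level_fraction, n_intervals, duty = 0.95,
                               level_step = 12, big_step = 90) {
  n_level <- round(level_fraction * n_intervals)
  is_level <- rep(FALSE, n_intervals)
  if (n_level > 0)  # evenly spread, always exactly n_level positions
    is_level[floor((0:(n_level - 1)) * n_intervals / n_level) + 1] <- TRUE
  step <- ifelse(is_level, level_step, big_step)
  sgn <- numeric(n_intervals)
  cum <- 0
  for (i in seq_len(n_intervals)) {   # stay above ground: climb when low
    sgn[i] <- if (cum <= step[i]) 1 else if (i %% 2 == 0) -1 else 1
    cum <- cum + sgn[i] * step[i]
  }
  phases(displacement_m = sgn * step, duration_s = 300, duty = duty)
}
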