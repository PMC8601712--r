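# Interval directions with the zero-carry rule: a zero displacement keeps
# the direction of the last non-zero displacement; leading zeros take the
# first non-zero direction that follows (all-zero series -> all zero).
carry_directions <- function(dz) {
  d <- sign(dz)
  nz <- which(d != 0)
  if (!length(nz)) return(d)
  if (nz[1] > 1) d[seq_len(nz[1] - 1)] <- d[nz[1]]
  for (i in seq_along(d)[-1]) if (d[i] == 0) d[i] <- d[i - 1]
  d
}

#' Decompose an altitude series into monotone runs
#'
#' A run is a maximal stretch of intervals sharing one vertical direction.
#' Under the default zero-carry rule, level 5-min intervals are absorbed
#' into the surrounding run, so a climb interrupted by a brief plateau is
#' still one ascent; this is the same direction rule that the vertical
#' tortuosity statistic uses, so "one run" and "one displacement" agree
#' across the package.
#'
#' @param series an [altitude_series()] with at least 2 samples.
#' @return data frame with one row per run: sample indices `i0`, `i1`,
#'   `direction` (+1/-1, or 0 for an all-level series), `displacement`
#'   (m, signed, `z[i1] - z[i0]`), `duration` (s) and `rate` (m/s).
#' @export
altitude_runs <- function(series) {
  vd <- vertical_displacement(series)
  d <- carry_directions(vd$dz)
  grp <- cumsum(c(1, diff(d) != 0))
  idx <- split(seq_along(d), grp)
  out <- do.call(rbind, lapply(idx, function(i) {
    i0 <- i[1]; i1 <- i[length(i)] + 1L
    data.frame(i0 = i0, i1 = i1, direction = d[i[1]],
               displacement = series$altitude[i1] - series$altitude[i0],
               duration = as.numeric(series$timestamp[i1]) -
                          as.numeric(series$timestamp[i0]))
  }))
  rownames(out) <- NULL
  out$rate <- out$displacement / out$duration
  out
}

#' Classify 5-min intervals by vertical displacement
#'
#' Each interval is `"level"` when its absolute altitude change is strictly
#' below 30 m (an average vertical speed under 0.1 m/s), `"large"` at 300 m
#' or more (at least 1 m/s), and `"intermediate"` in between. Run on the
#' raw altitude series: the definition refers to the change from the
#' preceding record, not to a smoothed path.
#'
#' @param series an [altitude_series()], at least 2 samples.
#' @param level_threshold_m,large_threshold_m class bounds (m).
#' @return List with `labels` (per interval), `level_fraction`, and
#'   `counts` (named: level / intermediate / large; they partition the
#'   intervals).
#' @export
classify_level_intervals <- function(series, level_threshold_m = 30,
                                     large_threshold_m = 300) {
  adz <- abs(vertical_displacement(series)$dz)
  labels <- ifelse(adz < level_threshold_m, "level",
            ifelse(adz >= large_threshold_m, "large", "intermediate"))
  counts <- c(level = sum(labels == "level"),
              intermediate = sum(labels == "intermediate"),
              large = sum(labels == "large"))
  list(labels = labels,
       level_fraction = counts[["level"]] / length(labels),
       counts = counts)
}

#' Mean vertical speed of a flight
#'
#' Mean over intervals of `|dz|/dt`: how much vertical motion per unit time
#' the flight involves, regardless of direction. A signed mean would
#' telescope to near zero on any out-and-back profile.
#'
#' @param series an [altitude_series()].
#' @param trim if `TRUE`, compute on the presumed cruising phase (see
#'   [trim_cruise()]); returns `NA` when the flight is untrimmable.
#' @return Non-negative scalar (m/s).
#' @export
mean_vertical_speed <- function(series, trim = FALSE) {
  if (trim) {
    series <- trim_cruise(series)
    if (isTRUE(attr(series, "untrimmable"))) return(NA_real_)
  }
  vd <- vertical_displacement(series)
  mean(abs(vd$dz) / vd$dt)
}

#' Vertical tortuosity of a flight
#'
#' The number of shifts between ascent and descent (and vice versa) divided
#' by the number of altitude recordings minus one. 0 means the bird never
#' reversed vertical direction; values approaching 1 mean it reversed at
#' nearly every recording. Level intervals carry the previous direction
#' (zero-carry), so a staircase climb counts its turns, not its plateaus.
#'
#' @param series an [altitude_series()] with at least 3 samples.
#' @param trim if `TRUE`, compute on the cruising phase ([trim_cruise()]).
#' @return Ratio in `[0, 1]`; 0 for an all-level series.
#' @export
vertical_tortuosity <- function(series, trim = FALSE) {
  if (trim) {
    series <- trim_cruise(series)
    if (isTRUE(attr(series, "untrimmable")) || nrow(series) < 3)
      return(NA_real_)
  }
  if (nrow(series) < 3) stopf("need at least 3 samples for tortuosity")
  d <- carry_directions(vertical_displacement(series)$dz)
  shifts <- sum(d[-1] != d[-length(d)] & d[-1] != 0 & d[-length(d)] != 0)
  shifts / (nrow(series) - 1)
}

#' Trim a flight to its presumed cruising phase
#'
#' Removes the initial and the terminal maximal stretch of intervals with a
#' constant non-zero vertical direction -- the first climb and the last
#' descent, whose length would otherwise dominate the whole-flight
#' statistics. A plateau ends the stretch, so a climb-plateau-descent
#' profile keeps its plateau. Profiles that are one monotone sweep (or
#' would keep fewer than 2 samples) are flagged untrimmable.
#'
#' @param series an [altitude_series()] with at least 4 samples.
#' @return The trimmed [altitude_series()]; a zero-row series with
#'   attribute `untrimmable = TRUE` when no cruising phase remains.
#' @export
trim_cruise <- function(series) {
  stopifnot(inherits(series, "altitude_series"))
  if (nrow(series) < 4) return(untrimmable(series))
  dz <- vertical_displacement(series)$dz
  s <- sign(dz)
  n <- length(dz)
  first_len <- if (s[1] == 0) 0L else {
    r <- which(s != s[1])
    if (length(r)) r[1] - 1L else n
  }
  last_len <- if (s[n] == 0) 0L else {
    sr <- rev(s)
    r <- which(sr != sr[1])
    if (length(r)) r[1] - 1L else n
  }
  keep0 <- first_len + 1L          # first kept sample index
  keep1 <- nrow(series) - last_len # last kept sample index
  if (keep1 - keep0 + 1L < 2) return(untrimmable(series))
  out <- altitude_series(series$timestamp[keep0:keep1],
                         series$altitude[keep0:keep1],
                         provenance = attr(series, "provenance"))
  out
}

untrimmable <- function(series) {
  out <- altitude_series(series$timestamp[0], series$altitude[0],
                         provenance = attr(series, "provenance"))
  attr(out, "untrimmable") <- TRUE
  out
}

#' Altitude-variation metrics for flight episodes
#'
#' Computes, per episode and per variant (full flight and cruising phase),
#' the near-level fraction and displacement class counts (on the raw
#' altitude series), the mean vertical speed and vertical tortuosity (on
#' the three-point smoothed series by default), and the maximum and median
#' altitude.
#'
#' @param episodes list of episodes from [extract_flight_episodes()].
#' @param config a [pipeline_config()].
#' @return data frame, one row per episode x variant; episodes with fewer
#'   than 4 altitude samples are skipped with a warning.
#' @export
flight_metrics <- function(episodes, config = pipeline_config()) {
  rows <- lapply(episodes, function(e) {
    if (is.null(e$altitude) || nrow(e$altitude) < 4) {
      warnf("episode %s skipped: too few altitude samples", e$id)
      return(NULL)
    }
    raw <- e$altitude
    sm <- rolling_mean3(raw)
    lvl_basis <- if (config$level_basis == "raw") raw else sm
    dz_basis <- if (config$dz_basis == "smoothed") sm else raw
    full_cls <- classify_level_intervals(lvl_basis, config$level_threshold_m,
                                         config$large_threshold_m)
    cruise <- trim_cruise(dz_basis)
    untrim <- isTRUE(attr(cruise, "untrimmable"))
    one <- function(variant, cls, mvz, tort) data.frame(
      episode_id = e$id, bird_id = e$bird_id, variant = variant,
      class = e$class, region = e$region, season = e$season,
      start = e$start, duration_s = e$duration_s,
      level_fraction = cls$level_fraction,
      n_level = cls$counts[["level"]],
      n_intermediate = cls$counts[["intermediate"]],
      n_large = cls$counts[["large"]],
      mean_vz = mvz, tortuosity = tort,
      max_alt = max(raw$altitude), median_alt = stats::median(raw$altitude),
      stringsAsFactors = FALSE)
    full <- one("full", full_cls,
                mean_vertical_speed(dz_basis),
                if (nrow(dz_basis) >= 3) vertical_tortuosity(dz_basis)
                else NA_real_)
    cr <- if (!untrim && nrow(cruise) >= 2) {
      lvl_cr <- if (config$level_basis == "raw")
        window_series(raw, cruise) else cruise
      one("cruise",
          classify_level_intervals(lvl_cr, config$level_threshold_m,
                                   config$large_threshold_m),
          mean_vertical_speed(cruise),
          if (nrow(cruise) >= 3) vertical_tortuosity(cruise) else NA_real_)
    } else NULL
    rbind(full, cr)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Restrict a series to the time window spanned by another.
window_series <- function(series, window) {
  sel <- series$timestamp >= window$timestamp[1] &
    series$timestamp <= window$timestamp[nrow(window)]
  altitude_series(series$timestamp[sel], series$altitude[sel],
                  provenance = attr(series, "provenance"))
}
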