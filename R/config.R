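#' Pipeline configuration
#'
#' Bundles every threshold of the flight-altitude pipeline into one object.
#' Defaults are the values used throughout the analysis; each can be
#' overridden here or from a YAML file via [read_config()].
#'
#' @param level_threshold_m near-level classification bound: a 5-min interval
#'   with absolute altitude change strictly below this is "level" (m).
#' @param large_threshold_m lower bound of the "large displacement" class (m);
#'   intervals with `|dz| >= large_threshold_m` average at least 1 m/s.
#' @param exploratory_min_displacement_m minimum vertical displacement of an
#'   exploratory-movement leg (m).
#' @param exploratory_min_rate_ms minimum mean vertical rate qualifying an
#'   exploratory movement (m/s).
#' @param core_hour_min_count flight-level 5-min samples required (out of at
#'   most 12) for a clock-hour to count as a core flight hour.
#' @param activity_duty_threshold duty-cycle fraction at or above which a
#'   5-min activity sample indicates sustained flapping; 0.6 maps to score
#'   >= 6 on the 0-10 scale and >= 3 on the 0-5 scale.
#' @param min_flight_duration_s episodes strictly longer than this are
#'   migratory flights; shorter ones are kept as "short" flights (s).
#' @param descent_min_duration_s minimum duration of an analysed descent (s).
#' @param ascent_windows_s windows over which maximum ascent rates are taken (s).
#' @param region_lat_breaks_degN ascending latitude breaks separating the
#'   sub-Saharan, Sahara and Europe bands (degrees North).
#' @param max_climb_benchmark_ms theoretical maximum sustainable climb rate
#'   used by the total-climb inclusion filter for ascent analyses (m/s).
#' @param terminated_leg_rule which leg(s) of a terminated exploratory flight
#'   must reach the displacement minimum: the ascent (`"ascent"`) or either
#'   leg (`"either"`).
#' @param level_basis altitude series used for near-level classification:
#'   `"raw"` (default) or `"smoothed"`.
#' @param dz_basis series used for vertical-displacement metrics (mean
#'   vertical speed, tortuosity, run decomposition): `"smoothed"` (default,
#'   three-point rolling mean) or `"raw"`.
#' @param descent_monotone `"nonincreasing"` tolerates level 5-min intervals
#'   inside a descent run; `"strict"` requires every interval to lose height.
#' @param season_rule `"calendar"` assigns Jul-Dec to autumn and Jan-Jun to
#'   spring; `"latitude"` uses the net latitudinal direction over the
#'   surrounding week where daily positions allow it.
#' @param contiguous_precore if `TRUE`, only qualifying 5-min samples
#'   contiguous with the core period extend an episode; the default counts
#'   all qualifying samples in the single adjacent hour.
#' @param alpha significance level for group comparisons.
#' @param rng_seed optional integer seed recorded in run manifests.
#' @return An object of class `"pipeline_config"` (a named list).
#' @export
pipeline_config <- function(level_threshold_m = 30,
                            large_threshold_m = 300,
                            exploratory_min_displacement_m = 500,
                            exploratory_min_rate_ms = 0.1,
                            core_hour_min_count = 7,
                            activity_duty_threshold = 0.6,
                            min_flight_duration_s = 10800,
                            descent_min_duration_s = 600,
                            ascent_windows_s = c(300, 1200),
                            region_lat_breaks_degN = c(8, 38),
                            max_climb_benchmark_ms = 1.16,
                            terminated_leg_rule = c("ascent", "either"),
                            level_basis = c("raw", "smoothed"),
                            dz_basis = c("smoothed", "raw"),
                            descent_monotone = c("nonincreasing", "strict"),
                            season_rule = c("calendar", "latitude"),
                            contiguous_precore = FALSE,
                            alpha = 0.05,
                            rng_seed = NULL) {
  cfg <- list(
    level_threshold_m = level_threshold_m,
    large_threshold_m = large_threshold_m,
    exploratory_min_displacement_m = exploratory_min_displacement_m,
    exploratory_min_rate_ms = exploratory_min_rate_ms,
    core_hour_min_count = core_hour_min_count,
    activity_duty_threshold = activity_duty_threshold,
    min_flight_duration_s = min_flight_duration_s,
    descent_min_duration_s = descent_min_duration_s,
    ascent_windows_s = ascent_windows_s,
    region_lat_breaks_degN = region_lat_breaks_degN,
    max_climb_benchmark_ms = max_climb_benchmark_ms,
    terminated_leg_rule = match.arg(terminated_leg_rule),
    level_basis = match.arg(level_basis),
    dz_basis = match.arg(dz_basis),
    descent_monotone = match.arg(descent_monotone),
    season_rule = match.arg(season_rule),
    contiguous_precore = isTRUE(contiguous_precore),
    alpha = alpha,
    rng_seed = rng_seed
  )
  num <- c("level_threshold_m", "large_threshold_m",
           "exploratory_min_displacement_m", "exploratory_min_rate_ms",
           "core_hour_min_count", "activity_duty_threshold",
           "min_flight_duration_s", "descent_min_duration_s",
           "max_climb_benchmark_ms", "alpha")
  for (k in num) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || cfg[[k]] <= 0)
      stopf("config key '%s' must be a single positive number", k)
  }
  if (any(cfg$ascent_windows_s <= 0) || any(cfg$ascent_windows_s %% 300 != 0))
    stopf("ascent_windows_s must be positive multiples of 300 s")
  if (is.unsorted(cfg$region_lat_breaks_degN, strictly = TRUE))
    stopf("region_lat_breaks_degN must be strictly ascending")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path YAML file of `key: value` pairs.
#' @return A [pipeline_config()] object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#'
#' @param config a [pipeline_config()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-32s %s\n", k,
                if (is.null(v)) "NULL" else paste(v, collapse = ", ")))
  }
  invisible(x)
}
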