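#' Multisensor logger dataset
#'
#' Container for the per-bird streams produced by the multisensor loggers:
#' 5-min accelerometer activity scores, 5-min barometric pressure, and
#' approximate daily latitudes from light-level geolocation. One object may
#' hold several birds; every stream row is keyed by `bird_id`.
#'
#' @param activity data frame with columns `bird_id` (character),
#'   `timestamp` (`POSIXct`, UTC, on a 5-min grid), `score` (integer) and
#'   `scale_max` (integer, 5 or 10).
#' @param pressure data frame with columns `bird_id`, `timestamp`
#'   (`POSIXct`, UTC) and `pressure_hpa`.
#' @param latitude data frame with columns `bird_id`, `date` (`Date`) and
#'   `latitude` (degrees North, `NA` allowed), or `NULL`.
#' @return A validated object of class `"logger_dataset"`. Gap positions in
#'   the 5-min grids are flagged in the `gap` column of each stream.
#' @details Validation is strict: any row breaking an invariant (score
#'   outside `[0, scale_max]`, `scale_max` not 5 or 10, pressure outside
#'   (300, 1100) hPa, non-monotone timestamps, latitude outside `[-90, 90]`)
#'   raises an error naming the offending rows. Nothing is dropped silently.
#' @export
logger_dataset <- function(activity = NULL, pressure = NULL, latitude = NULL) {
  activity <- normalise_stream(activity,
    c(bird_id = "character", timestamp = "POSIXct",
      score = "integer", scale_max = "integer"))
  pressure <- normalise_stream(pressure,
    c(bird_id = "character", timestamp = "POSIXct", pressure_hpa = "numeric"))
  latitude <- normalise_stream(latitude,
    c(bird_id = "character", date = "Date", latitude = "numeric"))

  for (s in list(activity, pressure, latitude)) {
    if (nrow(s) && any(grepl("[ ,\"]", s$bird_id)))
      stopf("bird_id must not contain spaces, commas or quotes")
  }
  check_rows("activity", activity, with(activity,
    score < 0 | score > scale_max | !(scale_max %in% c(5L, 10L))),
    "activity score outside [0, scale_max] or scale_max not in {5, 10}")
  check_rows("activity", activity, !on_grid(activity$timestamp),
    "timestamp not on the 5-min grid")
  check_rows("pressure", pressure, with(pressure,
    pressure_hpa <= 300 | pressure_hpa >= 1100),
    "pressure outside the plausible (300, 1100) hPa range")
  check_rows("latitude", latitude, with(latitude,
    !is.na(latitude) & (latitude < -90 | latitude > 90)),
    "latitude outside [-90, 90]")
  check_monotone("activity", activity)
  check_monotone("pressure", pressure)

  activity <- sort_stream(activity)
  pressure <- sort_stream(pressure)
  latitude <- latitude[order(latitude$bird_id, latitude$date), , drop = FALSE]
  rownames(latitude) <- NULL
  activity$gap <- ave_gap(activity)
  pressure$gap <- ave_gap(pressure)

  structure(list(activity = activity, pressure = pressure,
                 latitude = latitude),
            class = "logger_dataset")
}

normalise_stream <- function(df, spec) {
  if (is.null(df)) {
    df <- as.data.frame(lapply(spec, function(cl) switch(cl,
      character = character(0),
      POSIXct = as.POSIXct(character(0), tz = "UTC"),
      Date = as.Date(character(0)),
      integer = integer(0),
      numeric = numeric(0))), stringsAsFactors = FALSE)
    names(df) <- names(spec)
    return(df)
  }
  missing <- setdiff(names(spec), names(df))
  if (length(missing))
    stopf("stream is missing column(s): %s", paste(missing, collapse = ", "))
  df <- df[names(spec)]
  df$bird_id <- as.character(df$bird_id)
  if ("timestamp" %in% names(df)) {
    if (!inherits(df$timestamp, "POSIXct"))
      stopf("timestamp column must be POSIXct (UTC)")
    attr(df$timestamp, "tzone") <- "UTC"
  }
  if ("score" %in% names(df)) df$score <- as.integer(df$score)
  if ("scale_max" %in% names(df)) df$scale_max <- as.integer(df$scale_max)
  rownames(df) <- NULL
  df
}

check_rows <- function(stream, df, bad, why) {
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    stopf("%s stream: %s (row%s %s)", stream, why,
          if (sum(bad) > 1) "s" else "",
          paste(utils::head(which(bad), 10), collapse = ", "))
  }
}

check_monotone <- function(stream, df) {
  for (b in unique(df$bird_id)) {
    t <- df$timestamp[df$bird_id == b]
    if (is.unsorted(t, strictly = TRUE)) {
      i <- which(diff(as.numeric(t)) <= 0)[1]
      stopf("%s stream: timestamps not strictly increasing for bird '%s' (record %d)",
            stream, b, i + 1L)
    }
  }
}

sort_stream <- function(df) {
  df <- df[order(df$bird_id, df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  df
}

ave_gap <- function(df) {
  if (!nrow(df)) return(logical(0))
  unlist(lapply(split(df$timestamp, df$bird_id), flag_gaps),
         use.names = FALSE)
}

#' @export
print.logger_dataset <- function(x, ...) {
  cat(sprintf(
    "<logger_dataset> %d bird(s); %d activity, %d pressure, %d latitude rows\n",
    length(unique(c(x$activity$bird_id, x$pressure$bird_id))),
    nrow(x$activity), nrow(x$pressure), nrow(x$latitude)))
  invisible(x)
}

csv_header <- c("bird_id", "timestamp_utc", "activity_score",
                "activity_scale_max", "pressure_hpa", "latitude")

#' Read a logger dataset from CSV
#'
#' The interchange format is a single flat CSV with the columns
#' `bird_id, timestamp_utc, activity_score, activity_scale_max,
#' pressure_hpa, latitude`. A row may carry an activity sample, a pressure
#' sample, or both (same timestamp); empty fields mean "absent". Latitude is
#' daily and appears on the first row of its bird-date.
#'
#' @param path CSV file written by [write_logger_csv()] or an equivalent.
#' @return A validated [logger_dataset()].
#' @export
read_logger_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  if (!identical(names(df), csv_header))
    stopf("malformed header: expected '%s'", paste(csv_header, collapse = ","))
  if (!nrow(df)) return(logger_dataset())
  ts <- parse_utc(df$timestamp_utc)
  has_act <- df$activity_score != ""
  has_pre <- df$pressure_hpa != ""
  has_lat <- df$latitude != ""
  act <- data.frame(bird_id = df$bird_id[has_act],
                    timestamp = ts[has_act],
                    score = suppressWarnings(as.integer(df$activity_score[has_act])),
                    scale_max = suppressWarnings(as.integer(df$activity_scale_max[has_act])),
                    stringsAsFactors = FALSE)
  if (anyNA(act$score) || anyNA(act$scale_max))
    stopf("non-integer activity fields (row %s)",
          which(has_act)[which(is.na(act$score) | is.na(act$scale_max))[1]])
  pre <- data.frame(bird_id = df$bird_id[has_pre],
                    timestamp = ts[has_pre],
                    pressure_hpa = as.numeric(df$pressure_hpa[has_pre]),
                    stringsAsFactors = FALSE)
  lat <- data.frame(bird_id = df$bird_id[has_lat],
                    date = as.Date(ts[has_lat]),
                    latitude = as.numeric(df$latitude[has_lat]),
                    stringsAsFactors = FALSE)
  lat <- lat[!duplicated(lat[c("bird_id", "date")]), , drop = FALSE]
  logger_dataset(activity = if (nrow(act)) act,
                 pressure = if (nrow(pre)) pre,
                 latitude = if (nrow(lat)) lat)
}

#' Write a logger dataset to CSV
#'
#' Rows are sorted by bird then timestamp, timestamps are ISO-8601 UTC, and
#' absent values are written as empty fields (never the literal `"NA"`), so
#' output is deterministic and round-trips losslessly through
#' [read_logger_csv()].
#'
#' @param dataset a [logger_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_logger_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "logger_dataset"))
  act <- dataset$activity
  pre <- dataset$pressure
  key <- function(b, t) paste(b, as.numeric(t))
  all_keys <- unique(c(key(act$bird_id, act$timestamp),
                       key(pre$bird_id, pre$timestamp)))
  # latitude rides on sample rows; dates without any sample get a
  # latitude-only row at midnight so nothing is lost
  lat_ok <- dataset$latitude[!is.na(dataset$latitude$latitude), , drop = FALSE]
  if (nrow(lat_ok)) {
    have <- unique(paste(sub(" .*", "", all_keys),
                         as.Date(as.POSIXct(
                           as.numeric(sub(".* ", "", all_keys)),
                           origin = "1970-01-01", tz = "UTC"))))
    need <- paste(lat_ok$bird_id, lat_ok$date)
    extra <- lat_ok[!(need %in% have), , drop = FALSE]
    if (nrow(extra)) {
      all_keys <- unique(c(all_keys, key(
        extra$bird_id, as.POSIXct(paste(extra$date, "00:00:00"),
                                  tz = "UTC"))))
    }
  }
  if (length(all_keys)) {
    bird <- sub(" .*", "", all_keys)
    tnum <- as.numeric(sub(".* ", "", all_keys))
    o <- order(bird, tnum)
    bird <- bird[o]; tnum <- tnum[o]
    ts <- as.POSIXct(tnum, origin = "1970-01-01", tz = "UTC")
    ai <- match(key(bird, ts), key(act$bird_id, act$timestamp))
    pi_ <- match(key(bird, ts), key(pre$bird_id, pre$timestamp))
    lat_chr <- character(length(bird))
    if (nrow(dataset$latitude)) {
      lkey <- paste(dataset$latitude$bird_id, dataset$latitude$date)
      rkey <- paste(bird, as.Date(ts))
      first <- !duplicated(rkey)
      li <- match(rkey, lkey)
      show <- first & !is.na(li) & !is.na(dataset$latitude$latitude[li])
      lat_chr[show] <- format_dbl(dataset$latitude$latitude[li[show]])
    }
    num_chr <- format_dbl
    out <- data.frame(
      bird_id = bird,
      timestamp_utc = format_utc(ts),
      activity_score = ifelse(is.na(ai), "", as.character(act$score[ai])),
      activity_scale_max = ifelse(is.na(ai), "", as.character(act$scale_max[ai])),
      pressure_hpa = num_chr(pre$pressure_hpa[pi_]),
      latitude = lat_chr,
      stringsAsFactors = FALSE)
  } else {
    out <- as.data.frame(setNames(rep(list(character(0)), 6), csv_header))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(csv_header, collapse = ","), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(out), sep = ",")), con)
  invisible(path)
}
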