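`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Parse ISO-8601 UTC timestamps
#'
#' @param x character vector like `"2018-04-14T21:05:00Z"`.
#' @return `POSIXct` in UTC.
#' @keywords internal
parse_utc <- function(x) {
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad)) {
    stopf("unparseable ISO-8601 UTC timestamp at position %d: '%s'",
          bad[1], x[bad[1]])
  }
  out
}

format_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

# Floor a POSIXct to the start of its UTC clock-hour.
floor_hour <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 3600) * 3600,
             origin = "1970-01-01", tz = "UTC")
}

# TRUE where consecutive timestamps are not 300 s apart (first element FALSE).
flag_gaps <- function(t) {
  if (length(t) < 2) return(logical(length(t)))
  c(FALSE, diff(as.numeric(t)) != 300)
}

on_grid <- function(t) as.numeric(t) %% 300 == 0

# Shortest decimal representation that round-trips the doubles exactly:
# try 15 significant digits for the whole vector, escalate only where the
# value does not survive the round trip.
format_dbl <- function(x) {
  out <- character(length(x))
  ok <- which(!is.na(x))
  if (!length(ok)) return(out)
  s <- trimws(formatC(x[ok], digits = 15, format = "g"))
  for (d in 16:17) {
    bad <- which(as.numeric(s) != x[ok])
    if (!length(bad)) break
    s[bad] <- trimws(formatC(x[ok][bad], digits = d, format = "g"))
  }
  out[ok] <- s
  out
}
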