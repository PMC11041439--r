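# Internal helpers shared across modules: time arithmetic on epoch-millisecond
# timestamps, great-circle distance, and small validation utilities.

MS_PER_SEC <- 1000
MS_PER_DAY <- 86400 * 1000
EARTH_RADIUS_M <- 6371000  # spherical earth, haversine

#' Great-circle (haversine) distance
#'
#' Distance in meters between points given in decimal degrees, on a
#' 6371 km sphere. Vectorized over all arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Numeric vector of distances in meters.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

# Midnight instants (epoch ms) cutting calendar days in `tz`, covering
# [start_date, start_date + n_days]. Returns n_days + 1 boundaries.
day_boundaries_ms <- function(start_date, n_days, tz = "UTC") {
  start_date <- as.Date(start_date)
  dates <- seq(start_date, by = "day", length.out = n_days + 1)
  as.numeric(as.POSIXct(paste(dates, "00:00:00"), tz = tz)) * MS_PER_SEC
}

# Epoch-ms of local midnight starting `day` (a Date) in `tz`.
day_start_ms <- function(day, tz = "UTC") {
  as.numeric(as.POSIXct(paste(as.Date(day), "00:00:00"), tz = tz)) * MS_PER_SEC
}

day_end_ms <- function(day, tz = "UTC") {
  day_start_ms(as.Date(day) + 1L, tz)
}

# Local calendar date of epoch-ms timestamps.
ms_to_date <- function(t_ms, tz = "UTC") {
  as.Date(as.POSIXct(t_ms / MS_PER_SEC, origin = "1970-01-01", tz = tz), tz = tz)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

# Intersect a set of [start, end) intervals (two-column matrix) with a second
# set; both must be non-overlapping and sorted. Returns total overlap length.
interval_overlap <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1])
    hi <- pmin(a[i, 2], b[, 2])
    tot <- tot + sum(pmax(0, hi - lo))
  }
  tot
}
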