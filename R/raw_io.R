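# Raw-record data model and per-sensor text-file I/O.
#
# Each sensor source is stored as one UTF-8 CSV file with a header row and
# epoch-millisecond timestamps, mirroring the acquisition convention of one
# raw text file per sensor. Records are plain data.frames tagged with a
# `pd_kind` attribute so downstream code can dispatch on the source.

#' Supported sensor source kinds
#'
#' @return Character vector of source-kind identifiers.
#' @export
stream_kinds <- function() {
  c("accel", "gps", "calls", "screen", "apps", "sms")
}

# Column schema per source kind. `sms` is carried read-only for completeness;
# no feature consumes it.
.kind_schema <- list(
  accel  = c(t = "numeric", ax = "numeric", ay = "numeric", az = "numeric"),
  gps    = c(t = "numeric", lat = "numeric", lon = "numeric", accuracy = "numeric"),
  calls  = c(t = "numeric", direction = "character", duration_s = "numeric"),
  screen = c(t = "numeric", state = "character"),
  apps   = c(t = "numeric", app_id = "character", kb = "numeric"),
  sms    = c(t = "numeric", direction = "character")
)

.kind_file <- c(accel = "accel.csv", gps = "gps.csv", calls = "calls.csv",
                screen = "screen.csv", apps = "apps.csv", sms = "sms.csv")

as_stream <- function(df, kind) {
  df <- as.data.frame(df)
  attr(df, "pd_kind") <- kind
  df
}

#' @rdname read_stream
#' @param df A data.frame of records.
#' @export
stream_kind <- function(df) attr(df, "pd_kind")

# Per-row validity mask for a record data.frame of the given kind.
# Returns a list(valid = logical, reason = character).
.validate_rows <- function(df, kind) {
  n <- nrow(df)
  ok <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  flag <- function(bad, why) {
    bad <- bad & ok
    ok[bad] <<- FALSE
    reason[bad] <<- why
  }
  flag(!is.finite(df$t), "non-finite timestamp")
  if (kind == "accel") {
    flag(!is.finite(df$ax) | !is.finite(df$ay) | !is.finite(df$az),
         "non-finite acceleration")
  } else if (kind == "gps") {
    flag(!is.finite(df$lat) | df$lat < -90 | df$lat > 90,
         "lat outside [-90, 90]")
    flag(!is.finite(df$lon) | df$lon < -180 | df$lon > 180,
         "lon outside [-180, 180]")
  } else if (kind == "calls") {
    flag(!df$direction %in% c("incoming", "outgoing", "missed"),
         "unknown call direction")
    flag(!is.finite(df$duration_s) | df$duration_s < 0,
         "negative or non-finite duration")
    flag(df$direction == "missed" & df$duration_s != 0,
         "missed call with nonzero duration")
  } else if (kind == "screen") {
    flag(!df$state %in% c("on", "off"), "unknown screen state")
  } else if (kind == "apps") {
    flag(!nzchar(df$app_id) | is.na(df$app_id), "empty app_id")
    flag(!is.finite(df$kb) | df$kb < 0, "negative or non-finite kb")
  } else if (kind == "sms") {
    flag(!df$direction %in% c("incoming", "outgoing"), "unknown sms direction")
  }
  list(valid = ok, reason = reason)
}

#' Read a raw per-sensor log file
#'
#' Reads one sensor's raw CSV log, validates every row against the source
#' schema and invariants (coordinate bounds, nonnegative durations/traffic,
#' known enum values), drops invalid rows with a warning naming their line
#' numbers, and returns records sorted by timestamp. Out-of-order input is
#' sorted with a warning; well-formed rows are never silently dropped.
#'
#' @param path Path to the CSV file.
#' @param source_kind One of [stream_kinds()].
#' @return A data.frame of validated, time-sorted records with a `pd_kind`
#'   attribute; the number of dropped rows is attached as attribute
#'   `dropped_rows`.
#' @export
read_stream <- function(path, source_kind) {
  if (!source_kind %in% stream_kinds())
    stopf("unknown source_kind '%s'; expected one of: %s", source_kind,
          paste(stream_kinds(), collapse = ", "))
  if (!file.exists(path)) stopf("file not found: %s", path)
  schema <- .kind_schema[[source_kind]]
  df <- tryCatch(
    data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE,
                      colClasses = unname(schema), fill = TRUE,
                      showProgress = FALSE),
    error = function(e) stopf("failed to parse %s: %s", path, conditionMessage(e))
  )
  missing_cols <- setdiff(setdiff(names(schema), "accuracy"), names(df))
  if (length(missing_cols))
    stopf("%s: header does not match '%s' schema (missing: %s)", path,
          source_kind, paste(missing_cols, collapse = ", "))
  if (source_kind == "gps" && !"accuracy" %in% names(df))
    df$accuracy <- rep(NA_real_, nrow(df))
  df <- df[names(schema)]
  if (nrow(df)) {
    chk <- .validate_rows(df, source_kind)
    if (any(!chk$valid)) {
      bad <- which(!chk$valid)
      warnf("%s: dropped %d malformed row(s) [line %s: %s]", path, length(bad),
            paste(utils::head(bad + 1L, 5), collapse = ","),
            paste(unique(chk$reason[bad]), collapse = "; "))
      df <- df[chk$valid, , drop = FALSE]
    }
    if (is.unsorted(df$t)) {
      warnf("%s: records out of time order; sorting", path)
      df <- df[order(df$t), , drop = FALSE]
    }
    rownames(df) <- NULL
  }
  out <- as_stream(df, source_kind)
  attr(out, "dropped_rows") <- if (nrow(df)) sum(!chk$valid) else 0L
  out
}

#' Write a raw per-sensor log file
#'
#' Validates records against the source-kind invariants and writes them as a
#' header-row CSV. Round-trips with [read_stream()]: reading a written file
#' recovers the records exactly.
#'
#' @param records Data.frame of records (a `pd_kind` attribute, as produced by
#'   [read_stream()] or the simulator, identifies the source; otherwise pass
#'   `source_kind`).
#' @param path Output file path.
#' @param source_kind Source kind; defaults to the records' `pd_kind`.
#' @return `path`, invisibly.
#' @export
write_stream <- function(records, path, source_kind = stream_kind(records)) {
  if (is.null(source_kind) || !source_kind %in% stream_kinds())
    stopf("source_kind must be one of: %s", paste(stream_kinds(), collapse = ", "))
  schema <- .kind_schema[[source_kind]]
  records <- as.data.frame(records)
  missing_cols <- setdiff(setdiff(names(schema), "accuracy"), names(records))
  if (length(missing_cols))
    stopf("records lack column(s): %s", paste(missing_cols, collapse = ", "))
  if (source_kind == "gps" && !"accuracy" %in% names(records))
    records$accuracy <- rep(NA_real_, nrow(records))
  records <- records[names(schema)]
  if (nrow(records)) {
    chk <- .validate_rows(records, source_kind)
    if (any(!chk$valid))
      stopf("invalid record(s) at row %s: %s",
            paste(utils::head(which(!chk$valid), 5), collapse = ","),
            paste(unique(chk$reason[!chk$valid]), collapse = "; "))
    if (is.unsorted(records$t)) stopf("records must be sorted by t")
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    data.table::fwrite(records, path, sep = ",")
    TRUE
  }, error = function(e) stopf("cannot write %s: %s", path, conditionMessage(e)))
  invisible(path)
}

#' Bundle per-sensor streams for one user
#'
#' Container for a user's time-sorted record streams plus the timezone used
#' to cut calendar days. Each stream is validated on construction.
#'
#' @param user_id Nonempty identifier string.
#' @param ... Named streams (`accel`, `gps`, `calls`, `screen`, `apps`, `sms`),
#'   each a record data.frame of the matching kind.
#' @param tz IANA timezone used for day boundaries (default `"UTC"`).
#' @return An object of class `sensor_streams`.
#' @export
sensor_streams <- function(user_id, ..., tz = "UTC") {
  if (!is.character(user_id) || length(user_id) != 1L || !nzchar(user_id))
    stopf("user_id must be a nonempty string")
  streams <- list(...)
  if (length(streams) == 1L && is.null(names(streams)) && is.list(streams[[1]]) &&
      !is.data.frame(streams[[1]]))
    streams <- streams[[1]]
  bad <- setdiff(names(streams), stream_kinds())
  if (length(bad)) stopf("unknown stream kind(s): %s", paste(bad, collapse = ", "))
  for (k in names(streams)) {
    s <- as.data.frame(streams[[k]])
    if (nrow(s)) {
      chk <- .validate_rows(s, k)
      if (any(!chk$valid))
        stopf("stream '%s' has invalid rows: %s", k,
              paste(unique(chk$reason[!chk$valid]), collapse = "; "))
      if (is.unsorted(s$t)) stopf("stream '%s' is not time-sorted", k)
    }
    streams[[k]] <- as_stream(s, k)
  }
  structure(list(user_id = user_id, streams = streams, tz = tz),
            class = "sensor_streams")
}

#' @export
print.sensor_streams <- function(x, ...) {
  cat("<sensor_streams> user:", x$user_id, " tz:", x$tz, "\n")
  for (k in names(x$streams)) {
    s <- x$streams[[k]]
    span <- if (nrow(s)) sprintf(" [%s .. %s]",
                                 format(ms_to_date(min(s$t), x$tz)),
                                 format(ms_to_date(max(s$t), x$tz))) else ""
    cat(sprintf("  %-6s %8d records%s\n", k, nrow(s), span))
  }
  invisible(x)
}

#' Collapse repeated same-state screen events
#'
#' After device reboots the registry can log the same state twice in a row;
#' repeated states are collapsed to their first occurrence so that on/off
#' events strictly alternate.
#'
#' @param events Screen-event data.frame (`t`, `state`).
#' @return The normalized events, same shape.
#' @export
normalize_screen <- function(events) {
  events <- as.data.frame(events)
  if (nrow(events) <= 1L) return(as_stream(events, "screen"))
  if (is.unsorted(events$t)) stopf("screen events must be time-sorted")
  keep <- c(TRUE, events$state[-1] != events$state[-nrow(events)])
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  as_stream(out, "screen")
}

#' Write all streams of a user to a directory
#'
#' One CSV per sensor (`accel.csv`, `gps.csv`, ...), the dialect of
#' [write_stream()].
#'
#' @param streams A [sensor_streams()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_streams_dir <- function(streams, dir) {
  stopifnot(inherits(streams, "sensor_streams"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in names(streams$streams))
    write_stream(streams$streams[[k]], file.path(dir, .kind_file[[k]]), k)
  invisible(dir)
}

#' Read all per-sensor CSVs found in a directory
#'
#' @param dir Directory holding `accel.csv`, `gps.csv`, ... (any subset).
#' @param user_id User identifier for the bundle.
#' @param tz Day-boundary timezone.
#' @return A [sensor_streams()] object.
#' @export
read_streams_dir <- function(dir, user_id = basename(dir), tz = "UTC") {
  present <- .kind_file[file.exists(file.path(dir, .kind_file))]
  if (!length(present)) stopf("no sensor CSVs found in %s", dir)
  streams <- lapply(names(present), function(k)
    read_stream(file.path(dir, present[[k]]), k))
  names(streams) <- names(present)
  sensor_streams(user_id, streams, tz = tz)
}
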