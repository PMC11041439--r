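# Acquisition-gap detection and data-integrity quantification.
#
# A segment is a maximal run of samples with no inter-sample interruption
# greater than `max_interruption` (1 s for the 5 Hz embedded sensors); the
# data-integrity percentage is 100 * acquired hours / running hours. Devices
# are classified into power-saving subgroups by how strongly acquisition
# gaps coincide with screen-off spans.

#' Detect maximal uninterrupted sampling segments
#'
#' Splits a time-sorted sample vector into maximal runs whose consecutive
#' samples are at most `max_interruption` seconds apart. The complement of
#' the segments within `[first, last]` is the gap list. A single isolated
#' sample forms a zero-duration segment, so segment plus gap durations
#' always reconstruct the observed span exactly.
#'
#' @param samples Record data.frame with a `t` column (epoch ms), or a
#'   numeric vector of epoch-ms timestamps; must be sorted.
#' @param max_interruption Largest tolerated inter-sample spacing, seconds
#'   (default 1).
#' @return data.frame with columns `start`, `end` (epoch ms), plus the gap
#'   complement as attribute `gaps` (same shape).
#' @export
detect_gaps <- function(samples, max_interruption = 1) {
  t <- if (is.data.frame(samples)) samples$t else as.numeric(samples)
  if (is.unsorted(t)) stopf("samples must be sorted by t")
  if (!length(t)) {
    seg <- data.frame(start = numeric(0), end = numeric(0))
    attr(seg, "gaps") <- data.frame(start = numeric(0), end = numeric(0))
    return(seg)
  }
  brk <- which(diff(t) > max_interruption * MS_PER_SEC)
  starts <- t[c(1, brk + 1)]
  ends <- t[c(brk, length(t))]
  seg <- data.frame(start = starts, end = ends)
  attr(seg, "gaps") <- if (length(brk))
    data.frame(start = t[brk], end = t[brk + 1]) else
    data.frame(start = numeric(0), end = numeric(0))
  seg
}

#' Data-integrity percentage
#'
#' The share of running time covered by uninterrupted sampling:
#' `100 * acquired_hours / running_hours`.
#'
#' @param acquired_hours Hours covered by sampling segments.
#' @param running_hours Hours the acquisition was supposed to run; must be
#'   positive and at least `acquired_hours`.
#' @return Percentage in `[0, 100]`.
#' @export
integrity_percentage <- function(acquired_hours, running_hours) {
  if (running_hours <= 0) stopf("running_hours must be > 0 (integrity undefined)")
  if (acquired_hours < 0 || acquired_hours > running_hours)
    stopf("acquired_hours must lie in [0, running_hours]")
  100 * acquired_hours / running_hours
}

#' Per-sensor integrity report
#'
#' Computes sampling segments per sensor, intersects them with the declared
#' running intervals (the spans during which acquisition was supposed to be
#' active), and reports acquired hours, running hours, the integrity
#' percentage and the gap list per sensor plus a duration-weighted overall
#' figure.
#'
#' Event registries (calls, screen, apps) are not sampled streams, so by
#' default only the continuously sampled sensors are assessed; the 1 s
#' interruption rule matches the 5 Hz accelerometer, and a coarser
#' tolerance is used for the 1/min GPS cadence.
#'
#' @param streams A [sensor_streams()] object.
#' @param running_intervals Two-column matrix (or `c(start, end)`) of
#'   non-overlapping epoch-ms running spans.
#' @param sensors Sensors to assess (default `"accel"`, plus `"gps"` when
#'   present).
#' @param max_interruption Named seconds per sensor (default
#'   `c(accel = 1, gps = 120)`); unnamed scalar applies to all.
#' @return An `integrity_report`: per-sensor list (`segments`, `gaps`,
#'   `acquired_hours`, `running_hours`, `integrity_pct`) plus `overall`.
#' @export
compute_integrity_report <- function(streams, running_intervals,
                                     sensors = intersect(c("accel", "gps"),
                                                         names(streams$streams)),
                                     max_interruption = c(accel = 1, gps = 120)) {
  stopifnot(inherits(streams, "sensor_streams"))
  if (is.null(dim(running_intervals)))
    running_intervals <- matrix(running_intervals, ncol = 2, byrow = TRUE)
  if (!nrow(running_intervals)) stopf("running_intervals must be nonempty")
  if (any(running_intervals[, 2] <= running_intervals[, 1]))
    stopf("running intervals must have end > start")
  o <- order(running_intervals[, 1])
  running_intervals <- running_intervals[o, , drop = FALSE]
  if (nrow(running_intervals) > 1 &&
      any(running_intervals[-1, 1] < running_intervals[-nrow(running_intervals), 2]))
    stopf("running_intervals must be non-overlapping")
  running_h <- sum(running_intervals[, 2] - running_intervals[, 1]) /
    MS_PER_SEC / 3600
  per_sensor <- list()
  for (k in sensors) {
    if (!k %in% names(streams$streams)) stopf("no '%s' stream", k)
    mi <- if (is.null(names(max_interruption))) max_interruption[[1]]
          else if (k %in% names(max_interruption)) max_interruption[[k]] else 1
    seg <- detect_gaps(streams$streams[[k]], max_interruption = mi)
    acq_ms <- if (nrow(seg))
      interval_overlap(as.matrix(seg), running_intervals) else 0
    acq_h <- acq_ms / MS_PER_SEC / 3600
    per_sensor[[k]] <- list(
      segments = seg, gaps = attr(seg, "gaps"),
      acquired_hours = acq_h, running_hours = running_h,
      integrity_pct = integrity_percentage(min(acq_h, running_h), running_h))
  }
  tot_acq <- sum(vapply(per_sensor, `[[`, numeric(1), "acquired_hours"))
  tot_run <- running_h * length(per_sensor)
  structure(list(
    sensors = per_sensor,
    running_intervals = running_intervals,
    overall = list(acquired_hours = tot_acq, running_hours = tot_run,
                   integrity_pct = integrity_percentage(min(tot_acq, tot_run),
                                                        tot_run))),
    class = "integrity_report")
}

#' @export
print.integrity_report <- function(x, ...) {
  cat("<integrity_report>\n")
  for (k in names(x$sensors)) {
    s <- x$sensors[[k]]
    cat(sprintf("  %-6s acquired %8.1f h / running %8.1f h  integrity %5.1f%%  (%d gaps)\n",
                k, s$acquired_hours, s$running_hours, s$integrity_pct,
                nrow(s$gaps)))
  }
  cat(sprintf("  overall integrity %5.1f%%\n", x$overall$integrity_pct))
  invisible(x)
}

#' Classify a device's power-saving subgroup
#'
#' Subgroup B devices suspend embedded-sensor acquisition while the phone
#' is unused, so their gaps concentrate inside screen-off spans. The rule:
#' the device is `B` when at least `overlap_threshold` of the total gap
#' duration lies within screen-off intervals AND gaps exceed `gap_floor`
#' of running time; `A` when the gap fraction is at or below the floor;
#' `indeterminate` otherwise (substantial gaps uncorrelated with screen
#' state, or no screen events to correlate with).
#'
#' @param report An [compute_integrity_report()] result.
#' @param screen_events Screen on/off event data.frame covering the span.
#' @param overlap_threshold Minimum fraction of gap time inside screen-off
#'   spans to call B (default 0.8).
#' @param gap_floor Gap fraction of running time below which the device is
#'   A (default 0.05).
#' @return Character scalar `"A"`, `"B"` or `"indeterminate"`, with a
#'   `reason` attribute.
#' @export
classify_policy_subgroup <- function(report, screen_events,
                                     overlap_threshold = 0.8,
                                     gap_floor = 0.05) {
  stopifnot(inherits(report, "integrity_report"))
  run <- report$running_intervals
  run_ms <- sum(run[, 2] - run[, 1])
  gaps <- do.call(rbind, lapply(report$sensors, function(s) as.matrix(s$gaps)))
  if (is.null(gaps)) gaps <- matrix(numeric(0), 0, 2)
  gap_ms <- if (nrow(gaps)) interval_overlap(gaps, run) else 0
  gap_frac <- gap_ms / (run_ms * length(report$sensors))
  if (gap_frac <= gap_floor)
    return(structure("A", reason = sprintf("gap fraction %.1f%% <= floor",
                                           100 * gap_frac)))
  screen_events <- as.data.frame(screen_events)
  if (!nrow(screen_events))
    return(structure("indeterminate", reason = "no screen events"))
  screen_events <- normalize_screen(screen_events)
  # screen-off spans = running span minus on-sessions
  on_iv <- .screen_on_intervals(screen_events, run[1, 1], run[nrow(run), 2])
  off_iv <- .subtract_intervals(matrix(c(run[1, 1], run[nrow(run), 2]), 1), on_iv)
  in_off <- if (nrow(gaps)) interval_overlap(gaps, off_iv) else 0
  overlap <- in_off / max(gap_ms, 1)
  if (overlap >= overlap_threshold)
    structure("B", reason = sprintf("%.0f%% of gap time during screen-off",
                                    100 * overlap))
  else
    structure("indeterminate",
              reason = sprintf("gaps substantial (%.1f%%) but only %.0f%% within screen-off",
                               100 * gap_frac, 100 * overlap))
}

# Screen-on [on, off) intervals from normalized alternating events, clipped
# to [span_start, span_end); an unmatched leading "off" opens at span_start,
# an unmatched trailing "on" closes at span_end.
.screen_on_intervals <- function(events, span_start, span_end) {
  ev <- as.data.frame(events)
  if (!nrow(ev)) return(matrix(numeric(0), 0, 2))
  t <- ev$t; st <- ev$state
  if (st[1] == "off") { t <- c(span_start, t); st <- c("on", st) }
  if (st[length(st)] == "on") { t <- c(t, span_end); st <- c(st, "off") }
  iv <- cbind(t[st == "on"], t[st == "off"])
  iv[, 1] <- pmax(iv[, 1], span_start)
  iv[, 2] <- pmin(iv[, 2], span_end)
  iv[iv[, 2] > iv[, 1], , drop = FALSE]
}

#' Per-day gap table
#'
#' Tabulates each sensor's gaps split at local midnights — the shape used
#' by the `integrity` CLI stage.
#'
#' @param report An [compute_integrity_report()] result.
#' @param tz Day-cutting timezone.
#' @return data.frame (`day`, `sensor`, `gap_start`, `gap_end`) in epoch ms.
#' @export
gap_table <- function(report, tz = "UTC") {
  stopifnot(inherits(report, "integrity_report"))
  rows <- list()
  for (k in names(report$sensors)) {
    g <- report$sensors[[k]]$gaps
    for (i in seq_len(nrow(g))) {
      s <- g$start[i]; e <- g$end[i]
      while (s < e) {
        day <- ms_to_date(s, tz)
        cut <- min(e, day_end_ms(day, tz))
        rows[[length(rows) + 1]] <- data.frame(
          day = as.character(day), sensor = k, gap_start = s, gap_end = cut)
        s <- cut
      }
    }
  }
  if (!length(rows)) return(data.frame(day = character(0), sensor = character(0),
                                       gap_start = numeric(0), gap_end = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
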