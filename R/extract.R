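# Assembles the full per-day feature table from a user's sensor streams:
# call, screen, app and activity features plus the GPS location features
# (places clustered once over the whole window, dwell attributed per day).

# Row offsets of a time-sorted frame at each boundary instant, computed in
# one pass (findInterval re-validates sortedness of its second argument on
# every call, which is ruinous per-day on multi-million-row accel streams).
.day_offsets <- function(df, bnd_ms) findInterval(bnd_ms - 0.5, df$t)

.slice_rows <- function(df, off, i) {
  if (off[i + 1] <= off[i]) df[0, , drop = FALSE]
  else df[(off[i] + 1L):off[i + 1L], , drop = FALSE]
}

#' Extract the daily behavioral feature table
#'
#' Computes every per-day feature for each calendar day in the streams'
#' observed span: call aggregates, screen-use features with 24 hourly
#' `b_n` slots, per-category app traffic, hourly accelerometer activity
#' (`m_amp_n`, `s_a_n`, `s_r_n`, `percentage_activity`) and GPS location
#' features. Missing observations stay `NA` (see the individual feature
#' functions); downstream imputation happens in [build_matrix()].
#'
#' @param streams A [sensor_streams()] object.
#' @param high_threshold Activity dynamic-amplitude threshold, m/s2.
#' @param radius,min_dwell [cluster_fixes()] parameters.
#' @param category_map App-to-category map for [app_features()].
#' @param days Optional vector of dates to restrict to.
#' @return data.frame with one row per day (`day` column of class Date) and
#'   one column per feature; the fitted [cluster_fixes()] object (with home
#'   identified) is attached as attribute `clusters`, the per-day
#'   `visited_clusters` tables as attribute `visited`.
#' @export
extract_features <- function(streams, high_threshold = 0.5, radius = 100,
                             min_dwell = 300,
                             category_map = default_app_categories(),
                             days = NULL) {
  stopifnot(inherits(streams, "sensor_streams"))
  tz <- streams$tz
  s <- streams$streams
  all_t <- unlist(lapply(s, function(x) if (nrow(x)) range(x$t) else NULL))
  if (is.null(all_t)) stopf("streams contain no records")
  if (is.null(days)) {
    days <- seq(ms_to_date(min(all_t), tz), ms_to_date(max(all_t) - 1, tz),
                by = "day")
  } else days <- as.Date(days)

  clusters <- NULL
  if (!is.null(s$gps) && nrow(s$gps) >= 2) {
    clusters <- cluster_fixes(s$gps, radius = radius, min_dwell = min_dwell)
    if (nrow(clusters$clusters))
      clusters <- identify_home(clusters, s$gps, tz = tz)
  }

  bnd <- c(vapply(days, day_start_ms, numeric(1), tz = tz),
           day_end_ms(days[length(days)], tz))
  acc_off <- if (!is.null(s$accel)) .day_offsets(s$accel, bnd)

  hr_names <- function(pre) paste0(pre, "_", 1:24)
  rows <- vector("list", length(days))
  visited <- vector("list", length(days))
  for (i in seq_along(days)) {
    day <- days[i]
    ds <- day_start_ms(day, tz); de <- day_end_ms(day, tz)
    row <- list(day = as.character(day))

    cf <- if (!is.null(s$calls)) call_features(s$calls, day, tz)
          else list(mean_incoming = NA_real_, mean_outgoing = NA_real_,
                    tot_call_length = NA_real_, outgoing_call = NA_real_)
    row <- c(row, cf)

    if (!is.null(s$screen)) {
      sess <- screen_sessions(s$screen, day, tz)
      bf <- brightness_features(sess, day, tz)
    } else bf <- list(mean_time_usage = NA_real_, number_switch_on = NA_real_,
                      b = rep(NA_real_, 24))
    row <- c(row, bf[c("mean_time_usage", "number_switch_on")],
             stats::setNames(as.list(bf$b), hr_names("b")))

    af <- if (!is.null(s$apps)) app_features(s$apps, day, category_map, tz)
          else list(tot_kb_social = NA_real_, tot_kb_communication = NA_real_,
                    tot_kb_navigation = NA_real_, tot_kb = NA_real_)
    row <- c(row, af)

    if (!is.null(s$accel)) {
      acc_day <- .slice_rows(s$accel, acc_off, i)
      act <- activity_features(acc_day, day, high_threshold, tz)
    } else act <- list(m_amp = rep(NA_real_, 24), s_a = rep(NA_real_, 24),
                       s_r = rep(NA_real_, 24), percentage_activity = NA_real_)
    row <- c(row,
             stats::setNames(as.list(act$m_amp), hr_names("m_amp")),
             stats::setNames(as.list(act$s_a), hr_names("s_a")),
             stats::setNames(as.list(act$s_r), hr_names("s_r")),
             list(percentage_activity = act$percentage_activity))

    if (!is.null(clusters)) {
      gf <- gps_day_features(s$gps, clusters, day, tz)
      visited[[i]] <- gf$visited_clusters
      gf$visited_clusters <- NULL
    } else gf <- list(number_of_clusters = NA_real_, time_outside = NA_real_,
                      location_variance = NA_real_, entropy = NA_real_,
                      normalized_entropy = NA_real_)
    row <- c(row, gf)
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$day <- as.Date(out$day)
  rownames(out) <- NULL
  attr(out, "clusters") <- clusters
  attr(out, "visited") <- stats::setNames(visited, as.character(days))
  out
}
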