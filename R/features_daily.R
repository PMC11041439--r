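# Per-calendar-day behavioral features: call aggregates, screen-use
# sessions, per-app traffic by category, and hourly accelerometer activity.
#
# Hour-slot convention throughout: slot n (n = 1..24) covers local time
# [n-1, n). Means with an empty denominator (no incoming calls, no
# sessions, no samples in a slot) are reported as NA — "no observation" is
# behaviorally different from zero; imputation is the anomaly stage's job.

.day_filter <- function(df, day, tz) {
  ds <- day_start_ms(day, tz); de <- day_end_ms(day, tz)
  df[df$t >= ds & df$t < de, , drop = FALSE]
}

#' Daily call aggregates
#'
#' Mean incoming / outgoing call durations, total call time and outgoing
#' call count for one calendar day. Missed calls are excluded from every
#' feature.
#'
#' @param calls Call-record data.frame (`t`, `direction`, `duration_s`),
#'   time-sorted.
#' @param day Calendar date (anything `as.Date()` accepts).
#' @param tz Day-boundary timezone.
#' @return Named list: `mean_incoming`, `mean_outgoing` (s; `NA` when no
#'   such calls), `tot_call_length` (s), `outgoing_call` (count).
#' @export
call_features <- function(calls, day, tz = "UTC") {
  d <- .day_filter(as.data.frame(calls), day, tz)
  inc <- d$duration_s[d$direction == "incoming"]
  out <- d$duration_s[d$direction == "outgoing"]
  list(mean_incoming = if (length(inc)) mean(inc) else NA_real_,
       mean_outgoing = if (length(out)) mean(out) else NA_real_,
       tot_call_length = sum(inc) + sum(out),
       outgoing_call = length(out))
}

#' Screen-use sessions of one day
#'
#' Pairs screen-on with the following screen-off event and clips the
#' resulting sessions to the day: a session open at midnight is truncated
#' at the boundary with its remainder credited to the next day, and a day
#' that starts mid-session (first event is `off`) is counted from 00:00.
#'
#' @param events Screen events (`t`, `state`), time-sorted; repeated states
#'   are normalized away.
#' @param day Calendar date.
#' @param tz Day-boundary timezone.
#' @return data.frame (`on_t`, `off_t`, epoch ms) clipped to the day.
#' @export
screen_sessions <- function(events, day, tz = "UTC") {
  ev <- normalize_screen(as.data.frame(events))
  ds <- day_start_ms(day, tz); de <- day_end_ms(day, tz)
  if (!nrow(ev)) return(data.frame(on_t = numeric(0), off_t = numeric(0)))
  span_start <- min(ev$t[1], ds)
  span_end <- max(ev$t[nrow(ev)], de)
  iv <- .screen_on_intervals(ev, span_start, span_end)
  iv[, 1] <- pmax(iv[, 1], ds)
  iv[, 2] <- pmin(iv[, 2], de)
  iv <- iv[iv[, 2] > iv[, 1], , drop = FALSE]
  data.frame(on_t = iv[, 1], off_t = iv[, 2])
}

#' Daily screen-use features
#'
#' @param sessions Day-clipped sessions from [screen_sessions()].
#' @param day Calendar date.
#' @param tz Day-boundary timezone.
#' @return Named list: `mean_time_usage` (mean session length, s; `NA` when
#'   no sessions), `number_switch_on` (count of screen-on events within the
#'   day; a session truncated at 00:00 is not a switch-on), and `b` — 24
#'   seconds-of-use values, slot n covering local hour [n-1, n).
#' @export
brightness_features <- function(sessions, day, tz = "UTC") {
  ds <- day_start_ms(day, tz)
  hours <- cbind(ds + (0:23) * 3600 * MS_PER_SEC,
                 ds + (1:24) * 3600 * MS_PER_SEC)
  b <- numeric(24)
  if (nrow(sessions)) {
    iv <- cbind(sessions$on_t, sessions$off_t)
    b <- vapply(1:24, function(h)
      interval_overlap(hours[h, , drop = FALSE], iv) / MS_PER_SEC, numeric(1))
  }
  dur <- (sessions$off_t - sessions$on_t) / MS_PER_SEC
  list(mean_time_usage = if (nrow(sessions)) mean(dur) else NA_real_,
       number_switch_on = sum(sessions$on_t > ds),
       b = b)
}

#' Default app-to-category map
#'
#' Social: Facebook, Instagram, Twitter, LinkedIn. Communication: WhatsApp,
#' Messenger, Telegram, Skype, Hangouts. Navigation: Chrome, Firefox,
#' Browser, Google, YouTube, Tripadvisor. Matching is case-insensitive on
#' the app identifier; anything else counts only toward the daily total.
#'
#' @return Named character vector mapping app name to category.
#' @export
default_app_categories <- function() {
  c(Facebook = "social", Instagram = "social", Twitter = "social",
    LinkedIn = "social",
    WhatsApp = "communication", Messenger = "communication",
    Telegram = "communication", Skype = "communication",
    Hangouts = "communication",
    Chrome = "navigation", Firefox = "navigation", Browser = "navigation",
    Google = "navigation", YouTube = "navigation", Tripadvisor = "navigation")
}

#' Daily per-category app traffic
#'
#' @param records App-usage records (`t`, `app_id`, `kb`), time-sorted.
#' @param day Calendar date.
#' @param category_map Named app-to-category vector; default
#'   [default_app_categories()].
#' @param tz Day-boundary timezone.
#' @return Named list: `tot_kb_social`, `tot_kb_communication`,
#'   `tot_kb_navigation`, `tot_kb` (the latter includes uncategorized apps).
#' @export
app_features <- function(records, day, category_map = default_app_categories(),
                         tz = "UTC") {
  d <- .day_filter(as.data.frame(records), day, tz)
  cat <- unname(category_map[match(tolower(d$app_id),
                                   tolower(names(category_map)))])
  kb_of <- function(cc) sum(d$kb[!is.na(cat) & cat == cc])
  list(tot_kb_social = kb_of("social"),
       tot_kb_communication = kb_of("communication"),
       tot_kb_navigation = kb_of("navigation"),
       tot_kb = sum(d$kb))
}

#' Daily hourly accelerometer activity features
#'
#' Signal amplitude is the 3-axis Euclidean norm; the dynamic amplitude
#' subtracts standing gravity, `|norm - 9.81|`. Each wall-clock second that
#' contains samples is classified high-activity when its mean dynamic
#' amplitude exceeds `high_threshold`, else low. Per hour slot n
#' (local [n-1, n)): `m_amp` is the mean raw amplitude over the slot's
#' samples (`NA` when the slot has none), `s_a`/`s_r` count high/low
#' seconds. `percentage_activity` = high / (high + low) over the whole day.
#'
#' @param accel Accelerometer samples (`t`, `ax`, `ay`, `az`), time-sorted.
#' @param day Calendar date.
#' @param high_threshold Dynamic-amplitude threshold in m/s2 (default 0.5).
#' @param tz Day-boundary timezone.
#' @param gravity Standing-gravity magnitude subtracted for the dynamic
#'   amplitude (default 9.81 m/s2).
#' @return Named list: `m_amp`, `s_a`, `s_r` (24-vectors),
#'   `percentage_activity` (fraction in `[0,1]`, `NA` for a day with no
#'   samples).
#' @export
activity_features <- function(accel, day, high_threshold = 0.5, tz = "UTC",
                              gravity = 9.81) {
  d <- .day_filter(as.data.frame(accel), day, tz)
  m_amp <- rep(NA_real_, 24); s_a <- integer(24); s_r <- integer(24)
  if (!nrow(d)) {
    return(list(m_amp = m_amp, s_a = s_a, s_r = s_r,
                percentage_activity = NA_real_))
  }
  ds <- day_start_ms(day, tz)
  amp <- sqrt(d$ax^2 + d$ay^2 + d$az^2)
  dyn <- abs(amp - gravity)
  sec <- as.integer((d$t - ds) %/% MS_PER_SEC)   # 0 .. 86399
  # per-second mean dynamic amplitude -> high/low classification
  # (radix grouping; rowsum's factor coercion is too slow at 5 Hz x 86400 s)
  dt <- data.table::data.table(sec = sec, dyn = dyn, amp = amp)
  per_sec <- dt[, list(m = mean(dyn)), by = "sec"]
  high <- per_sec$m > high_threshold
  sec_hour <- per_sec$sec %/% 3600L + 1L
  s_a <- as.integer(tabulate(sec_hour[high], 24))
  s_r <- as.integer(tabulate(sec_hour[!high], 24))
  # per-hour mean raw amplitude
  dt[, "hour" := sec %/% 3600L + 1L]
  per_hour <- dt[, list(m = mean(amp)), by = "hour"]
  m_amp[per_hour$hour] <- per_hour$m
  tot <- sum(s_a) + sum(s_r)
  list(m_amp = m_amp, s_a = s_a, s_r = s_r,
       percentage_activity = if (tot > 0) sum(s_a) / tot else NA_real_)
}
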