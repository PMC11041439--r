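# Daily feature formulas: calls, screen sessions and hourly slots, app
# categories, accelerometer activity.

test_that("call aggregates follow the daily formulas, excluding missed calls", {
  calls <- rbind(mk_calls(9, "incoming", 60), mk_calls(10, "incoming", 120),
                 mk_calls(11, "outgoing", 300), mk_calls(12, "missed", 0))
  cf <- call_features(calls, DAY)
  expect_equal(cf$mean_incoming, 90)
  expect_equal(cf$mean_outgoing, 300)
  expect_equal(cf$tot_call_length, 480)
  expect_identical(cf$outgoing_call, 1L)

  # empty day: zeros with missing means
  cf0 <- call_features(calls, DAY + 1)
  expect_true(is.na(cf0$mean_incoming) && is.na(cf0$mean_outgoing))
  expect_equal(cf0$tot_call_length, 0)
  expect_identical(cf0$outgoing_call, 0L)

  # a lone missed call contributes nothing
  cf_m <- call_features(mk_calls(9, "missed", 0), DAY)
  expect_true(is.na(cf_m$mean_incoming))
  expect_equal(cf_m$tot_call_length, 0)
})

test_that("screen sessions pair on/off and split at midnight", {
  ev <- mk_screen(c(10 * 3600, 10 * 3600 + 300), c("on", "off"))
  ss <- screen_sessions(ev, DAY)
  expect_equal((ss$off_t - ss$on_t) / 1000, 300)

  # session 23:58 -> 00:04 next day: 120 s to day 1, 240 s to day 2
  ev2 <- mk_screen(c(23 * 3600 + 58 * 60, 24 * 3600 + 4 * 60), c("on", "off"))
  d1 <- screen_sessions(ev2, DAY)
  d2 <- screen_sessions(ev2, DAY + 1)
  expect_equal(sum(d1$off_t - d1$on_t) / 1000, 120)
  expect_equal(sum(d2$off_t - d2$on_t) / 1000, 240)

  # day starting with an off event: leading span counted from 00:00
  ev3 <- mk_screen(c(4 * 60, 9 * 3600), c("off", "on"))
  d3 <- screen_sessions(ev3, DAY)
  expect_equal(d3$on_t[1], D0)
  expect_equal((d3$off_t[1] - d3$on_t[1]) / 1000, 240)
})

test_that("brightness features use the b[n] = hour [n-1, n) slot convention", {
  ev <- mk_screen(c(10 * 3600, 10 * 3600 + 300), c("on", "off"))
  bf <- brightness_features(screen_sessions(ev, DAY), DAY)
  expect_identical(bf$number_switch_on, 1L)
  expect_equal(bf$mean_time_usage, 300)
  expect_equal(bf$b[11], 300)
  expect_equal(sum(bf$b), 300)

  # session 10:58-11:04 splits across the hour boundary
  ev2 <- mk_screen(c(10 * 3600 + 58 * 60, 11 * 3600 + 4 * 60), c("on", "off"))
  bf2 <- brightness_features(screen_sessions(ev2, DAY), DAY)
  expect_equal(bf2$b[11], 120)
  expect_equal(bf2$b[12], 240)

  bf0 <- brightness_features(screen_sessions(ev2[0, ], DAY), DAY)
  expect_equal(sum(bf0$b), 0)
  expect_identical(bf0$number_switch_on, 0L)
  expect_true(is.na(bf0$mean_time_usage))
})

test_that("b[n] conservation: slot totals equal session time (property)", {
  set.seed(77)
  for (trial in 1:20) {
    n <- sample(1:15, 1)
    on <- sort(runif(n, 0, 86000))
    off <- on + runif(n, 1, 500)
    # enforce alternation (drop overlapping sessions)
    keep <- c(TRUE, on[-1] > off[-n])
    on <- on[keep]; off <- pmin(off[keep], 86400)
    ev <- mk_screen(as.vector(rbind(on, off)), rep(c("on", "off"), length(on)))
    ss <- screen_sessions(ev, DAY)
    bf <- brightness_features(ss, DAY)
    expect_equal(sum(bf$b), sum(ss$off_t - ss$on_t) / 1000, tolerance = 1e-6)
    expect_true(all(bf$b >= 0 & bf$b <= 3600))
  }
})

test_that("app traffic maps Table-style categories and totals everything", {
  recs <- data.frame(t = ms_at(c(9, 10, 11)), app_id = c("WhatsApp", "Facebook", "zzz.app"),
                     kb = c(500, 200, 100))
  af <- app_features(recs, DAY)
  expect_equal(af$tot_kb_communication, 500)
  expect_equal(af$tot_kb_social, 200)
  expect_equal(af$tot_kb_navigation, 0)
  expect_equal(af$tot_kb, 800)
  expect_gte(af$tot_kb, af$tot_kb_social + af$tot_kb_communication +
               af$tot_kb_navigation)
  af2 <- app_features(data.frame(t = ms_at(9), app_id = "Chrome", kb = 300), DAY)
  expect_equal(af2$tot_kb_navigation, 300)
  af0 <- app_features(recs, DAY + 1)
  expect_equal(af0$tot_kb, 0)
})

test_that("activity features classify per-second dynamic amplitude", {
  set.seed(3)
  # one hour at rest starting 08:00 -> all low, m_amp near gravity
  rest <- mk_accel(8 * 3600, 9 * 3600, noise_sd = 0.05)
  act <- activity_features(rest, DAY)
  expect_identical(act$s_a[9], 0L)
  expect_identical(act$s_r[9], 3600L)
  expect_equal(act$m_amp[9], 9.81, tolerance = 0.01)
  expect_true(is.na(act$m_amp[1]))  # slot without samples
  expect_identical(act$s_a[1] + act$s_r[1], 0L)
  expect_equal(act$percentage_activity, 0)

  # 600 s of walking-like oscillation inside an otherwise-restful window
  dyn_fun <- function(tt) ifelse(tt >= 8.5 * 3600 & tt < 8.5 * 3600 + 600,
                                 1.5 * sin(2 * pi * 2 * tt), 0)
  mixed <- mk_accel(8 * 3600, 9 * 3600, noise_sd = 0.05, dyn_fun = dyn_fun)
  act2 <- activity_features(mixed, DAY)
  expect_identical(act2$s_a[9], 600L)
  expect_identical(act2$s_r[9], 3000L)
  expect_equal(act2$percentage_activity, 600 / 3600)

  # percentage_activity = s_a / (s_a + s_r) on constructed counts
  expect_equal(sum(act2$s_a, na.rm = TRUE) /
                 (sum(act2$s_a, na.rm = TRUE) + sum(act2$s_r, na.rm = TRUE)),
               act2$percentage_activity)

  # s_a + s_r equals the number of seconds containing samples
  expect_identical(sum(act2$s_a) + sum(act2$s_r), 3600L)

  act0 <- activity_features(rest[0, ], DAY)
  expect_true(is.na(act0$percentage_activity))
})

test_that("FeatureDay invariants hold on generated data (property)", {
  for (seed in c(31, 32)) {
    g <- generate_streams(user_profile(holidays = 2), policy_model("B"),
                          n_days = 2, seed = seed)
    f <- extract_features(g$streams)
    b <- as.matrix(f[, paste0("b_", 1:24)])
    expect_true(all(b >= 0 & b <= 3600))
    expect_true(all(rowSums(b) <= 86400))
    sa <- as.matrix(f[, paste0("s_a_", 1:24)])
    sr <- as.matrix(f[, paste0("s_r_", 1:24)])
    expect_true(all(sa + sr <= 3600))
    pa <- f$percentage_activity
    expect_true(all(is.na(pa) | (pa >= 0 & pa <= 1)))
    expect_true(all(f$tot_kb >= f$tot_kb_social + f$tot_kb_communication +
                      f$tot_kb_navigation - 1e-9))
    # truth high seconds match the classified high seconds per day
    expect_equal(rowSums(sa), g$truth$high_seconds, tolerance = 0.01,
                 ignore_attr = TRUE)
  }
})
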