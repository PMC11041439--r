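# In-code fixtures shared across the suite. Timestamps are epoch ms; D0 is
# the UTC midnight opening the canonical test day.

D0 <- as.numeric(as.POSIXct("2023-03-06 00:00:00", tz = "UTC")) * 1000
DAY <- as.Date("2023-03-06")

ms_at <- function(hh, mm = 0, ss = 0) D0 + (hh * 3600 + mm * 60 + ss) * 1000

# accel samples at `hz` covering [from_s, to_s) seconds-of-day, at rest
# unless dyn_fun supplies an added vertical component per time (seconds)
mk_accel <- function(from_s, to_s, hz = 5, noise_sd = 0, dyn_fun = NULL,
                     day0 = D0) {
  tt <- seq(from_s, to_s - 1 / hz, by = 1 / hz)
  az <- rep(9.81, length(tt))
  if (noise_sd > 0) az <- az + rnorm(length(tt), 0, noise_sd)
  if (!is.null(dyn_fun)) az <- az + dyn_fun(tt)
  data.frame(t = day0 + tt * 1000, ax = 0, ay = 0, az = az)
}

mk_gps <- function(t_s, lat, lon, day0 = D0)
  data.frame(t = day0 + t_s * 1000, lat = lat, lon = lon, accuracy = 10)

mk_calls <- function(hh, direction, duration_s, day0 = D0)
  data.frame(t = day0 + hh * 3600 * 1000, direction = direction,
             duration_s = duration_s)

mk_screen <- function(t_s, state, day0 = D0)
  data.frame(t = day0 + t_s * 1000, state = state)

# a stationary GPS bout: one fix per cadence seconds at (lat, lon) + jitter
mk_bout <- function(from_s, to_s, lat, lon, cadence = 60, jitter_m = 0,
                    day0 = D0) {
  t_s <- seq(from_s, to_s, by = cadence)
  j <- function(n) if (jitter_m > 0) rnorm(n, 0, jitter_m) / 111320 else 0
  mk_gps(t_s, lat + j(length(t_s)), lon + j(length(t_s)), day0)
}

# wrap a raw matrix as a feature_matrix for direct knn_gas tests
fm_wrap <- function(X, days = seq_len(nrow(X))) {
  colnames(X) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  structure(list(X = X, days = days, features = colnames(X),
                 missing_mask = matrix(FALSE, nrow(X), ncol(X)),
                 dropped = character(0),
                 center = rep(0, ncol(X)), scale = rep(1, ncol(X))),
            class = "feature_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force k-NN GAS oracle: explicit double loop
gas_oracle <- function(X, k) {
  n <- nrow(X)
  vapply(seq_len(n), function(i) {
    d <- numeric(0)
    for (j in seq_len(n)) if (j != i)
      d <- c(d, sqrt(sum((X[i, ] - X[j, ])^2)))
    mean(sort(d)[seq_len(k)])
  }, numeric(1))
}

expect_silent_streams <- function(...) suppressWarnings(sensor_streams(...))
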