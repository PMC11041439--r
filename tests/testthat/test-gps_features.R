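# Place clustering, home inference, and the per-day location features.

test_that("two stationary bouts 1 km apart form two clusters with even dwell", {
  set.seed(8)
  b1 <- mk_bout(0, 1800, 45.00, 7.70, jitter_m = 5)       # 30 min
  b2 <- mk_bout(2000, 3800, 45.009, 7.70, jitter_m = 5)   # ~1 km north, 30 min
  fixes <- rbind(b1, b2)
  cl <- cluster_fixes(fixes, radius = 100)
  expect_identical(nrow(cl$clusters), 2L)
  expect_equal(sort(cl$clusters$p), c(0.5, 0.5), tolerance = 0.05)
  # brute-force single-linkage oracle on pairwise haversine distances
  n <- nrow(fixes)
  adj <- matrix(FALSE, n, n)
  for (i in 1:n) adj[i, ] <- haversine_m(fixes$lat[i], fixes$lon[i],
                                         fixes$lat, fixes$lon) <= 100
  comp <- seq_len(n)
  repeat {
    nc <- vapply(1:n, function(i) min(comp[adj[i, ]]), numeric(1))
    if (identical(nc, comp)) break
    comp <- nc
  }
  expect_identical(length(unique(comp)), 2L)

  # all fixes within 10 m -> a single cluster holding all dwell
  one <- mk_bout(0, 3600, 45, 7, jitter_m = 2)
  cl1 <- cluster_fixes(one)
  expect_identical(nrow(cl1$clusters), 1L)
  expect_equal(cl1$clusters$p, 1)

  # fewer than 2 fixes -> empty set
  expect_identical(nrow(cluster_fixes(mk_gps(0, 45, 7))$clusters), 0L)
})

test_that("transit fixes are excluded from clustering but keep their dwell", {
  set.seed(9)
  b1 <- mk_bout(0, 1800, 45.00, 7.70, jitter_m = 3)
  # 2 km in 10 min -> ~3.3 m/s, above the 1.5 m/s default
  trans <- mk_gps(seq(1860, 2340, by = 60), seq(45.0005, 45.0175, length.out = 9), 7.70)
  b2 <- mk_bout(2400, 4200, 45.018, 7.70, jitter_m = 3)
  cl <- cluster_fixes(rbind(b1, trans, b2))
  expect_identical(nrow(cl$clusters), 2L)
  moving <- which(cl$assignment == 0)
  expect_gt(length(moving), 0)
  expect_gt(sum(cl$fix_dwell_s[moving]), 0)
})

test_that("home is the top night-dwell cluster with documented tie/fallback rules", {
  # night at place H, day at place W
  night <- mk_bout(0, 6 * 3600 - 60, 45.00, 7.70, jitter_m = 2)
  day <- mk_bout(8 * 3600, 20 * 3600, 45.02, 7.70, jitter_m = 2)
  fixes <- rbind(night, day)
  cl <- identify_home(cluster_fixes(fixes), fixes)
  h <- cl$clusters[cl$home_index, ]
  expect_lt(haversine_m(h$lat, h$lon, 45.00, 7.70), 20)

  # single cluster -> that cluster is home
  one <- mk_bout(0, 3600, 45, 7)
  cl1 <- identify_home(cluster_fixes(one), one)
  expect_identical(cl1$home_index, 1L)

  # no night fixes -> fallback to total dwell, flagged low-confidence
  dayonly <- rbind(mk_bout(8 * 3600, 10 * 3600, 45.00, 7.70),
                   mk_bout(11 * 3600, 19 * 3600, 45.02, 7.70))
  cl2 <- identify_home(cluster_fixes(dayonly), dayonly)
  expect_identical(as.integer(cl2$home_index), which.max(cl2$clusters$dwell_s))
  expect_true(isTRUE(attr(cl2$home_index, "low_confidence")))

  # equal night dwell (none) ties broken by larger total dwell
  expect_identical(cl2$clusters$dwell_s[cl2$home_index],
                   max(cl2$clusters$dwell_s))
})

test_that("per-day GPS features match the closed forms", {
  # all fixes at one point: variance 0, entropy 0, time_outside 0
  one <- mk_bout(0, 7200, 45, 7)
  cl <- identify_home(cluster_fixes(one), one)
  gf <- gps_day_features(one, cl, DAY)
  expect_equal(gf$location_variance, 0)
  expect_equal(gf$entropy, 0)
  expect_equal(gf$time_outside, 0)
  expect_identical(gf$number_of_clusters, 1L)

  # two clusters with 50/50 dwell: entropy = ln 2, normalized = 1
  b1 <- mk_bout(0, 1800, 45.00, 7.70)
  b2 <- mk_bout(2000, 3800, 45.009, 7.70)
  fixes <- rbind(b1, b2)
  cl2 <- identify_home(cluster_fixes(fixes), fixes)
  gf2 <- gps_day_features(fixes, cl2, DAY)
  expect_equal(gf2$entropy, log(2), tolerance = 0.02)
  expect_equal(gf2$normalized_entropy, 1, tolerance = 0.01)

  # population variance arithmetic: lats {0,0}, lons {0, 0.02} -> 1e-4 deg^2
  two <- mk_gps(c(0, 60), c(0, 0), c(0, 0.02))
  cl0 <- cluster_fixes(two)   # empty set is fine; variance needs no clusters
  gf3 <- gps_day_features(two, cl0, DAY)
  expect_equal(gf3$location_variance, 1e-4)

  # day without fixes -> everything missing
  gf4 <- gps_day_features(fixes, cl2, DAY + 30)
  expect_true(is.na(gf4$location_variance) && is.na(gf4$entropy))
  expect_identical(nrow(gf4$visited_clusters), 0L)
})

test_that("entropy bounds and uniform-maximum property hold on dwell vectors", {
  # direct closed forms via constructed two-bout days with uneven dwell
  p <- c(0.8, 0.2)
  expect_equal(-sum(p * log(p)), 0.5004024, tolerance = 1e-6)
  set.seed(10)
  for (k in 2:6) {
    p <- runif(k); p <- p / sum(p)
    h <- -sum(p * log(p))
    expect_gte(h, 0)
    expect_lte(h, log(k) + 1e-12)
  }
  # maximum iff uniform
  expect_equal(-sum(rep(1 / 4, 4) * log(rep(1 / 4, 4))), log(4))
})

test_that("visited clusters are ordered by distance from home", {
  set.seed(11)
  b1 <- mk_bout(0, 6 * 3600, 45.00, 7.70, jitter_m = 2)        # home (night)
  b2 <- mk_bout(7 * 3600, 9 * 3600, 45.03, 7.70, jitter_m = 2) # far
  b3 <- mk_bout(10 * 3600, 12 * 3600, 45.01, 7.70, jitter_m = 2) # near
  fixes <- rbind(b1, b2, b3)
  cl <- identify_home(cluster_fixes(fixes), fixes)
  gf <- gps_day_features(fixes, cl, DAY)
  expect_identical(gf$number_of_clusters, 3L)
  expect_false(is.unsorted(gf$visited_clusters$distance_m))
  expect_equal(gf$visited_clusters$distance_m[1], 0, tolerance = 5)
  # time outside home = 1 - home share of attributed dwell
  expect_gt(gf$time_outside, 0)
  expect_lt(gf$time_outside, 100)
})

test_that("location variance is translation-invariant and null iff coincident", {
  set.seed(12)
  fx <- mk_gps(seq(0, 600, 60), 45 + rnorm(11, 0, 1e-4), 7 + rnorm(11, 0, 1e-4))
  cl <- cluster_fixes(fx)
  v1 <- gps_day_features(fx, cl, DAY)$location_variance
  fx2 <- fx; fx2$lat <- fx2$lat + 0.5; fx2$lon <- fx2$lon - 0.3
  v2 <- gps_day_features(fx2, cluster_fixes(fx2), DAY)$location_variance
  expect_equal(v1, v2, tolerance = 1e-9)
  expect_gt(v1, 0)
})
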