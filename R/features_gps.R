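# GPS mobility features: stay-point clustering of fixes into visited
# places, home identification, and the per-day location features
# (number_of_clusters, time_outside, location_variance, entropy,
# visited_clusters).
#
# Clustering runs once over the whole observation window so cluster
# identities are stable across days; dwell is then attributed per day.

#' Cluster GPS fixes into visited places
#'
#' Density-based stay-point clustering on great-circle distance. Fixes
#' implying a speed above `speed_max` relative to the previous fix are
#' treated as transit and excluded from clustering (they still contribute
#' to total tracked dwell). Stationary fixes are binned into grid cells of
#' half the cluster radius and cells are single-linkage joined when their
#' occupied centers lie within `radius` of each other — a standard
#' grid-accelerated approximation of "a fix joins a cluster when it is
#' within the radius of the cluster's members". Clusters whose total dwell
#' falls below `min_dwell` are dissolved to noise.
#'
#' Dwell attribution: each fix carries the time since the previous fix,
#' capped at `2 * fix_cadence` so tracking holes do not inflate dwell; the
#' first fix carries one cadence.
#'
#' @param fixes GPS fixes (`t` epoch ms, `lat`, `lon`), time-sorted.
#' @param radius Cluster joining radius, meters (default 100).
#' @param min_dwell Minimum total dwell for a surviving cluster, seconds
#'   (default 300).
#' @param speed_max Transit speed threshold, m/s (default 1.5).
#' @param fix_cadence Nominal fix spacing in seconds; default the median
#'   observed spacing.
#' @return A `place_clusters` object: `clusters` data.frame (`lat`, `lon`
#'   dwell-weighted centroids, `dwell_s`, `n_fixes`, `p` dwell proportion),
#'   `assignment` (per-fix cluster index, 0 = transit/noise), `fix_dwell_s`
#'   (per-fix attributed dwell), `home_index` (`NA` until
#'   [identify_home()]), and `n_fixes`.
#' @export
cluster_fixes <- function(fixes, radius = 100, min_dwell = 300,
                          speed_max = 1.5, fix_cadence = NULL) {
  fixes <- as.data.frame(fixes)
  n <- nrow(fixes)
  empty <- structure(list(
    clusters = data.frame(lat = numeric(0), lon = numeric(0),
                          dwell_s = numeric(0), n_fixes = integer(0),
                          p = numeric(0)),
    assignment = integer(n), fix_dwell_s = numeric(n),
    home_index = NA_integer_, n_fixes = n,
    params = list(radius = radius, min_dwell = min_dwell,
                  speed_max = speed_max)), class = "place_clusters")
  if (n < 2) return(empty)
  if (is.unsorted(fixes$t)) stopf("fixes must be time-sorted")

  dt_s <- c(NA, diff(fixes$t)) / MS_PER_SEC
  cadence <- fix_cadence
  if (is.null(cadence)) cadence <- stats::median(dt_s, na.rm = TRUE)
  dwell <- pmin(dt_s, 2 * cadence)
  dwell[1] <- min(cadence, 2 * cadence)
  step_m <- c(0, haversine_m(fixes$lat[-n], fixes$lon[-n],
                             fixes$lat[-1], fixes$lon[-1]))
  speed <- step_m / pmax(dt_s, 1e-9)
  speed[1] <- 0
  stationary <- speed <= speed_max

  if (!any(stationary)) { empty$fix_dwell_s <- dwell; return(empty) }

  # grid binning at radius/2
  mlat <- mean(fixes$lat[stationary])
  dlat <- (radius / 2) / 111320
  dlon <- (radius / 2) / (111320 * max(0.05, cos(mlat * pi / 180)))
  ci <- floor(fixes$lat / dlat)
  cj <- floor(fixes$lon / dlon)
  cell_id <- paste(ci, cj)
  cell_id[!stationary] <- NA
  cells <- unique(stats::na.omit(cell_id))
  cell_of <- match(cell_id, cells)
  grp <- factor(cell_of[stationary], levels = seq_along(cells))
  c_lat <- as.vector(tapply(fixes$lat[stationary], grp, mean))
  c_lon <- as.vector(tapply(fixes$lon[stationary], grp, mean))

  # single-linkage connected components over occupied cells
  m <- length(cells)
  comp <- seq_len(m)
  if (m > 1) {
    d <- outer(seq_len(m), seq_len(m), function(i, j)
      haversine_m(c_lat[i], c_lon[i], c_lat[j], c_lon[j]))
    adj <- d <= radius
    repeat {
      new_comp <- vapply(seq_len(m), function(i) min(comp[adj[i, ]]), numeric(1))
      if (identical(new_comp, comp)) break
      comp <- new_comp
    }
  }
  comp <- match(comp, sort(unique(comp)))

  assignment <- integer(n)
  assignment[stationary] <- comp[cell_of[stationary]]

  # dissolve clusters under the dwell floor, re-index survivors by dwell rank
  k <- max(comp)
  cl_dwell <- vapply(seq_len(k), function(c) sum(dwell[assignment == c]),
                     numeric(1))
  keep <- which(cl_dwell >= min_dwell)
  if (!length(keep)) { empty$fix_dwell_s <- dwell; return(empty) }
  rank <- order(cl_dwell[keep], decreasing = TRUE)
  remap <- integer(k)
  remap[keep[rank]] <- seq_along(keep)
  assignment <- ifelse(assignment > 0, remap[pmax(assignment, 1)], 0L)

  kk <- length(keep)
  cl <- data.frame(lat = numeric(kk), lon = numeric(kk), dwell_s = numeric(kk),
                   n_fixes = integer(kk), p = numeric(kk))
  for (c in seq_len(kk)) {
    mbr <- assignment == c
    w <- dwell[mbr]
    cl$lat[c] <- sum(fixes$lat[mbr] * w) / sum(w)
    cl$lon[c] <- sum(fixes$lon[mbr] * w) / sum(w)
    cl$dwell_s[c] <- sum(w)
    cl$n_fixes[c] <- sum(mbr)
  }
  cl$p <- cl$dwell_s / sum(cl$dwell_s)
  structure(list(clusters = cl, assignment = as.integer(assignment),
                 fix_dwell_s = dwell, home_index = NA_integer_, n_fixes = n,
                 params = list(radius = radius, min_dwell = min_dwell,
                               speed_max = speed_max)),
            class = "place_clusters")
}

#' @export
print.place_clusters <- function(x, ...) {
  cat(sprintf("<place_clusters> %d cluster(s) over %d fixes\n",
              nrow(x$clusters), x$n_fixes))
  if (nrow(x$clusters)) {
    df <- x$clusters
    df$home <- seq_len(nrow(df)) == (x$home_index %||NA% -1L)
    print(df, digits = 6)
  }
  invisible(x)
}

`%||NA%` <- function(a, b) if (is.na(a)) b else a

#' Identify the home cluster
#'
#' Home is the cluster with the greatest dwell during local night hours
#' (00:00-06:00) across all days; ties break toward greater total dwell.
#' With no night-time fixes the cluster with the greatest total dwell is
#' used and the result is flagged low-confidence.
#'
#' @param clusters A [cluster_fixes()] result.
#' @param fixes The same fixes the clusters were computed from.
#' @param tz Local timezone for the night window.
#' @return The `place_clusters` object with `home_index` set (attribute
#'   `low_confidence` = TRUE on the index when the fallback was used).
#' @export
identify_home <- function(clusters, fixes, tz = "UTC") {
  stopifnot(inherits(clusters, "place_clusters"))
  fixes <- as.data.frame(fixes)
  k <- nrow(clusters$clusters)
  if (k == 0) stopf("no clusters; cannot identify home")
  if (nrow(fixes) != clusters$n_fixes)
    stopf("fixes do not match the clustered fix set")
  lt <- as.POSIXlt(fixes$t / MS_PER_SEC, origin = "1970-01-01", tz = tz)
  night <- lt$hour < 6
  a <- clusters$assignment
  night_dwell <- vapply(seq_len(k), function(c)
    sum(clusters$fix_dwell_s[night & a == c]), numeric(1))
  low_conf <- FALSE
  if (all(night_dwell == 0)) {
    low_conf <- TRUE
    score <- clusters$clusters$dwell_s
  } else score <- night_dwell
  best <- which(score == max(score))
  if (length(best) > 1)
    best <- best[which.max(clusters$clusters$dwell_s[best])]
  home <- as.integer(best)
  if (low_conf) attr(home, "low_confidence") <- TRUE
  clusters$home_index <- home
  clusters
}

#' Per-day GPS location features
#'
#' `location_variance` is the population variance of the day's longitudes
#' plus that of its latitudes (degrees squared, unprojected).
#' `entropy = -sum(p_i log p_i)` in nats over the day's dwell proportions
#' across place clusters; `normalized_entropy` divides by `log(k)` over
#' the day's visited clusters (0 when fewer than 2). `time_outside` is the
#' percentage of the day's attributed dwell (including transit) spent away
#' from the home cluster. `visited_clusters` lists the day's places
#' ordered by haversine distance from the home centroid.
#'
#' @param fixes The full fix set the clusters were computed from.
#' @param clusters A [cluster_fixes()] result, ideally after
#'   [identify_home()]; without a home index the top-dwell cluster is used.
#' @param day Calendar date.
#' @param tz Day-boundary timezone.
#' @return Named list: `number_of_clusters`, `time_outside` (percent),
#'   `location_variance` (deg^2), `entropy` (nats), `normalized_entropy`,
#'   `visited_clusters` (data.frame `lat`, `lon`, `distance_m`). All `NA`
#'   (empty for `visited_clusters`) when the day has no fixes.
#' @export
gps_day_features <- function(fixes, clusters, day, tz = "UTC") {
  stopifnot(inherits(clusters, "place_clusters"))
  fixes <- as.data.frame(fixes)
  if (nrow(fixes) != clusters$n_fixes)
    stopf("fixes do not match the clustered fix set")
  ds <- day_start_ms(day, tz); de <- day_end_ms(day, tz)
  sel <- fixes$t >= ds & fixes$t < de
  na_out <- list(number_of_clusters = NA_integer_, time_outside = NA_real_,
                 location_variance = NA_real_, entropy = NA_real_,
                 normalized_entropy = NA_real_,
                 visited_clusters = data.frame(lat = numeric(0),
                                               lon = numeric(0),
                                               distance_m = numeric(0)))
  if (!any(sel)) return(na_out)
  lat <- fixes$lat[sel]; lon <- fixes$lon[sel]
  pvar <- function(x) mean((x - mean(x))^2)
  loc_var <- pvar(lon) + pvar(lat)

  a <- clusters$assignment[sel]
  w <- clusters$fix_dwell_s[sel]
  tot_dwell <- sum(w)
  k_all <- nrow(clusters$clusters)
  day_dwell <- if (k_all) vapply(seq_len(k_all), function(c) sum(w[a == c]),
                                 numeric(1)) else numeric(0)
  visited <- which(day_dwell > 0)
  k_day <- length(visited)
  p <- day_dwell[visited] / sum(day_dwell[visited])
  entropy <- if (k_day) -sum(p * log(p)) else 0
  norm_entropy <- if (k_day >= 2) entropy / log(k_day) else 0

  home <- clusters$home_index
  if (is.na(home) && k_all) home <- which.max(clusters$clusters$dwell_s)
  home_dwell <- if (!is.na(home)) sum(w[a == home]) else 0
  time_outside <- if (tot_dwell > 0) 100 * (tot_dwell - home_dwell) / tot_dwell
                  else NA_real_

  vc <- clusters$clusters[visited, c("lat", "lon"), drop = FALSE]
  vc$distance_m <- if (!is.na(home))
    haversine_m(vc$lat, vc$lon, clusters$clusters$lat[home],
                clusters$clusters$lon[home])
  else rep(NA_real_, nrow(vc))
  vc <- vc[order(vc$distance_m), , drop = FALSE]
  rownames(vc) <- NULL
  list(number_of_clusters = k_day, time_outside = time_outside,
       location_variance = loc_var, entropy = entropy,
       normalized_entropy = norm_entropy, visited_clusters = vc)
}
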