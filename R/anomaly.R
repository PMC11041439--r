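# Day-level anomaly screening: z-standardized day-by-feature matrix,
# principal-component feature screen, and the k-nearest-neighbor global
# anomaly score (GAS) — the mean Euclidean distance from a day to its k
# nearest other days in standardized feature space.

#' Build the standardized day-by-feature matrix
#'
#' Takes the [extract_features()] table, z-standardizes every feature over
#' its non-missing entries, drops zero-variance columns (with a message),
#' and imputes missing entries on the standardized scale.
#'
#' @param feature_days data.frame from [extract_features()] (a `day` column
#'   plus numeric feature columns), at least 2 rows.
#' @param impute `"median"` (default; per-feature median of the
#'   standardized observed values), `"mean"` (0 by construction), or
#'   `"zero"`.
#' @return A `feature_matrix`: `X` (days x features, standardized and
#'   imputed), `days`, `features`, `missing_mask`, `dropped` (names of
#'   removed columns), `center`, `scale`.
#' @export
build_matrix <- function(feature_days, impute = c("median", "mean", "zero")) {
  impute <- match.arg(impute)
  if (nrow(feature_days) < 2) stopf("need at least 2 days to build a matrix")
  days <- if ("day" %in% names(feature_days)) feature_days$day
          else seq_len(nrow(feature_days))
  num <- vapply(feature_days, is.numeric, logical(1))
  num["day" == names(feature_days)] <- FALSE
  X <- as.matrix(feature_days[, num, drop = FALSE])
  mask <- is.na(X)
  ctr <- apply(X, 2, function(x) mean(x, na.rm = TRUE))
  scl <- apply(X, 2, function(x) stats::sd(x, na.rm = TRUE))
  ok <- is.finite(scl) & scl > 0
  dropped <- colnames(X)[!ok]
  if (length(dropped))
    message("dropping ", length(dropped), " zero-variance/empty feature(s): ",
            paste(utils::head(dropped, 8), collapse = ", "),
            if (length(dropped) > 8) ", ..." else "")
  X <- X[, ok, drop = FALSE]
  mask <- mask[, ok, drop = FALSE]
  ctr <- ctr[ok]; scl <- scl[ok]
  X <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  if (any(mask)) {
    fill <- switch(impute,
      median = apply(X, 2, function(x) stats::median(x, na.rm = TRUE)),
      mean = rep(0, ncol(X)),
      zero = rep(0, ncol(X)))
    idx <- which(mask, arr.ind = TRUE)
    X[idx] <- fill[idx[, 2]]
  }
  structure(list(X = X, days = days, features = colnames(X),
                 missing_mask = mask, dropped = dropped,
                 center = ctr, scale = scl),
            class = "feature_matrix")
}

#' Screen features by principal component analysis
#'
#' Decomposes the standardized matrix, keeps the smallest set of leading
#' components explaining at least `variance_frac` of total variance, and
#' scores each feature by its strongest contribution to the kept
#' components: the maximum over kept components of |loading| times the
#' component's standard deviation. Features reaching the
#' `loading_quantile` quantile of these scores are selected — the "most
#' descriptive" subset of the feature pool. Weighting by the component
#' scale matters: with many features and few days, each near-noise feature
#' ends up dominating some low-variance minor component with a large raw
#' loading, so an unweighted max-|loading| rule selects noise; scaling by
#' the component sdev ranks features by the variance they actually carry.
#' The selection is never empty (fallback: top 5 features by score).
#'
#' @param matrix A [build_matrix()] result.
#' @param variance_frac Cumulative explained-variance cutoff (default 0.9).
#' @param loading_quantile Quantile of max-|loading| a feature must reach
#'   (default 0.75).
#' @return Character vector of selected feature names; attributes
#'   `n_components`, `explained_variance`, `max_loading`.
#' @export
pca_screen <- function(matrix, variance_frac = 0.9, loading_quantile = 0.75) {
  stopifnot(inherits(matrix, "feature_matrix"))
  X <- matrix$X
  max_comp <- min(nrow(X) - 1L, ncol(X))
  if (ncol(X) > nrow(X) - 1L)
    warnf("more features (%d) than decomposable components (%d); proceeding with %d",
          ncol(X), max_comp, max_comp)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = max_comp)
  var_exp <- pc$sdev[seq_len(max_comp)]^2
  cum <- cumsum(var_exp) / sum(pc$sdev^2)
  n_keep <- if (any(cum >= variance_frac)) which(cum >= variance_frac)[1]
            else max_comp
  L <- abs(pc$rotation[, seq_len(n_keep), drop = FALSE])
  L <- sweep(L, 2, pc$sdev[seq_len(n_keep)], "*")
  max_load <- apply(L, 1, max)
  thr <- stats::quantile(max_load, loading_quantile, names = FALSE)
  sel <- names(max_load)[max_load >= thr]
  if (!length(sel))
    sel <- names(sort(max_load, decreasing = TRUE))[seq_len(min(5, length(max_load)))]
  structure(sel, n_components = n_keep,
            explained_variance = cum[n_keep], max_loading = max_load)
}

#' k-nearest-neighbor global anomaly score
#'
#' Scores each day by the mean Euclidean distance to its k nearest other
#' days in (optionally feature-screened) standardized space; high scores
#' mark days that differ most from the rest. Neighbor ties are broken by
#' day order, so the result is deterministic.
#'
#' @param matrix A [build_matrix()] result.
#' @param k Neighbor count, `1 <= k <= days - 1` (default 5).
#' @param features Optional feature subset (e.g. from [pca_screen()]).
#' @param top_m How many top-ranked days to flag; default
#'   `max(1, ceiling(0.05 * days))`.
#' @return An `anomaly_report`: data.frame `scores` (`day`, `score`,
#'   `rank`, `flagged`) in day order, plus `ranking` (days by descending
#'   score), `k`, `selected_features`.
#' @export
knn_gas <- function(matrix, k = 5, features = NULL, top_m = NULL) {
  stopifnot(inherits(matrix, "feature_matrix"))
  X <- matrix$X
  if (!is.null(features)) {
    missing_f <- setdiff(features, colnames(X))
    if (length(missing_f))
      stopf("unknown feature(s): %s", paste(missing_f, collapse = ", "))
    X <- X[, features, drop = FALSE]
  }
  n <- nrow(X)
  if (k < 1 || k > n - 1)
    stopf("k must satisfy 1 <= k <= days - 1 (k = %s, days = %d)", k, n)
  if (is.null(top_m)) top_m <- max(1L, as.integer(ceiling(0.05 * n)))
  D <- as.matrix(stats::dist(X))
  scores <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    idx <- order(d, seq_along(d))  # ties broken by day order
    mean(d[idx[seq_len(k)]])
  }, numeric(1))
  ranking <- order(-scores, seq_len(n))
  rank <- integer(n); rank[ranking] <- seq_len(n)
  df <- data.frame(day = matrix$days, score = scores, rank = rank,
                   flagged = rank <= top_m)
  structure(list(scores = df, ranking = matrix$days[ranking], k = k,
                 selected_features = if (is.null(features)) colnames(X)
                                     else features,
                 top_m = top_m),
            class = "anomaly_report")
}

#' @export
print.anomaly_report <- function(x, ...) {
  cat(sprintf("<anomaly_report> %d days, k = %d, %d feature(s), %d flagged\n",
              nrow(x$scores), x$k, length(x$selected_features),
              sum(x$scores$flagged)))
  top <- x$scores[order(x$scores$rank), ][seq_len(min(5, nrow(x$scores))), ]
  print(top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Regime-recovery metrics against simulation ground truth
#'
#' For synthetic data with labeled day regimes: how many injected holidays
#' land in the top `top_n` anomaly ranks, and how separated holiday scores
#' are from workday scores.
#'
#' @param report A [knn_gas()] result whose days match the truth calendar.
#' @param truth The `truth` element of [generate_streams()].
#' @param top_n Rank cutoff for recovery (default: the report's flag count).
#' @return Named list: `n_holidays`, `n_recovered`, `fraction_recovered`
#'   (`NA` when the truth holds no holidays), `separation` (median holiday
#'   GAS minus median workday GAS).
#' @export
recover_regimes <- function(report, truth, top_n = NULL) {
  stopifnot(inherits(report, "anomaly_report"))
  if (is.null(top_n)) top_n <- report$top_m
  sc <- report$scores
  reg <- truth$regimes[match(as.Date(sc$day), as.Date(truth$dates))]
  if (anyNA(reg)) stopf("report days do not match the truth calendar")
  hol <- reg == "holiday"
  wrk <- reg == "workday"
  sep <- if (any(hol) && any(wrk))
    stats::median(sc$score[hol]) - stats::median(sc$score[wrk]) else NA_real_
  if (!any(hol))
    return(list(n_holidays = 0L, n_recovered = NA_integer_,
                fraction_recovered = NA_real_, separation = sep))
  rec <- sum(sc$rank[hol] <= top_n)
  list(n_holidays = sum(hol), n_recovered = rec,
       fraction_recovered = rec / sum(hol), separation = sep)
}
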