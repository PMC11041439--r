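# Matrix assembly, PCA feature screen, and k-NN GAS scoring.

test_that("build_matrix standardizes, drops constants, and imputes on the z scale", {
  df <- data.frame(day = as.Date("2023-01-01") + 0:2,
                   a = c(1, 2, 3), const = c(5, 5, 5), m = c(1, NA, 3))
  expect_message(fm <- build_matrix(df), "zero-variance")
  expect_false("const" %in% fm$features)
  expect_equal(mean(fm$X[, "a"]), 0)
  expect_equal(sd(fm$X[, "a"]), 1)
  # observed z-values of m are +-1/sqrt(2); their median is 0 -> imputed 0
  expect_equal(sort(fm$X[c(1, 3), "m"]), c(-1, 1) / sqrt(2))
  expect_equal(unname(fm$X[2, "m"]), 0)
  expect_true(fm$missing_mask[2, "m"])
  expect_error(build_matrix(df[1, ]), "at least 2 days")
})

test_that("pca_screen keeps structure and survives degenerate inputs", {
  set.seed(21)
  # strong structured signal vs tiny noise: the signal feature is selected
  sig <- rep(c(-3, 3), each = 10) + rnorm(20, 0, 0.1)
  df <- data.frame(day = as.Date("2023-01-01") + 0:19,
                   a = sig, b = rnorm(20, 0, 0.1))
  fm <- build_matrix(df)
  sel <- pca_screen(fm, variance_frac = 0.9, loading_quantile = 0.5)
  expect_true("a" %in% sel)

  # variance_frac = 1 keeps every component
  sel_all <- pca_screen(fm, variance_frac = 1)
  expect_identical(attr(sel_all, "n_components"), 2L)

  # i.i.d. noise: selection is the quantile-sized subset, no crash
  noise <- as.data.frame(matrix(rnorm(20 * 8), 20))
  noise$day <- as.Date("2023-01-01") + 0:19
  fme <- build_matrix(noise)
  sel_n <- pca_screen(fme, loading_quantile = 0.75)
  expect_gte(length(sel_n), 1)
  expect_lte(length(sel_n), 8)

  # p > n - 1 proceeds with a warning
  wide <- as.data.frame(matrix(rnorm(4 * 10), 4))
  wide$day <- as.Date("2023-01-01") + 0:3
  expect_warning(pca_screen(build_matrix(wide)), "more features")
})

test_that("knn_gas matches hand-computed scores and rejects bad k", {
  # frozen from the brute-force oracle: rows 0,1,2,10 in 1-D with k = 2
  fm <- fm_wrap(matrix(c(0, 1, 2, 10), ncol = 1))
  expect_equal(gas_oracle(fm$X, 2), c(1.5, 1.0, 1.5, 8.5))
  rep <- knn_gas(fm, k = 2)
  expect_equal(rep$scores$score, c(1.5, 1.0, 1.5, 8.5))
  expect_identical(rep$scores$rank[4], 1L)
  expect_identical(rep$ranking[1], 4L)

  # identical rows score 0
  fm0 <- fm_wrap(matrix(1, 3, 2))
  expect_equal(knn_gas(fm0, k = 1)$scores$score, rep(0, 3))

  expect_error(knn_gas(fm, k = 4), "k must satisfy")
  expect_error(knn_gas(fm, k = 0), "k must satisfy")
  expect_error(knn_gas(fm, k = 1, features = "nope"), "unknown feature")
})

test_that("knn_gas equals the brute-force oracle on random matrices (property)", {
  set.seed(99)
  for (trial in 1:10) {
    n <- sample(5:50, 1); p <- sample(2:20, 1)
    X <- matrix(rnorm(n * p), n)
    k <- sample(seq_len(n - 1), 1)
    expect_equal(knn_gas(fm_wrap(X), k = k)$scores$score, gas_oracle(X, k),
                 tolerance = 1e-12)
  }
})

test_that("GAS is invariant to row order and raw-feature translation", {
  set.seed(41)
  df <- as.data.frame(matrix(rnorm(30), 10))
  df$day <- as.Date("2023-01-01") + 0:9
  s1 <- knn_gas(build_matrix(df), k = 3)$scores$score
  # adding a constant to a raw column is removed by standardization
  df2 <- df; df2$V1 <- df2$V1 + 100
  s2 <- knn_gas(build_matrix(df2), k = 3)$scores$score
  expect_equal(s1, s2, tolerance = 1e-9)
  # permuting days permutes scores with them
  perm <- sample(10)
  raw <- knn_gas(fm_wrap(as.matrix(df[, 1:3])), k = 3)$scores$score
  s3 <- knn_gas(fm_wrap(as.matrix(df[perm, 1:3])), k = 3)$scores$score
  expect_equal(s3, raw[perm], tolerance = 1e-12)
})

test_that("moving a row away from the centroid never lowers its GAS", {
  set.seed(55)
  X <- matrix(rnorm(20 * 4), 20)
  dirn <- rnorm(4); dirn <- dirn / sqrt(sum(dirn^2))
  prev <- -Inf
  for (step in c(0, 0.5, 1, 2, 4, 8)) {
    Xs <- X
    Xs[7, ] <- colMeans(X) + step * dirn
    sc <- knn_gas(fm_wrap(Xs), k = 4)$scores$score[7]
    expect_gte(sc + 1e-12, prev)
    prev <- sc
  }
})

test_that("recover_regimes reports holiday recovery and the null cases", {
  g <- generate_streams(user_profile(holidays = 2), policy_model("A"),
                        n_days = 4, seed = 61,
                        sensors = c("screen", "calls", "apps"))
  f <- extract_features(g$streams)
  fm <- suppressMessages(build_matrix(f))
  rep <- knn_gas(fm, k = 2)
  rec <- recover_regimes(rep, g$truth, top_n = 1)
  expect_identical(rec$n_holidays, 1L)
  expect_true(rec$n_recovered %in% c(0L, 1L))

  # no holidays -> recovery n/a
  g0 <- generate_streams(user_profile(), policy_model("A"), n_days = 4,
                         seed = 62, sensors = c("screen", "calls", "apps"))
  f0 <- extract_features(g0$streams)
  rec0 <- recover_regimes(knn_gas(suppressMessages(build_matrix(f0)), k = 2),
                          g0$truth)
  expect_identical(rec0$n_holidays, 0L)
  expect_true(is.na(rec0$fraction_recovered))
})
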