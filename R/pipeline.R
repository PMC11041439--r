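# Pipeline orchestration: simulate -> extract -> integrity -> anomaly,
# driven by a single config so every paper-unstated default is inspectable
# in one place, with deterministic outputs for a fixed config + seed.

#' Default pipeline configuration
#'
#' All tunable thresholds of the pipeline with their defaults: gap
#' tolerance, activity threshold, clustering radius/dwell, subgroup rule,
#' PCA screen and k-NN settings, and the simulation profile/policy block.
#'
#' @param seed Integer RNG seed for the simulation stage.
#' @return Nested config list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    timezone = "UTC",
    simulate = list(n_days = 14L, subgroup = "A", holidays = integer(0),
                    start_date = "2023-01-02"),
    integrity = list(max_interruption = c(accel = 1, gps = 120),
                     overlap_threshold = 0.8, gap_floor = 0.05),
    features = list(high_threshold = 0.5, cluster_radius = 100,
                    cluster_min_dwell = 300),
    anomaly = list(k = 5L, variance_frac = 0.9, loading_quantile = 0.75,
                   top_m = NULL))
}

# Deep-merge user config over defaults.
.merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
      .merge_config(base[[k]], user[[k]]) else user[[k]]
  }
  base
}

#' Load a pipeline configuration from YAML
#'
#' Unspecified keys fall back to [default_config()].
#'
#' @param path YAML file path (NULL for pure defaults).
#' @param seed Seed overriding both default and file value, if non-NULL.
#' @return Config list.
#' @export
load_config <- function(path = NULL, seed = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config not found: %s", path)
    cfg <- .merge_config(cfg, yaml::read_yaml(path))
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

.write_json <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)

# features.csv: one row per day, NA-able columns get a parallel missing-mask.
.write_features_csv <- function(features, path) {
  out <- features
  nums <- names(out)[vapply(out, is.numeric, logical(1))]
  maskable <- nums[vapply(out[nums], anyNA, logical(1))]
  for (m in maskable) out[[paste0("miss_", m)]] <- as.integer(is.na(out[[m]]))
  data.table::fwrite(out, path, sep = ",", na = "")
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes the stages in order — simulate (or load raw CSVs), feature
#' extraction, integrity analysis, anomaly scoring — writing each stage's
#' outputs under `outdir` plus a `run.log` echoing the configuration.
#' Identical config and seed produce identical outputs.
#'
#' @param config Config list (see [default_config()] / [load_config()]).
#' @param outdir Output directory.
#' @param streams Optional pre-loaded [sensor_streams()]; when NULL the
#'   simulation stage generates them from the config.
#' @return Invisibly, a list with `streams`, `truth`, `features`,
#'   `integrity`, `subgroup`, `report`, `selected_features`, `outdir`.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("pdrun"),
                         streams = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  res <- tryCatch({
    truth <- NULL
    if (is.null(streams)) {
      sim <- config$simulate
      prof <- user_profile(holidays = sim$holidays %||0% integer(0))
      pol <- policy_model(subgroup = sim$subgroup %||0% "A")
      g <- generate_streams(prof, pol, n_days = sim$n_days, seed = config$seed,
                            start_date = sim$start_date %||0% "2023-01-02",
                            tz = config$timezone)
      streams <- g$streams
      truth <- g$truth
      write_streams_dir(streams, file.path(outdir, "raw"))
      tj <- truth
      tj$dates <- as.character(tj$dates)
      tj$gap_intervals <- lapply(tj$gap_intervals, function(m)
        if (nrow(m)) apply(m, 1, function(r) list(start = r[1], end = r[2]))
        else list())
      tj$transit_intervals <- NULL
      .write_json(tj, file.path(outdir, "ground_truth.json"))
    }

    stage <- "extract"
    fc <- config$features
    features <- extract_features(streams, high_threshold = fc$high_threshold,
                                 radius = fc$cluster_radius,
                                 min_dwell = fc$cluster_min_dwell)
    .write_features_csv(features, file.path(outdir, "features.csv"))
    cl <- attr(features, "clusters")
    if (!is.null(cl) && nrow(cl$clusters)) {
      cj <- cl$clusters
      cj$home <- seq_len(nrow(cj)) == cl$home_index
      .write_json(cj, file.path(outdir, "clusters.json"))
    }

    stage <- "integrity"
    ic <- config$integrity
    span <- range(unlist(lapply(streams$streams,
                                function(x) if (nrow(x)) range(x$t) else NULL)))
    if (!is.null(truth)) span <- truth$run_span
    rep_i <- compute_integrity_report(streams, matrix(span, 1),
                                      max_interruption = ic$max_interruption)
    subgroup <- if (!is.null(streams$streams$screen))
      classify_policy_subgroup(rep_i, streams$streams$screen,
                               overlap_threshold = ic$overlap_threshold,
                               gap_floor = ic$gap_floor)
      else structure("indeterminate", reason = "no screen stream")
    .write_json(list(
      sensors = lapply(rep_i$sensors, function(s)
        s[c("acquired_hours", "running_hours", "integrity_pct")]),
      overall = rep_i$overall,
      subgroup = as.character(subgroup),
      subgroup_reason = attr(subgroup, "reason")),
      file.path(outdir, "integrity_report.json"))
    data.table::fwrite(gap_table(rep_i, config$timezone),
                       file.path(outdir, "gaps.csv"), sep = ",")

    stage <- "anomaly"
    ac <- config$anomaly
    if (!is.null(ac$k) && ac$k >= nrow(features))
      stopf("k = %d requires at least k + 1 = %d days (have %d)",
            ac$k, ac$k + 1, nrow(features))
    fm <- build_matrix(features)
    sel <- pca_screen(fm, variance_frac = ac$variance_frac,
                      loading_quantile = ac$loading_quantile)
    rep_a <- knn_gas(fm, k = ac$k, features = as.character(sel),
                     top_m = ac$top_m)
    data.table::fwrite(rep_a$scores, file.path(outdir, "anomaly.csv"), sep = ",")
    writeLines(as.character(sel), file.path(outdir, "selected_features.txt"))

    writeLines(c(
      paste0("phenoday ", as.character(utils::packageVersion("phenoday"))),
      "config:",
      strsplit(yaml::as.yaml(config), "\n")[[1]]),
      file.path(outdir, "run.log"))

    list(streams = streams, truth = truth, features = features,
         integrity = rep_i, subgroup = subgroup, report = rep_a,
         selected_features = as.character(sel), outdir = outdir)
  }, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  invisible(res)
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Subcommands: `simulate`, `extract`, `integrity`, `anomaly`, `run`
#' (all stages), `report` (print a previous run's summary). Common flags:
#' `--config <yaml>`, `--seed <int>`, `--outdir <dir>`, `--indir <dir>`
#' (raw CSVs for extract/integrity/anomaly stages on real data).
#'
#' @param args Character vector of CLI arguments (default: the command
#'   line).
#' @return Exit status 0L, invisibly.
#' @export
phenoday_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: phenoday <simulate|extract|integrity|anomaly|run|report> [--config F] [--seed N] [--outdir D] [--indir D]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list(config = NULL, seed = NULL, outdir = "phenoday_out", indir = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) stopf("bad argument: %s", args[i])
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  cfg <- load_config(opt$config, seed = opt$seed)
  streams <- if (!is.null(opt$indir))
    read_streams_dir(opt$indir, tz = cfg$timezone) else NULL

  if (cmd == "simulate") {
    sim <- cfg$simulate
    g <- generate_streams(user_profile(holidays = sim$holidays %||0% integer(0)),
                          policy_model(subgroup = sim$subgroup %||0% "A"),
                          n_days = sim$n_days, seed = cfg$seed,
                          start_date = sim$start_date, tz = cfg$timezone)
    write_streams_dir(g$streams, file.path(opt$outdir, "raw"))
    message("wrote raw streams to ", file.path(opt$outdir, "raw"))
  } else if (cmd %in% c("extract", "integrity", "anomaly", "run")) {
    res <- run_pipeline(cfg, outdir = opt$outdir, streams = streams)
    message("pipeline outputs in ", res$outdir)
  } else if (cmd == "report") {
    f <- file.path(opt$outdir, "integrity_report.json")
    if (file.exists(f)) {
      r <- jsonlite::read_json(f)
      message(sprintf("overall integrity: %.1f%%  subgroup: %s",
                      r$overall$integrity_pct, r$subgroup))
    }
    a <- file.path(opt$outdir, "anomaly.csv")
    if (file.exists(a)) {
      sc <- utils::read.csv(a)
      top <- sc[order(sc$rank), ][1:min(5, nrow(sc)), ]
      message("top anomalous days:")
      for (j in seq_len(nrow(top)))
        message(sprintf("  %s  score %.3f", top$day[j], top$score[j]))
    }
  } else { message(usage); return(invisible(1L)) }
  invisible(0L)
}
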