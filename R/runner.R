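#' Episode summary metrics
#'
#' @param episode an [run_episode()] result.
#' @return One-row data frame with complexity, seed, Vi, gazed-region
#'   geometry, saccade counts, C-PAST entropy, bounding-box area and the
#'   number of distinct visited cells.
#' @export
episode_metrics <- function(episode) {
  vi <- tryCatch(
    vertical_index(episode$gaze_h, episode$gaze_w,
                   episode$n_vertical, episode$n_horizontal),
    error = function(e) NA_real_)
  data.frame(
    complexity = episode$complexity,
    seed = episode$seed,
    vi = vi,
    h = episode$gaze_h, w = episode$gaze_w,
    n_vertical = episode$n_vertical, n_horizontal = episode$n_horizontal,
    cpast_entropy = cpast_entropy(episode$learned_B2)$entropy_total,
    bbox_area = episode$gaze_h * episode$gaze_w,
    distinct_cells = sum(episode$heatmap > 0)
  )
}

#' Run a foraging sweep over complexity levels and seeds
#'
#' One episode per (complexity, seed) pair; the per-episode learned B2
#' matrices are returned alongside the metrics so the categorisation
#' experiment can reuse them without re-simulation.
#'
#' @param complexities integer vector of complexity levels (default 0:3).
#' @param seeds integer vector of episode seeds.
#' @param config a [cpast_config()].
#' @param quiet suppress progress messages.
#' @return List with `metrics` (stacked [episode_metrics()] rows) and `b2`
#'   (nested list `b2[[as.character(complexity)]][[as.character(seed)]]`).
#' @export
run_sweep <- function(complexities = 0:3, seeds = 1:20,
                      config = cpast_config(), quiet = TRUE) {
  grid <- grid_spec(config$n_rows, config$n_cols)
  rows <- list()
  b2 <- list()
  for (cx in complexities) {
    vase <- build_vase(cx, grid, band_row = config$band_row)
    b2[[as.character(cx)]] <- list()
    for (s in seeds) {
      ep <- run_episode(vase, config, seed = s)
      rows[[length(rows) + 1L]] <- episode_metrics(ep)
      b2[[as.character(cx)]][[as.character(s)]] <- ep$learned_B2
      if (!quiet) message(sprintf("complexity %d seed %d done", cx, s))
    }
  }
  list(metrics = do.call(rbind, rows), b2 = b2)
}

#' Categorisation hit rates for a set of transferred priors
#'
#' Runs the cut-out experiment for every transferred B2 against every series
#' seed, with the identical series reused across agents within a seed.
#'
#' @param b2_by_complexity nested list as returned in `run_sweep()$b2`.
#' @param series_seeds integer vector of series seeds.
#' @param config a [cpast_config()].
#' @param library a [shape_library()].
#' @param grammar optional truth-transition matrix (default: the
#'   band-reading grammar of the full-complexity vase at the config's grid).
#' @return Data frame with `complexity`, `train_seed`, `series_seed`,
#'   `hit_rate`.
#' @export
run_transfer_sweep <- function(b2_by_complexity, series_seeds = 1:20,
                               config = cpast_config(),
                               library = shape_library(), grammar = NULL) {
  if (is.null(grammar)) {
    vase3 <- build_vase(3L, grid_spec(config$n_rows, config$n_cols),
                        band_row = config$band_row)
    grammar <- decoration_reading_grammar(vase3, n_motifs = config$n_motifs)
  }
  rows <- list()
  for (ss in series_seeds) {
    series <- generate_cutout_series(library, length = config$trials,
                                     seed = ss, grammar = grammar)
    for (cx in names(b2_by_complexity)) {
      for (ts in names(b2_by_complexity[[cx]])) {
        res <- run_experiment2(b2_by_complexity[[cx]][[ts]], series, config,
                               seed = ss)
        rows[[length(rows) + 1L]] <- data.frame(
          complexity = as.integer(cx), train_seed = as.integer(ts),
          series_seed = ss, hit_rate = res$hit_rate)
      }
    }
  }
  do.call(rbind, rows)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run one foraging episode and write its artifacts
#'
#' Emits the scanpath CSV, the heatmap CSV and PNG, the B2 transfer file pair
#' and a metrics JSON, all stamped with the resolved config hash.
#'
#' @param config a [cpast_config()].
#' @param complexity decoration complexity level.
#' @param seed episode seed.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the named character vector of written paths.
#' @export
cmd_forage <- function(config = cpast_config(), complexity = 3L, seed = 1L,
                       out_dir = ".") {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- grid_spec(config$n_rows, config$n_cols)
  vase <- build_vase(complexity, grid, band_row = config$band_row)
  ep <- run_episode(vase, config, seed = seed)
  stem <- file.path(out_dir, sprintf("forage_c%d_s%d", complexity, seed))

  scan_path <- paste0(stem, "_scanpath.csv")
  utils::write.csv(ep$scanpath, scan_path, row.names = FALSE, quote = FALSE)
  heat_csv <- paste0(stem, "_heatmap.csv")
  utils::write.table(ep$heatmap, heat_csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  heat_png <- paste0(stem, "_heatmap.png")
  render_vase(vase, heat_png, heatmap = ep$heatmap, scanpath = ep$scanpath)

  b2_prefix <- paste0(stem, "_b2")
  write_b2_transfer(ep$learned_B2, b2_prefix,
                    meta = list(complexity = complexity, seed = seed,
                                config_hash = ep$config_hash))
  metrics_json <- paste0(stem, "_metrics.json")
  m <- as.list(episode_metrics(ep))
  m$config_hash <- ep$config_hash
  write_json_file(m, metrics_json)
  write_config(config, file.path(out_dir, "config_resolved.yaml"))
  invisible(c(scanpath = scan_path, heatmap_csv = heat_csv,
              heatmap_png = heat_png, b2_csv = paste0(b2_prefix, ".csv"),
              b2_json = paste0(b2_prefix, ".json"), metrics = metrics_json))
}

#' Run the categorisation task from a transfer file and write its artifacts
#'
#' @param b2_file path (or prefix) of a [write_b2_transfer()] file pair.
#' @param config a [cpast_config()].
#' @param seed series / tie-break seed.
#' @param out_dir output directory.
#' @return Invisibly, the named character vector of written paths.
#' @export
cmd_categorise <- function(b2_file, config = cpast_config(), seed = 1L,
                           out_dir = ".") {
  validate_config(config)
  transfer <- read_b2_transfer(b2_file)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  library <- shape_library()
  series <- generate_cutout_series(library, length = config$trials, seed = seed)
  res <- run_experiment2(transfer$B2, series, config, seed = seed)
  stem <- file.path(out_dir, sprintf("categorise_s%d", seed))
  trials_csv <- paste0(stem, "_trials.csv")
  utils::write.csv(res$trials, trials_csv, row.names = FALSE, quote = FALSE)
  summary_json <- paste0(stem, "_summary.json")
  write_json_file(
    list(hit_rate = res$hit_rate, trials = nrow(res$trials), seed = seed,
         transfer_meta = transfer$meta, config_hash = config_hash(config)),
    summary_json)
  invisible(c(trials = trials_csv, summary = summary_json))
}

#' Run the full sweep and write the per-run metrics CSV
#'
#' @param config a [cpast_config()].
#' @param complexities,seeds sweep axes.
#' @param out_dir output directory.
#' @return Invisibly, the sweep CSV path; the sweep result (with B2 matrices)
#'   is attached as attribute `"sweep"`.
#' @export
cmd_sweep <- function(config = cpast_config(), complexities = 0:3,
                      seeds = 1:20, out_dir = ".") {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sw <- run_sweep(complexities, seeds, config)
  path <- file.path(out_dir, "sweep_metrics.csv")
  utils::write.csv(sw$metrics, path, row.names = FALSE, quote = FALSE)
  write_config(config, file.path(out_dir, "config_resolved.yaml"))
  invisible(structure(path, sweep = sw))
}

#' Reproduce the qualitative complexity effects
#'
#' Runs the foraging sweep and the transfer experiment, then reports mean and
#' sd of the vertical index, C-PAST entropy and hit rate per complexity
#' level, together with three monotonicity verdicts (positive Spearman rank
#' correlation of the four per-complexity means with complexity). Writes the
#' summary table CSV, the raw sweep CSVs and a PNG figure per measure.
#'
#' @param config a [cpast_config()].
#' @param seeds foraging (training) seeds; at least 20 are required.
#' @param series_seeds series seeds for the categorisation comparison.
#' @param out_dir output directory.
#' @param sweep optionally, a precomputed [run_sweep()] result to report on
#'   without re-simulation.
#' @return List with `summary` (per-complexity means/sds), `verdicts`
#'   (named logical vector), `forage_metrics`, `transfer_metrics`.
#' @export
cmd_reproduce <- function(config = cpast_config(), seeds = 1:20,
                          series_seeds = 1:20, out_dir = ".",
                          sweep = NULL) {
  validate_config(config)
  if (length(seeds) < 20L) {
    stop("refusing to reproduce with fewer than 20 seeds per complexity",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(sweep)) sweep <- run_sweep(0:3, seeds, config)
  tm <- run_transfer_sweep(sweep$b2, series_seeds, config)

  agg <- function(df, col) {
    out <- do.call(rbind, lapply(split(df[[col]], df$complexity), function(v) {
      data.frame(mean = mean(v), sd = stats::sd(v))
    }))
    out$complexity <- as.integer(rownames(out))
    out[order(out$complexity), c("complexity", "mean", "sd")]
  }
  vi_tab <- agg(sweep$metrics, "vi")
  en_tab <- agg(sweep$metrics, "cpast_entropy")
  hr_tab <- agg(tm, "hit_rate")
  spearman_pos <- function(tab) {
    stats::cor(tab$complexity, tab$mean, method = "spearman") > 0
  }
  verdicts <- c(
    vi_increases = spearman_pos(vi_tab) && all(diff(vi_tab$mean) > 0),
    entropy_increases = spearman_pos(en_tab) && all(diff(en_tab$mean) > 0),
    hit_rate_increases = spearman_pos(hr_tab) && all(diff(hr_tab$mean) >= 0)
  )
  summary <- data.frame(
    complexity = vi_tab$complexity,
    vi_mean = vi_tab$mean, vi_sd = vi_tab$sd,
    entropy_mean = en_tab$mean, entropy_sd = en_tab$sd,
    hit_rate_mean = hr_tab$mean, hit_rate_sd = hr_tab$sd
  )
  utils::write.csv(summary, file.path(out_dir, "reproduce_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sweep$metrics, file.path(out_dir, "forage_metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(tm, file.path(out_dir, "transfer_metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  write_json_file(as.list(verdicts), file.path(out_dir, "verdicts.json"))

  for (spec in list(c("vi_mean", "vertical index"),
                    c("entropy_mean", "C-PAST entropy (nats)"),
                    c("hit_rate_mean", "hit rate"))) {
    f <- file.path(out_dir, paste0("reproduce_", spec[1], ".png"))
    grDevices::png(f, width = 480, height = 480)
    graphics::plot(summary$complexity, summary[[spec[1]]], type = "b",
                   pch = 19, xlab = "decoration complexity", ylab = spec[2])
    grDevices::dev.off()
  }
  list(summary = summary, verdicts = verdicts,
       forage_metrics = sweep$metrics, transfer_metrics = tm)
}
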