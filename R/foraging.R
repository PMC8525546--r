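#' Classify a saccade as vertical, horizontal or excluded
#'
#' A saccade is vertical when its absolute row displacement exceeds its
#' absolute column displacement, horizontal in the opposite case, and
#' excluded on ties (which covers pure diagonals and zero-length moves), so
#' no saccade is double-counted.
#'
#' @param from,to length-2 vectors of 0-based `(row, col)` positions.
#' @return `"vertical"`, `"horizontal"` or `"excluded"`.
#' @export
classify_saccade <- function(from, to) {
  dr <- abs(to[1] - from[1])
  dc <- abs(to[2] - from[2])
  if (dr > dc) "vertical" else if (dc > dr) "horizontal" else "excluded"
}

#' Bounding box of the gazed region
#'
#' @param scanpath matrix or data frame with 0-based `row`, `col` columns.
#' @return Named integer vector `c(h = , w = )`: height and width of the
#'   visited-cell bounding box (a single point has h = w = 1).
#' @export
gaze_region <- function(scanpath) {
  r <- scanpath[, "row"]
  cc <- scanpath[, "col"]
  if (length(r) == 0) stop("empty scanpath", call. = FALSE)
  c(h = as.integer(max(r) - min(r) + 1L), w = as.integer(max(cc) - min(cc) + 1L))
}

#' Run one visual-foraging episode
#'
#' The training experiment. The agent starts at the grid centre and makes
#' `config$timesteps` saccades. Each timestep it scores every candidate
#' location by expected free energy (using the one-step transition-propagated
#' motif belief), moves greedily, observes the pigment at the new location,
#' remaps its local likelihood there and performs level-1 inference. After
#' every 4 level-1 cycles one level-2 motif inference is performed on the
#' cycle's four observations, followed by one Dirichlet update of the B2
#' counts. All stochasticity (tie-breaking only) flows through the seeded
#' session RNG, so results are fully reproducible from `(vase, config, seed)`.
#'
#' @param vase a [build_vase()] stimulus.
#' @param config a [cpast_config()].
#' @param seed integer master seed for the episode.
#' @return An object of class `episode_result`: list with `scanpath` (data
#'   frame `t`, `row`, `col`, `loc`, `observation`, `saccade` — row `t = 0`
#'   is the start), `heatmap` (visit-count matrix summing to `timesteps + 1`),
#'   `n_vertical`, `n_horizontal`, `gaze_h`, `gaze_w`, `learned_B2`,
#'   `b2_counts`, `trace` (per-step G of the chosen action and argmax motif),
#'   `complexity`, `seed`, `config_hash`.
#' @export
run_episode <- function(vase, config = cpast_config(), seed = 1L) {
  validate_config(config)
  set.seed(as.integer(seed))
  grid <- vase$grid
  model <- init_model(vase, config)
  weights <- c(risk = config$w_risk, ambiguity = config$w_ambiguity,
               novelty = config$w_novelty)

  loc <- rowcol_to_loc(grid$n_rows %/% 2L, grid$n_cols %/% 2L, grid)
  all_locs <- seq_len(grid$n_loc) - 1L
  all_rc <- loc_to_rowcol(all_locs, grid)

  n_t <- config$timesteps
  path_loc <- integer(n_t + 1L)
  path_loc[1] <- loc
  obs_seq <- character(n_t + 1L)
  obs_seq[1] <- pigment_at(vase, loc)
  g_chosen <- numeric(n_t)
  q2_argmax <- integer(n_t)

  q2 <- model$D2
  ev_loc <- integer(0)
  ev_out <- character(0)

  for (t in seq_len(n_t)) {
    cands <- all_locs
    if (is.finite(config$saccade_limit)) {
      rc0 <- loc_to_rowcol(loc, grid)
      cheb <- pmax(abs(all_rc[, "row"] - rc0[1, "row"]),
                   abs(all_rc[, "col"] - rc0[1, "col"]))
      cands <- all_locs[cheb <= config$saccade_limit]
    }
    q2_pred <- as.vector(model$B2 %*% q2)
    G <- efe_all(cands, q2_pred, model, q2_prev = q2, weights = weights,
                 rate = config$learning_rate)
    loc <- select_action(G, cands, temperature = config$policy_temperature)
    obs <- pigment_at(vase, loc)
    local <- remap_likelihood(vase, loc)
    infer_level1(local, obs, model$D1, epsilon = config$epsilon)

    path_loc[t + 1L] <- loc
    obs_seq[t + 1L] <- obs
    g_chosen[t] <- min(G)
    q2_argmax[t] <- which.max(q2) - 1L
    ev_loc <- c(ev_loc, loc)
    ev_out <- c(ev_out, obs)

    if (t %% 4L == 0L) {
      q2_new <- infer_level2(list(loc = ev_loc, outcome = ev_out), model, q2,
                             B2 = model$B2)
      model$b2_counts <- update_dirichlet(model$b2_counts, q2_new, q2,
                                          rate = config$learning_rate)
      model$B2 <- normalize_columns(model$b2_counts)
      q2 <- q2_new
      ev_loc <- integer(0)
      ev_out <- character(0)
    }
  }

  rc <- loc_to_rowcol(path_loc, grid)
  sacc <- c(NA_character_,
            vapply(seq_len(n_t), function(t) {
              classify_saccade(rc[t, ], rc[t + 1L, ])
            }, character(1)))
  scanpath <- data.frame(t = 0:n_t, row = rc[, "row"], col = rc[, "col"],
                         loc = path_loc, observation = obs_seq,
                         saccade = sacc, stringsAsFactors = FALSE)
  heatmap <- matrix(0L, grid$n_rows, grid$n_cols)
  for (l in path_loc) {
    i <- loc_to_rowcol(l, grid) + 1L
    heatmap[i] <- heatmap[i] + 1L
  }
  hw <- gaze_region(scanpath)

  structure(
    list(
      scanpath = scanpath,
      heatmap = heatmap,
      n_vertical = sum(sacc == "vertical", na.rm = TRUE),
      n_horizontal = sum(sacc == "horizontal", na.rm = TRUE),
      gaze_h = hw[["h"]], gaze_w = hw[["w"]],
      learned_B2 = model$B2,
      b2_counts = model$b2_counts,
      trace = data.frame(t = seq_len(n_t), g_chosen = g_chosen,
                         q2_argmax = q2_argmax),
      complexity = vase$complexity,
      seed = as.integer(seed),
      config_hash = config_hash(config)
    ),
    class = "episode_result"
  )
}

#' @export
print.episode_result <- function(x, ...) {
  vi <- tryCatch(
    vertical_index(x$gaze_h, x$gaze_w, x$n_vertical, x$n_horizontal),
    error = function(e) NA_real_)
  cat(sprintf(
    "<episode_result> complexity %d, seed %d: %d saccades (%d vertical, %d horizontal)\n",
    x$complexity, x$seed, nrow(x$scanpath) - 1L, x$n_vertical, x$n_horizontal))
  cat(sprintf("  gazed region %d x %d, Vi = %s, C-PAST entropy = %.4f nats\n",
              x$gaze_h, x$gaze_w,
              ifelse(is.na(vi), "undefined", sprintf("%.4f", vi)),
              cpast_entropy(x$learned_B2)$entropy_total))
  invisible(x)
}
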