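#' Shape and cut-out library for the categorisation task
#'
#' The hidden states of the categorisation task are the four foraging motifs
#' rendered as 5x5 binary shape masks (horizontal line, descending oblique,
#' ascending oblique, vertical line) plus one aversive "+" shape that is
#' never a correct answer. Cues are cut-outs: the part of a shape mask
#' visible through a small occlusion window. A cut-out is compatible with
#' every shape whose mask shows exactly the same visible cells through the
#' same window, which makes some cues ambiguous (e.g. the centre cell alone
#' is consistent with all shapes) and others uniquely identifying.
#'
#' @param windows optional named list of occlusion windows (two-column
#'   matrices of 0-based cells); defaults to a catalogue of nine windows
#'   mixing single probes, half occlusions and diagonal probes.
#' @return An object of class `shape_library`: list with `shapes` (names),
#'   `masks` (list of 5x5 0/1 matrices), `plus_id` (0-based id of "+"),
#'   `windows`, `cutouts` (data-frame catalogue with `cutout_id`, `window`,
#'   `visible` pattern string and `compatible` list-column of 0-based shape
#'   ids), and `lookup` (shape x window matrix of cutout ids).
#' @export
shape_library <- function(windows = NULL) {
  k <- 0:4
  cellmat <- function(rows, cols) cbind(row = rows, col = cols)
  shape_cells <- list(
    horizontal   = cellmat(rep(2L, 5), k),
    oblique_down = cellmat(k, k),
    oblique_up   = cellmat(4L - k, k),
    vertical     = cellmat(k, rep(2L, 5)),
    plus         = unique(rbind(cellmat(rep(2L, 5), k), cellmat(k, rep(2L, 5))))
  )
  masks <- lapply(shape_cells, function(cells) {
    m <- matrix(0L, 5, 5)
    m[cells + 1L] <- 1L
    m
  })

  if (is.null(windows)) {
    grid5 <- as.matrix(expand.grid(row = 0:4, col = 0:4))
    windows <- list(
      centre  = cellmat(2L, 2L),
      left    = grid5[grid5[, "col"] <= 1L, ],
      right   = grid5[grid5[, "col"] >= 3L, ],
      top     = grid5[grid5[, "row"] <= 1L, ],
      bottom  = grid5[grid5[, "row"] >= 3L, ],
      diag    = cellmat(1:3, 1:3),
      anti    = cellmat(1:3, 3:1),
      mid_row = cellmat(rep(2L, 5), k),
      mid_col = cellmat(k, rep(2L, 5))
    )
  }

  visible_pattern <- function(mask, win) {
    paste(mask[win + 1L], collapse = "")
  }

  n_shapes <- length(masks)
  cutout_key <- character(0)
  cutouts <- list()
  lookup <- matrix(NA_integer_, n_shapes, length(windows),
                   dimnames = list(names(masks), names(windows)))
  for (w in seq_along(windows)) {
    pats <- vapply(masks, visible_pattern, character(1), win = windows[[w]])
    for (s in seq_len(n_shapes)) {
      key <- paste(names(windows)[w], pats[s], sep = ":")
      id <- match(key, cutout_key)
      if (is.na(id)) {
        cutout_key <- c(cutout_key, key)
        id <- length(cutout_key)
        cutouts[[id]] <- list(
          cutout_id = id, window = names(windows)[w], visible = pats[s],
          compatible = which(pats == pats[s]) - 1L
        )
      }
      lookup[s, w] <- id
    }
  }
  lib <- structure(
    list(
      shapes = names(masks), masks = masks, plus_id = n_shapes - 1L,
      windows = windows,
      cutouts = cutouts,
      lookup = lookup
    ),
    class = "shape_library"
  )
  ## invariants: every cutout compatible with >= 1 shape, ambiguity exists
  stopifnot(all(vapply(cutouts, function(ct) length(ct$compatible), 1L) >= 1L),
            any(vapply(cutouts, function(ct) {
              sum(ct$compatible != lib$plus_id) >= 2L
            }, logical(1))))
  lib
}

#' @export
print.shape_library <- function(x, ...) {
  n_amb <- sum(vapply(x$cutouts, function(ct) {
    sum(ct$compatible != x$plus_id) >= 2L
  }, logical(1)))
  cat(sprintf("<shape_library> %d shapes (+ aversive '%s'), %d windows, %d cut-outs (%d ambiguous)\n",
              length(x$shapes) - 1L, x$shapes[x$plus_id + 1L],
              length(x$windows), length(x$cutouts), n_amb))
  invisible(x)
}

#' Motif-adjacency grammar of a decoration
#'
#' Measures the empirical motif-succession structure of a vase: entry
#' `(i, j)` is proportional to the number of (motif-j cell, motif-i cell)
#' pairs within a Chebyshev radius, column-normalised. This is the spatial
#' succession statistics of the decoration and is used as the generating
#' chain of the cut-out series, so that the cue sequence carries the
#' artefact's motif grammar. By default same-motif pairs are excluded: a
#' succession of cues means moving on to the next motif of the decoration,
#' not re-reading the one just categorised.
#'
#' @param vase a [build_vase()] stimulus (normally the full complexity-3
#'   vase).
#' @param radius Chebyshev neighbourhood radius (default 6 cells).
#' @param n_motifs size of the motif space (default 4).
#' @param exclude_self drop same-motif adjacency (default `TRUE`).
#' @return Column-stochastic `n_motifs x n_motifs` matrix.
#' @export
motif_transition_grammar <- function(vase, radius = 6L, n_motifs = 4L,
                                     exclude_self = TRUE) {
  present <- motifs_present(vase)
  if (length(present) < 1L) stop("vase has no motifs", call. = FALSE)
  cells <- which(vase$motif_label >= 0L, arr.ind = TRUE)  # 1-based
  lab <- vase$motif_label[cells]
  n <- nrow(cells)
  counts <- matrix(0, n_motifs, n_motifs)
  for (a in seq_len(n)) {
    near <- abs(cells[, 1] - cells[a, 1]) <= radius &
      abs(cells[, 2] - cells[a, 2]) <= radius
    near[a] <- FALSE
    tab <- tabulate(lab[near] + 1L, nbins = n_motifs)
    counts[, lab[a] + 1L] <- counts[, lab[a] + 1L] + tab
  }
  if (exclude_self) diag(counts) <- 0
  empty <- colSums(counts) == 0
  counts[, empty] <- 1  # motifs absent from the vase: uniform column
  normalize_columns(counts)
}

#' Band-reading grammar of a decoration
#'
#' The Markov chain obtained by reading the full decoration band by band:
#' each motif is tiled `n_reps` times across its band, so a reader encounters
#' it in runs of `n_reps` before moving on to the next band (bands ordered
#' top to bottom, wrapping around). The resulting truth-transition matrix has
#' self-transition probability `(n_reps - 1) / n_reps` and passes the
#' remaining mass to the band successor. This is the default generating
#' chain of the cut-out series: cues repeat a motif a few times, as the
#' artefact itself does, then alternate.
#'
#' @param vase a [build_vase()] stimulus (normally the full complexity-3
#'   vase); its stencil layout defines the band order and repetition count.
#' @param n_motifs size of the shape space the chain runs over (default 4).
#' @return Column-stochastic `n_motifs x n_motifs` matrix.
#' @export
decoration_reading_grammar <- function(vase = build_vase(3L), n_motifs = 4L) {
  band_top <- vapply(vase$stencils, function(s) min(s$cells[, "row"]), 0L)
  ids <- vapply(vase$stencils, function(s) s$motif_id, 0L)
  order_ids <- ids[order(band_top)]
  n_reps <- vase$stencils[[1]]$n_reps
  Tm <- matrix(0, n_motifs, n_motifs)
  stay <- (n_reps - 1) / n_reps
  for (k in seq_along(order_ids)) {
    m <- order_ids[k]
    succ <- order_ids[if (k == length(order_ids)) 1L else k + 1L]
    Tm[m + 1L, m + 1L] <- Tm[m + 1L, m + 1L] + stay
    Tm[succ + 1L, m + 1L] <- Tm[succ + 1L, m + 1L] + 1 - stay
  }
  missing <- setdiff(seq_len(n_motifs), order_ids + 1L)
  for (j in missing) Tm[, j] <- 1 / n_motifs
  normalize_columns(Tm)
}

#' Generate the predetermined cut-out series
#'
#' Draws the sequence of true shapes from the Markov chain given by the
#' decoration's band-reading grammar (so successive cues follow the
#' artefact's motif succession statistics: runs of a motif, then the next
#' band), then pairs each truth with an occlusion window drawn uniformly.
#' The series is fully determined by its seed and is reused unchanged for
#' every agent in a comparison. The "+" shape is never a truth.
#'
#' @param library a [shape_library()].
#' @param length number of trials (default 100).
#' @param seed integer series seed.
#' @param grammar column-stochastic truth-transition matrix over the
#'   non-"+" shapes; defaults to [decoration_reading_grammar()] of the
#'   default complexity-3 vase.
#' @return An object of class `cutout_series`: data frame with `trial`,
#'   `true_shape` (0-based), `window`, `cutout_id`, carrying the library and
#'   grammar as attributes.
#' @export
generate_cutout_series <- function(library = shape_library(), length = 100L,
                                   seed = 1L, grammar = NULL) {
  if (length < 1L) stop("series length must be >= 1", call. = FALSE)
  n_real <- base::length(library$shapes) - 1L
  if (is.null(grammar)) {
    grammar <- decoration_reading_grammar(build_vase(3L), n_motifs = n_real)
  }
  if (!all(dim(grammar) == n_real)) {
    stop("grammar dimension must match the number of non-'+' shapes",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  truth <- integer(length)
  truth[1] <- sample.int(n_real, 1L) - 1L
  if (length > 1L) {
    for (i in 2:length) {
      truth[i] <- sample.int(n_real, 1L, prob = grammar[, truth[i - 1L] + 1L]) - 1L
    }
  }
  win_ids <- sample.int(base::length(library$windows), length, replace = TRUE)
  series <- data.frame(
    trial = seq_len(length),
    true_shape = truth,
    window = names(library$windows)[win_ids],
    cutout_id = library$lookup[cbind(truth + 1L, win_ids)]
  )
  structure(series, class = c("cutout_series", "data.frame"),
            library = library, grammar = grammar, seed = as.integer(seed))
}

## Embed a learned motif-transition block into the shape space. Rows of
## shapes the agent never experienced (including the "+") get the likelihood
## floor. Columns for never-experienced states are filled with the agent's
## marginal next-motif expectation (the row means of its experienced
## columns): an attention style trained on few motifs keeps predicting the
## motifs it knows even from unfamiliar states, whereas a dispersed style
## stays open. Columns are renormalised.
embed_b2_shapes <- function(B2, n_shapes, epsilon) {
  k <- nrow(B2)
  B <- matrix(epsilon, n_shapes, n_shapes)
  B[seq_len(k), seq_len(k)] <- B2
  if (k < n_shapes) {
    marginal <- rowMeans(B[, seq_len(k), drop = FALSE])
    B[, (k + 1L):n_shapes] <- marginal
  }
  normalize_columns(B)
}

#' Run one categorisation trial
#'
#' Three moments: a blank display propagates the carried belief one step
#' through the transferred transition matrix (the prior); the cut-out cue is
#' observed with a deterministic compatibility likelihood (floor `epsilon`
#' off the compatible set); the agent selects the maximum-posterior shape,
#' with a fixed log-penalty on the aversive "+" so a real shape is always
#' committed to. Ties are broken uniformly at random via the session RNG.
#'
#' @param cutout a cut-out record from the library (`library$cutouts[[id]]`).
#' @param prev_belief normalised belief over shapes carried from the previous
#'   trial.
#' @param B2_shapes column-stochastic shape-transition matrix (the embedded
#'   transferred B2).
#' @param library a [shape_library()].
#' @param plus_penalty decision-stage log-penalty on "+" (default -8).
#' @param epsilon likelihood floor.
#' @return A `trial_record` list: `cutout_id`, `prior`, `posterior`,
#'   `decision` (0-based shape), `hit` (filled by the caller when the truth
#'   is known: `NA` here).
#' @export
run_trial <- function(cutout, prev_belief, B2_shapes, library,
                      plus_penalty = -8, epsilon = 1e-3) {
  if (abs(sum(prev_belief) - 1) > 1e-6 || any(prev_belief < 0)) {
    stop("prev_belief must be normalised", call. = FALSE)
  }
  n_shapes <- length(library$shapes)
  prior <- as.vector(B2_shapes %*% prev_belief)
  lik <- rep(epsilon, n_shapes)
  lik[cutout$compatible + 1L] <- 1
  posterior <- lik * prior
  posterior <- posterior / sum(posterior)
  scores <- log(posterior)
  scores[library$plus_id + 1L] <- scores[library$plus_id + 1L] + plus_penalty
  best <- which(scores == max(scores))
  pick <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
  structure(
    list(cutout_id = cutout$cutout_id, prior = prior, posterior = posterior,
         decision = pick - 1L, hit = NA),
    class = "trial_record"
  )
}

#' Run the full categorisation experiment with a frozen transferred prior
#'
#' Presents the predetermined cut-out series to an agent whose
#' shape-transition prior is the (frozen) B2 learned during foraging. The
#' first-trial belief is uniform; thereafter the posterior is carried
#' forward through the blank-display propagation. No learning takes place:
#' the transferred matrix is bit-identical before and after the run.
#'
#' @param B2_transferred column-stochastic motif-transition matrix from
#'   [run_episode()] (or [read_b2_transfer()]).
#' @param series a [generate_cutout_series()] object.
#' @param config a [cpast_config()] (uses `epsilon` and `plus_penalty`).
#' @param seed integer seed for decision tie-breaking.
#' @return List with `trials` (data frame `trial`, `true_shape`, `cutout_id`,
#'   `decision`, `hit`), `records` (full trial records), `hit_rate`,
#'   `B2_shapes` (the embedded matrix used).
#' @export
run_experiment2 <- function(B2_transferred, series, config = cpast_config(),
                            seed = 1L) {
  library <- attr(series, "library")
  n_shapes <- length(library$shapes)
  if (nrow(B2_transferred) != ncol(B2_transferred) ||
      nrow(B2_transferred) > n_shapes - 1L) {
    stop(sprintf(
      "config error: transferred matrix is %dx%d but the library has %d non-'+' shapes",
      nrow(B2_transferred), ncol(B2_transferred), n_shapes - 1L), call. = FALSE)
  }
  frozen <- B2_transferred
  set.seed(as.integer(seed))
  B2s <- embed_b2_shapes(B2_transferred, n_shapes, config$epsilon)
  belief <- rep(1 / n_shapes, n_shapes)
  records <- vector("list", nrow(series))
  decision <- integer(nrow(series))
  for (i in seq_len(nrow(series))) {
    ct <- library$cutouts[[series$cutout_id[i]]]
    rec <- run_trial(ct, belief, B2s, library,
                     plus_penalty = config$plus_penalty,
                     epsilon = config$epsilon)
    rec$hit <- rec$decision == series$true_shape[i]
    records[[i]] <- rec
    decision[i] <- rec$decision
    belief <- rec$posterior
  }
  stopifnot(identical(frozen, B2_transferred))  # no-learning guarantee
  trials <- data.frame(
    trial = series$trial, true_shape = series$true_shape,
    cutout_id = series$cutout_id, decision = decision,
    hit = decision == series$true_shape
  )
  list(trials = trials, records = records, hit_rate = hit_rate(trials),
       B2_shapes = B2s)
}
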