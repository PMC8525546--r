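#' Column-normalise a non-negative matrix
#'
#' @param m numeric matrix with non-negative entries and no all-zero column.
#' @return Matrix of the same shape whose columns each sum to 1.
#' @export
normalize_columns <- function(m) {
  if (any(m < 0)) stop("negative entries cannot be normalised", call. = FALSE)
  s <- colSums(m)
  if (any(s == 0)) stop("degenerate input: all-zero column", call. = FALSE)
  sweep(m, 2, s, "/")
}

#' Initialise the agent's hierarchical generative model
#'
#' Builds the two-level parameter set. Level 1: a deterministic likelihood
#' `A1` over the 9 local states (rebuilt from [remap_likelihood()] after every
#' saccade), deterministic action-conditioned transitions `B1` (a saccade
#' lands exactly where it aims), and a log-preference vector `C` that strongly
#' favours observing pigment. Level 2: a deterministic likelihood `A2` mapping
#' each motif to its normalised pigment map, a column-stochastic motif
#' transition matrix `B2` obtained by normalising the Dirichlet counts
#' `b2_counts`, and uniform initial priors `D1`, `D2`. Only `b2_counts` is
#' ever learned.
#'
#' The motif state space matches the vase: a complexity-c decoration carries
#' c + 1 motifs, so B2 is (c+1) x (c+1). Transfer into the fixed-size
#' categorisation shape space is handled downstream by embedding the learned
#' block with a likelihood-floor fill for never-seen shapes (see
#' [run_experiment2()]).
#'
#' @param vase a [build_vase()] stimulus.
#' @param config a [cpast_config()].
#' @param n_motifs size of the motif state space; defaults to the number of
#'   motifs present on the vase.
#' @return An object of class `hierarchical_model` with fields `A1`, `A2`,
#'   `B1`, `B2`, `b2_counts`, `P_pig` (per-location, per-motif Bernoulli
#'   pigment probability used for evidence and prediction), `C`, `C_probs`,
#'   `D1`, `D2`, `config`, `grid`.
#' @export
init_model <- function(vase, config = cpast_config(), n_motifs = NULL) {
  if (config$dirichlet_seed <= 0) {
    stop("config error: dirichlet_seed must be positive", call. = FALSE)
  }
  grid <- vase$grid
  eps <- config$epsilon
  present <- motifs_present(vase)
  n_m <- if (is.null(n_motifs)) length(present) else as.integer(n_motifs)
  if (any(present >= n_m)) {
    stop("config error: vase contains motif ids outside the model state space",
         call. = FALSE)
  }

  A2 <- matrix(1 / grid$n_loc, nrow = grid$n_loc, ncol = n_m,
               dimnames = list(NULL, paste0("m", seq_len(n_m) - 1L)))
  P_pig <- matrix(eps, nrow = grid$n_loc, ncol = n_m,
                  dimnames = dimnames(A2))
  for (m in present) {
    map <- as_loc_vector(motif_pigment_map(vase, m))
    A2[, m + 1L] <- map
    P_pig[map > 0, m + 1L] <- 1
  }

  counts <- config$dirichlet_seed *
    (matrix(1, n_m, n_m) + config$b2_persistence * diag(n_m))
  dimnames(counts) <- list(paste0("to_m", seq_len(n_m) - 1L),
                           paste0("from_m", seq_len(n_m) - 1L))
  C <- c(pigment = config$pref_pigment, no_pigment = config$pref_no_pigment)
  C_probs <- exp(C) / sum(exp(C))

  centre <- rowcol_to_loc(grid$n_rows %/% 2L, grid$n_cols %/% 2L, grid)
  structure(
    list(
      A1 = remap_likelihood(vase, centre)$outcome_probs,
      A2 = A2,
      B1 = diag(9),  # action a moves the local state to patch position a
      b2_counts = counts,
      B2 = normalize_columns(counts),
      P_pig = P_pig,
      C = C, C_probs = C_probs,
      D1 = rep(1 / 9, 9),
      D2 = rep(1 / n_m, n_m),
      config = config, grid = grid
    ),
    class = "hierarchical_model"
  )
}

#' @export
print.hierarchical_model <- function(x, ...) {
  cat(sprintf("<hierarchical_model> %d motifs over %d locations\n",
              ncol(x$B2), x$grid$n_loc))
  cat("  B2 (column-stochastic motif transitions):\n")
  print(round(x$B2, 3))
  cat(sprintf("  Dirichlet mass %.3f, C = (%+g pigment, %+g no_pigment)\n",
              sum(x$b2_counts), x$C[["pigment"]], x$C[["no_pigment"]]))
  invisible(x)
}

#' Dirichlet update of the motif-transition counts
#'
#' One learning step: the counts are incremented by
#' `rate * q2_now %o% q2_prev`, the posterior co-occurrence of the
#' transition just evidenced. Total count mass grows by exactly `rate`;
#' column-normalising the result gives the new B2.
#'
#' @param b2_counts positive count matrix (rows: next motif, columns:
#'   previous motif).
#' @param q2_now,q2_prev normalised motif posteriors.
#' @param rate learning rate (> 0).
#' @return Updated count matrix.
#' @export
update_dirichlet <- function(b2_counts, q2_now, q2_prev, rate = 1.0) {
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  for (q in list(q2_now, q2_prev)) {
    if (any(q < 0) || abs(sum(q) - 1) > 1e-6) {
      stop("posterior must be normalised and non-negative", call. = FALSE)
    }
  }
  b2_counts + rate * (q2_now %o% q2_prev)
}

#' Write a learned motif-transition matrix as a transfer artifact
#'
#' Serialises B2 as a plain CSV matrix (rows: next motif, columns: previous
#' motif) with a JSON sidecar recording provenance. This file pair is the
#' object the categorisation task consumes.
#'
#' @param B2 column-stochastic matrix.
#' @param prefix output path prefix; writes `<prefix>.csv` + `<prefix>.json`.
#' @param meta named list merged into the sidecar (e.g. complexity, seed,
#'   config hash).
#' @return Invisibly, the two paths.
#' @export
write_b2_transfer <- function(B2, prefix, meta = list()) {
  stopifnot(is.matrix(B2), nrow(B2) == ncol(B2))
  csv <- paste0(prefix, ".csv")
  json <- paste0(prefix, ".json")
  utils::write.table(format(B2, digits = 17, scientific = TRUE, trim = TRUE),
                     csv, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  side <- c(list(n_motifs = ncol(B2)), meta)
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' Read a B2 transfer artifact
#'
#' @param prefix path prefix as used by [write_b2_transfer()], or the `.csv`
#'   path itself.
#' @return List with `B2` (validated column-stochastic matrix) and `meta`
#'   (sidecar contents, `NULL` if the sidecar is missing).
#' @export
read_b2_transfer <- function(prefix) {
  csv <- if (grepl("\\.csv$", prefix)) prefix else paste0(prefix, ".csv")
  if (!file.exists(csv)) stop("transfer file not found: ", csv, call. = FALSE)
  lines <- readLines(csv)
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(lines[i], ",")[[1]]))
    if (any(is.na(v))) {
      stop(sprintf("parse error in %s at line %d: non-numeric entry", csv, i),
           call. = FALSE)
    }
    v
  })
  n <- length(rows)
  if (any(vapply(rows, length, 1L) != n)) {
    stop(sprintf("parse error in %s: matrix is not square (%d rows)", csv, n),
         call. = FALSE)
  }
  B2 <- do.call(rbind, rows)
  if (any(B2 < 0) || any(abs(colSums(B2) - 1) > 1e-6)) {
    stop("transfer matrix is not column-stochastic", call. = FALSE)
  }
  jsonp <- sub("\\.csv$", ".json", csv)
  meta <- if (file.exists(jsonp)) jsonlite::read_json(jsonp) else NULL
  list(B2 = B2, meta = meta)
}
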