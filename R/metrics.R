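#' Vertical index of a scanpath
#'
#' Normalised contrast of height-weighted vertical saccades against
#' width-weighted horizontal saccades:
#' `Vi = (h * n_vert - w * n_horiz) / (h * n_vert + w * n_horiz)`,
#' bounded in \[-1, 1\]; +1 is a purely vertical scanpath, -1 purely
#' horizontal. `h` and `w` are the height and width of the gazed-region
#' bounding box (see [gaze_region()]).
#'
#' The `"printed"` denominator variant `h * n_vert + w * n_vert` is kept for
#' comparison with the uncorrected published formula; it does not bound the
#' index for horizontal-dominant paths and is not the default.
#'
#' @param h,w positive integers: gazed-region height and width.
#' @param n_vert,n_horiz non-negative saccade counts.
#' @param denominator `"corrected"` (default) or `"printed"`.
#' @return Scalar index.
#' @export
vertical_index <- function(h, w, n_vert, n_horiz,
                           denominator = c("corrected", "printed")) {
  denominator <- match.arg(denominator)
  if (h < 1 || w < 1 || n_vert < 0 || n_horiz < 0) {
    stop("h, w must be >= 1 and counts >= 0", call. = FALSE)
  }
  num <- h * n_vert - w * n_horiz
  den <- if (denominator == "corrected") h * n_vert + w * n_horiz
         else h * n_vert + w * n_vert
  if (den == 0) {
    stop("vertical index undefined: zero weighted-saccade mass", call. = FALSE)
  }
  num / den
}

#' C-PAST entropy of a learned motif-transition matrix
#'
#' Phenotypes an attention style by the Shannon entropy (nats, 0 log 0 = 0)
#' of each column of the column-stochastic B2 matrix, summed over columns.
#' A deterministic transition structure scores 0; `N` uniform columns score
#' `N * log(N)`.
#'
#' @param B2 column-stochastic matrix (columns sum to 1, entries >= 0).
#' @return An object of class `cpast_result`: list with `entropy_total` and
#'   `per_column_entropy`.
#' @export
cpast_entropy <- function(B2) {
  if (any(B2 < 0) || any(abs(colSums(B2) - 1) > 1e-6)) {
    stop("B2 must be column-stochastic", call. = FALSE)
  }
  per_col <- apply(B2, 2, function(p) -sum(xlogx(p)))
  structure(
    list(entropy_total = sum(per_col), per_column_entropy = per_col),
    class = "cpast_result"
  )
}

#' @export
print.cpast_result <- function(x, ...) {
  cat(sprintf("<cpast_result> total entropy %.4f nats (per column: %s)\n",
              x$entropy_total,
              paste(sprintf("%.4f", x$per_column_entropy), collapse = ", ")))
  invisible(x)
}

#' Hit rate of a categorisation run
#'
#' @param trials a data frame with a logical `hit` column, or a list of
#'   trial records each having `$hit`.
#' @return Fraction of hits in \[0, 1\].
#' @export
hit_rate <- function(trials) {
  hits <- if (is.data.frame(trials)) trials$hit
          else vapply(trials, function(tr) isTRUE(tr$hit), logical(1))
  if (length(hits) == 0) stop("empty trial list", call. = FALSE)
  mean(as.logical(hits))
}
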