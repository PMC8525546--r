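#' 3x3 neighbourhood of a location
#'
#' The agent's local hidden-state space: the 8 locations surrounding the
#' current location plus the location itself, in row-major order (so the
#' centre is always at position 5 of the returned vector). Positions that
#' fall off the grid are marked with the sentinel `-1`.
#'
#' @param loc 0-based location index.
#' @param grid a [grid_spec()].
#' @return Integer vector of length 9.
#' @export
neighborhood <- function(loc, grid) {
  rc <- loc_to_rowcol(loc, grid)
  rows <- rc[1, "row"] + (-1:1)
  cols <- rc[1, "col"] + (-1:1)
  out <- integer(9)
  i <- 0L
  for (r in rows) {
    for (c in cols) {
      i <- i + 1L
      out[i] <- if (r < 0L || r >= grid$n_rows || c < 0L || c >= grid$n_cols)
        -1L else r * grid$n_cols + c
    }
  }
  out
}

#' Remap the local observation likelihood
#'
#' The remapping trick: after every saccade the agent's level-1 likelihood is
#' rebuilt from the 3x3 patch of the generative process around the new
#' location, so the agent only ever represents its immediate surroundings and
#' never a global scene model. Each of the 9 local states gets a
#' deterministic outcome distribution over {pigment, no_pigment} read off the
#' vase; off-grid positions observe no pigment deterministically.
#'
#' @param vase a [build_vase()] stimulus (the generative process).
#' @param loc 0-based location index of the agent.
#' @return An object of class `local_likelihood`: list with `center`,
#'   `local_states` (length-9 integer vector, sentinel -1 off-grid) and
#'   `outcome_probs` (2 x 9 matrix, rows `pigment` / `no_pigment`, columns
#'   summing to 1).
#' @export
remap_likelihood <- function(vase, loc) {
  states <- neighborhood(loc, vase$grid)
  p_pig <- vapply(states, function(s) {
    if (s < 0L) 0 else as.numeric(vase$pigment[loc_to_rowcol(s, vase$grid) + 1L])
  }, numeric(1))
  probs <- rbind(pigment = p_pig, no_pigment = 1 - p_pig)
  structure(
    list(center = as.integer(loc), local_states = states, outcome_probs = probs),
    class = "local_likelihood"
  )
}

#' @export
print.local_likelihood <- function(x, ...) {
  cat(sprintf("<local_likelihood> centred on location %d\n", x$center))
  sym <- ifelse(x$local_states < 0L, ".",
                ifelse(x$outcome_probs["pigment", ] > 0.5, "#", "o"))
  for (r in 0:2) cat(" ", paste(sym[r * 3 + 1:3], collapse = " "), "\n")
  cat("  (# pigment, o blank, . off-grid)\n")
  invisible(x)
}
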