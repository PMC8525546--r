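#' Grid specification for a vase stimulus
#'
#' Defines the discrete location space the agent forages over. Locations are
#' indexed row-major and 0-based, so location `row * n_cols + col` sits at
#' 0-based `(row, col)`; a 6x6 grid numbers its cells 0-35 and the default
#' 30x30 grid has 900 locations.
#'
#' @param n_rows,n_cols positive integer grid dimensions (default 30 x 30).
#' @return An object of class `grid_spec` with fields `n_rows`, `n_cols`,
#'   `n_loc`.
#' @export
grid_spec <- function(n_rows = 30L, n_cols = 30L) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L) {
    stop("grid dimensions must be positive integers", call. = FALSE)
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, n_loc = n_rows * n_cols),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d (%d locations, row-major 0-based)\n",
              x$n_rows, x$n_cols, x$n_loc))
  invisible(x)
}

#' Convert between location indices and (row, col) pairs
#'
#' Both sides of the bijection are 0-based; locations are row-major.
#'
#' @param loc integer vector of location indices in `[0, n_loc)`.
#' @param row,col integer vectors of 0-based coordinates.
#' @param grid a [grid_spec()].
#' @return `loc_to_rowcol` returns a two-column integer matrix (`row`, `col`);
#'   `rowcol_to_loc` returns an integer vector.
#' @export
loc_to_rowcol <- function(loc, grid) {
  loc <- as.integer(loc)
  if (any(is.na(loc)) || any(loc < 0L) || any(loc >= grid$n_loc)) {
    stop("location index out of range", call. = FALSE)
  }
  cbind(row = loc %/% grid$n_cols, col = loc %% grid$n_cols)
}

#' @rdname loc_to_rowcol
#' @export
rowcol_to_loc <- function(row, col, grid) {
  row <- as.integer(row)
  col <- as.integer(col)
  if (any(row < 0L) || any(row >= grid$n_rows) ||
      any(col < 0L) || any(col >= grid$n_cols)) {
    stop("row/col out of range", call. = FALSE)
  }
  row * grid$n_cols + col
}

## flatten a grid-shaped matrix into location (row-major) order
as_loc_vector <- function(mat) as.vector(t(mat))

#' Motif stencil library
#'
#' Builds the four motif stencils used to decorate a vase, in increasing order
#' of verticality: a horizontal line segment, an oblique descending below the
#' line, an oblique ascending above it, and a vertical segment below the lower
#' obliques. Each stencil is a set of 0-based `(row, col)` cells, tiled
#' `n_reps` times across the grid with a 2-cell gap between repetitions.
#'
#' @param grid a [grid_spec()].
#' @param band_row 0-based row of the horizontal decoration band; default
#'   `floor(n_rows / 2) - 1`.
#' @param seg_len cells per stencil (default 5).
#' @param n_reps repetitions of each stencil across the band (default 4).
#' @return A list of stencils, each a list with `motif_id`, `name` and a
#'   two-column `cells` matrix.
#' @export
motif_stencils <- function(grid, band_row = NULL, seg_len = 5L, n_reps = 4L) {
  seg_len <- as.integer(seg_len)
  n_reps <- as.integer(n_reps)
  if (seg_len < 2L || n_reps < 1L) {
    stop("seg_len must be >= 2 and n_reps >= 1", call. = FALSE)
  }
  if (is.null(band_row)) band_row <- grid$n_rows %/% 2L - 1L
  band_row <- as.integer(band_row)

  anchors <- 1L + (seg_len + 2L) * (seq_len(n_reps) - 1L)
  k <- seq_len(seg_len) - 1L

  cells_for <- function(rows, cols) {
    do.call(rbind, lapply(anchors, function(a) cbind(row = rows, col = a + cols)))
  }
  add_meta <- function(s) c(s, list(seg_len = seg_len, n_reps = n_reps))
  stencils <- list(
    list(motif_id = 0L, name = "horizontal",
         cells = cells_for(rep(band_row, seg_len), k)),
    list(motif_id = 1L, name = "oblique_down",
         cells = cells_for(band_row + 3L + k, k)),
    list(motif_id = 2L, name = "oblique_up",
         cells = cells_for(band_row - 3L - k, k)),
    list(motif_id = 3L, name = "vertical",
         cells = cells_for(band_row + 10L + k, rep(2L, seg_len)))
  )
  stencils <- lapply(stencils, add_meta)
  for (s in stencils) {
    if (any(s$cells[, "row"] < 0L) || any(s$cells[, "row"] >= grid$n_rows) ||
        any(s$cells[, "col"] < 0L) || any(s$cells[, "col"] >= grid$n_cols)) {
      stop(sprintf(
        "grid %dx%d too small to host stencil '%s' (band row %d)",
        grid$n_rows, grid$n_cols, s$name, band_row), call. = FALSE)
    }
  }
  stencils
}

#' Build a synthetic vase stimulus
#'
#' Constructs the generative process: a binary pigment grid plus the
#' ground-truth motif identity of every pigment cell. The four complexity
#' levels are cumulative. Level 0 is a straight horizontal line of pigment
#' segments; level 1 adds oblique segments below the line; level 2 adds
#' obliques above the line as well; level 3 adds vertical segments below the
#' lower obliques. Construction is fully deterministic.
#'
#' @param complexity integer in 0..3.
#' @param grid a [grid_spec()]; the default 30 x 30 grid hosts all stencils.
#' @param band_row,seg_len,n_reps stencil layout overrides, see
#'   [motif_stencils()].
#' @return An object of class `vase_stimulus`: a list with `grid`,
#'   `pigment` (0/1 integer matrix), `motif_label` (integer matrix, -1 on
#'   background), `complexity`, `band_row` and the placed `stencils`.
#' @export
build_vase <- function(complexity, grid = grid_spec(), band_row = NULL,
                       seg_len = 5L, n_reps = 4L) {
  complexity <- as.integer(complexity)
  if (is.na(complexity) || !(complexity %in% 0:3)) {
    stop("complexity must be one of 0, 1, 2, 3", call. = FALSE)
  }
  if (is.null(band_row)) band_row <- grid$n_rows %/% 2L - 1L
  stencils <- motif_stencils(grid, band_row = band_row,
                             seg_len = seg_len, n_reps = n_reps)

  pigment <- matrix(0L, grid$n_rows, grid$n_cols)
  motif_label <- matrix(-1L, grid$n_rows, grid$n_cols)
  for (s in stencils[seq_len(complexity + 1L)]) {
    idx <- s$cells + 1L  # to 1-based matrix indexing
    pigment[idx] <- 1L
    motif_label[idx] <- s$motif_id
  }
  structure(
    list(grid = grid, pigment = pigment, motif_label = motif_label,
         complexity = complexity, band_row = as.integer(band_row),
         stencils = stencils[seq_len(complexity + 1L)]),
    class = "vase_stimulus"
  )
}

#' @export
print.vase_stimulus <- function(x, ...) {
  cat(sprintf("<vase_stimulus> complexity %d, %d x %d grid, %d pigment cells, motifs {%s}\n",
              x$complexity, x$grid$n_rows, x$grid$n_cols, sum(x$pigment),
              paste(motifs_present(x), collapse = ", ")))
  invisible(x)
}

#' Motif ids present on a vase
#' @param vase a [build_vase()] stimulus.
#' @return Sorted integer vector of motif ids with at least one pigment cell.
#' @export
motifs_present <- function(vase) {
  sort(unique(vase$motif_label[vase$motif_label >= 0L]))
}

#' Ground-truth pigment query
#'
#' Reads the generative process at one location. Pure function of
#' `(vase, loc)`.
#'
#' @param vase a `vase_stimulus`.
#' @param loc 0-based location index.
#' @return `"pigment"` or `"no_pigment"`.
#' @export
pigment_at <- function(vase, loc) {
  rc <- loc_to_rowcol(loc, vase$grid)
  ifelse(vase$pigment[rc + 1L] == 1L, "pigment", "no_pigment")
}

#' Normalised pigment map of one motif
#'
#' Returns P(location | motif): the indicator of the motif's cells,
#' normalised to sum to 1 over the grid. This is the column of the level-2
#' likelihood associated with the motif.
#'
#' @param vase a `vase_stimulus`.
#' @param motif_id motif id present on the vase.
#' @return A numeric matrix of the grid's shape summing to 1.
#' @export
motif_pigment_map <- function(vase, motif_id) {
  motif_id <- as.integer(motif_id)
  if (!(motif_id %in% motifs_present(vase))) {
    stop(sprintf("motif %d is not present on this complexity-%d vase",
                 motif_id, vase$complexity), call. = FALSE)
  }
  ind <- (vase$motif_label == motif_id) * 1
  ind / sum(ind)
}

#' Export a vase as plain CSV matrices
#'
#' Writes `<prefix>_pigment.csv` (0/1) and `<prefix>_motifs.csv`
#' (motif labels, -1 on background), both without row names.
#'
#' @param vase a `vase_stimulus`.
#' @param prefix output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_vase_csv <- function(vase, prefix) {
  paths <- paste0(prefix, c("_pigment.csv", "_motifs.csv"))
  utils::write.table(vase$pigment, paths[1], sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(vase$motif_label, paths[2], sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

#' Render a vase (and optionally a visit heatmap) to PNG
#'
#' @param vase a `vase_stimulus`.
#' @param file output PNG path.
#' @param heatmap optional matrix of visit counts to overlay as colour.
#' @param scanpath optional matrix/data.frame with 0-based `row`, `col`
#'   columns drawn as a connected path.
#' @return Invisibly, `file`.
#' @export
render_vase <- function(vase, file, heatmap = NULL, scanpath = NULL) {
  grDevices::png(file, width = 640, height = 640)
  on.exit(grDevices::dev.off(), add = TRUE)
  img <- if (is.null(heatmap)) vase$pigment else heatmap
  ## image() draws column-major from bottom; transpose + flip for row 0 on top
  z <- t(img[rev(seq_len(nrow(img))), , drop = FALSE])
  cols <- if (is.null(heatmap)) c("grey95", "grey10") else
    grDevices::hcl.colors(64, "viridis")
  graphics::image(x = seq_len(vase$grid$n_cols), y = seq_len(vase$grid$n_rows),
                  z = z, col = cols, axes = FALSE, xlab = "", ylab = "",
                  main = sprintf("complexity %d", vase$complexity))
  if (!is.null(scanpath)) {
    graphics::lines(scanpath[, "col"] + 1, vase$grid$n_rows - scanpath[, "row"],
                    col = "red", lwd = 1)
  }
  invisible(file)
}
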