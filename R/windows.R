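#' Recognition-window specification
#'
#' Describes the fixed-size rectangular recognition window (RW) that tiles an
#' image, and the scan strides. The default is the non-overlapping 6 x 6
#' square window; overlap is expressed by setting a stride smaller than the
#' window size.
#'
#' @param height,width window size `n_a x n_b` in pixels (default 6 x 6).
#' @param stride_rows,stride_cols scan strides; default equal to the window
#'   size, i.e. non-overlapping.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(height = 6L, width = 6L,
                        stride_rows = height, stride_cols = width) {
  height <- as.integer(height); width <- as.integer(width)
  stride_rows <- as.integer(stride_rows); stride_cols <- as.integer(stride_cols)
  if (height < 1L || width < 1L) stop("window size must be >= 1", call. = FALSE)
  if (stride_rows < 1L || stride_cols < 1L) stop("strides must be >= 1", call. = FALSE)
  structure(list(height = height, width = width,
                 stride_rows = stride_rows, stride_cols = stride_cols),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %d x %d, stride %d x %d%s\n",
              x$height, x$width, x$stride_rows, x$stride_cols,
              if (x$stride_rows == x$height && x$stride_cols == x$width)
                " (non-overlapping)" else ""))
  invisible(x)
}

#' Shape of the recognition-window grid
#'
#' Number of vertical and horizontal window placements for an image of the
#' given size. Partial windows at the right and bottom margins are discarded
#' (never padded), so every window holds exactly `n_a * n_b` pixels. A 48 x 48
#' image scanned by a non-overlapping 6 x 6 window yields an 8 x 8 grid of 64
#' windows.
#'
#' @param img_height,img_width image size in pixels.
#' @param spec a [window_spec()].
#' @return Integer vector `c(rows, cols)`; `c(0, 0)` with a warning when the
#'   window does not fit.
#' @export
window_grid_shape <- function(img_height, img_width, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  if (img_height < spec$height || img_width < spec$width) {
    warning("window larger than image: empty window grid", call. = FALSE)
    return(c(rows = 0L, cols = 0L))
  }
  c(rows = (img_height - spec$height) %/% spec$stride_rows + 1L,
    cols = (img_width - spec$width) %/% spec$stride_cols + 1L)
}

# top-left origins (1-based), row-major order
window_origins <- function(img_height, img_width, spec) {
  g <- window_grid_shape(img_height, img_width, spec)
  if (g[1] == 0L) return(list(grid = g, rows = integer(0), cols = integer(0)))
  list(grid = g,
       rows = seq.int(1L, by = spec$stride_rows, length.out = g[1]),
       cols = seq.int(1L, by = spec$stride_cols, length.out = g[2]))
}

#' Enumerate recognition windows over an image
#'
#' Windows are produced in row-major order (top-to-down, then left-to-right),
#' matching the raster scan of the image. In non-overlapping mode the window
#' blocks are pairwise disjoint and tile the top-left
#' `(rows * n_a) x (cols * n_b)` region.
#'
#' @param img a [gray_image()].
#' @param spec a [window_spec()].
#' @return A list of `window` objects, each with fields `origin` (row, col of
#'   the top-left pixel, 1-based), `block` (the `n_a x n_b` intensity matrix)
#'   and `grid_pos` (row, col in the window grid).
#' @export
enumerate_windows <- function(img, spec = window_spec()) {
  stopifnot(inherits(img, "gray_image"))
  o <- window_origins(img$height, img$width, spec)
  out <- vector("list", as.integer(o$grid[1]) * as.integer(o$grid[2]))
  k <- 0L
  for (wr in seq_along(o$rows)) {
    for (wc in seq_along(o$cols)) {
      k <- k + 1L
      r0 <- o$rows[wr]; c0 <- o$cols[wc]
      out[[k]] <- structure(
        list(origin = c(row = r0, col = c0),
             block = img$pixels[r0:(r0 + spec$height - 1L),
                                c0:(c0 + spec$width - 1L), drop = FALSE],
             grid_pos = c(row = wr, col = wc)),
        class = "rw_window")
    }
  }
  out
}

#' Build the next pyramid level by 2 x 2 mean downsampling
#'
#' Each output pixel is the mean of a disjoint 2 x 2 block of the source,
#' rounded half-up; trailing odd rows/columns are dropped, so the output is
#' `floor(h/2) x floor(w/2)`. The gray-level alphabet `L` is unchanged. Used
#' to produce the first pyramid level `L1` from the base level `L0`; windows
#' are then re-analyzed on the subsampled image with the same recognition
#' window.
#'
#' @param img a [gray_image()] with at least 2 rows and 2 columns.
#' @return A [gray_image()] of half size.
#' @export
build_pyramid_level <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  h2 <- img$height %/% 2L; w2 <- img$width %/% 2L
  if (h2 < 1L || w2 < 1L) {
    stop("image must be at least 2 x 2 to build a pyramid level", call. = FALSE)
  }
  p <- img$pixels
  ri <- seq.int(1L, 2L * h2, by = 2L)
  ci <- seq.int(1L, 2L * w2, by = 2L)
  s <- (p[ri, ci, drop = FALSE] + p[ri + 1L, ci, drop = FALSE] +
        p[ri, ci + 1L, drop = FALSE] + p[ri + 1L, ci + 1L, drop = FALSE]) / 4
  gray_image(round_mat(s), levels = img$levels)
}

#' Image pyramid
#'
#' Level 1 is the native image (`L0`); each further level halves the previous
#' one with [build_pyramid_level()].
#'
#' @param img a [gray_image()].
#' @param levels number of pyramid levels (default 2: `L0` and `L1`).
#' @return A list of [gray_image()]s, one per level.
#' @export
build_pyramid <- function(img, levels = 2L) {
  stopifnot(inherits(img, "gray_image"), levels >= 1L)
  out <- vector("list", levels)
  out[[1]] <- img
  for (k in seq_len(levels - 1L)) out[[k + 1L]] <- build_pyramid_level(out[[k]])
  out
}
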