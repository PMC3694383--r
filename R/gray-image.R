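#' Grayscale image container
#'
#' A `gray_image` is an integer-valued matrix of gray levels together with the
#' size of its gray-level alphabet `L`. Every pixel must lie in `[0, L - 1]`.
#' The matrix is indexed `[row, col]` with the origin at the top-left corner;
#' traversal order throughout the package is row-major (top-to-down, then
#' left-to-right), matching the conventional raster scan.
#'
#' @param pixels integer matrix of gray levels (doubles holding whole numbers
#'   are accepted and stored as integers).
#' @param levels number of gray levels `L` (default 256, i.e. 8-bit).
#' @return An object of class `gray_image` with fields `pixels`, `levels`,
#'   `height` and `width`.
#' @examples
#' img <- gray_image(matrix(0:63, 8, 8), levels = 256)
#' img$height
#' @export
gray_image <- function(pixels, levels = 256L) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L) stop("`levels` must be >= 2", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  v <- as.vector(pixels)
  if (anyNA(v) || any(!is.finite(v))) stop("pixels must be finite", call. = FALSE)
  if (any(v != floor(v))) stop("pixels must be whole numbers", call. = FALSE)
  if (any(v < 0) || any(v > levels - 1L)) {
    stop(sprintf("pixels must lie in [0, %d]", levels - 1L), call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, levels = levels,
         height = nrow(pixels), width = ncol(pixels)),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, L = %d, range [%d, %d]\n",
              x$height, x$width, x$levels,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
as.matrix.gray_image <- function(x, ...) x$pixels

#' Per-pixel class label map
#'
#' A `label_map` pairs with a [gray_image()] of the same size and assigns each
#' pixel an integer class identifier. `NA` is the reserved margin marker used
#' for pixels not covered by any recognition window (see [segment_image()]);
#' it is excluded from error scoring.
#'
#' @param labels integer matrix of class identifiers (`NA` allowed for margin).
#' @param classes vector of valid class identifiers; defaults to the sorted
#'   distinct non-`NA` labels present.
#' @return An object of class `label_map` with fields `labels`, `classes`,
#'   `height` and `width`.
#' @export
label_map <- function(labels, classes = NULL) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  v <- as.vector(labels)
  if (any(!is.na(v) & v != floor(v))) stop("labels must be whole numbers", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (is.null(classes)) classes <- sort(unique(labels[!is.na(labels)]))
  classes <- as.integer(classes)
  bad <- !is.na(labels) & !(labels %in% classes)
  if (any(bad)) stop("labels contain values outside `classes`", call. = FALSE)
  structure(
    list(labels = labels, classes = classes,
         height = nrow(labels), width = ncol(labels)),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d, classes: %s\n", x$height, x$width,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' @export
as.matrix.label_map <- function(x, ...) x$labels

# run expr with a private RNG stream seeded by `seed`; global RNG untouched
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
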