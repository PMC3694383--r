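#' Gray-level histogram of a recognition window
#'
#' `p(i)` is the probability that gray level `i` in `[0, L - 1]` appears
#' within the window: `count(i) / (n_a * n_b)`. The probabilities are
#' non-negative and sum to one.
#'
#' @param window an `rw_window` from [enumerate_windows()], or a plain
#'   integer matrix/vector of gray levels.
#' @param levels number of gray levels `L`.
#' @return An object of class `gray_histogram` with fields `p` (length-`L`
#'   probability vector, index `i + 1` holds `p(i)`) and `levels`.
#' @export
gray_histogram <- function(window, levels = 256L) {
  v <- window_values(window)
  levels <- as.integer(levels)
  if (length(v) == 0L) stop("empty window", call. = FALSE)
  if (any(v < 0L) || any(v > levels - 1L)) {
    stop("window intensities outside [0, levels - 1]", call. = FALSE)
  }
  p <- tabulate(v + 1L, nbins = levels) / length(v)
  structure(list(p = p, levels = levels), class = "gray_histogram")
}

window_values <- function(window) {
  if (inherits(window, "rw_window")) as.vector(window$block)
  else if (inherits(window, "gray_image")) as.vector(window$pixels)
  else if (is.numeric(window)) as.integer(window)
  else stop("`window` must be an rw_window, gray_image or numeric", call. = FALSE)
}

#' Generalized N-order moment of a gray-level histogram
#'
#' `M(n1) = sum_i i^n1 * p(i)`. With `n1 = 1` this is the mean gray level of
#' the window; `n1 = 0` gives 1 (normalization, `0^0 = 1`). The moment mainly
#' measures informative content: background zones show very low `M` values.
#'
#' @param h a [gray_histogram()].
#' @param n1 moment order, a natural number.
#' @return A single numeric value.
#' @export
moment <- function(h, n1 = 1L) {
  stopifnot(inherits(h, "gray_histogram"))
  check_order(n1, "n1", min = 0L)
  i <- seq.int(0L, h$levels - 1L)
  sum(i^n1 * h$p)
}

#' Generalized N-order central moment of a gray-level histogram
#'
#' `C(n2) = sum_i (i - M)^n2 * p(i)`, measuring the amplitude dispersion of
#' the window around its average. By default the centering value `M` is the
#' first-order mean `M(1)`; `center_order` switches to the literal raw moment
#' `M(center_order)` for fidelity experiments with higher-order centering.
#' `C(2)` is the gray-level variance and is zero iff the window is constant.
#'
#' @param h a [gray_histogram()].
#' @param n2 central-moment order, a natural number.
#' @param center_order order of the raw moment used for centering (default 1,
#'   the mean).
#' @return A single numeric value.
#' @export
central_moment <- function(h, n2 = 2L, center_order = 1L) {
  stopifnot(inherits(h, "gray_histogram"))
  check_order(n2, "n2", min = 0L)
  check_order(center_order, "center_order", min = 1L)
  i <- seq.int(0L, h$levels - 1L)
  m <- sum(i^center_order * h$p)
  sum((i - m)^n2 * h$p)
}

check_order <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    stop(sprintf("`%s` must be a whole number >= %d", name, min), call. = FALSE)
  }
  invisible(TRUE)
}
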