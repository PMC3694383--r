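#' Displacements of the discrete circumference of radius d
#'
#' The all-directions displacement set: every offset `(dr, dc)` at Chebyshev
#' distance `d`, i.e. `max(|dr|, |dc|) = d` — the perimeter of the square ring
#' of half-width `d`. There are exactly `8 * d` such offsets (16 at `d = 2`,
#' matching the 16 pixel pairs each circumference contributes), enumerated
#' clockwise from the top-left corner `(-d, -d)`. This replaces the four
#' cardinal directions of the classic co-occurrence construction with all
#' directions at once.
#'
#' @param d ring radius in pixels, `>= 1`.
#' @return An object of class `ring_offsets`: list with `d` and `offsets`
#'   (an `8d x 2` integer matrix of `(dr, dc)` displacements).
#' @examples
#' nrow(ring_offsets(2)$offsets)  # 16
#' @export
ring_offsets <- function(d) {
  d <- as.integer(d)
  if (is.na(d) || d < 1L) stop("`d` must be >= 1", call. = FALSE)
  top    <- cbind(-d, seq.int(-d, d))              # left -> right
  right  <- cbind(seq.int(-d + 1L, d), d)          # top -> bottom
  bottom <- cbind(d, seq.int(d - 1L, -d))          # right -> left
  left   <- cbind(seq.int(d - 1L, -d + 1L), -d)    # bottom -> top
  offs <- rbind(top, right, bottom, left)
  dimnames(offs) <- list(NULL, c("dr", "dc"))
  structure(list(d = d, offsets = offs), class = "ring_offsets")
}

#' All-directions co-occurrence matrix of a recognition window
#'
#' Every pixel of the window is taken as the center of a discrete
#' circumference of radius `d`; each (center, ring partner) pair increments
#' cell `(center value, partner value)` of the `L x L` count matrix. Ring
#' partners may lie outside the window but inside the full image — this is
#' how contextual information around the window enters the statistics.
#' Partners falling outside the image are skipped and the matrix is
#' normalized over the realized pairs, so `sum(p) = 1` also for windows near
#' a border. For a fully interior window the total count is exactly
#' `n_a * n_b * 8d` (a 3 x 3 window at `d = 2` contributes 144 increments).
#'
#' Counts are held sparsely (only realized `(i, j)` cells); use
#' [as.matrix()][as.matrix.cooc_matrix] for the dense `L x L` probability
#' matrix.
#'
#' @param img the full [gray_image()] providing context around the window.
#' @param window an `rw_window` from [enumerate_windows()], or a 1-based
#'   `c(row, col, height, width)` window descriptor.
#' @param d ring radius, `>= 1`.
#' @return An object of class `cooc_matrix`: fields `i`, `j` (0-based gray
#'   levels of the realized cells), `count`, `total`, `p` (cell
#'   probabilities), `d` and `levels`.
#' @export
cooccurrence_matrix <- function(img, window, d) {
  stopifnot(inherits(img, "gray_image"))
  if (inherits(window, "rw_window")) {
    r0 <- window$origin[["row"]]; c0 <- window$origin[["col"]]
    na <- nrow(window$block); nb <- ncol(window$block)
  } else {
    window <- as.integer(window)
    r0 <- window[1]; c0 <- window[2]; na <- window[3]; nb <- window[4]
  }
  if (r0 < 1L || c0 < 1L || r0 + na - 1L > img$height || c0 + nb - 1L > img$width) {
    stop("window does not lie inside the image", call. = FALSE)
  }
  offs <- ring_offsets(d)$offsets
  px <- img$pixels
  H <- img$height; W <- img$width; L <- img$levels
  cr <- rep.int(seq.int(r0, r0 + na - 1L), nb)
  cc <- rep(seq.int(c0, c0 + nb - 1L), each = na)
  ci <- px[cbind(cr, cc)]
  m <- nrow(offs)
  pr <- outer(cr, offs[, 1L], "+")
  pc <- outer(cc, offs[, 2L], "+")
  ok <- pr >= 1L & pr <= H & pc >= 1L & pc <= W
  if (!any(ok)) {
    stop("degenerate co-occurrence matrix: no ring partner lies inside the image",
         call. = FALSE)
  }
  i <- rep.int(ci, m)[ok]
  j <- px[(pc[ok] - 1L) * H + pr[ok]]
  new_cooc(i, j, d = as.integer(d), levels = L)
}

# aggregate ordered (i, j) level pairs into a sparse cooc_matrix
new_cooc <- function(i, j, d, levels) {
  key <- as.double(i) * levels + as.double(j)
  r <- rle(sort(key))
  cells <- r$values
  structure(
    list(i = as.integer(cells %/% levels),
         j = as.integer(cells %% levels),
         count = r$lengths,
         total = length(key),
         p = r$lengths / length(key),
         d = d, levels = as.integer(levels)),
    class = "cooc_matrix")
}

#' Build a co-occurrence matrix from an explicit count matrix
#'
#' Convenience constructor for crafted distributions (closed-form checks,
#' examples): row index `i + 1`, column index `j + 1` hold the count of the
#' ordered gray-level pair `(i, j)`.
#'
#' @param counts square non-negative matrix of pair counts.
#' @param d nominal ring radius recorded on the object.
#' @return A `cooc_matrix`.
#' @export
cooccurrence_from_counts <- function(counts, d = 1L) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts))
  if (any(counts < 0) || sum(counts) <= 0) {
    stop("`counts` must be non-negative with positive total", call. = FALSE)
  }
  L <- nrow(counts)
  nz <- which(counts > 0, arr.ind = TRUE)
  cnt <- counts[nz]
  ord <- order((nz[, 1] - 1) * L + (nz[, 2] - 1))
  structure(
    list(i = as.integer(nz[ord, 1] - 1L), j = as.integer(nz[ord, 2] - 1L),
         count = cnt[ord], total = sum(cnt), p = cnt[ord] / sum(cnt),
         d = as.integer(d), levels = L),
    class = "cooc_matrix")
}

#' @export
print.cooc_matrix <- function(x, ...) {
  cat(sprintf("<cooc_matrix> L = %d, d = %d, %d realized cells, %d pairs\n",
              x$levels, x$d, length(x$i), x$total))
  invisible(x)
}

#' Dense probability matrix of a co-occurrence matrix
#'
#' @param x a `cooc_matrix`.
#' @param what `"p"` for probabilities (default) or `"count"` for raw counts.
#' @param ... unused.
#' @return An `L x L` matrix; entry `[i + 1, j + 1]` is `p_d(i, j)`.
#' @export
as.matrix.cooc_matrix <- function(x, what = c("p", "count"), ...) {
  what <- match.arg(what)
  m <- matrix(0, x$levels, x$levels)
  m[cbind(x$i + 1L, x$j + 1L)] <- x[[what]]
  m
}

#' Marginal statistics of a co-occurrence matrix
#'
#' Means and standard deviations of the two pair members,
#' `mu_x = sum i p(i,j)`, `sigma_x = sqrt(sum (i - mu_x)^2 p(i,j))` (and
#' likewise for `j`), plus the gray-level difference distribution
#' `p_{x-y}(k) = sum_{|i-j|=k} p(i,j)^q` over `k` in `[0, L - 1]`. With the
#' default exponent `q = 1`, `p_{x-y}` sums to one.
#'
#' @param cm a `cooc_matrix`.
#' @param q exponent applied to each cell probability before aggregation into
#'   `p_{x-y}` (default 1).
#' @return An object of class `cooc_marginals` with fields `mu_x`, `mu_y`,
#'   `sigma_x`, `sigma_y`, `p_diff` (length-`L` vector, index `k + 1`) and `q`.
#' @export
marginals <- function(cm, q = 1L) {
  stopifnot(inherits(cm, "cooc_matrix"))
  check_order(q, "q", min = 1L)
  p <- cm$p
  mu_x <- sum(cm$i * p); mu_y <- sum(cm$j * p)
  sigma_x <- sqrt(sum((cm$i - mu_x)^2 * p))
  sigma_y <- sqrt(sum((cm$j - mu_y)^2 * p))
  k <- abs(cm$i - cm$j)
  p_diff <- numeric(cm$levels)
  agg <- rowsum(p^q, k)
  p_diff[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  structure(list(mu_x = mu_x, mu_y = mu_y,
                 sigma_x = sigma_x, sigma_y = sigma_y,
                 p_diff = p_diff, q = as.integer(q), levels = cm$levels),
            class = "cooc_marginals")
}
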