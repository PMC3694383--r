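#' Generalized homogeneity
#'
#' `HG(d)(n3) = sum_{i,j} p_d(i,j)^n3`. High on uniform zones, low on
#' disconnected zones or zones mixing several textures. `n3 = 1` always gives
#' 1 (normalization); for `n3 >= 2` the value is maximal (= 1) iff all mass
#' sits in a single cell, and equals `1/m` for uniform mass over `m` cells at
#' `n3 = 2`.
#'
#' @param cm a `cooc_matrix` from [cooccurrence_matrix()].
#' @param n3 exponent, a natural number `>= 1`.
#' @return A single numeric value.
#' @export
homogeneity <- function(cm, n3 = 2L) {
  stopifnot(inherits(cm, "cooc_matrix")); check_order(n3, "n3")
  sum(cm$p^n3)
}

#' Generalized contrast
#'
#' `CT(d)(n4, n5) = sum_{i,j} |i - j|^n4 * p_d(i,j)^n5`. Approximately zero
#' on zones of near-constant intensity (exactly zero when all mass is on the
#' diagonal) and high where pixel intensities vary strongly across distance
#' `d`.
#'
#' @param cm a `cooc_matrix`.
#' @param n4,n5 exponents, natural numbers `>= 1`.
#' @return A single numeric value.
#' @export
contrast <- function(cm, n4 = 2L, n5 = 1L) {
  stopifnot(inherits(cm, "cooc_matrix"))
  check_order(n4, "n4"); check_order(n5, "n5")
  sum(abs(cm$i - cm$j)^n4 * cm$p^n5)
}

#' Generalized inverse difference
#'
#' `ID(d)(n6, n7) = sum_{i,j} p_d(i,j)^n6 / (1 + (i - j)^n7)`. Sensitive to
#' fine local structure (microtexture): mass near the diagonal is weighted
#' most. For odd `n7` the printed denominator `1 + (i-j)^n7` vanishes at
#' `i - j = -1`; the implementation therefore substitutes `|i - j|^n7` for
#' odd `n7` (the even case is computed exactly as written, where the two
#' forms coincide).
#'
#' @param cm a `cooc_matrix`.
#' @param n6,n7 exponents, natural numbers `>= 1`.
#' @return A single numeric value.
#' @export
inverse_difference <- function(cm, n6 = 1L, n7 = 2L) {
  stopifnot(inherits(cm, "cooc_matrix"))
  check_order(n6, "n6"); check_order(n7, "n7")
  dd <- if (n7 %% 2L == 0L) (cm$i - cm$j)^n7 else abs(cm$i - cm$j)^n7
  sum(cm$p^n6 / (1 + dd))
}

#' Generalized co-occurrence entropy
#'
#' `ET(d)(n8, n9) = -sum_{i,j} p_d(i,j)^n8 * (log_k1 p_d(i,j))^n9`.
#' Proportional to the randomness of the zone; zero for a constant window and
#' `log_k1(m)` for uniform mass over `m` cells at `n8 = n9 = 1`. Cells with
#' `p = 0` contribute nothing. The sign convention is exactly the printed
#' leading minus: for even `n9` the result is non-positive.
#'
#' @param cm a `cooc_matrix`.
#' @param n8,n9 exponents, natural numbers `>= 1`.
#' @param k1 logarithm base, `>= 2`.
#' @return A single numeric value.
#' @export
entropy <- function(cm, n8 = 1L, n9 = 1L, k1 = 2L) {
  stopifnot(inherits(cm, "cooc_matrix"))
  check_order(n8, "n8"); check_order(n9, "n9"); check_order(k1, "k1", min = 2L)
  p <- cm$p[cm$p > 0]
  -sum(p^n8 * (log(p, base = k1))^n9)
}

#' Generalized co-occurrence correlation
#'
#' `CR(d)(n10, n11) = sum_{i,j} (i - mu_x)(i - mu_y) p_d(i,j)^n10 /
#' (sigma_x sigma_y)^n11` in the `"as_printed"` variant. The `"haralick"`
#' variant uses the standard cross-moment `(i - mu_x)(j - mu_y)` instead.
#' The two differ in sign structure: for mass at `p(0,1) = p(1,0) = 1/2`
#' the haralick variant gives -1 and the as-printed variant +1. Used to
#' identify spatial constraints among windows composing the same pattern.
#'
#' When the window is constant, `sigma_x * sigma_y = 0` and the value is the
#' sentinel 0 with attribute `degenerate = TRUE`, so feature maps remain
#' total over background windows.
#'
#' @param cm a `cooc_matrix`.
#' @param m the [marginals()] of `cm` (computed if missing).
#' @param n10,n11 exponents, natural numbers `>= 1`.
#' @param variant `"as_printed"` (default) or `"haralick"`.
#' @return A single numeric value, with attribute `degenerate` set to `TRUE`
#'   when the variance vanished.
#' @export
correlation <- function(cm, m = marginals(cm), n10 = 1L, n11 = 1L,
                        variant = c("as_printed", "haralick")) {
  stopifnot(inherits(cm, "cooc_matrix"), inherits(m, "cooc_marginals"))
  check_order(n10, "n10"); check_order(n11, "n11")
  variant <- match.arg(variant)
  denom <- (m$sigma_x * m$sigma_y)^n11
  if (denom == 0) return(structure(0, degenerate = TRUE))
  second <- if (variant == "haralick") cm$j - m$mu_y else cm$i - m$mu_y
  sum((cm$i - m$mu_x) * second * cm$p^n10) / denom
}

#' Generalized difference entropy
#'
#' `DE(d)(n12, n13) = -sum_k p_{x-y}(k)^n12 * (log_k2 p_{x-y}(k))^n13` over
#' the gray-level difference distribution of [marginals()]. Zero-probability
#' terms contribute nothing; the printed leading minus is kept, so even `n13`
#' yields non-positive values. Used to characterize spatial constraints
#' between different textural patterns.
#'
#' @param m a `cooc_marginals`.
#' @param n12,n13 exponents, natural numbers `>= 1`.
#' @param k2 logarithm base, `>= 2`.
#' @return A single numeric value.
#' @export
difference_entropy <- function(m, n12 = 2L, n13 = 2L, k2 = 2L) {
  stopifnot(inherits(m, "cooc_marginals"))
  check_order(n12, "n12"); check_order(n13, "n13"); check_order(k2, "k2", min = 2L)
  p <- m$p_diff[m$p_diff > 0]
  -sum(p^n12 * (log(p, base = k2))^n13)
}
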