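#' Operator specification
#'
#' Bundles an operator identity with its exponent/base/radius parameters.
#' Recognized names and their parameters:
#' \describe{
#'   \item{`M`}{N-order moment; `n1`.}
#'   \item{`C`}{N-order central moment; `n2`, optional `center_order`.}
#'   \item{`HG`}{homogeneity; `n3`, `d`.}
#'   \item{`CT`}{contrast; `n4`, `n5`, `d`.}
#'   \item{`ID`}{inverse difference; `n6`, `n7`, `d`.}
#'   \item{`ET`}{entropy; `n8`, `n9`, `k1`, `d`.}
#'   \item{`CR`}{correlation; `n10`, `n11`, `d`, optional `variant`.}
#'   \item{`DE`}{difference entropy; `n12`, `n13`, `k2`, `d`, optional `q`.}
#' }
#' All exponents are natural numbers; log bases `k1`, `k2` are `>= 2`; the
#' ring radius `d` applies to second-order operators only.
#'
#' @param name operator name, one of `M`, `C`, `HG`, `CT`, `ID`, `ET`, `CR`,
#'   `DE`.
#' @param ... named parameters (see above). Unspecified parameters take the
#'   defaults of the corresponding operator function.
#' @return An object of class `operator_spec` with fields `name`, `params`,
#'   `d` and `label` (a compact display string such as `"HG(d=2,n3=2)"`).
#' @export
op_spec <- function(name, ...) {
  name <- match.arg(name, c("M", "C", "HG", "CT", "ID", "ET", "CR", "DE"))
  params <- list(...)
  defaults <- switch(name,
    M  = list(n1 = 1L),
    C  = list(n2 = 2L, center_order = 1L),
    HG = list(n3 = 2L, d = 2L),
    CT = list(n4 = 2L, n5 = 1L, d = 2L),
    ID = list(n6 = 1L, n7 = 2L, d = 2L),
    ET = list(n8 = 1L, n9 = 1L, k1 = 2L, d = 2L),
    CR = list(n10 = 1L, n11 = 1L, d = 2L, variant = "as_printed"),
    DE = list(n12 = 2L, n13 = 2L, k2 = 2L, d = 2L, q = 1L))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown parameter(s) for %s: %s", name,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  defaults[names(params)] <- params
  for (nm in names(defaults)) {
    if (!is.character(defaults[[nm]])) {
      check_order(defaults[[nm]], nm, min = if (nm %in% c("k1", "k2")) 2L else 1L)
      defaults[[nm]] <- as.integer(defaults[[nm]])
    }
  }
  d <- defaults$d
  shown <- defaults[setdiff(names(defaults), c("variant", "center_order"))]
  shown <- shown[order(match(names(shown), c("d", setdiff(names(shown), "d"))))]
  label <- sprintf("%s(%s)", name,
                   paste(sprintf("%s=%s", names(shown), unlist(shown)), collapse = ","))
  structure(list(name = name, params = defaults, d = d, label = label),
            class = "operator_spec")
}

#' @export
print.operator_spec <- function(x, ...) {
  cat("<operator_spec>", x$label, "\n")
  invisible(x)
}

# evaluate one operator given precomputed window context
eval_operator <- function(op, hist = NULL, cm = NULL, marg = NULL) {
  p <- op$params
  v <- switch(op$name,
    M  = moment(hist, p$n1),
    C  = central_moment(hist, p$n2, center_order = p$center_order),
    HG = homogeneity(cm, p$n3),
    CT = contrast(cm, p$n4, p$n5),
    ID = inverse_difference(cm, p$n6, p$n7),
    ET = entropy(cm, p$n8, p$n9, p$k1),
    CR = correlation(cm, marg, p$n10, p$n11, variant = p$variant),
    DE = difference_entropy(marg, p$n12, p$n13, p$k2))
  as.numeric(v)
}

is_second_order <- function(op) !(op$name %in% c("M", "C"))

#' Pairwise operator dependence table
#'
#' The empirical dependence level between every pair of the eight operators,
#' on a 1 (low) to 4 (high) scale, derived from their joint behavior under
#' the segmentation task. `M` and `C` are maximally dependent (4), as are
#' `HG`/`CT`, `ID`/`ET` and `CR`/`DE`. The table is symmetric; the diagonal
#' is `NA` (self-dependence is not defined here). Used as voting weights by
#' [classify_window()].
#'
#' @return An 8 x 8 integer matrix with dimnames
#'   `M, C, HG, CT, ID, ET, CR, DE` and `NA` diagonal.
#' @export
dependence_table <- function() {
  ops <- c("M", "C", "HG", "CT", "ID", "ET", "CR", "DE")
  m <- matrix(c(
    NA, 4, 3, 3, 2, 2, 1, 2,
    4, NA, 2, 3, 2, 3, 2, 2,
    3, 2, NA, 4, 3, 3, 1, 1,
    3, 3, 4, NA, 3, 2, 2, 2,
    2, 2, 3, 3, NA, 4, 3, 2,
    2, 3, 3, 2, 4, NA, 3, 3,
    1, 2, 1, 2, 3, 3, NA, 4,
    2, 2, 1, 2, 2, 3, 4, NA), 8, 8, byrow = TRUE,
    dimnames = list(ops, ops))
  storage.mode(m) <- "integer"
  m
}

#' Body-region parameter presets
#'
#' Parameter grids for the four tuned body regions (brain, heart, liver,
#' bone): for each operator, the set of exponent/base/radius values found to
#' span the useful range under the segmentation task. Shipped as YAML files
#' under `inst/extdata/presets/`.
#'
#' @param region `"brain"`, `"heart"`, `"liver"` or `"bone"`.
#' @return A named list: per operator name, a named list of candidate value
#'   vectors.
#' @export
texture_preset <- function(region = c("brain", "heart", "liver", "bone")) {
  region <- match.arg(region)
  path <- system.file("extdata", "presets", paste0(region, ".yaml"),
                      package = "mritex", mustWork = TRUE)
  yaml::read_yaml(path)
}

#' Default operator set for a body region
#'
#' One [op_spec()] per operator, using the lead value of each parameter in
#' the region's preset grid, except that the ring radius prefers `d = 2`
#' when the grid allows it (the radius most broadly useful across regions).
#'
#' @param region body region preset name (default `"brain"`).
#' @return A list of eight `operator_spec` objects.
#' @export
default_operator_set <- function(region = "brain") {
  grid <- texture_preset(region)
  lapply(names(grid), function(nm) {
    g <- grid[[nm]]
    pick <- lapply(names(g), function(pn) {
      v <- g[[pn]]
      if (pn == "d" && 2L %in% v) 2L else v[[1]]
    })
    names(pick) <- names(g)
    do.call(op_spec, c(list(name = nm), pick))
  })
}

#' Build an operator set from a plain list (YAML/JSON friendly)
#'
#' Each entry must have a `name` plus any [op_spec()] parameters, e.g.
#' `list(list(name = "HG", n3 = 2, d = 2))`.
#'
#' @param x a list of parameter lists.
#' @return A list of `operator_spec` objects.
#' @export
operator_set_from_list <- function(x) {
  lapply(x, function(e) {
    stopifnot(!is.null(e$name))
    do.call(op_spec, e)
  })
}

operator_set_to_list <- function(ops) {
  lapply(ops, function(op) c(list(name = op$name), op$params))
}
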