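# ---- fast per-window evaluation engine ----------------------------------
#
# Second-order operators at radius d need, per window, the co-occurrence
# pairs of every window pixel with its square-ring partners taken from the
# FULL image. The engine precomputes, once per image and radius, the key
# i*L + j of every (pixel, offset) pair (NA where the partner falls outside
# the image); a window's matrix is then a gather + run-length count.

cooc_from_keys <- function(key, d, levels) {
  r <- rle(sort(key))
  cells <- r$values
  structure(
    list(i = as.integer(cells %/% levels),
         j = as.integer(cells %% levels),
         count = r$lengths,
         total = length(key),
         p = r$lengths / length(key),
         d = as.integer(d), levels = as.integer(levels)),
    class = "cooc_matrix")
}

pair_key_matrix <- function(img, d) {
  px <- img$pixels
  H <- img$height; W <- img$width; L <- img$levels
  offs <- ring_offsets(d)$offsets
  K <- matrix(NA_real_, H * W, nrow(offs))
  for (m in seq_len(nrow(offs))) {
    dr <- offs[m, 1L]; dc <- offs[m, 2L]
    rs <- max(1L, 1L - dr):min(H, H - dr)
    cs <- max(1L, 1L - dc):min(W, W - dc)
    if (length(rs) < 1L || length(cs) < 1L) next
    lin <- rep((cs - 1L) * H, each = length(rs)) + rs
    K[lin, m] <- as.double(px[lin]) * L +
      as.double(px[rep((cs + dc - 1L) * H, each = length(rs)) + (rs + dr)])
  }
  K
}

# values: n_windows x n_ops matrix (row-major window order); grid: c(rows, cols)
window_feature_matrix <- function(img, ops, wspec) {
  stopifnot(inherits(img, "gray_image"))
  o <- window_origins(img$height, img$width, wspec)
  if (o$grid[1] == 0L) {
    stop("window grid is empty: window larger than image", call. = FALSE)
  }
  H <- img$height
  na <- wspec$height; nb <- wspec$width
  second <- vapply(ops, is_second_order, logical(1))
  need_hist <- any(!second)
  ds <- sort(unique(vapply(ops[second], function(op) op$d, integer(1))))
  keys <- lapply(ds, function(d) pair_key_matrix(img, d))
  names(keys) <- as.character(ds)
  # (d, q) pairs for which marginals are needed
  marg_need <- unique(do.call(rbind, lapply(ops, function(op) {
    if (op$name == "CR") c(op$d, 1L)
    else if (op$name == "DE") c(op$d, op$params$q)
    else NULL
  })))
  nwin <- as.integer(o$grid[1]) * as.integer(o$grid[2])
  vals <- matrix(NA_real_, nwin, length(ops))
  colnames(vals) <- vapply(ops, function(op) op$label, character(1))
  roff <- 0L:(na - 1L)
  k <- 0L
  for (wr in seq_along(o$rows)) {
    for (wc in seq_along(o$cols)) {
      k <- k + 1L
      r0 <- o$rows[wr]; c0 <- o$cols[wc]
      idx <- rep((c0 - 1L + 0L:(nb - 1L)) * H, each = na) + (r0 + roff)
      hist <- if (need_hist) gray_histogram(img$pixels[idx], img$levels) else NULL
      cms <- list(); margs <- list()
      for (d in ds) {
        kk <- keys[[as.character(d)]][idx, ]
        kk <- kk[!is.na(kk)]
        if (length(kk) == 0L) {
          stop("degenerate co-occurrence matrix: no ring partner lies inside the image",
               call. = FALSE)
        }
        cms[[as.character(d)]] <- cooc_from_keys(kk, d, img$levels)
      }
      if (!is.null(marg_need)) {
        for (r in seq_len(nrow(marg_need))) {
          key <- paste(marg_need[r, 1], marg_need[r, 2], sep = "_")
          margs[[key]] <- marginals(cms[[as.character(marg_need[r, 1])]],
                                    q = marg_need[r, 2])
        }
      }
      for (oi in seq_along(ops)) {
        op <- ops[[oi]]
        mg <- if (op$name == "CR") margs[[paste(op$d, 1L, sep = "_")]]
              else if (op$name == "DE") margs[[paste(op$d, op$params$q, sep = "_")]]
              else NULL
        vals[k, oi] <- eval_operator(op, hist = hist,
                                     cm = cms[[as.character(op$d)]], marg = mg)
      }
    }
  }
  list(values = vals, grid = o$grid, rows = o$rows, cols = o$cols)
}

# ---- public feature-map API ----------------------------------------------

#' Compute the feature map of one operator over an image
#'
#' Applies the operator to every recognition window in row-major order,
#' yielding one value per window — a subsampled "image" of operator
#' responses (a 48 x 48 image under a non-overlapping 6 x 6 window gives an
#' 8 x 8 map). First-order operators consume only the window's pixels;
#' second-order operators additionally read ring context from the full
#' image around the window.
#'
#' @param img a [gray_image()].
#' @param op an [op_spec()].
#' @param spec a [window_spec()].
#' @param level pyramid level index recorded on the map (0 = native).
#' @return An object of class `feature_map`: fields `values` (rows x cols
#'   numeric matrix, one cell per window), `operator`, `source_shape`,
#'   `window` and `level`.
#' @export
compute_feature_map <- function(img, op, spec = window_spec(), level = 0L) {
  stopifnot(inherits(op, "operator_spec"))
  wm <- window_feature_matrix(img, list(op), spec)
  new_feature_map(matrix(wm$values[, 1L], wm$grid[1], wm$grid[2], byrow = TRUE),
                  op, img, spec, level)
}

new_feature_map <- function(values, op, img, spec, level) {
  structure(list(values = values, operator = op,
                 source_shape = c(height = img$height, width = img$width),
                 window = spec, level = as.integer(level)),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map> %s, %d x %d (from %d x %d, level %d)\n",
              x$operator$label, nrow(x$values), ncol(x$values),
              x$source_shape[1], x$source_shape[2], x$level))
  invisible(x)
}

#' Rescale a feature map to integer gray levels
#'
#' Linear min-max rescaling of the map values to `[0, L - 1]`, rounded
#' half-up, so the map becomes an exportable [gray_image()]. A constant map
#' (degenerate range) becomes all zeros.
#'
#' @param fm a [compute_feature_map()] result.
#' @param levels target gray-level count `L` (default 256).
#' @return A [gray_image()] the size of the map.
#' @export
scale_to_levels <- function(fm, levels = 256L) {
  stopifnot(inherits(fm, "feature_map"))
  v <- fm$values
  if (any(!is.finite(v))) stop("feature map contains non-finite values", call. = FALSE)
  lo <- min(v); hi <- max(v)
  out <- if (hi == lo) matrix(0L, nrow(v), ncol(v))
         else round_mat((v - lo) / (hi - lo) * (levels - 1))
  gray_image(out, levels = levels)
}

#' Build a feature space over images, operators and pyramid levels
#'
#' One [feature map][compute_feature_map] per (image, operator, pyramid
#' level), with deterministic ordering. Level `k > 0` is the image
#' downsampled `k` times with [build_pyramid_level()], re-analyzed with the
#' same recognition window.
#'
#' @param imgs a list of [gray_image()]s (names are used as image ids;
#'   unnamed lists get ids `img1`, `img2`, ...).
#' @param ops a list of [op_spec()]s.
#' @param spec a [window_spec()].
#' @param levels number of pyramid levels (default 2).
#' @return An object of class `feature_space`: `maps[[image]][[level]]` holds
#'   `grid` plus a windows x operators value matrix; `get_feature_map()`
#'   extracts a single `feature_map`.
#' @export
build_feature_space <- function(imgs, ops, spec = window_spec(), levels = 2L) {
  if (length(imgs) == 0L) stop("`imgs` must be non-empty", call. = FALSE)
  if (length(ops) == 0L) stop("`ops` must be non-empty", call. = FALSE)
  if (inherits(imgs, "gray_image")) imgs <- list(imgs)
  ids <- names(imgs)
  if (is.null(ids) || any(ids == "")) ids <- paste0("img", seq_along(imgs))
  maps <- vector("list", length(imgs)); names(maps) <- ids
  for (ii in seq_along(imgs)) {
    pyr <- build_pyramid(imgs[[ii]], levels)
    per_level <- vector("list", levels)
    for (lv in seq_len(levels)) {
      wm <- tryCatch(window_feature_matrix(pyr[[lv]], ops, spec),
                     error = function(e) {
                       stop(sprintf("image '%s', level %d: %s",
                                    ids[ii], lv - 1L, conditionMessage(e)),
                            call. = FALSE)
                     })
      wm$source_shape <- c(pyr[[lv]]$height, pyr[[lv]]$width)
      per_level[[lv]] <- wm
    }
    names(per_level) <- paste0("L", seq_len(levels) - 1L)
    maps[[ii]] <- per_level
  }
  structure(list(maps = maps, images = ids, ops = ops,
                 window = spec, levels = as.integer(levels)),
            class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("<feature_space> %d image(s) x %d operator(s) x %d level(s)\n",
              length(x$images), length(x$ops), x$levels))
  invisible(x)
}

#' Extract one feature map from a feature space
#'
#' @param fs a [build_feature_space()] result.
#' @param image image id or index.
#' @param op operator label, name or index into the space's operator list.
#' @param level pyramid level index (0 = native).
#' @return A `feature_map`.
#' @export
get_feature_map <- function(fs, image = 1L, op = 1L, level = 0L) {
  stopifnot(inherits(fs, "feature_space"))
  lv <- fs$maps[[image]][[paste0("L", level)]]
  if (is.null(lv)) stop("no such image/level in feature space", call. = FALSE)
  labels <- vapply(fs$ops, function(o) o$label, character(1))
  oi <- if (is.numeric(op)) as.integer(op)
        else if (op %in% labels) match(op, labels)
        else match(op, vapply(fs$ops, function(o) o$name, character(1)))
  if (is.na(oi)) stop("no such operator in feature space", call. = FALSE)
  img_stub <- list(height = lv$source_shape[1], width = lv$source_shape[2])
  new_feature_map(matrix(lv$values[, oi], lv$grid[1], lv$grid[2], byrow = TRUE),
                  fs$ops[[oi]], img_stub, fs$window, level)
}
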