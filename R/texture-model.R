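# ---- window labelling helpers --------------------------------------------

# nearest-neighbor label downsampling (top-left of each 2x2 block), `times` halvings
downsample_labels <- function(labels, times) {
  for (k in seq_len(times)) {
    h2 <- nrow(labels) %/% 2L; w2 <- ncol(labels) %/% 2L
    labels <- labels[seq.int(1L, 2L * h2, 2L), seq.int(1L, 2L * w2, 2L), drop = FALSE]
  }
  labels
}

# majority class per window, row-major; ties or all-NA -> NA (excluded)
window_majority_classes <- function(labels, wspec, grid, rows, cols) {
  na <- wspec$height; nb <- wspec$width
  out <- integer(as.integer(grid[1]) * as.integer(grid[2]))
  k <- 0L
  for (wr in seq_along(rows)) {
    for (wc in seq_along(cols)) {
      k <- k + 1L
      blk <- labels[rows[wr]:(rows[wr] + na - 1L), cols[wc]:(cols[wc] + nb - 1L)]
      v <- blk[!is.na(blk)]
      if (length(v) == 0L) { out[k] <- NA_integer_; next }
      tab <- table(v)
      top <- tab[tab == max(tab)]
      out[k] <- if (length(top) > 1L) NA_integer_ else as.integer(names(top))
    }
  }
  out
}

col_metadata <- function(ops, levels) {
  data.frame(
    op = rep(seq_along(ops), times = levels),
    level = rep(seq_len(levels) - 1L, each = length(ops)),
    name = rep(vapply(ops, function(o) o$name, character(1)), times = levels),
    key = paste0(rep(vapply(ops, function(o) o$label, character(1)), times = levels),
                 "@L", rep(seq_len(levels) - 1L, each = length(ops))),
    stringsAsFactors = FALSE)
}

# ---- model fitting --------------------------------------------------------

#' Fit the supervised interval texture model
#'
#' For every (class, operator, pyramid level), the model records the numeric
#' interval `[q-quantile, (1 - q)-quantile]` of that operator's feature
#' values over the training windows of that class. Window class is the
#' majority pixel label of the window's block (ties exclude the window);
#' level-`k` windows are labelled on the correspondingly downsampled label
#' map. The set of intervals is the mathematical model of the task: at
#' classification time a window votes for the classes whose intervals it
#' falls into, weighted by operator dependence (see [classify_window()]).
#'
#' @param space a [build_feature_space()] over the training images.
#' @param labels a [label_map()] or list of label maps, parallel to the
#'   space's images.
#' @param classes class identifiers to model; defaults to all classes
#'   observed among training windows.
#' @param quantile tail fraction `q` trimmed from each side of the training
#'   distribution (default 0.01; use 0 for exact min/max intervals).
#' @return An object of class `texture_model`: fields `classes`, `ops`,
#'   `window`, `levels`, `quantile`, `columns` (feature-column metadata) and
#'   `intervals` (per class, a `2 x n_columns` low/high matrix).
#' @export
fit_interval_model <- function(space, labels, classes = NULL, quantile = 0.01) {
  stopifnot(inherits(space, "feature_space"))
  if (inherits(labels, "label_map")) labels <- list(labels)
  if (length(labels) != length(space$images)) {
    stop("`labels` must supply one label map per image in the space", call. = FALSE)
  }
  if (quantile < 0 || quantile >= 0.5) stop("`quantile` must be in [0, 0.5)", call. = FALSE)
  cols <- col_metadata(space$ops, space$levels)
  nops <- length(space$ops)
  # pooled training rows per level: features + window class
  feats <- vector("list", space$levels)
  wclass <- vector("list", space$levels)
  for (ii in seq_along(space$images)) {
    lm <- labels[[ii]]
    stopifnot(inherits(lm, "label_map"))
    for (lv in seq_len(space$levels)) {
      wm <- space$maps[[ii]][[lv]]
      lab_lv <- downsample_labels(lm$labels, lv - 1L)
      wo <- window_origins(nrow(lab_lv), ncol(lab_lv), space$window)
      if (any(wo$grid != wm$grid)) {
        stop(sprintf("label map for image '%s' does not match its image size",
                     space$images[ii]), call. = FALSE)
      }
      cl <- window_majority_classes(lab_lv, space$window, wo$grid, wo$rows, wo$cols)
      feats[[lv]] <- rbind(feats[[lv]], wm$values)
      wclass[[lv]] <- c(wclass[[lv]], cl)
    }
  }
  if (is.null(classes)) classes <- sort(unique(unlist(wclass)))
  classes <- as.integer(classes[!is.na(classes)])
  intervals <- lapply(classes, function(cl) {
    m <- matrix(NA_real_, 2L, nrow(cols),
                dimnames = list(c("low", "high"), cols$key))
    for (lv in seq_len(space$levels)) {
      sel <- which(!is.na(wclass[[lv]]) & wclass[[lv]] == cl)
      if (length(sel) == 0L) {
        stop(sprintf("class %d has no training windows at level %d", cl, lv - 1L),
             call. = FALSE)
      }
      ci <- which(cols$level == lv - 1L)
      for (jj in seq_along(ci)) {
        x <- feats[[lv]][sel, jj]
        m[, ci[jj]] <- stats::quantile(x, c(quantile, 1 - quantile),
                                       names = FALSE, type = 7)
      }
    }
    m
  })
  names(intervals) <- as.character(classes)
  structure(list(classes = classes, ops = space$ops, window = space$window,
                 levels = space$levels, quantile = quantile,
                 columns = cols, intervals = intervals),
            class = "texture_model")
}

#' @export
print.texture_model <- function(x, ...) {
  cat(sprintf("<texture_model> %d class(es), %d operator(s), %d level(s), q = %g\n",
              length(x$classes), length(x$ops), x$levels, x$quantile))
  invisible(x)
}

# ---- classification -------------------------------------------------------

# dependence matrix over feature columns: same operator name (e.g. across
# levels) -> 4; distinct names -> tabled value; diagonal 0 so the quadratic
# form sums dependence over *other* matched columns only.
column_dependence <- function(cols, dep) {
  D <- matrix(0, nrow(cols), nrow(cols))
  for (a in seq_len(nrow(cols))) {
    for (b in seq_len(nrow(cols))) {
      if (a == b) next
      D[a, b] <- if (cols$name[a] == cols$name[b]) 4
                 else dep[cols$name[a], cols$name[b]]
    }
  }
  D
}

# F: n x ncol feature matrix -> integer class per row
classify_matrix <- function(F, model, dep = dependence_table()) {
  D <- column_dependence(model$columns, dep)
  scores <- matrix(0, nrow(F), length(model$classes))
  for (ci in seq_along(model$classes)) {
    iv <- model$intervals[[ci]]
    Mm <- sweep(F, 2, iv["low", ], ">=") & sweep(F, 2, iv["high", ], "<=")
    Mm[is.na(Mm)] <- FALSE
    storage.mode(Mm) <- "double"
    nmatch <- rowSums(Mm)
    quad <- rowSums((Mm %*% D) * Mm)
    scores[, ci] <- nmatch + quad / pmax(nmatch - 1, 1)
  }
  model$classes[max.col(scores, ties.method = "first")]
}

#' Classify one window's feature vector
#'
#' A window scores each class by the dependence-weighted number of operators
#' whose value falls inside that class's interval: each matching operator
#' contributes `1 + mean(dependence to the other matching operators)`, with
#' dependence taken from [dependence_table()] (operators of the same name on
#' different pyramid levels count as maximally dependent, 4). The class with
#' the highest score wins; ties break deterministically towards the earliest
#' class in the model's class order. The score is a sum over matched
#' operators, so permuting operator order never changes the result.
#'
#' @param features numeric vector of feature values, one per model column
#'   (in column order, or named by column key).
#' @param model a [fit_interval_model()] result.
#' @param dep dependence table (default [dependence_table()]).
#' @return A single class identifier from `model$classes`.
#' @export
classify_window <- function(features, model, dep = dependence_table()) {
  stopifnot(inherits(model, "texture_model"))
  keys <- model$columns$key
  if (!is.null(names(features))) {
    if (!all(keys %in% names(features))) {
      stop("`features` must cover every model column", call. = FALSE)
    }
    features <- features[keys]
  } else if (length(features) != length(keys)) {
    stop("`features` must cover every model column", call. = FALSE)
  }
  classify_matrix(matrix(as.numeric(features), nrow = 1L), model, dep)
}

# combined L0-window feature matrix across pyramid levels: the level-k value
# of an L0 window is taken from the level-k window containing its halved
# center pixel (clamped at margins)
combined_feature_matrix <- function(img, model) {
  pyr <- build_pyramid(img, model$levels)
  wspec <- model$window
  wms <- lapply(pyr, function(im) window_feature_matrix(im, model$ops, wspec))
  base <- wms[[1L]]
  nwin <- nrow(base$values)
  nops <- length(model$ops)
  F <- matrix(NA_real_, nwin, nrow(model$columns))
  colnames(F) <- model$columns$key
  F[, model$columns$level == 0L] <- base$values
  if (model$levels > 1L) {
    # row-major window center coordinates at level 0
    ctr_r <- rep(base$rows + wspec$height %/% 2L, each = length(base$cols))
    ctr_c <- rep(base$cols + wspec$width %/% 2L, times = length(base$rows))
    for (lv in 2L:model$levels) {
      wm <- wms[[lv]]
      rk <- ceiling(ctr_r / 2^(lv - 1L))
      ck <- ceiling(ctr_c / 2^(lv - 1L))
      wr <- pmin(pmax((rk - 1L) %/% wspec$stride_rows + 1L, 1L), wm$grid[1])
      wc <- pmin(pmax((ck - 1L) %/% wspec$stride_cols + 1L, 1L), wm$grid[2])
      rowidx <- (wr - 1L) * as.integer(wm$grid[2]) + wc
      F[, model$columns$level == lv - 1L] <- wm$values[rowidx, , drop = FALSE]
    }
  }
  list(F = F, grid = base$grid, rows = base$rows, cols = base$cols)
}

#' Segment an image with a fitted texture model
#'
#' Classifies every recognition window of the image (combining feature
#' columns from all model pyramid levels) and paints the window's class over
#' its pixel block. Margin pixels not covered by any window keep the
#' reserved margin marker `NA`.
#'
#' @param img a [gray_image()].
#' @param model a [fit_interval_model()] result.
#' @param dep dependence table (default [dependence_table()]).
#' @return A [label_map()] the size of `img`.
#' @export
segment_image <- function(img, model, dep = dependence_table()) {
  stopifnot(inherits(img, "gray_image"), inherits(model, "texture_model"))
  cf <- combined_feature_matrix(img, model)
  cls <- classify_matrix(cf$F, model, dep)
  out <- matrix(NA_integer_, img$height, img$width)
  na <- model$window$height; nb <- model$window$width
  k <- 0L
  for (wr in seq_along(cf$rows)) {
    for (wc in seq_along(cf$cols)) {
      k <- k + 1L
      out[cf$rows[wr]:(cf$rows[wr] + na - 1L),
          cf$cols[wc]:(cf$cols[wc] + nb - 1L)] <- cls[k]
    }
  }
  label_map(out, classes = model$classes)
}

#' Pixelwise segmentation error
#'
#' Fraction of evaluated pixels whose predicted label differs from the true
#' label. Pixels carrying the reserved margin marker `NA` in either map are
#' excluded. Per-class over- and under-segmentation fractions (false
#' positives and misses, each relative to the class's true pixel count) are
#' attached as attribute `per_class`.
#'
#' @param pred,truth [label_map()]s of identical size.
#' @return A single numeric fraction in `[0, 1]` with attribute `per_class`
#'   (data frame: class, over, under).
#' @export
segmentation_error <- function(pred, truth) {
  stopifnot(inherits(pred, "label_map"), inherits(truth, "label_map"))
  if (pred$height != truth$height || pred$width != truth$width) {
    stop("`pred` and `truth` must have the same shape", call. = FALSE)
  }
  p <- pred$labels; t <- truth$labels
  mask <- !is.na(p) & !is.na(t)
  if (!any(mask)) stop("no evaluable pixels (all margin)", call. = FALSE)
  err <- mean(p[mask] != t[mask])
  per <- do.call(rbind, lapply(sort(unique(t[mask])), function(cl) {
    nc <- sum(mask & t == cl)
    data.frame(class = cl,
               over = sum(mask & p == cl & t != cl) / nc,
               under = sum(mask & p != cl & t == cl) / nc)
  }))
  structure(err, per_class = per)
}

# ---- model serialization --------------------------------------------------

#' Write / read a texture model as JSON
#'
#' @param model a `texture_model`.
#' @param path output (input) path.
#' @return `path` invisibly (`write`); a `texture_model` (`read`).
#' @export
write_texture_model <- function(model, path) {
  stopifnot(inherits(model, "texture_model"))
  doc <- list(
    classes = model$classes,
    ops = operator_set_to_list(model$ops),
    window = unclass(model$window),
    levels = model$levels,
    quantile = model$quantile,
    intervals = lapply(model$intervals, function(m) {
      list(keys = colnames(m), low = unname(m["low", ]), high = unname(m["high", ]))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_texture_model
#' @export
read_texture_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  ops <- operator_set_from_list(doc$ops)
  wspec <- do.call(window_spec, doc$window)
  cols <- col_metadata(ops, doc$levels)
  intervals <- lapply(doc$intervals, function(e) {
    m <- rbind(low = as.numeric(e$low), high = as.numeric(e$high))
    colnames(m) <- e$keys
    m[, cols$key, drop = FALSE]
  })
  names(intervals) <- as.character(doc$classes)
  structure(list(classes = as.integer(doc$classes), ops = ops, window = wspec,
                 levels = as.integer(doc$levels), quantile = doc$quantile,
                 columns = cols, intervals = intervals),
            class = "texture_model")
}

# ---- parameter grid search ------------------------------------------------

# normalized overlap of two intervals: |intersection| / |union span|
interval_overlap <- function(a, b) {
  inter <- min(a[2], b[2]) - max(a[1], b[1])
  span <- max(a[2], b[2]) - min(a[1], b[1])
  if (span <= 0) return(if (inter >= 0) 1 else 0)  # degenerate: point intervals
  max(inter, 0) / span
}

#' Grid-search refinement of operator parameters
#'
#' Deterministic replacement for interactive parameter adjustment: every
#' parameter combination in a body-region preset grid is evaluated on the
#' training images, and for each operator the combination minimizing the
#' summed normalized inter-class interval overlap is selected (smaller
#' overlap = better class separation on that operator's feature axis). Ties
#' resolve to the earliest combination in grid order.
#'
#' @param imgs a list of training [gray_image()]s.
#' @param labels parallel list of [label_map()]s.
#' @param region preset name (see [texture_preset()]).
#' @param wspec a [window_spec()].
#' @param quantile interval trim fraction used during scoring.
#' @return A list of eight tuned [op_spec()]s.
#' @export
tune_operator_set <- function(imgs, labels, region = "brain",
                              wspec = window_spec(), quantile = 0.01) {
  grid <- texture_preset(region)
  cand <- list(); cand_name <- character(0)
  for (nm in names(grid)) {
    combos <- expand.grid(grid[[nm]], KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(combos))) {
      cand[[length(cand) + 1L]] <- do.call(op_spec, c(list(name = nm), as.list(combos[r, , drop = FALSE])))
      cand_name <- c(cand_name, nm)
    }
  }
  space <- build_feature_space(imgs, cand, wspec, levels = 1L)
  model <- fit_interval_model(space, labels, quantile = quantile)
  ncls <- length(model$classes)
  if (ncls < 2L) stop("tuning requires at least two classes", call. = FALSE)
  score <- vapply(seq_along(cand), function(jj) {
    s <- 0
    for (a in seq_len(ncls - 1L)) {
      for (b in (a + 1L):ncls) {
        s <- s + interval_overlap(model$intervals[[a]][, jj],
                                  model$intervals[[b]][, jj])
      }
    }
    s
  }, numeric(1))
  lapply(names(grid), function(nm) {
    jj <- which(cand_name == nm)
    cand[[jj[which.min(score[jj])]]]
  })
}
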