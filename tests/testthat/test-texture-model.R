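test_that("the dependence table is symmetric with levels in 1..4", {
  dep <- dependence_table()
  expect_equal(dim(dep), c(8L, 8L))
  expect_true(all(is.na(diag(dep))))
  off <- dep[upper.tri(dep)]
  expect_true(all(off %in% 1:4))
  expect_identical(dep, t(dep))
  expect_equal(dep["M", "C"], 4L)     # mean and variance: strongly joint
  expect_equal(dep["CR", "DE"], 4L)
  expect_equal(dep["M", "CR"], 1L)
})

test_that("interval fitting records per-class quantile ranges", {
  ph <- make_phantom(phantom_preset("tworegion", size = 48, seed = 5))
  ops <- list(op_spec("M"), op_spec("C"), op_spec("HG", d = 1))
  space <- build_feature_space(list(ph$image), ops, window_spec(), levels = 1)
  model0 <- fit_interval_model(space, ph$labels, quantile = 0)
  # quantile 0 -> exact min/max of the training values
  wm <- space$maps[[1]][[1]]
  lab_cls <- mritex:::window_majority_classes(ph$labels$labels, window_spec(),
                                             wm$grid,
                                             mritex:::window_origins(48, 48, window_spec())$rows,
                                             mritex:::window_origins(48, 48, window_spec())$cols)
  for (cl in model0$classes) {
    sel <- which(!is.na(lab_cls) & lab_cls == cl)
    for (jj in seq_along(ops)) {
      expect_equal(unname(model0$intervals[[as.character(cl)]][, jj]),
                   range(wm$values[sel, jj]))
    }
  }
  # the flat and textured classes have disjoint mean-intensity intervals
  ivM1 <- model0$intervals[["1"]][, 1]
  ivM2 <- model0$intervals[["2"]][, 1]
  expect_true(ivM1["high"] < ivM2["low"] || ivM2["high"] < ivM1["low"])
  # single-class fit spans the observed range
  one <- label_map(matrix(1L, 48, 48))
  m1 <- fit_interval_model(space, one, quantile = 0)
  expect_equal(unname(m1$intervals[["1"]][, 1]), range(wm$values[, 1]))
  expect_error(fit_interval_model(space, ph$labels, classes = c(1, 2, 9)),
               "class 9")
})

test_that("training windows always fall inside their own zero-quantile intervals", {
  ph <- make_phantom(phantom_preset("brainlike", size = 96, seed = 2))
  ops <- default_operator_set("brain")
  space <- build_feature_space(list(ph$image), ops, window_spec(), levels = 1)
  model <- fit_interval_model(space, ph$labels, quantile = 0)
  wm <- space$maps[[1]][[1]]
  wo <- mritex:::window_origins(96, 96, window_spec())
  cls <- mritex:::window_majority_classes(ph$labels$labels, window_spec(),
                                          wo$grid, wo$rows, wo$cols)
  for (k in which(!is.na(cls))) {
    iv <- model$intervals[[as.character(cls[k])]]
    expect_true(all(wm$values[k, ] >= iv["low", ] - 1e-12 &
                    wm$values[k, ] <= iv["high", ] + 1e-12))
  }
})

hand_model <- function() {
  ops <- default_operator_set("brain")
  cols <- mritex:::col_metadata(ops, 1L)
  in_iv <- c(0, 1); out_iv <- c(2, 3)
  make_iv <- function(matching) {
    m <- matrix(rep(out_iv, nrow(cols)), 2, nrow(cols),
                dimnames = list(c("low", "high"), cols$key))
    m[, cols$name %in% matching] <- in_iv
    m
  }
  structure(list(classes = c(1L, 2L), ops = ops, window = window_spec(),
                 levels = 1L, quantile = 0,
                 columns = cols,
                 intervals = list("1" = make_iv(c("M", "C")),
                                  "2" = make_iv(c("HG", "CT", "ID", "ET")))),
            class = "texture_model")
}

test_that("dependence-weighted voting favors more strongly joint matches", {
  model <- hand_model()
  feats <- rep(0.5, 8)
  names(feats) <- model$columns$key
  # class 1 matches on {M, C}: score 2 + (4+4)/1 = 10
  # class 2 matches on {HG, CT, ID, ET}: 4 + 2*(4+3+3+3+2+4)/3 = 16.67 -> wins
  expect_equal(classify_window(feats, model), 2L)
  # unique full match wins outright
  m2 <- hand_model()
  m2$intervals[["1"]][] <- rep(c(0, 1), 8)
  expect_equal(classify_window(feats, m2), 1L)
  # order-free: shuffling the named features never changes the answer
  set.seed(1)
  for (r in 1:5) expect_equal(classify_window(sample(feats), model), 2L)
  # ... nor does permuting the model's columns wholesale
  perm <- c(3, 1, 8, 2, 5, 4, 7, 6)
  m3 <- model
  m3$columns <- model$columns[perm, ]
  m3$intervals <- lapply(model$intervals, function(m) m[, perm])
  expect_equal(classify_window(feats[m3$columns$key], m3), 2L)
  expect_error(classify_window(feats[1:3], model), "every model column")
})

test_that("segmentation paints window classes and reserves NA margins", {
  ph <- make_phantom(phantom_preset("tworegion", size = 50, seed = 5))
  ops <- list(op_spec("M"), op_spec("C"), op_spec("CT", d = 1))
  space <- build_feature_space(list(ph$image), ops, window_spec(), levels = 1)
  model <- fit_interval_model(space, ph$labels, quantile = 0)
  # constant background-valued image -> all background (margin aside)
  flat <- gray_image(matrix(10L, 50, 50))
  segf <- segment_image(flat, model)
  expect_true(all(segf$labels[1:48, 1:48] == 1L))
  expect_true(all(is.na(segf$labels[49:50, ])))   # discarded margin
  # held-out phantom from the same process: boundary-quantized recovery
  ph2 <- make_phantom(phantom_preset("tworegion", size = 50, seed = 99))
  seg2 <- segment_image(ph2$image, model)
  # residual error is confined to window-quantized boundary columns
  err <- segmentation_error(seg2, ph2$labels)
  expect_lt(as.numeric(err), 0.05)
})

test_that("pyramid levels contribute independent feature columns", {
  ph <- make_phantom(phantom_preset("tworegion", size = 48, seed = 12))
  ops <- list(op_spec("M"), op_spec("C"))
  space <- build_feature_space(list(ph$image), ops, window_spec(), levels = 2)
  model <- fit_interval_model(space, ph$labels, quantile = 0.01)
  expect_equal(nrow(model$columns), 4L)
  seg <- segment_image(ph$image, model)
  err <- segmentation_error(seg, ph$labels)
  expect_lt(as.numeric(err), 0.05)
})

test_that("segmentation error counts mismatched pixels and per-class fractions", {
  a <- label_map(matrix(rep(c(1L, 2L), each = 50), 10, 10))
  expect_equal(as.numeric(segmentation_error(a, a)), 0)
  b <- label_map(matrix(rep(c(2L, 1L), each = 50), 10, 10))
  expect_equal(as.numeric(segmentation_error(b, a)), 1)
  # exactly 10% of pixels flipped
  p <- a$labels; p[1:10] <- 3L - p[1:10]
  err <- segmentation_error(label_map(p), a)
  expect_equal(as.numeric(err), 0.10)
  per <- attr(err, "per_class")
  expect_equal(per$under[per$class == 1], 10 / 50)
  expect_equal(per$over[per$class == 2], 10 / 50)
  expect_error(segmentation_error(a, label_map(matrix(1L, 5, 5))), "same shape")
})

test_that("models survive a JSON round trip", {
  ph <- make_phantom(phantom_preset("tworegion", size = 48, seed = 5))
  ops <- default_operator_set("brain")
  space <- build_feature_space(list(ph$image), ops, window_spec(), levels = 1)
  model <- fit_interval_model(space, ph$labels, quantile = 0.01)
  path <- withr_tempfile("json")
  write_texture_model(model, path)
  back <- read_texture_model(path)
  expect_equal(back$classes, model$classes)
  expect_equal(back$intervals, model$intervals)
  expect_equal(back$columns$key, model$columns$key)
  seg1 <- segment_image(ph$image, model)
  seg2 <- segment_image(ph$image, back)
  expect_identical(seg1$labels, seg2$labels)
})

test_that("grid search picks separating parameters deterministically", {
  ph <- make_phantom(phantom_preset("tworegion", size = 48, seed = 4))
  tuned <- tune_operator_set(list(ph$image), list(ph$labels), region = "brain")
  expect_length(tuned, 8L)
  expect_equal(vapply(tuned, function(o) o$name, character(1)),
               c("M", "C", "HG", "CT", "ID", "ET", "CR", "DE"))
  tuned2 <- tune_operator_set(list(ph$image), list(ph$labels), region = "brain")
  expect_identical(vapply(tuned, function(o) o$label, character(1)),
                   vapply(tuned2, function(o) o$label, character(1)))
})
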