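#' Read a grayscale image from PNG or TIFF
#'
#' Decodes a single-channel raster into a [gray_image()]. Multi-channel files
#' are accepted only when they collapse losslessly to one channel (identical
#' RGB channels; a fully opaque alpha channel is dropped). Samples wider than
#' the requested gray-level alphabet (e.g. a 16-bit file read with
#' `levels = 256`) are requantized with [quantize()], so a full-range file
#' maps its maximum sample to `levels - 1`. Samples that already fit
#' `[0, levels - 1]` are kept as-is, which makes [write_image()] round trips
#' bit-exact.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param levels target number of gray levels `L` (default 256).
#' @return A [gray_image()] with `L = levels`.
#' @export
read_gray_image <- function(path, levels = 256L) {
  s <- read_samples(path)
  levels <- as.integer(levels)
  if (max(s$samples) >= levels) {
    img <- gray_image(s$samples, levels = max(2L, max(s$samples) + 1L))
    quantize(img, levels)
  } else {
    gray_image(s$samples, levels = levels)
  }
}

# decode to an integer sample matrix plus its bit depth
read_samples <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    info <- attributes(arr)
    bits <- if (!is.null(info$bits.per.sample)) info$bits.per.sample else 8L
  } else {
    stop(sprintf("unsupported image format '.%s' (PNG or TIFF expected)", ext), call. = FALSE)
  }
  m <- collapse_channels(arr, path)
  m <- matrix(as.vector(m), nrow(m), ncol(m))   # drop decoder metadata attrs
  list(samples = round_mat(m * (2^bits - 1)), bits = bits)
}

collapse_channels <- function(arr, path) {
  if (is.matrix(arr)) return(arr)
  nc <- dim(arr)[3]
  if (nc %in% c(2L, 4L)) {            # trailing alpha channel
    alpha <- arr[, , nc]
    if (any(alpha != 1)) {
      stop(sprintf("'%s' has a non-trivial alpha channel; cannot collapse losslessly", path),
           call. = FALSE)
    }
    arr <- arr[, , -nc, drop = FALSE]
    nc <- dim(arr)[3]
  }
  if (nc == 1L) return(arr[, , 1])
  for (k in 2:nc) {
    if (any(arr[, , k] != arr[, , 1])) {
      stop(sprintf("'%s' has unequal color channels; cannot collapse losslessly", path),
           call. = FALSE)
    }
  }
  arr[, , 1]
}

round_mat <- function(m) {
  out <- floor(m + 0.5)               # half-up, independent of IEC 60559 ties
  storage.mode(out) <- "integer"
  out
}

#' Requantize a grayscale image to a new gray-level alphabet
#'
#' Equal-width binning over the observed intensity range:
#' `floor((v - min) * target_levels / (max - min + 1))`. The mapping is
#' monotone non-decreasing; when the input range is at least `target_levels`
#' wide, both output extremes `0` and `target_levels - 1` are attained. A
#' constant image maps to all zeros (the range is degenerate and any constant
#' is equally valid; zero is chosen for determinism). For an image spanning
#' its full container range the rule reduces to the container formula
#' `floor(v * L_out / L_in)`.
#'
#' @param img a [gray_image()].
#' @param target_levels target `L` (>= 2).
#' @return A [gray_image()] with `levels = target_levels`.
#' @examples
#' ramp <- gray_image(matrix(0:255, 16, 16), 256)
#' range(quantize(ramp, 8)$pixels)  # 0 7
#' @export
quantize <- function(img, target_levels) {
  stopifnot(inherits(img, "gray_image"))
  target_levels <- as.integer(target_levels)
  if (is.na(target_levels) || target_levels < 2L) {
    stop("`target_levels` must be >= 2", call. = FALSE)
  }
  v <- img$pixels
  lo <- min(v); hi <- max(v)
  if (lo == hi) {
    out <- matrix(0L, img$height, img$width)
  } else {
    out <- floor((v - lo) * (target_levels / (hi - lo + 1)))
    out[out > target_levels - 1L] <- target_levels - 1L   # guard fp edge
    storage.mode(out) <- "integer"
  }
  gray_image(out, levels = target_levels)
}

#' Write a grayscale image or label map to PNG or TIFF
#'
#' Gray images with `L <= 256` are stored with their integer gray levels as
#' raw 8-bit samples, so `read_gray_image(path, levels = L)` reproduces the
#' pixels bit-exactly. Label maps are written with one gray value per class
#' (the class identifier itself); `NA` margin pixels are stored as
#' `na_value`.
#'
#' @param img a [gray_image()] or [label_map()].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @param na_value gray value used for `NA` labels (label maps only).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, na_value = 255L) {
  if (inherits(img, "gray_image")) {
    if (img$levels > 256L) stop("only L <= 256 images can be written", call. = FALSE)
    m <- img$pixels
  } else if (inherits(img, "label_map")) {
    m <- img$labels
    m[is.na(m)] <- as.integer(na_value)
    if (any(m < 0L | m > 255L)) {
      stop("label identifiers must lie in [0, 255] to be written as 8-bit gray", call. = FALSE)
    }
  } else {
    stop("`img` must be a gray_image or label_map", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  norm <- m / 255
  if (ext == "png") {
    png::writePNG(norm, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, where = path, bits.per.sample = 8L)
  } else {
    stop(sprintf("unsupported image format '.%s' (PNG or TIFF expected)", ext), call. = FALSE)
  }
  invisible(path)
}

#' Read a label map written by [write_image()]
#'
#' @param path path to the image file.
#' @param na_value gray value decoded back to `NA` (margin marker); use
#'   `NULL` to keep all values.
#' @return A [label_map()].
#' @export
read_label_map <- function(path, na_value = 255L) {
  s <- read_samples(path)$samples
  if (!is.null(na_value)) s[s == as.integer(na_value)] <- NA_integer_
  label_map(s)
}
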