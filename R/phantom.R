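#' Texture patch specification
#'
#' Describes the pixel process filling a phantom region. Kinds:
#' \describe{
#'   \item{`constant`}{every pixel equals `mean`.}
#'   \item{`uniform_noise`}{i.i.d. uniform on `[mean - amplitude, mean + amplitude]`.}
#'   \item{`gaussian_noise`}{i.i.d. normal with mean `mean` and sd `sd`.}
#'   \item{`checkerboard`}{two levels `mean - amplitude` / `mean + amplitude`
#'     alternating with the given `period`; optional additive gaussian noise
#'     of sd `sd`.}
#'   \item{`stripes`}{sinusoidal stripes of the given `period` and
#'     `orientation` (degrees), levels within `mean +/- amplitude`, optional
#'     noise `sd`.}
#'   \item{`blob_process`}{gaussian noise smoothed by repeated 3x3 box
#'     averaging (`smooth` passes), rescaled to `mean +/- amplitude`: coarse
#'     blobby texture.}
#' }
#' All generated intensities are clipped to `[0, L - 1]`.
#'
#' @param kind one of the kinds above.
#' @param mean central gray level.
#' @param amplitude half-range of the deterministic pattern (default 0).
#' @param sd standard deviation of additive gaussian noise (default 0).
#' @param period pattern period in pixels (default 2).
#' @param orientation stripe orientation in degrees (default 0).
#' @param smooth smoothing passes for `blob_process` (default 2).
#' @return An object of class `texture_patch_spec`.
#' @export
texture_patch_spec <- function(kind = c("constant", "uniform_noise", "gaussian_noise",
                                        "checkerboard", "stripes", "blob_process"),
                               mean = 128, amplitude = 0, sd = 0,
                               period = 2L, orientation = 0, smooth = 2L) {
  kind <- match.arg(kind)
  if (period < 1L) stop("`period` must be >= 1", call. = FALSE)
  structure(list(kind = kind, mean = mean, amplitude = amplitude, sd = sd,
                 period = as.integer(period), orientation = orientation,
                 smooth = as.integer(smooth)),
            class = "texture_patch_spec")
}

#' Generate a texture patch
#'
#' Deterministic given `seed`: all randomness flows from the supplied seed
#' through a private RNG stream (the caller's RNG state is untouched).
#' Periodic kinds (checkerboard, stripes) are exactly periodic; noise kinds
#' have their empirical mean close to the specified mean.
#'
#' @param spec a [texture_patch_spec()].
#' @param h,w patch size in pixels.
#' @param levels gray-level count `L` for clipping (default 256).
#' @param seed integer seed.
#' @return A [gray_image()] of size `h x w`.
#' @export
make_texture_patch <- function(spec, h, w, levels = 256L, seed = 1L) {
  stopifnot(inherits(spec, "texture_patch_spec"))
  h <- as.integer(h); w <- as.integer(w)
  vals <- with_local_seed(seed, {
    base <- switch(spec$kind,
      constant = matrix(spec$mean, h, w),
      uniform_noise = matrix(stats::runif(h * w, spec$mean - spec$amplitude,
                                          spec$mean + spec$amplitude), h, w),
      gaussian_noise = matrix(stats::rnorm(h * w, spec$mean, spec$sd), h, w),
      checkerboard = {
        rr <- (matrix(seq_len(h), h, w) - 1L) %/% spec$period
        cc <- (matrix(seq_len(w), h, w, byrow = TRUE) - 1L) %/% spec$period
        spec$mean + spec$amplitude * ifelse((rr + cc) %% 2L == 0L, -1, 1)
      },
      stripes = {
        th <- spec$orientation * pi / 180
        rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
        phase <- (rr * sin(th) + cc * cos(th)) * 2 * pi / spec$period
        spec$mean + spec$amplitude * sin(phase)
      },
      blob_process = {
        z <- matrix(stats::rnorm(h * w), h, w)
        for (k in seq_len(spec$smooth)) z <- box_blur3(z)
        rng <- max(z) - min(z)
        if (rng == 0) matrix(spec$mean, h, w)
        else spec$mean + spec$amplitude * (2 * (z - min(z)) / rng - 1)
      })
    if (spec$sd > 0 && spec$kind %in% c("checkerboard", "stripes")) {
      base <- base + matrix(stats::rnorm(h * w, 0, spec$sd), h, w)
    }
    base
  })
  gray_image(round_mat(pmin(pmax(vals, 0), levels - 1)), levels = levels)
}

box_blur3 <- function(z) {
  h <- nrow(z); w <- ncol(z)
  pad <- z[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  acc <- matrix(0, h, w)
  for (dr in 0:2) for (dc in 0:2) {
    acc <- acc + pad[dr + seq_len(h), dc + seq_len(w)]
  }
  acc / 9
}

#' Phantom specification
#'
#' A phantom is a background patch overlaid with regions (evaluated in
#' order; later regions overwrite earlier ones), each carrying its own
#' texture and class label. Supported region shapes: `disk`
#' (`center = c(row, col)`, `radius`), `annulus` (`center`, `r_in`, `r_out`)
#' and `rectangle` (`row`, `col`, `height`, `width`).
#'
#' @param height,width phantom size in pixels.
#' @param levels gray-level count `L` (default 256).
#' @param background a [texture_patch_spec()] for unclaimed pixels.
#' @param background_label class label of the background (default 1).
#' @param regions list of region descriptors: each a list with `shape`,
#'   geometry fields (see above), `texture` (a [texture_patch_spec()]) and
#'   `label`.
#' @param seed integer master seed; every random draw derives from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height, width, levels = 256L,
                         background = texture_patch_spec("gaussian_noise", mean = 16, sd = 6),
                         background_label = 1L, regions = list(), seed = 1L) {
  structure(list(height = as.integer(height), width = as.integer(width),
                 levels = as.integer(levels), background = background,
                 background_label = as.integer(background_label),
                 regions = regions, seed = as.integer(seed)),
            class = "phantom_spec")
}

region_mask <- function(reg, h, w) {
  rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  shape <- match.arg(reg$shape, c("disk", "annulus", "rectangle"))
  if (shape == "disk") {
    d2 <- (rr - reg$center[1])^2 + (cc - reg$center[2])^2
    ok <- reg$radius >= 0 && reg$center[1] - reg$radius >= 1 &&
      reg$center[1] + reg$radius <= h && reg$center[2] - reg$radius >= 1 &&
      reg$center[2] + reg$radius <= w
    if (!ok) stop("disk region extends outside the image frame", call. = FALSE)
    d2 <= reg$radius^2
  } else if (shape == "annulus") {
    if (reg$r_in >= reg$r_out) stop("annulus requires r_in < r_out", call. = FALSE)
    ok <- reg$center[1] - reg$r_out >= 1 && reg$center[1] + reg$r_out <= h &&
      reg$center[2] - reg$r_out >= 1 && reg$center[2] + reg$r_out <= w
    if (!ok) stop("annulus region extends outside the image frame", call. = FALSE)
    d2 <- (rr - reg$center[1])^2 + (cc - reg$center[2])^2
    d2 > reg$r_in^2 & d2 <= reg$r_out^2
  } else {
    if (reg$row < 1 || reg$col < 1 || reg$row + reg$height - 1 > h ||
        reg$col + reg$width - 1 > w) {
      stop("rectangle region extends outside the image frame", call. = FALSE)
    }
    rr >= reg$row & rr < reg$row + reg$height &
      cc >= reg$col & cc < reg$col + reg$width
  }
}

#' Generate a synthetic phantom image with ground-truth labels
#'
#' Renders the background patch, then each region's patch masked by its
#' geometry, in order (later regions overwrite earlier ones). The label map
#' mirrors the region geometry exactly; boundary pixels take the topmost
#' region's label. Deterministic given the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `image` (a [gray_image()]) and `labels`
#'   (a [label_map()]).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  img <- make_texture_patch(spec$background, h, w, spec$levels, seed = spec$seed)$pixels
  lab <- matrix(spec$background_label, h, w)
  for (k in seq_along(spec$regions)) {
    reg <- spec$regions[[k]]
    mask <- region_mask(reg, h, w)
    patch <- make_texture_patch(reg$texture, h, w, spec$levels,
                                seed = spec$seed + 1000L * k)$pixels
    img[mask] <- patch[mask]
    lab[mask] <- as.integer(reg$label)
  }
  list(image = gray_image(img, spec$levels),
       labels = label_map(lab))
}

#' Standard phantom presets
#'
#' `brainlike` emulates the gross layout the operators assume in
#' head-and-body imagery: a low-intensity noisy background (class 1), a
#' large textured central "tissue" disk covering well over 20% of the frame
#' (class 2), and a bright thin boundary annulus around it, akin to a skull
#' rim (class 3). `tworegion` is a minimal left/right split used for smoke
#' tests.
#'
#' @param preset `"brainlike"` or `"tworegion"`.
#' @param size side length in pixels (square phantom; default 96, use 512
#'   for full-scale runs).
#' @param seed integer seed.
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(preset = c("brainlike", "tworegion"),
                           size = 96L, seed = 1L) {
  preset <- match.arg(preset)
  size <- as.integer(size)
  ctr <- c(size / 2, size / 2)
  if (preset == "brainlike") {
    r_tissue <- round(0.30 * size)
    r_skull <- round(0.37 * size)
    phantom_spec(
      height = size, width = size, seed = seed,
      background = texture_patch_spec("gaussian_noise", mean = 16, sd = 6),
      background_label = 1L,
      regions = list(
        list(shape = "annulus", center = ctr, r_in = r_tissue, r_out = r_skull,
             texture = texture_patch_spec("gaussian_noise", mean = 235, sd = 8),
             label = 3L),
        list(shape = "disk", center = ctr, radius = r_tissue,
             texture = texture_patch_spec("stripes", mean = 120, amplitude = 45,
                                          sd = 12, period = 7L, orientation = 30),
             label = 2L)))
  } else {
    phantom_spec(
      height = size, width = size, seed = seed,
      background = texture_patch_spec("constant", mean = 10),
      background_label = 1L,
      regions = list(
        list(shape = "rectangle", row = 1, col = size %/% 2 + 1,
             height = size, width = size - size %/% 2,
             texture = texture_patch_spec("checkerboard", mean = 160,
                                          amplitude = 60, period = 3L),
             label = 2L)))
  }
}

#' Build a phantom spec from a plain (YAML/JSON) list
#'
#' @param x a list mirroring [phantom_spec()]'s fields; texture entries are
#'   parameter lists for [texture_patch_spec()].
#' @return A [phantom_spec()].
#' @export
phantom_spec_from_list <- function(x) {
  bg <- if (is.null(x$background)) texture_patch_spec("gaussian_noise", mean = 16, sd = 6)
        else do.call(texture_patch_spec, x$background)
  regions <- lapply(x$regions, function(r) {
    r$texture <- do.call(texture_patch_spec, r$texture)
    r$center <- unlist(r$center)
    r
  })
  phantom_spec(height = x$height, width = x$width,
               levels = if (is.null(x$levels)) 256L else x$levels,
               background = bg,
               background_label = if (is.null(x$background_label)) 1L else x$background_label,
               regions = regions,
               seed = if (is.null(x$seed)) 1L else x$seed)
}
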