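# shared fixture builders (all programmatic, seeded)

withr_tempfile <- function(ext) tempfile(fileext = paste0(".", ext))

random_image <- function(h, w, L = 256L, seed = 1L) {
  set.seed(seed)
  gray_image(matrix(sample(0L:(L - 1L), h * w, replace = TRUE), h, w), levels = L)
}

# 0/1 checkerboard with (1,1) = 0
checker_image <- function(h, w, L = 2L) {
  m <- (outer(seq_len(h), seq_len(w), "+")) %% 2L
  gray_image(m, levels = L)
}

# union of the preset exponent grids, used by the oracle sweeps
sweep_grid <- list(
  HG = expand.grid(n3 = c(2, 3, 4)),
  CT = expand.grid(n4 = c(2, 3), n5 = c(1, 2)),
  ID = expand.grid(n6 = c(1, 2, 3), n7 = c(2, 3)),
  ET = expand.grid(n8 = c(1, 2, 3, 4), n9 = c(1, 2, 3), k1 = 2),
  CR = expand.grid(n10 = c(1, 2, 3, 4), n11 = c(1, 2, 3, 4, 6),
                   variant = c("as_printed", "haralick"),
                   stringsAsFactors = FALSE),
  DE = expand.grid(n12 = c(1, 2, 3, 4), n13 = c(2, 3, 4), k2 = 2))
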