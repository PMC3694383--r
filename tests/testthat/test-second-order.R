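const_cm <- function(v = 5L, L = 8L) {
  counts <- matrix(0, L, L); counts[v + 1L, v + 1L] <- 36
  cooccurrence_from_counts(counts, d = 1)
}

uniform_cm <- function(m, L = 8L) {
  # uniform mass over the first m diagonal-adjacent cells
  counts <- matrix(0, L, L)
  cells <- cbind(seq_len(m), c(seq_len(m - 1) + 1, 1))
  counts[cells] <- 1
  cooccurrence_from_counts(counts, d = 1)
}

test_that("closed forms hold on degenerate and uniform matrices", {
  cm <- const_cm()
  expect_equal(homogeneity(cm, 1), 1)
  expect_equal(homogeneity(cm, 3), 1)
  expect_equal(contrast(cm, 2, 1), 0)
  expect_equal(entropy(cm, 1, 1, 2), 0)
  expect_equal(inverse_difference(cm, 1, 4), 1)
  expect_equal(difference_entropy(marginals(cm), 1, 1, 2), 0)
  cr <- correlation(cm)
  expect_equal(as.numeric(cr), 0)
  expect_true(attr(cr, "degenerate"))
  for (m in c(2, 4, 7)) {
    u <- uniform_cm(m)
    expect_equal(homogeneity(u, 2), 1 / m)
    expect_equal(entropy(u, 1, 1, 2), log2(m))
  }
  # uniform p_diff over m values -> DE(1,1) = log_k2(m)
  dcounts <- matrix(0, 8, 8); dcounts[cbind(1, 1:4)] <- 1
  expect_equal(difference_entropy(marginals(cooccurrence_from_counts(dcounts)), 1, 1, 2), 2)
})

test_that("checkerboard values match hand enumeration at d = 1", {
  cb <- checker_image(10, 10)
  cm <- cooccurrence_matrix(cb, c(3, 3, 6, 6), d = 1)
  expect_equal(homogeneity(cm, 2), 0.25)       # four cells of p = 1/4
  expect_equal(contrast(cm, 2, 1), 0.5)        # 1^2 * (1/4 + 1/4)
  expect_equal(inverse_difference(cm, 1, 2), 0.75)  # 0.5/1 + 0.5/2
  expect_equal(entropy(cm, 1, 1, 2), 2.0)
  expect_equal(difference_entropy(marginals(cm), 1, 1, 2), 1.0)
})

test_that("contrast scales as (L-1)^n4 between 0/1 and 0/(L-1) checkerboards", {
  base <- checker_image(10, 10)
  wide <- gray_image(base$pixels * 255L, levels = 256L)
  for (n4 in c(2, 3)) {
    ct1 <- contrast(cooccurrence_matrix(base, c(3, 3, 6, 6), 1), n4, 1)
    ctL <- contrast(cooccurrence_matrix(wide, c(3, 3, 6, 6), 1), n4, 1)
    expect_equal(ctL, 255^n4 * ct1)
  }
})

test_that("correlation variants expose the printed-vs-standard difference", {
  diag2 <- cooccurrence_from_counts(matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(as.numeric(correlation(diag2, n10 = 1, n11 = 1)), 1.0)
  expect_equal(as.numeric(correlation(diag2, n10 = 1, n11 = 1, variant = "haralick")), 1.0)
  anti2 <- cooccurrence_from_counts(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(as.numeric(correlation(anti2, variant = "haralick")), -1.0)
  expect_equal(as.numeric(correlation(anti2, variant = "as_printed")), 1.0)
})

test_that("even log exponents make the printed sign convention non-positive", {
  img <- random_image(12, 12, L = 8, seed = 21)
  cm <- cooccurrence_matrix(img, c(4, 4, 6, 6), d = 1)
  expect_lte(entropy(cm, 1, 2, 2), 0)
  expect_lte(difference_entropy(marginals(cm), 1, 2, 2), 0)
  # ET(1,1) is bounded by 2 log2 L
  expect_lte(entropy(cm, 1, 1, 2), 2 * log2(cm$levels))
})

test_that("contrast vanishes iff all mass is diagonal; single-cell mass maximizes HG", {
  dcm <- cooccurrence_from_counts(diag(c(2, 3, 1)))
  expect_equal(contrast(dcm, 2, 1), 0)
  expect_lt(homogeneity(dcm, 2), 1)
  expect_equal(homogeneity(const_cm(), 2), 1)
  off <- cooccurrence_from_counts(matrix(c(1, 1, 0, 1), 2, 2))
  expect_gt(contrast(off, 2, 1), 0)
})

test_that("every operator matches the brute-force oracle on random matrices", {
  img <- random_image(16, 16, L = 8, seed = 55)
  for (d in 1:3) {
    cm <- cooccurrence_matrix(img, c(6, 6, 6, 6), d = d)
    P <- as.matrix(cm)
    expect_equal(homogeneity(cm, 2), oracle_hg(P, 2), tolerance = 1e-10)
    expect_equal(contrast(cm, 2, 1), oracle_ct(P, 2, 1), tolerance = 1e-10)
    expect_equal(inverse_difference(cm, 1, 3), oracle_id(P, 1, 3), tolerance = 1e-10)
    expect_equal(entropy(cm, 2, 3, 2), oracle_et(P, 2, 3, 2), tolerance = 1e-10)
    expect_equal(as.numeric(correlation(cm, n10 = 2, n11 = 3)),
                 oracle_cr(P, 2, 3), tolerance = 1e-10)
    expect_equal(difference_entropy(marginals(cm, 2), 3, 2, 2),
                 oracle_de(P, 3, 2, 2, q = 2), tolerance = 1e-10)
  }
})

test_that("homogeneity with unit exponent is the normalization identity", {
  for (s in 1:3) {
    img <- random_image(10, 10, L = 16, seed = s)
    cm <- cooccurrence_matrix(img, c(2, 3, 5, 4), d = 2)
    expect_equal(homogeneity(cm, 1), 1, tolerance = 1e-12)
  }
})

test_that("homogeneity separates uniform zones from boundary zones", {
  ph <- make_phantom(phantom_preset("tworegion", size = 48, seed = 3))
  fm <- compute_feature_map(ph$image, op_spec("HG", n3 = 2, d = 1), window_spec())
  # columns 1-4 of the map lie in the flat region, columns 5-8 in the texture
  flat <- mean(fm$values[, 1:3])
  boundary <- mean(fm$values[, 4:5])
  expect_gt(flat, boundary)
})
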