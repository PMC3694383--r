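test_that("square-ring offsets enumerate the discrete circumference", {
  for (d in 1:4) {
    ro <- ring_offsets(d)
    offs <- ro$offsets
    expect_equal(nrow(offs), 8L * d)
    expect_true(all(pmax(abs(offs[, 1]), abs(offs[, 2])) == d))
    expect_equal(anyDuplicated(paste(offs[, 1], offs[, 2])), 0L)
  }
  expect_equal(nrow(ring_offsets(1)$offsets), 8L)   # the 8-neighborhood
  expect_equal(nrow(ring_offsets(2)$offsets), 16L)  # 16 pairs per circumference
  expect_equal(nrow(ring_offsets(3)$offsets), 24L)
  expect_equal(unname(ring_offsets(2)$offsets[1, ]), c(-2L, -2L))
  expect_error(ring_offsets(0), ">= 1")
})

test_that("a fully interior window contributes n_a*n_b*8d increments", {
  img <- random_image(9, 9, L = 8, seed = 4)
  cm <- cooccurrence_matrix(img, c(4, 4, 3, 3), d = 2)
  expect_equal(cm$total, 144L)                       # 9 centers x 16 partners
  expect_equal(sum(cm$p), 1, tolerance = 1e-12)
  expect_identical(as.matrix(cm, "count"),
                   oracle_cooc_dense(img$pixels, 4, 4, 3, 3, 2, 8))
})

test_that("border windows skip out-of-image partners and renormalize", {
  img <- random_image(9, 9, L = 8, seed = 6)
  cm <- cooccurrence_matrix(img, c(1, 1, 3, 3), d = 2)   # image corner
  expect_lt(cm$total, 144L)
  expect_equal(sum(cm$p), 1, tolerance = 1e-12)
  expect_identical(as.matrix(cm, "count"),
                   oracle_cooc_dense(img$pixels, 1, 1, 3, 3, 2, 8))
  tiny <- gray_image(matrix(0L, 2, 2), levels = 2)
  expect_error(cooccurrence_matrix(tiny, c(1, 1, 2, 2), d = 3), "degenerate")
  expect_error(cooccurrence_matrix(img, c(8, 8, 3, 3), d = 1), "inside the image")
})

test_that("constant images concentrate all mass in one diagonal cell", {
  img <- gray_image(matrix(5L, 8, 8), levels = 8)
  cm <- cooccurrence_matrix(img, c(3, 3, 4, 4), d = 1)
  expect_equal(length(cm$i), 1L)
  expect_equal(c(cm$i, cm$j), c(5L, 5L))
  expect_equal(cm$p, 1)
})

test_that("matrices match the brute-force enumeration on random images", {
  img <- random_image(16, 16, L = 8, seed = 123)
  for (d in 1:3) {
    for (orig in list(c(1, 1), c(6, 6), c(11, 11), c(1, 11))) {
      cm <- cooccurrence_matrix(img, c(orig[1], orig[2], 6, 6), d = d)
      expect_identical(as.matrix(cm, "count"),
                       oracle_cooc_dense(img$pixels, orig[1], orig[2], 6, 6, d, 8))
    }
  }
})

test_that("whole-image windows give exactly symmetric counts", {
  # when every pixel is a center, each ordered pair has its reverse counted
  img <- random_image(10, 10, L = 6, seed = 9)
  for (d in 1:2) {
    counts <- as.matrix(cooccurrence_matrix(img, c(1, 1, 10, 10), d = d), "count")
    expect_identical(counts, t(counts))
  }
})

test_that("marginals agree with direct computation and sum rules", {
  img <- gray_image(matrix(5L, 8, 8), levels = 8)
  m <- marginals(cooccurrence_matrix(img, c(3, 3, 4, 4), d = 1))
  expect_equal(c(m$mu_x, m$mu_y, m$sigma_x, m$sigma_y), c(5, 5, 0, 0))
  expect_equal(m$p_diff[1], 1)

  # balanced checkerboard window with full interior context at d = 1:
  # every center has 4 equal-valued (diagonal) and 4 differing partners
  cb <- checker_image(10, 10)
  cmc <- cooccurrence_matrix(cb, c(3, 3, 6, 6), d = 1)
  mc <- marginals(cmc, q = 1)
  expect_equal(mc$p_diff[1:2], c(0.5, 0.5))
  expect_equal(mc$mu_x, 0.5)

  img2 <- random_image(8, 8, L = 8, seed = 77)
  cm2 <- cooccurrence_matrix(img2, c(2, 2, 5, 5), d = 2)
  P <- as.matrix(cm2)
  for (q in 1:2) {
    m2 <- marginals(cm2, q = q)
    expect_equal(m2$p_diff, oracle_pdiff(P, q), tolerance = 1e-12)
    if (q == 1) expect_equal(sum(m2$p_diff), 1, tolerance = 1e-12)
  }
})

test_that("the sparse and dense constructors agree", {
  counts <- matrix(c(2, 1, 0, 0, 3, 0, 1, 0, 1), 3, 3)
  cm <- cooccurrence_from_counts(counts, d = 1)
  expect_equal(as.matrix(cm, "count"), counts)
  expect_equal(sum(cm$p), 1)
  expect_error(cooccurrence_from_counts(matrix(0, 2, 2)), "positive total")
})
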