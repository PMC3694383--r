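# Independent brute-force oracles: plain loops, no shared code with the
# package internals. All matrices of gray levels are 0-based integer values.

# dense co-occurrence count matrix for a window at (r0, c0), size na x nb,
# square-ring radius d, with context from the full image
oracle_cooc_dense <- function(px, r0, c0, na, nb, d, L) {
  H <- nrow(px); W <- ncol(px)
  counts <- matrix(0, L, L)
  for (r in r0:(r0 + na - 1)) {
    for (c in c0:(c0 + nb - 1)) {
      for (dr in -d:d) {
        for (dc in -d:d) {
          if (max(abs(dr), abs(dc)) != d) next
          pr <- r + dr; pc <- c + dc
          if (pr < 1 || pr > H || pc < 1 || pc > W) next
          i <- px[r, c] + 1L; j <- px[pr, pc] + 1L
          counts[i, j] <- counts[i, j] + 1
        }
      }
    }
  }
  counts
}

oracle_hist <- function(v, L) {
  p <- numeric(L)
  for (x in v) p[x + 1L] <- p[x + 1L] + 1
  p / length(v)
}

oracle_moment <- function(p, n1) {
  s <- 0
  for (i in seq_along(p)) s <- s + (i - 1)^n1 * p[i]
  s
}

oracle_central_moment <- function(p, n2, center_order = 1) {
  m <- oracle_moment(p, center_order)
  s <- 0
  for (i in seq_along(p)) s <- s + ((i - 1) - m)^n2 * p[i]
  s
}

# second-order oracles on a dense probability matrix P (P[i+1, j+1] = p(i,j))
oracle_hg <- function(P, n3) {
  s <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) s <- s + P[i, j]^n3
  s
}

oracle_ct <- function(P, n4, n5) {
  s <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    s <- s + abs(i - j)^n4 * P[i, j]^n5
  }
  s
}

oracle_id <- function(P, n6, n7) {
  s <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    dd <- if (n7 %% 2 == 0) (i - j)^n7 else abs(i - j)^n7
    s <- s + P[i, j]^n6 / (1 + dd)
  }
  s
}

oracle_et <- function(P, n8, n9, k1) {
  s <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    if (P[i, j] > 0) s <- s + P[i, j]^n8 * (log(P[i, j]) / log(k1))^n9
  }
  -s
}

oracle_cr <- function(P, n10, n11, variant = "as_printed") {
  L <- nrow(P)
  mux <- muy <- 0
  for (i in 1:L) for (j in 1:L) {
    mux <- mux + (i - 1) * P[i, j]
    muy <- muy + (j - 1) * P[i, j]
  }
  vx <- vy <- 0
  for (i in 1:L) for (j in 1:L) {
    vx <- vx + ((i - 1) - mux)^2 * P[i, j]
    vy <- vy + ((j - 1) - muy)^2 * P[i, j]
  }
  den <- (sqrt(vx) * sqrt(vy))^n11
  if (den == 0) return(0)
  s <- 0
  for (i in 1:L) for (j in 1:L) {
    second <- if (variant == "haralick") (j - 1) - muy else (i - 1) - muy
    s <- s + ((i - 1) - mux) * second * P[i, j]^n10
  }
  s / den
}

oracle_pdiff <- function(P, q = 1) {
  L <- nrow(P)
  pd <- numeric(L)
  for (i in 1:L) for (j in 1:L) {
    k <- abs(i - j)
    pd[k + 1] <- pd[k + 1] + P[i, j]^q
  }
  pd
}

oracle_de <- function(P, n12, n13, k2, q = 1) {
  pd <- oracle_pdiff(P, q)
  s <- 0
  for (k in seq_along(pd)) {
    if (pd[k] > 0) s <- s + pd[k]^n12 * (log(pd[k]) / log(k2))^n13
  }
  -s
}
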