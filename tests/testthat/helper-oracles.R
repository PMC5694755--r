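# Independent reference implementations used to validate the package's
# computations. These deliberately share no code with the package internals.

# Quadratic-space affine-gap local alignment DP (Gotoh), scores only.
# Gap of length L costs open + (L - 1) * extend.
sw_oracle <- function(a, b, scores, open = 10, extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in a (move along b)
  F <- matrix(NEG, n + 1, m + 1)  # gap in b
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open, F[i - 1, j] - extend)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + scores[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Naive Ward agglomeration via the Lance-Williams update applied to the
# distance matrix as given. Returns merge heights (ascending by merge) and
# the cophenetic distance matrix implied by the merge sequence.
ward_oracle <- function(D) {
  n <- nrow(D)
  active <- as.list(seq_len(n))       # member indices per cluster
  d <- D
  coph <- matrix(0, n, n)
  heights <- numeric(n - 1)
  sizes <- rep(1, n)
  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (d[i, j] < best[1] - 1e-15) best <- c(d[i, j], i, j)
      }
    }
    i <- best[2]; j <- best[3]
    h <- best[1]
    heights[step] <- h
    for (a in active[[i]]) for (b in active[[j]]) {
      coph[a, b] <- h; coph[b, a] <- h
    }
    ni <- sizes[i]; nj <- sizes[j]
    newd <- sapply(seq_len(k), function(l) {
      if (l == i || l == j) return(NA_real_)
      nl <- sizes[l]
      ((ni + nl) * d[i, l] + (nj + nl) * d[j, l] - nl * d[i, j]) /
        (ni + nj + nl)
    })
    keep <- setdiff(seq_len(k), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    active <- c(active[keep], list(c(active[[i]], active[[j]])))
    sizes <- c(sizes[keep], ni + nj)
  }
  list(heights = heights, cophenetic = coph)
}

# Direct-summation Jensen-Shannon divergence on two probability vectors.
jsd_oracle <- function(p, q) {
  m <- (p + q) / 2
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + 0.5 * p[i] * log(p[i] / m[i])
    if (q[i] > 0) s <- s + 0.5 * q[i] * log(q[i] / m[i])
  }
  s
}

# Random amino-acid sequences over a chosen alphabet.
random_seqs <- function(n, len_range = c(5, 16),
                        alphabet = recold:::AA_ALPHABET) {
  vapply(seq_len(n), function(i) {
    L <- sample(seq(len_range[1], len_range[2]), 1)
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
}
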