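test_that("the Jensen-Shannon divergence obeys its identities", {
  td <- toy_density_pair(c(1, 0), c(0.5, 0.5))
  r <- jensen_shannon(td$P, td$Q)
  expect_equal(r$global, 0.5 * log(4 / 3) + 0.25 * log(2 / 3) +
                 0.25 * log(2), tolerance = 1e-12)
  expect_equal(round(r$global, 6), 0.215762)
  expect_equal(sum(r$local), r$global, tolerance = 1e-9)
  expect_equal(jensen_shannon(td$Q, td$P)$global, r$global)

  same <- toy_density_pair(c(0.3, 0.7), c(0.3, 0.7))
  rs <- jensen_shannon(same$P, same$Q)
  expect_equal(rs$global, 0)
  expect_true(all(rs$local == 0))

  disj <- toy_density_pair(c(1, 0), c(0, 1))
  expect_equal(jensen_shannon(disj$P, disj$Q)$global, log(2),
               tolerance = 1e-12)

  # bits option rescales by log(2)
  expect_equal(jensen_shannon(td$P, td$Q, base = "bits")$global,
               r$global / log(2), tolerance = 1e-12)

  other <- toy_density_pair(c(0.2, 0.8), c(0.2, 0.8))
  other$Q$grid$edges[[1]] <- other$Q$grid$edges[[1]] + 1
  expect_error(jensen_shannon(other$P, other$Q), "different grids")
})

test_that("JSD matches direct summation on random distributions", {
  set.seed(19)
  for (i in 1:20) {
    p <- runif(10); p <- p / sum(p)
    q <- runif(10); q <- q / sum(q)
    # sparsify some entries to exercise the 0 log 0 convention
    if (i %% 3 == 0) { p[1:3] <- 0; p <- p / sum(p) }
    td <- toy_density_pair(p, q)
    r <- jensen_shannon(td$P, td$Q)
    expect_equal(r$global, jsd_oracle(p, q), tolerance = 1e-12)
    expect_gte(r$global, 0)
    expect_lte(r$global, log(2) + 1e-12)
    expect_equal(sum(r$local), r$global, tolerance = 1e-9)
  }
})

test_that("the pairwise-sample JSD matrix is consistent with its entries", {
  set.seed(2)
  pts <- matrix(rnorm(60), 30, 2)
  g <- make_grid(pts, bins = 30L)
  mk <- function(rows, id) {
    p <- estimate_pdf(pts[rows, , drop = FALSE], g, 0.3, sample_id = id)
    p
  }
  pdfs <- list(mk(1:10, "a"), mk(11:20, "b"), mk(21:30, "c"))
  J <- pairwise_sample_jsd(pdfs)
  expect_equal(diag(J), c(a = 0, b = 0, c = 0))
  expect_identical(J, t(J))
  expect_equal(J["a", "b"], jensen_shannon(pdfs[[1]], pdfs[[2]])$global)
  expect_equal(J["b", "c"], jensen_shannon(pdfs[[2]], pdfs[[3]])$global)

  Jsame <- pairwise_sample_jsd(list(mk(1:10, "x"), mk(1:10, "y")))
  expect_equal(Jsame["x", "y"], 0)
})

test_that("contributing bins select the top fraction with ties included", {
  set.seed(23)
  ptsA <- matrix(rnorm(20, -1, 0.2), 10, 2)
  ptsB <- matrix(rnorm(20, 1, 0.2), 10, 2)
  rownames(ptsA) <- paste0("a", 1:10)
  rownames(ptsB) <- paste0("b", 1:10)
  g <- make_grid(rbind(ptsA, ptsB), bins = 30L)
  P <- estimate_pdf(ptsA, g, 0.2, sample_id = "A")
  Q <- estimate_pdf(ptsB, g, 0.2, sample_id = "B")
  r <- jensen_shannon(P, Q)

  cs <- contributing_sequences(r, ptsA, ptsB, g, top_frac = 0.01)
  n_pos <- sum(r$local > 0)
  expect_gte(length(cs$bins), ceiling(0.01 * n_pos))
  expect_true(all(r$local[cs$bins] >= cs$cutoff))

  # top_frac = 1 returns every sequence sitting in a positive bin
  all_cs <- contributing_sequences(r, ptsA, ptsB, g, top_frac = 1)
  binsA <- recold:::grid_bin_index(g, ptsA)
  expect_setequal(all_cs$A$sequence, rownames(ptsA)[r$local[binsA] > 0])

  # identical samples: empty set
  r0 <- jensen_shannon(P, P)
  cs0 <- contributing_sequences(r0, ptsA, ptsA, g)
  expect_length(cs0$bins, 0L)
  expect_equal(nrow(cs0$A), 0L)
})

test_that("bootstrap thresholds are reproducible and shrink with depth", {
  set.seed(10)
  pts <- matrix(rnorm(100), 50, 2)
  g <- make_grid(pts, bins = 30L)
  pdf <- estimate_pdf(pts, g, 0.3, sample_id = "s")

  b1 <- bootstrap_significance(pdf, n_points = 100, n_boot = 50, seed = 5)
  b2 <- bootstrap_significance(pdf, n_points = 100, n_boot = 50, seed = 5)
  expect_identical(b1$jsd_samples, b2$jsd_samples)
  expect_identical(b1$threshold, b2$threshold)
  expect_true(all(b1$jsd_samples >= 0))
  expect_gte(b1$threshold, 0)

  # the 99th percentile with linear interpolation lies between the 99th
  # and 100th order statistics of 100 replicates
  b100 <- bootstrap_significance(pdf, n_points = 50, n_boot = 100, seed = 2)
  o <- sort(b100$jsd_samples)
  expect_gte(b100$threshold, o[99])
  expect_lte(b100$threshold, o[100])

  # ten-fold more resampled points: sampling noise shrinks
  med_small <- median(bootstrap_significance(pdf, 40, 40, seed = 3)$jsd_samples)
  med_large <- median(bootstrap_significance(pdf, 400, 40, seed = 3)$jsd_samples)
  expect_lt(med_large, med_small)

  expect_error(bootstrap_significance(pdf, 10, n_boot = 1), "n_boot")
})

test_that("position frequencies count residues per column", {
  m <- position_frequency_matrix(c("CAAS", "CAAS"))
  expect_equal(m[1, "C"], 1)
  expect_equal(m[4, "S"], 1)
  expect_equal(rowSums(m), rep(1, 4), ignore_attr = TRUE)

  m2 <- position_frequency_matrix(c("CA", "CT"))
  expect_equal(m2[2, "A"], 0.5)
  expect_equal(m2[2, "T"], 0.5)

  expect_error(position_frequency_matrix(c("CA", "CAT")), "mixed lengths")

  # the shared-suffix motif set: positions 6-11 each dominated by one
  # residue, spelling the YQLIWG-type consensus
  pfm <- position_frequency_matrix(shared_suffix_set())
  expect_equal(rowSums(pfm), rep(1, 11), ignore_attr = TRUE)
  consensus <- colnames(pfm)[apply(pfm, 1, which.max)]
  expect_identical(consensus[6:11], c("Y", "Q", "L", "I", "W", "G"))
  expect_true(all(apply(pfm, 1, max)[6:11] >= 0.9))
})
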