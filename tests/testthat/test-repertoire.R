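test_that("clonotype tables merge duplicate sequences and validate input", {
  path <- write_tsv_fixture(data.frame(sequence = c("CAAS", "CAAT", "CAAS"),
                                       count = c(5, 3, 2)))
  rep <- read_clonotype_table(path, dialect = "simple")
  expect_s3_class(rep, "repertoire")
  expect_length(rep$sequences, 2L)
  expect_equal(rep$counts[rep$sequences == "CAAS"], 7)
  expect_equal(total_reads(rep), 10)

  empty <- write_tsv_fixture(data.frame(sequence = character(0),
                                        count = numeric(0)))
  expect_error(read_clonotype_table(empty), "no clonotypes")

  bad <- write_tsv_fixture(data.frame(sequence = c("CAAS", "CAXS"),
                                      count = c(1, 1)))
  expect_error(read_clonotype_table(bad), "row 2")

  missing <- write_tsv_fixture(data.frame(seq = "CAAS", count = 1))
  expect_error(read_clonotype_table(missing), "column 'sequence'")

  expect_error(repertoire("CAAS", 0), "positive integer")
  expect_error(repertoire("CAAS", 1.5), "positive integer")
})

test_that("MiXCR-style exports are read with configurable column names", {
  path <- write_tsv_fixture(data.frame(cloneId = 0:1,
                                       cloneCount = c(12, 4),
                                       aaSeqCDR3 = c("CAASNYQLIWG", "CAAS"),
                                       check.names = FALSE))
  rep <- read_clonotype_table(path, dialect = "mixcr", sample_id = "m1")
  expect_equal(rep$sample_id, "m1")
  expect_equal(total_reads(rep), 16)
  expect_error(
    read_clonotype_table(path, dialect = "mixcr", count_col = "readCount"),
    "readCount")
})

test_that("repertoires round-trip through the simple dialect", {
  rep <- repertoire(c("CAAS", "CAATW"), c(7, 3), "rt")
  path <- write_clonotype_table(rep, tempfile(fileext = ".tsv"))
  back <- read_clonotype_table(path, sample_id = "rt")
  expect_equal(back$sequences, rep$sequences)
  expect_equal(back$counts, rep$counts)
})

test_that("subsampling follows the original relative frequencies", {
  single <- repertoire("CAAS", 100)
  sub <- subsample_repertoire(single, 7, seed = 3)
  expect_equal(sub$sequences, "CAAS")
  expect_equal(sub$counts, 7)

  two <- repertoire(c("CAAAAW", "CTTTTW"), c(500, 500))
  # each drawn count stays within 4 binomial standard deviations of n/2
  sd4 <- 4 * sqrt(10000 * 0.5 * 0.5)
  for (s in 1:50) {
    d <- subsample_repertoire(two, 10000, seed = s)
    expect_true(all(abs(d$counts - 5000) <= sd4))
  }

  # expectation over seeds matches original frequencies within 3 SE
  skewed <- repertoire(c("CAAS", "CAAT", "CAAW"), c(60, 30, 10))
  n <- total_reads(skewed)
  draws <- sapply(1:200, function(s) {
    d <- subsample_repertoire(skewed, n, seed = s)
    d$counts[match(skewed$sequences, d$sequences)] / n
  })
  draws[is.na(draws)] <- 0
  p <- skewed$counts / n
  se <- sqrt(p * (1 - p) / n) / sqrt(200)
  expect_true(all(abs(rowMeans(draws) - p) <= 3 * se + 1e-12))

  expect_error(subsample_repertoire(single, 0), "n_target")
  expect_identical(subsample_repertoire(two, 100, seed = 9)$counts,
                   subsample_repertoire(two, 100, seed = 9)$counts)
})

test_that("read depth is equalized to the minimum and the minimum sample passes through", {
  reps <- list(repertoire(c("CAAS", "CAAT"), c(600, 400), "a"),
               repertoire(c("CAAS", "CAAW"), c(1500, 500), "b"),
               repertoire(c("CAAY", "CAAT"), c(300, 200), "c"))
  eq <- equalize_read_depth(reps, seed = 1)
  expect_equal(vapply(eq, total_reads, numeric(1)), c(500, 500, 500))
  expect_identical(eq[[3]], reps[[3]])

  same <- equalize_read_depth(reps[c(3, 3)], seed = 1)
  expect_equal(vapply(same, total_reads, numeric(1)), c(500, 500))
  expect_error(equalize_read_depth(reps[1]), ">= 2")
})

test_that("overlap fraction is set arithmetic over unique sequences", {
  A <- repertoire(c("CAAW", "CAAY"), c(1, 2), "A")
  B <- repertoire(c("CAAY", "CAAT"), c(5, 1), "B")
  ov <- overlap_fraction(A, B)
  expect_equal(ov$fraction, 1 / 3)
  expect_equal(ov$n_shared, 1L)
  expect_equal(ov$n_union, 3L)
  expect_equal(overlap_fraction(B, A)$fraction, ov$fraction)

  expect_equal(overlap_fraction(A, A),
               list(fraction = 1, n_shared = 2L, n_union = 2L))
  C <- repertoire(c("CTTT", "CSSS"), c(1, 1), "C")
  expect_equal(overlap_fraction(A, C),
               list(fraction = 0, n_shared = 0L, n_union = 4L))
})

test_that("Bray-Curtis matches its formula and the vegan reference", {
  A <- repertoire("CAAS", 3, "A")
  B <- repertoire(c("CAAS", "CAAT"), c(1, 1), "B")
  expect_equal(bray_curtis(A, B), 0.6)
  expect_equal(bray_curtis(B, A), 0.6)
  expect_equal(bray_curtis(A, A), 0)
  C <- repertoire(c("CTTT"), 5, "C")
  expect_equal(bray_curtis(A, C), 1)

  skip_if_not_installed("vegan")
  set.seed(11)
  seqs <- random_seqs(12, c(4, 8))
  a <- repertoire(seqs[1:8], sample(1:20, 8, replace = TRUE), "a")
  b <- repertoire(seqs[5:12], sample(1:20, 8, replace = TRUE), "b")
  uni <- union(a$sequences, b$sequences)
  comm <- rbind(a$counts[match(uni, a$sequences)],
                b$counts[match(uni, b$sequences)])
  comm[is.na(comm)] <- 0
  expect_equal(bray_curtis(a, b),
               as.numeric(vegan::vegdist(comm, method = "bray")))
})
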