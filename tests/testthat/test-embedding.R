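test_that("SMACOF recovers exactly embeddable configurations", {
  # two points: embedded distance equals the dissimilarity
  S2 <- matrix(c(0, 5, 5, 0), 2, 2)
  X2 <- embed_mds(S2, embedding_config("mds", max_iter = 500))
  expect_equal(as.numeric(dist(X2)), 5, tolerance = 1e-6)

  # equilateral triangle
  S3 <- matrix(1, 3, 3); diag(S3) <- 0
  X3 <- embed_mds(S3, embedding_config("mds", max_iter = 500))
  expect_equal(as.numeric(dist(X3)), rep(1, 3), tolerance = 1e-6)

  # unit square
  s2r <- sqrt(2)
  S4 <- matrix(c(0, 1, 1, s2r,
                 1, 0, s2r, 1,
                 1, s2r, 0, 1,
                 s2r, 1, 1, 0), 4, 4)
  X4 <- embed_mds(S4, embedding_config("mds", max_iter = 1000))
  expect_equal(sort(as.numeric(dist(X4))), sort(c(1, 1, 1, 1, s2r, s2r)),
               tolerance = 1e-6)
})

test_that("SMACOF stress is non-increasing across iterations", {
  set.seed(31)
  for (rep in 1:5) {
    S <- as.matrix(dist(matrix(runif(30), 15, 2))) +
      matrix(runif(225, 0, 0.05), 15, 15)
    S <- (S + t(S)) / 2; diag(S) <- 0
    X <- embed_mds(S, embedding_config("mds", max_iter = 200))
    st <- attr(X, "stress")
    expect_true(all(diff(st) <= 1e-10))
  }
})

test_that("geodesics follow shortest paths on the kNN graph", {
  # 3 collinear points, k = 1: the ends connect through the middle
  Sc <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  G <- geodesic_distances(Sc, k = 1)
  expect_equal(G[1, 3], 2)

  # path of 5 points with unit steps
  Sp <- abs(outer(1:5, 1:5, "-")) * 1.0
  Gp <- geodesic_distances(Sp, k = 1)
  expect_equal(Gp[1, 5], 4)

  # complete graph: geodesics equal direct dissimilarities when the
  # triangle inequality holds (metric input)
  set.seed(4)
  pts <- matrix(rnorm(30), 15, 2)
  Sm <- as.matrix(dist(pts))
  expect_equal(geodesic_distances(Sm, k = 14), Sm, ignore_attr = TRUE)

  # two far pairs with k = 1 leave the graph disconnected
  Sd <- matrix(10, 4, 4); diag(Sd) <- 0
  Sd[1, 2] <- Sd[2, 1] <- 0.1
  Sd[3, 4] <- Sd[4, 3] <- 0.1
  expect_error(geodesic_distances(Sd, k = 1), "2 components")
})

test_that("geodesics match an independent Dijkstra implementation", {
  skip_if_not_installed("igraph")
  set.seed(12)
  for (rep in 1:5) {
    S <- as.matrix(dist(matrix(rnorm(40), 20, 2)))
    k <- 4
    G <- geodesic_distances(S, k)
    A <- recold:::knn_graph(S, k)
    W <- ifelse(is.na(A), 0, A)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    ref <- igraph::distances(g, algorithm = "dijkstra")
    expect_equal(G, ref, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("ISOMAP on a complete graph matches plain MDS distances", {
  set.seed(9)
  S <- as.matrix(dist(matrix(rnorm(30), 15, 2)))
  Xi <- embed_isomap(S, embedding_config("isomap", k_neighbors = 14,
                                         max_iter = 500))
  Xm <- embed_mds(S, embedding_config("mds", max_iter = 500))
  expect_equal(as.numeric(dist(Xi)), as.numeric(dist(Xm)),
               tolerance = 1e-4)
})

test_that("spectral embedding separates weakly connected blobs by sign", {
  # two tight blobs, one weak bridge
  set.seed(21)
  blob <- function(cx) cbind(rnorm(10, cx, 0.05), rnorm(10, 0, 0.05))
  pts <- rbind(blob(0), blob(5))
  S <- as.matrix(dist(pts))
  X <- embed_spectral(S, embedding_config("spectral", k_neighbors = 10,
                                          dim = 2))
  expect_identical(dim(X), c(20L, 2L))
  expect_true(all(is.finite(X)))
  # one blob on each side of zero (bridge points may sit exactly at zero)
  s1 <- sign(mean(X[1:10, 1])); s2 <- sign(mean(X[11:20, 1]))
  expect_true(s1 * s2 < 0)
  expect_true(all(X[1:10, 1] * s1 >= -1e-8))
  expect_true(all(X[11:20, 1] * s2 >= -1e-8))

  # complete graph with equal weights: degenerate spectrum, shape only
  Se <- matrix(1, 8, 8); diag(Se) <- 0
  Xe <- embed_spectral(Se, embedding_config("spectral", k_neighbors = 7))
  expect_identical(dim(Xe), c(8L, 2L))
  expect_true(all(is.finite(Xe)))
})

test_that("t-SNE keeps zero-dissimilarity pairs adjacent and recovers families", {
  # an identical sequence (S = 0 to its twin) stays its mutual nearest
  # neighbour in the embedding
  seqs <- c("CAASAYQLIWG", "CAWDSNTGKLTF", "CILRGDTQYFGS", "CQQSNTWPLTFG",
            "CAVRGGSYIPTF", "CASSLGQAYEQY", "CAWSVSDLAKNI", "CGARGQNTEAFF",
            "CASRTGELFFGE", "CAYRSAGNMLTF")
  S0 <- dissimilarity_from_scores(pairwise_score_matrix(seqs))
  S <- rbind(cbind(S0, S0[, 1]), c(S0[1, ], 0))
  for (seed in 1:10) {
    X <- embed_tsne(S, embedding_config("tsne", perplexity = 4, seed = seed,
                                        max_iter = 400))
    d <- as.matrix(dist(X)); diag(d) <- Inf
    expect_equal(which.min(d[1, ]), 11L, ignore_attr = TRUE)
    expect_equal(which.min(d[11, ]), 1L, ignore_attr = TRUE)
  }

  expect_error(embed_tsne(S, embedding_config("tsne", perplexity = 12)),
               "perplexity")

  # three well-separated families: nearest-centroid label recovery
  fams <- list(
    motif_family("CAASAYQLIWG", variable = 2:5, sub_rate = 0.5,
                 indel_prob = 0.05, name = "f1"),
    motif_family("CAWDSNTGKLTF", variable = 2:6, sub_rate = 0.5,
                 indel_prob = 0.05, name = "f2"),
    motif_family("CILRGDTQYFGS", variable = 2:6, sub_rate = 0.5,
                 indel_prob = 0.05, name = "f3"))
  design <- synthetic_design(fams, list(
    list(sample_id = "s", weights = c(1, 1, 1) / 3, n_unique = 60)),
    seed = 13)
  rep1 <- generate_repertoires(design)
  truth <- attr(rep1, "truth")
  S3 <- dissimilarity_from_scores(
    pairwise_score_matrix(truth$sequence))
  X3 <- embed_tsne(S3, embedding_config("tsne", perplexity = 10, seed = 1))
  cent <- apply(X3, 2, function(col) tapply(col, truth$family, mean))
  dc <- as.matrix(dist(rbind(cent, X3)))[-(1:3), 1:3]
  pred <- rownames(cent)[apply(dc, 1, which.min)]
  expect_gte(mean(pred == truth$family), 0.95)
})

test_that("embeddings are deterministic and preserve row order", {
  set.seed(17)
  S <- as.matrix(dist(matrix(rnorm(40), 20, 2)))
  rownames(S) <- colnames(S) <- paste0("q", 1:20)
  for (m in c("mds", "isomap", "spectral", "tsne")) {
    cfg <- embedding_config(m, k_neighbors = 5, perplexity = 5, seed = 99,
                            max_iter = 120)
    X1 <- embed_dissimilarity(S, cfg)
    X2 <- embed_dissimilarity(S, cfg)
    expect_identical(X1, X2)
    expect_identical(rownames(X1), rownames(S))
    expect_identical(attr(X1, "method"), m)
  }
  expect_error(embed_mds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})
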