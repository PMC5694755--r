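#' Embedding configuration
#'
#' Parameters shared by the four embedding methods. `k_neighbors` is used by
#' the neighborhood-graph methods (ISOMAP, spectral embedding), `perplexity`
#' by t-SNE, `max_iter`/`tol` by the iterative optimizers.
#'
#' @param method one of `"mds"`, `"isomap"`, `"spectral"`, `"tsne"`.
#' @param dim target dimensionality (default 2).
#' @param k_neighbors neighborhood size for the kNN graph (default 10).
#' @param perplexity t-SNE perplexity (default 30; must be < number of
#'   points).
#' @param seed integer seed for the stochastic stages.
#' @param max_iter,tol optimizer controls; `max_iter` defaults to 1000 for
#'   t-SNE (the conventional gradient-descent budget) and 300 for the
#'   majorization methods.
#' @return An object of class `embedding_config`.
#' @export
embedding_config <- function(method = c("mds", "isomap", "spectral", "tsne"),
                             dim = 2L, k_neighbors = 10L, perplexity = 30,
                             seed = 1L, max_iter = NULL, tol = 1e-9) {
  method <- match.arg(method)
  if (is.null(max_iter)) max_iter <- if (method == "tsne") 1000L else 300L
  stopifnot(dim >= 1L, k_neighbors >= 1L, perplexity > 0)
  structure(list(method = method, dim = as.integer(dim),
                 k_neighbors = as.integer(k_neighbors),
                 perplexity = perplexity, seed = as.integer(seed),
                 max_iter = as.integer(max_iter), tol = tol),
            class = "embedding_config")
}

check_dissimilarity <- function(S) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (!isTRUE(all.equal(S, t(S), check.attributes = FALSE,
                        tolerance = 1e-8))) {
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  }
  invisible(S)
}

# Raw stress of a configuration against target dissimilarities.
mds_stress <- function(S, X) {
  d <- as.matrix(dist(X))
  sum((S[upper.tri(S)] - d[upper.tri(d)])^2)
}

# SMACOF majorization: minimizes raw stress by repeated Guttman transforms,
# which guarantee a non-increasing stress sequence.
smacof_engine <- function(S, dim, seed, max_iter, tol, init = NULL) {
  n <- nrow(S)
  if (is.null(init)) {
    # Torgerson (classical scaling) start, with a seeded random fallback when
    # the double-centered matrix is rank-deficient for the requested dim.
    init <- suppressWarnings(cmdscale(S, k = min(dim, n - 1L)))
    if (!is.matrix(init)) init <- matrix(init, nrow = n)
    if (ncol(init) < dim || anyNA(init)) {
      extra <- withr_seed(seed, matrix(rnorm(n * dim, sd = 1e-4), n, dim))
      pad <- matrix(0, n, dim)
      if (ncol(init) > 0) pad[, seq_len(ncol(init))] <- init
      init <- pad + extra
    }
  }
  X <- init
  dmat <- as.matrix(dist(X))
  stress <- numeric(0)
  s_old <- sum((S[upper.tri(S)] - dmat[upper.tri(dmat)])^2)
  for (it in seq_len(max_iter)) {
    ratio <- ifelse(dmat > 0, S / dmat, 0)
    diag(ratio) <- 0
    B <- -ratio
    diag(B) <- rowSums(ratio)
    X <- B %*% X / n
    dmat <- as.matrix(dist(X))
    s_new <- sum((S[upper.tri(S)] - dmat[upper.tri(dmat)])^2)
    stress <- c(stress, s_new)
    if (s_old - s_new < tol * max(s_old, .Machine$double.eps)) break
    s_old <- s_new
  }
  attr(X, "stress") <- stress
  X
}

finalize_embedding <- function(X, S, method) {
  rownames(X) <- rownames(S)
  if (any(!is.finite(X))) stop("embedding produced non-finite coordinates",
                               call. = FALSE)
  attr(X, "method") <- method
  X
}

#' Metric MDS embedding by SMACOF
#'
#' Minimizes the raw stress (sum of squared differences between the input
#' dissimilarities and the embedded Euclidean distances) by iterative
#' majorization. The stress sequence, available as `attr(x, "stress")`, is
#' non-increasing by construction.
#'
#' @param S symmetric dissimilarity matrix.
#' @param cfg an [embedding_config()].
#' @return N×d coordinate matrix; rows follow the row order of `S`.
#' @export
embed_mds <- function(S, cfg = embedding_config("mds")) {
  check_dissimilarity(S)
  X <- smacof_engine(S, cfg$dim, cfg$seed, cfg$max_iter, cfg$tol)
  finalize_embedding(X, S, "mds")
}

# k-nearest-neighbor graph on a dissimilarity matrix, symmetrized by union.
# Returns the weighted adjacency with NA marking absent edges.
knn_graph <- function(S, k) {
  n <- nrow(S)
  k <- min(k, n - 1L)
  A <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    ord <- order(S[i, -i])[seq_len(k)]
    nb <- seq_len(n)[-i][ord]
    A[i, nb] <- S[i, nb]
  }
  # union symmetrization: keep an edge if either endpoint selected it
  sym <- pmin(A, t(A), na.rm = TRUE)
  sym
}

# Connected components of an adjacency pattern (non-NA = edge).
graph_components <- function(A) {
  n <- nrow(A)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(!is.na(A[v, ]) & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Geodesic distances on a k-nearest-neighbor graph
#'
#' Builds the union-symmetrized kNN graph over the dissimilarity matrix and
#' computes all-pairs shortest-path (geodesic) distances with the
#' Floyd–Warshall algorithm.
#'
#' @param S symmetric dissimilarity matrix.
#' @param k neighborhood size.
#' @return Symmetric geodesic distance matrix.
#' @export
geodesic_distances <- function(S, k) {
  check_dissimilarity(S)
  A <- knn_graph(S, k)
  comp <- graph_components(A)
  if (max(comp) > 1L) {
    stop(sprintf(
      "kNN graph is disconnected (%d components); increase k_neighbors",
      max(comp)), call. = FALSE)
  }
  G <- ifelse(is.na(A), Inf, A)
  diag(G) <- 0
  n <- nrow(G)
  for (m in seq_len(n)) {
    G <- pmin(G, outer(G[, m], G[m, ], "+"))
  }
  dimnames(G) <- dimnames(S)
  G
}

#' ISOMAP embedding
#'
#' Replaces the input dissimilarities with geodesic distances along the
#' k-nearest-neighbor graph ([geodesic_distances()]), then embeds the
#' geodesic matrix by the same stress-minimizing SMACOF iteration as
#' [embed_mds()].
#'
#' @inheritParams embed_mds
#' @return N×d coordinate matrix.
#' @export
embed_isomap <- function(S, cfg = embedding_config("isomap")) {
  check_dissimilarity(S)
  G <- geodesic_distances(S, cfg$k_neighbors)
  X <- smacof_engine(G, cfg$dim, cfg$seed, cfg$max_iter, cfg$tol)
  attr(X, "geodesics") <- G
  finalize_embedding(X, S, "isomap")
}

#' Spectral embedding (Laplacian eigenmaps)
#'
#' Builds the union-symmetrized kNN adjacency (unit edge weights), forms the
#' symmetric normalized graph Laplacian, and returns the coordinates given by
#' the eigenvectors of the d smallest nonzero eigenvalues (mapped back
#' through the degree normalization). Eigenvector signs are fixed so the
#' result is deterministic.
#'
#' @inheritParams embed_mds
#' @return N×d coordinate matrix.
#' @export
embed_spectral <- function(S, cfg = embedding_config("spectral")) {
  check_dissimilarity(S)
  A <- knn_graph(S, cfg$k_neighbors)
  comp <- graph_components(A)
  if (max(comp) > 1L) {
    stop(sprintf(
      "kNN graph is disconnected (%d components); increase k_neighbors",
      max(comp)), call. = FALSE)
  }
  W <- ifelse(is.na(A), 0, 1)
  diag(W) <- 0
  deg <- rowSums(W)
  dinv <- 1 / sqrt(pmax(deg, .Machine$double.eps))
  Lsym <- diag(nrow(W)) - (dinv * W) %*% diag(dinv)
  Lsym <- (Lsym + t(Lsym)) / 2
  eig <- eigen(Lsym, symmetric = TRUE)
  ord <- order(eig$values)             # ascending
  take <- ord[seq(2L, 1L + cfg$dim)]   # skip the trivial constant mode
  U <- eig$vectors[, take, drop = FALSE]
  Y <- dinv * U
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(Y))) {
    piv <- which.max(abs(Y[, j]))
    if (Y[piv, j] < 0) Y[, j] <- -Y[, j]
  }
  finalize_embedding(Y, S, "spectral")
}

#' t-SNE embedding of a precomputed dissimilarity matrix
#'
#' Exact t-SNE: input-space joint probabilities use a Gaussian kernel on the
#' (squared) dissimilarities with per-point bandwidths calibrated by binary
#' search to the target perplexity; the embedded space uses the Student-t
#' kernel. Optimized by gradient descent with momentum and early
#' exaggeration. Deterministic given `cfg$seed`.
#'
#' @inheritParams embed_mds
#' @return N×d coordinate matrix.
#' @export
embed_tsne <- function(S, cfg = embedding_config("tsne")) {
  check_dissimilarity(S)
  n <- nrow(S)
  if (cfg$perplexity >= n) {
    stop("perplexity must be smaller than the number of points",
         call. = FALSE)
  }
  P <- tsne_joint_probabilities(S, cfg$perplexity)
  max_iter <- max(cfg$max_iter, 250L)
  exaggeration_stop <- min(100L, max_iter %/% 2L)
  Y <- withr_seed(cfg$seed, matrix(rnorm(n * cfg$dim, sd = 1e-4), n, cfg$dim))
  gain <- matrix(1, n, cfg$dim)
  inc <- matrix(0, n, cfg$dim)
  eta <- max(n / 48, 50)  # the "auto" learning-rate heuristic
  Pex <- P * 12
  for (it in seq_len(max_iter)) {
    Puse <- if (it <= exaggeration_stop) Pex else P
    sq <- rowSums(Y^2)
    num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    PQ <- (Puse - Q) * num
    grad <- 4 * (diag(rowSums(PQ)) - PQ) %*% Y
    momentum <- if (it <= exaggeration_stop) 0.5 else 0.8
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- momentum * inc - eta * gain * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  finalize_embedding(Y, S, "tsne")
}

# Symmetrized joint probabilities from a distance matrix, per-point Gaussian
# bandwidth found by binary search on the conditional-distribution entropy.
tsne_joint_probabilities <- function(S, perplexity) {
  n <- nrow(S)
  D2 <- S^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in seq_len(64)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { H <- 0; p <- rep(0, length(w)) }
      else {
        p <- w / sw
        H <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      diff <- H - target
      if (abs(diff) < 1e-5) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.xmin)
}

#' Embed a dissimilarity matrix
#'
#' Dispatcher over the four embedding methods; see [embed_mds()],
#' [embed_isomap()], [embed_spectral()], [embed_tsne()].
#'
#' @param S symmetric dissimilarity matrix.
#' @param cfg an [embedding_config()]; `cfg$method` selects the method.
#' @return N×d coordinate matrix with `attr(,"method")` set.
#' @export
embed_dissimilarity <- function(S, cfg = embedding_config()) {
  switch(cfg$method,
         mds = embed_mds(S, cfg),
         isomap = embed_isomap(S, cfg),
         spectral = embed_spectral(S, cfg),
         tsne = embed_tsne(S, cfg))
}
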