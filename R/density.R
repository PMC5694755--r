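#' Build the shared discretization grid over the embedded space
#'
#' The grid must be built from the union of ALL samples' embedded points so
#' that every sample's density lives on the same support. Each axis is padded
#' by a tenth of its observed span on both sides:
#' range `[min - (max - min)/10, max + (max - min)/10]`, divided into `bins`
#' equal-width bins.
#'
#' @param points N×d coordinate matrix (the full embedding).
#' @param bins number of bins per axis (default 400).
#' @return An object of class `embed_grid`: list with `edges` (per-axis bin
#'   edges), `centers` (per-axis bin centers), `bins`, `dim`.
#' @export
make_grid <- function(points, bins = 400L) {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 2L, bins >= 2L)
  d <- ncol(points)
  if (bins^d > 5e6) {
    stop("grid too large: bins^dim exceeds 5e6 cells", call. = FALSE)
  }
  edges <- vector("list", d)
  centers <- vector("list", d)
  for (k in seq_len(d)) {
    lo <- min(points[, k]); hi <- max(points[, k])
    if (hi - lo <= 0) {
      stop(sprintf("degenerate range on axis %d: all points identical", k),
           call. = FALSE)
    }
    pad <- (hi - lo) / 10
    e <- seq(lo - pad, hi + pad, length.out = bins + 1L)
    edges[[k]] <- e
    centers[[k]] <- (e[-1] + e[-length(e)]) / 2
  }
  structure(list(edges = edges, centers = centers, bins = as.integer(bins),
                 dim = d),
            class = "embed_grid")
}

# All bin centers as a (bins^d) x d matrix, first axis varying fastest.
grid_center_matrix <- function(grid) {
  as.matrix(expand.grid(grid$centers, KEEP.OUT.ATTRS = FALSE))
}

# Bin index per axis for each point: half-open [lo, hi) intervals, final bin
# closed. Errors if any point is outside the grid range.
grid_bin_index <- function(grid, points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == grid$dim)
  idx <- matrix(0L, nrow(points), grid$dim)
  for (k in seq_len(grid$dim)) {
    e <- grid$edges[[k]]
    if (any(points[, k] < e[1] | points[, k] > e[length(e)])) {
      stop("point outside grid range; build the grid from all samples' points",
           call. = FALSE)
    }
    i <- findInterval(points[, k], e, rightmost.closed = TRUE,
                      left.open = FALSE)
    idx[, k] <- pmin(i, grid$bins)
  }
  # flatten to a single linear index, first axis fastest
  lin <- idx[, 1]
  if (grid$dim > 1) {
    for (k in 2:grid$dim) lin <- lin + (idx[, k] - 1L) * grid$bins^(k - 1L)
  }
  lin
}

# Normalization constant of the d-dimensional exponential kernel
# exp(-r / h): integral over R^d equals S_{d-1} * h^d * Gamma(d).
exp_kernel_norm <- function(h, d) {
  (2 * pi^(d / 2) / gamma(d / 2)) * gamma(d) * h^d
}

#' Maximum-likelihood cross-validated bandwidth
#'
#' Selects the exponential-kernel bandwidth maximizing the summed held-out
#' log-likelihood over k folds. The default candidate ladder is log-spaced
#' over \[1e-2, 1e1\] times the median nearest-neighbor distance of the
#' points.
#'
#' @param points n×d coordinates of one sample.
#' @param candidates positive candidate bandwidths; `NULL` for the default
#'   ladder.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed controlling the fold assignment.
#' @param n_candidates size of the default ladder.
#' @return The selected bandwidth, with the candidate ladder and per-candidate
#'   log-likelihoods attached as attributes.
#' @export
optimize_bandwidth <- function(points, candidates = NULL, folds = 5L,
                               seed = 1L, n_candidates = 15L) {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- ncol(points)
  if (is.null(candidates)) {
    dmat <- as.matrix(dist(points))
    diag(dmat) <- Inf
    nn <- apply(dmat, 1, min)
    scale <- median(nn[is.finite(nn)])
    if (!is.finite(scale) || scale <= 0) scale <- max(dmat[is.finite(dmat)]) / n
    if (!is.finite(scale) || scale <= 0) scale <- 1
    candidates <- exp(seq(log(1e-2), log(1e1),
                          length.out = n_candidates)) * scale
  }
  if (any(candidates <= 0)) {
    stop("bandwidth candidates must be positive", call. = FALSE)
  }
  if (length(candidates) == 1L) return(candidates)
  folds <- min(folds, n)
  stopifnot(folds >= 2L || length(candidates) == 1L)
  fold_id <- withr_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  ll <- vapply(candidates, function(h) {
    tot <- 0
    for (f in seq_len(folds)) {
      test <- points[fold_id == f, , drop = FALSE]
      train <- points[fold_id != f, , drop = FALSE]
      if (nrow(train) == 0L || nrow(test) == 0L) next
      s <- .kernel_sum_cpp(test, train, rep(1, nrow(train)), h)
      dens <- s / (nrow(train) * exp_kernel_norm(h, d))
      tot <- tot + sum(log(pmax(dens, .Machine$double.xmin)))
    }
    tot
  }, numeric(1))
  best <- candidates[which.max(ll)]
  attr(best, "candidates") <- candidates
  attr(best, "loglik") <- ll
  best
}

#' Exponential-kernel density on a grid
#'
#' Estimates a sample's probability distribution over the shared grid: the
#' unnormalized density at each bin center is the weighted sum of
#' `exp(-||c - y_j|| / h)` over the sample's embedded points, then the bin
#' probabilities are normalized to sum to 1. With integer weights the result
#' is identical to duplicating each point `weight` times.
#'
#' @param points n×d coordinates of one sample (must lie inside the grid).
#' @param grid an [make_grid()] object built from all samples' points.
#' @param bandwidth positive kernel bandwidth.
#' @param weights optional non-negative per-point weights (e.g. read counts);
#'   default all 1.
#' @param sample_id label stored on the result.
#' @return An object of class `density_grid`: list with `prob` (numeric
#'   vector over bins, first axis fastest, summing to 1), `grid`,
#'   `bandwidth`, `sample_id`.
#' @export
estimate_pdf <- function(points, grid, bandwidth, weights = NULL,
                         sample_id = "sample") {
  stopifnot(inherits(grid, "embed_grid"), bandwidth > 0)
  points <- as.matrix(points)
  if (is.null(weights)) weights <- rep(1, nrow(points))
  stopifnot(length(weights) == nrow(points), all(weights >= 0))
  if (sum(weights) <= 0) stop("weights must not all be zero", call. = FALSE)
  grid_bin_index(grid, points)  # validates points are inside the grid
  centers <- grid_center_matrix(grid)
  s <- .kernel_sum_cpp(centers, points, as.numeric(weights),
                       as.numeric(bandwidth))
  p <- s / sum(s)
  structure(list(prob = p, grid = grid, bandwidth = as.numeric(bandwidth),
                 sample_id = sample_id),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("density_grid '%s': %d bins/axis, %d-D, bandwidth %.4g\n",
              x$sample_id, x$grid$bins, x$grid$dim, x$bandwidth))
  invisible(x)
}

# Plain-R brute-force kernel sum; reference for the compiled evaluation.
kernel_sum_ref <- function(eval_points, points, weights, h) {
  apply(as.matrix(eval_points), 1, function(c0) {
    r <- sqrt(rowSums(sweep(as.matrix(points), 2, c0)^2))
    sum(weights * exp(-r / h))
  })
}
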