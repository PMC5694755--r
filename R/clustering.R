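#' Ward agglomerative clustering of a sample-distance matrix
#'
#' Agglomerates the samples under Ward's minimum-variance criterion, applying
#' the Lance–Williams Ward update to the supplied distance matrix as-is (the
#' JSD matrix is not squared-Euclidean; the update is still well defined and
#' is the convention used for repertoire JSD matrices). Alternative linkages
#' are available for comparison.
#'
#' @param distances symmetric non-negative matrix with zero diagonal (e.g.
#'   from [pairwise_sample_jsd()]); dimnames are used as leaf labels.
#' @param linkage `"ward"` (default), `"average"`, or `"complete"`.
#' @return An `hclust` object (merge table, heights, labels).
#' @export
ward_linkage <- function(distances, linkage = c("ward", "average",
                                                "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(distances), nrow(distances) == ncol(distances),
            nrow(distances) >= 2L)
  if (!isTRUE(all.equal(distances, t(distances), check.attributes = FALSE))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(distances < 0)) {
    stop("distance matrix must be non-negative", call. = FALSE)
  }
  if (any(abs(diag(distances)) > 1e-12)) {
    stop("distance matrix must have zero diagonal", call. = FALSE)
  }
  method <- switch(linkage, ward = "ward.D", average = "average",
                   complete = "complete")
  hclust(as.dist(distances), method = method)
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the original pairwise distances and the
#' cophenetic (tree-implied) distances of the dendrogram — a diagnostic of
#' the distortion introduced by the hierarchical representation. Equals 1
#' for ultrametric inputs.
#'
#' @param distances the matrix the dendrogram was built from.
#' @param dendrogram an `hclust` object over the same samples.
#' @return Correlation in \[-1, 1\].
#' @export
cophenetic_correlation <- function(distances, dendrogram) {
  stopifnot(inherits(dendrogram, "hclust"))
  d0 <- as.dist(distances)
  if (length(d0) < 2L) {
    stop("cophenetic correlation is undefined for fewer than 3 samples",
         call. = FALSE)
  }
  dc <- cophenetic(dendrogram)
  if (sd(d0) == 0 || sd(dc) == 0) {
    stop("cophenetic correlation undefined: constant distances",
         call. = FALSE)
  }
  cor(as.vector(d0), as.vector(dc))
}

#' Linkage table of a dendrogram
#'
#' @param dendrogram an `hclust` object.
#' @return Data frame with one row per merge: the two merged cluster ids
#'   (negative = original sample index, positive = earlier merge), the merge
#'   height, and the size of the merged cluster.
#' @export
linkage_table <- function(dendrogram) {
  stopifnot(inherits(dendrogram, "hclust"))
  sizes <- integer(nrow(dendrogram$merge))
  count <- function(id) if (id < 0) 1L else sizes[id]
  for (r in seq_len(nrow(dendrogram$merge))) {
    sizes[r] <- count(dendrogram$merge[r, 1]) + count(dendrogram$merge[r, 2])
  }
  data.frame(left = dendrogram$merge[, 1], right = dendrogram$merge[, 2],
             height = dendrogram$height, size = sizes)
}

#' Newick export of a dendrogram
#'
#' @param dendrogram an `hclust` object.
#' @param path optional output file; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly if written to `path`).
#' @export
as_newick <- function(dendrogram, path = NULL) {
  stopifnot(inherits(dendrogram, "hclust"))
  phy <- ape::as.phylo(dendrogram)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
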