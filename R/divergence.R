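#' Jensen–Shannon divergence between two density grids
#'
#' Computes the JSD between two discretized distributions on the same grid,
#' together with its per-bin decomposition: the local divergence at bin x is
#' `0.5 * [P(x) log(P(x)/M(x)) + Q(x) log(Q(x)/M(x))]` with `M = (P + Q)/2`
#' and the convention `0 log 0 = 0`; the global JSD is the sum of the local
#' map. Symmetric in (P, Q), bounded by `log 2` (or 1 bit).
#'
#' @param P,Q [estimate_pdf()] objects on an identical grid.
#' @param base `"nats"` (natural log, default) or `"bits"` (log2).
#' @return An object of class `jsd_result`: list with `global` (numeric),
#'   `local` (per-bin vector), `pair` (the two sample ids), `base`.
#' @examples
#' # two-bin toy distributions: JSD((1,0), (0.5,0.5)) ~ 0.2158 nats
#' @export
jensen_shannon <- function(P, Q, base = c("nats", "bits")) {
  base <- match.arg(base)
  stopifnot(inherits(P, "density_grid"), inherits(Q, "density_grid"))
  if (!identical(P$grid$edges, Q$grid$edges)) {
    stop("density grids are defined on different grids", call. = FALSE)
  }
  local <- jsd_local(P$prob, Q$prob, base)
  structure(list(global = sum(local), local = local,
                 pair = c(P$sample_id, Q$sample_id), base = base),
            class = "jsd_result")
}

# Local JSD map of two probability vectors.
jsd_local <- function(p, q, base = "nats") {
  m <- (p + q) / 2
  lg <- if (base == "bits") log2 else log
  term <- function(a) ifelse(a > 0, a * lg(a / m), 0)
  0.5 * (term(p) + term(q))
}

#' @export
print.jsd_result <- function(x, ...) {
  cat(sprintf("JSD(%s, %s) = %.6f %s\n", x$pair[1], x$pair[2], x$global,
              x$base))
  invisible(x)
}

#' Pairwise-sample JSD matrix
#'
#' The symmetric matrix of global JSD values between all pairs of sample
#' densities — the inter-sample distance matrix fed to [ward_linkage()].
#'
#' @param pdfs list of [estimate_pdf()] objects on a common grid.
#' @param base see [jensen_shannon()].
#' @return Symmetric M×M matrix with zero diagonal, sample ids as dimnames.
#' @export
pairwise_sample_jsd <- function(pdfs, base = c("nats", "bits")) {
  base <- match.arg(base)
  stopifnot(is.list(pdfs), length(pdfs) >= 2L)
  M <- length(pdfs)
  ids <- vapply(pdfs, `[[`, character(1), "sample_id")
  out <- matrix(0, M, M, dimnames = list(ids, ids))
  for (i in seq_len(M - 1)) {
    for (j in (i + 1):M) {
      v <- jensen_shannon(pdfs[[i]], pdfs[[j]], base)$global
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  out
}

#' Sequences driving a pairwise repertoire difference
#'
#' Ranks grid bins by local JSD and selects the top fraction (default 1%) of
#' the bins with positive local divergence, ties at the cutoff included. The
#' sequences of either sample whose embedded points fall in the selected bins
#' are reported as contributing to the pairwise difference.
#'
#' @param result a [jensen_shannon()] result.
#' @param pointsA,pointsB embedded coordinates of the two samples' sequences
#'   (row names are the sequences), on the grid the densities were built on.
#' @param grid the shared [make_grid()] object.
#' @param top_frac fraction of positive-local-JSD bins to select (default
#'   0.01).
#' @return An object of class `contributing_set`: list with `bins` (selected
#'   bin indices), `cutoff` (local JSD at the selection threshold), and `A`,
#'   `B`: data frames (sequence, bin, local_jsd) for each sample.
#' @export
contributing_sequences <- function(result, pointsA, pointsB, grid,
                                   top_frac = 0.01) {
  stopifnot(inherits(result, "jsd_result"), inherits(grid, "embed_grid"),
            top_frac > 0, top_frac <= 1)
  pos <- which(result$local > 0)
  if (length(pos) == 0L) {
    return(structure(list(bins = integer(0), cutoff = NA_real_,
                          A = empty_contrib(), B = empty_contrib()),
                     class = "contributing_set"))
  }
  n_sel <- ceiling(top_frac * length(pos))
  ord <- pos[order(result$local[pos], decreasing = TRUE)]
  cutoff <- result$local[ord[n_sel]]
  sel <- pos[result$local[pos] >= cutoff]  # ties at the cutoff included
  pick <- function(points) {
    points <- as.matrix(points)
    bins <- grid_bin_index(grid, points)
    keep <- bins %in% sel
    data.frame(sequence = rownames(points)[keep], bin = bins[keep],
               local_jsd = result$local[bins[keep]],
               stringsAsFactors = FALSE)
  }
  structure(list(bins = sel, cutoff = cutoff,
                 A = pick(pointsA), B = pick(pointsB)),
            class = "contributing_set")
}

empty_contrib <- function() {
  data.frame(sequence = character(0), bin = integer(0),
             local_jsd = numeric(0), stringsAsFactors = FALSE)
}

#' @export
print.contributing_set <- function(x, ...) {
  cat(sprintf("contributing_set: %d bins, %d + %d sequences\n",
              length(x$bins), nrow(x$A), nrow(x$B)))
  invisible(x)
}

#' Bootstrap significance threshold for a sample's density
#'
#' Resamples point locations from the naive density's discrete bin
#' distribution (`n_points` draws, matching the sample's observed read
#' count), re-estimates the density by KDE from the resampled points with
#' the naive bandwidth, and records the JSD between the naive and
#' re-estimated densities. Repeating `n_boot` times yields a null
#' distribution of sampling-noise JSDs; its 99th percentile (linear
#' interpolation between order statistics) is the one-sided 99% threshold —
#' a pairwise naive JSD exceeding it is significant at the 1% level.
#'
#' @param pdf_naive an [estimate_pdf()] result.
#' @param n_points number of points to resample per replicate (the sample's
#'   total read count in the standard procedure).
#' @param n_boot number of bootstrap replicates (default 100).
#' @param seed integer seed.
#' @param percentile threshold percentile (default 99).
#' @param jitter logical; draw points uniformly within the selected bin
#'   rather than exactly at its center (default TRUE, avoiding coincident
#'   points).
#' @param base see [jensen_shannon()].
#' @return An object of class `bootstrap_result`: list with `jsd_samples`,
#'   `threshold`, `percentile`, `n_points`, `n_boot`.
#' @export
bootstrap_significance <- function(pdf_naive, n_points, n_boot = 100L,
                                   seed = 1L, percentile = 99,
                                   jitter = TRUE, base = c("nats", "bits")) {
  base <- match.arg(base)
  stopifnot(inherits(pdf_naive, "density_grid"), n_points >= 1)
  if (n_boot < 2L) stop("`n_boot` must be >= 2", call. = FALSE)
  grid <- pdf_naive$grid
  centers <- grid_center_matrix(grid)
  widths <- vapply(grid$edges, function(e) e[2] - e[1], numeric(1))
  n_points <- as.integer(round(n_points))
  jsds <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bins <- sample.int(length(pdf_naive$prob), n_points, replace = TRUE,
                         prob = pdf_naive$prob)
      pts <- centers[bins, , drop = FALSE]
      if (jitter) {
        for (k in seq_len(grid$dim)) {
          pts[, k] <- pts[, k] + runif(n_points, -widths[k] / 2,
                                       widths[k] / 2)
        }
      }
      pdf_boot <- estimate_pdf(pts, grid, pdf_naive$bandwidth,
                               sample_id = "boot")
      jensen_shannon(pdf_naive, pdf_boot, base)$global
    }, numeric(1))
  })
  structure(list(jsd_samples = jsds,
                 threshold = unname(quantile(jsds, percentile / 100,
                                             type = 7)),
                 percentile = percentile, n_points = n_points,
                 n_boot = as.integer(n_boot)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "bootstrap_result: %d replicates of %d points, %g%% threshold %.6g\n",
    x$n_boot, x$n_points, x$percentile, x$threshold))
  invisible(x)
}

#' Position frequency matrix of equal-length sequences
#'
#' Relative frequency of each canonical amino acid at each position over a
#' set of equal-length sequences — the numeric content of a sequence logo.
#' Group sequences by length before calling.
#'
#' @param sequences non-empty character vector of equal-length amino-acid
#'   sequences.
#' @return L×20 matrix (positions × residues); each row sums to 1.
#' @export
position_frequency_matrix <- function(sequences) {
  stopifnot(length(sequences) >= 1L)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("sequences have mixed lengths; group by length before computing position frequencies",
         call. = FALSE)
  }
  L <- lens[1]
  chars <- do.call(rbind, strsplit(sequences, ""))
  bad <- setdiff(unique(as.vector(chars)), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue '%s'", bad[1]), call. = FALSE)
  }
  out <- t(vapply(seq_len(L), function(p) {
    tab <- table(factor(chars[, p], levels = AA_ALPHABET))
    as.numeric(tab) / length(sequences)
  }, numeric(length(AA_ALPHABET))))
  dimnames(out) <- list(position = seq_len(L), residue = AA_ALPHABET)
  out
}
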