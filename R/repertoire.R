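#' Construct a repertoire
#'
#' A repertoire is a sample's collection of unique CDR3 amino-acid sequences
#' (clonotypes) together with their observed read counts. Rows with identical
#' sequences are merged by summing their counts; sequences must use the
#' canonical 20-letter amino-acid alphabet (uppercase) and counts must be
#' positive integers.
#'
#' @param sequences character vector of CDR3 amino-acid sequences.
#' @param counts integer vector of read counts, one per sequence.
#' @param sample_id sample label.
#' @return An object of class `repertoire`: a list with elements `sample_id`,
#'   `sequences` (unique, in first-appearance order), `counts`, and
#'   `total_reads`.
#' @examples
#' rep <- repertoire(c("CAAS", "CAAT", "CAAS"), c(5, 3, 2), "S1")
#' rep$counts          # CAAS merged to 7
#' total_reads(rep)    # 10
#' @export
repertoire <- function(sequences, counts, sample_id = "sample") {
  if (length(sequences) == 0L) {
    stop("repertoire has no clonotypes (empty table)", call. = FALSE)
  }
  if (length(sequences) != length(counts)) {
    stop("`sequences` and `counts` must have equal length", call. = FALSE)
  }
  sequences <- as.character(sequences)
  bad <- which(!grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"),
                      sequences))
  if (length(bad) > 0L) {
    stop(sprintf(
      "non-canonical residue in sequence at row %d: '%s' (only the 20 canonical uppercase amino-acid letters are allowed)",
      bad[1], sequences[bad[1]]), call. = FALSE)
  }
  counts_num <- suppressWarnings(as.numeric(counts))
  if (anyNA(counts_num) || any(counts_num < 1) ||
      any(counts_num != round(counts_num))) {
    bad <- which(is.na(counts_num) | counts_num < 1 |
                 counts_num != round(counts_num))[1]
    stop(sprintf("count at row %d is not a positive integer: '%s'",
                 bad, as.character(counts[bad])), call. = FALSE)
  }
  merged <- tapply(counts_num, factor(sequences, levels = unique(sequences)),
                   sum)
  structure(
    list(sample_id = as.character(sample_id),
         sequences = names(merged),
         counts = as.numeric(merged),
         total_reads = sum(as.numeric(merged))),
    class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("repertoire '%s': %d unique sequences, %d reads\n",
              x$sample_id, length(x$sequences), as.integer(x$total_reads)))
  invisible(x)
}

#' Total read count of a repertoire
#' @param rep a [repertoire()].
#' @return Sum of clonotype counts.
#' @export
total_reads <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  rep$total_reads
}

#' Read a clonotype table
#'
#' Reads a tab-separated clonotype table into a [repertoire()]. Two column
#' dialects are supported: `"simple"` (columns `sequence` and `count`) and
#' `"mixcr"` (a MiXCR-style export; the amino-acid CDR3 and clone-count column
#' headers are configurable because they differ between MiXCR versions).
#' Duplicate sequences are merged by summing counts.
#'
#' @param path path to a tab-separated file with a header row.
#' @param dialect `"simple"` or `"mixcr"`.
#' @param sample_id sample label; defaults to the file name without extension.
#' @param seq_col,count_col column names used by the `"mixcr"` dialect.
#' @return A [repertoire()].
#' @export
read_clonotype_table <- function(path, dialect = c("simple", "mixcr"),
                                 sample_id = NULL,
                                 seq_col = "aaSeqCDR3",
                                 count_col = "cloneCount") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  cols <- if (dialect == "simple") c("sequence", "count") else
    c(seq_col, count_col)
  missing_cols <- setdiff(cols, names(tab))
  if (length(missing_cols) > 0L) {
    stop(sprintf("column '%s' missing from %s (dialect '%s')",
                 missing_cols[1], path, dialect), call. = FALSE)
  }
  repertoire(tab[[cols[1]]], tab[[cols[2]]], sample_id = sample_id)
}

#' Write a repertoire as a simple-dialect clonotype table
#'
#' @param rep a [repertoire()].
#' @param path output path; a tab-separated table with columns `sequence` and
#'   `count` is written.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(rep, path) {
  stopifnot(inherits(rep, "repertoire"))
  write.table(data.frame(sequence = rep$sequences, count = rep$counts),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subsample a repertoire to a target read depth
#'
#' Draws `n_target` reads from the repertoire's relative clone frequencies —
#' the inverse-CDF construction: uniform variates are mapped through the
#' cumulative relative frequency distribution of the observed unique
#' sequences, equivalent to a multinomial draw. Clones with zero drawn count
#' are dropped, so the result contains observed sequences only.
#'
#' @param rep a [repertoire()].
#' @param n_target target total read count (≥ 1).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return A [repertoire()] with `total_reads == n_target`.
#' @export
subsample_repertoire <- function(rep, n_target, seed = 1L) {
  stopifnot(inherits(rep, "repertoire"))
  if (!is.numeric(n_target) || length(n_target) != 1L || n_target < 1) {
    stop("`n_target` must be a single integer >= 1", call. = FALSE)
  }
  n_target <- as.integer(round(n_target))
  probs <- rep$counts / rep$total_reads
  drawn <- withr_seed(seed, {
    as.vector(rmultinom(1L, size = n_target, prob = probs))
  })
  keep <- drawn > 0L
  repertoire(rep$sequences[keep], drawn[keep], sample_id = rep$sample_id)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Equalize read depth across repertoires
#'
#' Subsamples every repertoire to the minimum total read count among the
#' inputs. The repertoire already at the minimum depth is passed through
#' unchanged; the others are redrawn from their relative clone frequencies
#' (see [subsample_repertoire()]).
#'
#' @param reps list of at least two [repertoire()] objects.
#' @param seed integer seed; per-sample sub-seeds are derived from it.
#' @return List of repertoires, all with equal `total_reads`.
#' @export
equalize_read_depth <- function(reps, seed = 1L) {
  if (!is.list(reps) || length(reps) < 2L) {
    stop("`reps` must be a list of >= 2 repertoires", call. = FALSE)
  }
  stopifnot(all(vapply(reps, inherits, logical(1), "repertoire")))
  depths <- vapply(reps, total_reads, numeric(1))
  n_min <- min(depths)
  lapply(seq_along(reps), function(i) {
    if (depths[i] == n_min) reps[[i]]
    else subsample_repertoire(reps[[i]], n_min,
                              seed = as.integer(seed) + i)
  })
}

#' Fraction of unique sequences shared between two repertoires
#'
#' The number of distinct sequences present in both samples over the number
#' of distinct sequences in their union.
#'
#' @param repA,repB [repertoire()] objects.
#' @return List with `fraction`, `n_shared`, `n_union`.
#' @examples
#' a <- repertoire(c("CAAS", "CAAT"), c(1, 1), "A")
#' b <- repertoire(c("CAAT", "CAAW"), c(1, 1), "B")
#' overlap_fraction(a, b)  # 1 shared of 3 -> 1/3
#' @export
overlap_fraction <- function(repA, repB) {
  stopifnot(inherits(repA, "repertoire"), inherits(repB, "repertoire"))
  shared <- intersect(repA$sequences, repB$sequences)
  uni <- union(repA$sequences, repB$sequences)
  list(fraction = length(shared) / length(uni),
       n_shared = length(shared),
       n_union = length(uni))
}

#' Bray–Curtis dissimilarity between two repertoires
#'
#' The count-based ecological baseline: `1 - 2 * C / (N_A + N_B)` where `C`
#' is the summed minimum count over shared sequences and `N` the total reads.
#'
#' @param repA,repB [repertoire()] objects.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(repA, repB) {
  stopifnot(inherits(repA, "repertoire"), inherits(repB, "repertoire"))
  shared <- intersect(repA$sequences, repB$sequences)
  C <- sum(pmin(repA$counts[match(shared, repA$sequences)],
                repB$counts[match(shared, repB$sequences)]))
  1 - 2 * C / (repA$total_reads + repB$total_reads)
}
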