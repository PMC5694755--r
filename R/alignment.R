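# Cache of parsed score tables, keyed by matrix name.
.matrix_cache <- new.env(parent = emptyenv())

#' Load a bundled amino-acid substitution matrix
#'
#' Ten standard NCBI score tables are bundled as pinned plain-text copies:
#' PAM30, PAM100, PAM120, PAM160, PAM250, BLOSUM45, BLOSUM50, BLOSUM62,
#' BLOSUM80, and BLOSUM100. Only the 20 canonical amino acids are retained
#' (ambiguity codes and stop are dropped).
#'
#' @param name matrix name, e.g. `"BLOSUM62"`.
#' @return A symmetric 20×20 integer matrix with the canonical residues as
#'   dimnames.
#' @examples
#' m <- substitution_matrix("BLOSUM62")
#' m["A", "A"]  # 4
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  name <- toupper(name)
  allowed <- c("PAM30", "PAM100", "PAM120", "PAM160", "PAM250",
               "BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100")
  if (!name %in% allowed) {
    stop(sprintf("unknown substitution matrix '%s'; available: %s",
                 name, paste(allowed, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(.matrix_cache[[name]])) return(.matrix_cache[[name]])
  path <- system.file("extdata", "matrices", paste0(name, ".txt"),
                      package = "recold", mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  labs <- vapply(rows, `[`, character(1), 1)
  vals <- t(vapply(rows, function(r) as.integer(r[-1]),
                   integer(length(header))))
  dimnames(vals) <- list(labs, header)
  m <- vals[AA_ALPHABET, AA_ALPHABET]
  storage.mode(m) <- "integer"
  stopifnot(isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
  .matrix_cache[[name]] <- m
  m
}

#' Alignment parameter set
#'
#' Bundles a substitution matrix with affine gap penalties. The defaults
#' (BLOSUM62, gap open 10, gap extend 1) are the standard settings for CDR3
#' comparison. Two affine-gap conventions are supported: the striped-SW
#' convention in which a gap of length L costs `open + (L-1)*extend`
#' (default), and the alternative `open + L*extend`.
#'
#' @param matrix matrix name passed to [substitution_matrix()], or a 20×20
#'   score matrix with residue dimnames.
#' @param gap_open non-negative gap opening penalty.
#' @param gap_extend non-negative gap extension penalty.
#' @param first_residue_full_open logical; see Description.
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 10L,
                             gap_extend = 1L,
                             first_residue_full_open = TRUE) {
  if (is.character(matrix)) {
    name <- toupper(matrix)
    matrix <- substitution_matrix(matrix)
  } else {
    name <- "custom"
    stopifnot(is.matrix(matrix),
              identical(rownames(matrix), AA_ALPHABET),
              identical(colnames(matrix), AA_ALPHABET))
  }
  if (gap_open < 0 || gap_extend < 0) {
    stop("gap penalties must be non-negative", call. = FALSE)
  }
  structure(list(matrix_name = name, scores = matrix,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 first_residue_full_open = isTRUE(first_residue_full_open)),
            class = "alignment_params")
}

# Encode amino-acid strings as 0-based integer vectors; errors on
# non-canonical residues.
encode_aa <- function(sequences) {
  lapply(sequences, function(s) {
    idx <- match(strsplit(s, "")[[1]], AA_ALPHABET)
    if (anyNA(idx)) {
      stop(sprintf("invalid residue in sequence '%s'", s), call. = FALSE)
    }
    idx - 1L
  })
}

#' Smith–Waterman local alignment score
#'
#' Maximum local-alignment score of two amino-acid sequences under an affine
#' gap model. Symmetric in its arguments and never negative (the empty local
#' alignment scores 0).
#'
#' @param a,b amino-acid sequences (canonical 20-letter alphabet).
#' @param params an [alignment_params()].
#' @return Non-negative integer score.
#' @examples
#' smith_waterman_score("AAAA", "AAAA")  # 16 under BLOSUM62
#' @export
smith_waterman_score <- function(a, b, params = alignment_params()) {
  stopifnot(inherits(params, "alignment_params"))
  enc <- encode_aa(c(a, b))
  .sw_score_cpp(enc[[1]], enc[[2]], params$scores,
                params$gap_open, params$gap_extend,
                params$first_residue_full_open)
}

#' Pairwise Smith–Waterman score matrix
#'
#' Computes the full symmetric matrix of local-alignment scores over a list
#' of unique sequences (upper triangle computed and mirrored). The diagonal
#' holds self-alignment scores, which depend on sequence length — the reason
#' the scores are subsequently length-adjusted by
#' [dissimilarity_from_scores()].
#'
#' @param sequences character vector of unique amino-acid sequences.
#' @param params an [alignment_params()].
#' @return Symmetric numeric matrix with the sequences as dimnames.
#' @export
pairwise_score_matrix <- function(sequences, params = alignment_params()) {
  stopifnot(inherits(params, "alignment_params"))
  if (length(sequences) < 2L) {
    stop("need at least 2 sequences", call. = FALSE)
  }
  if (anyDuplicated(sequences)) {
    stop("`sequences` contains duplicates; deduplicate before scoring",
         call. = FALSE)
  }
  enc <- encode_aa(sequences)
  D <- .sw_matrix_cpp(enc, params$scores, params$gap_open,
                      params$gap_extend, params$first_residue_full_open)
  dimnames(D) <- list(sequences, sequences)
  D
}

#' Length-adjusted dissimilarity from a score matrix
#'
#' Converts pairwise local-alignment scores into a dissimilarity:
#' `S[i,j] = 1 - 2 * D[i,j] / (D[i,i] + D[j,j])`. Self-alignment scores grow
#' with sequence length, so the raw scores conflate similarity with length;
#' dividing twice the cross-score by the sum of the two self-scores removes
#' this length effect. Identical sequences map to 0; pairs with no
#' positively-scoring local alignment map to 1.
#'
#' @param D symmetric score matrix from [pairwise_score_matrix()], with
#'   strictly positive diagonal.
#' @return Symmetric dissimilarity matrix with exact zero diagonal and
#'   entries ≤ 1.
#' @export
dissimilarity_from_scores <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (!isTRUE(all.equal(D, t(D), check.attributes = FALSE))) {
    stop("score matrix must be symmetric", call. = FALSE)
  }
  dg <- diag(D)
  if (any(dg <= 0)) {
    stop("zero self-alignment score: cannot length-normalize", call. = FALSE)
  }
  S <- 1 - 2 * D / outer(dg, dg, "+")
  diag(S) <- 0
  S <- (S + t(S)) / 2  # enforce exact symmetry against rounding
  S
}

#' Dissimilarity matrix for a set of repertoires
#'
#' Convenience wrapper: collects the union of unique sequences across the
#' repertoires, scores all pairs, and applies the length adjustment.
#'
#' @param reps list of [repertoire()] objects.
#' @param params an [alignment_params()].
#' @return List with `S` (dissimilarity matrix over the union of unique
#'   sequences), `sequences`, and `membership` (logical matrix, sequences ×
#'   samples).
#' @export
repertoire_dissimilarity <- function(reps, params = alignment_params()) {
  stopifnot(is.list(reps),
            all(vapply(reps, inherits, logical(1), "repertoire")))
  seqs <- unique(unlist(lapply(reps, `[[`, "sequences")))
  D <- pairwise_score_matrix(seqs, params)
  S <- dissimilarity_from_scores(D)
  membership <- vapply(reps, function(r) seqs %in% r$sequences,
                       logical(length(seqs)))
  if (is.null(dim(membership))) {
    membership <- matrix(membership, ncol = length(reps))
  }
  colnames(membership) <- vapply(reps, `[[`, character(1), "sample_id")
  rownames(membership) <- seqs
  list(S = S, sequences = seqs, membership = membership)
}
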