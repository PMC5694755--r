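#' Define a CDR3 motif family
#'
#' A family is a consensus template with designated variable positions,
#' mimicking CDR3 anatomy: a conserved N-terminal cysteine flank, a variable
#' central segment, and a conserved F/W-containing C-terminal flank.
#' Generated sequences substitute random residues at variable positions and
#' occasionally insert or delete a residue inside the variable span.
#'
#' @param consensus amino-acid template string (canonical alphabet).
#' @param variable integer positions allowed to vary (default: everything
#'   between the first residue and the last 6).
#' @param sub_rate per-position substitution probability at variable
#'   positions.
#' @param indel_prob probability of a single insertion or deletion inside the
#'   variable span.
#' @param name family label.
#' @return An object of class `motif_family`.
#' @export
motif_family <- function(consensus, variable = NULL, sub_rate = 0.5,
                         indel_prob = 0.1, name = consensus) {
  stopifnot(is.character(consensus), length(consensus) == 1L)
  chars <- strsplit(consensus, "")[[1]]
  if (!all(chars %in% AA_ALPHABET)) {
    stop("consensus contains non-canonical residues", call. = FALSE)
  }
  L <- length(chars)
  if (is.null(variable)) {
    variable <- if (L > 7L) seq(2L, L - 6L) else seq_len(L)
  }
  stopifnot(all(variable >= 1L & variable <= L),
            sub_rate >= 0, sub_rate <= 1, indel_prob >= 0, indel_prob <= 1)
  structure(list(consensus = consensus, variable = as.integer(variable),
                 sub_rate = sub_rate, indel_prob = indel_prob,
                 name = as.character(name)),
            class = "motif_family")
}

# One random draw from a family (RNG state of the caller).
draw_family_sequence <- function(fam) {
  chars <- strsplit(fam$consensus, "")[[1]]
  for (p in fam$variable) {
    if (runif(1) < fam$sub_rate) {
      chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1L)
    }
  }
  if (length(fam$variable) > 0 && runif(1) < fam$indel_prob) {
    span <- range(fam$variable)
    if (runif(1) < 0.5 && diff(span) >= 1) {
      drop_at <- sample(seq(span[1], min(span[2], length(chars))), 1L)
      chars <- chars[-drop_at]
    } else {
      at <- sample(seq(span[1], min(span[2], length(chars))), 1L)
      chars <- append(chars, sample(AA_ALPHABET, 1L), after = at)
    }
  }
  paste(chars, collapse = "")
}

# Pool of distinct sequences from one family. The pool aims for `target`
# sequences but tolerates exhausting a small sequence space as long as
# `required` (the actual per-sample demand) is met; otherwise it is a
# design error.
family_pool <- function(fam, target, required = target) {
  pool <- character(0)
  stagnant <- 0L
  while (length(pool) < target && stagnant < 30L) {
    before <- length(pool)
    batch <- replicate(max(target, 32L), draw_family_sequence(fam))
    pool <- unique(c(pool, batch))
    stagnant <- if (length(pool) > before) 0L else stagnant + 1L
  }
  if (length(pool) < required) {
    stop(sprintf(
      "family '%s' cannot supply %d unique sequences (sequence space too small)",
      fam$name, required), call. = FALSE)
  }
  pool[seq_len(min(target, length(pool)))]
}

#' Define a synthetic repertoire study design
#'
#' @param families list of [motif_family()] objects.
#' @param samples list of per-sample specifications, each a list with
#'   `sample_id`, `weights` (mixture weights over `families`, summing to 1),
#'   `n_unique` (number of unique sequences), and optionally `count_alpha`
#'   (power-law exponent of the clone-size distribution, default 2.5).
#' @param seed integer seed.
#' @param pool_factor family sequence pools are `pool_factor` times the
#'   maximum per-sample demand, so samples sharing a family overlap partially
#'   rather than identically.
#' @return An object of class `synthetic_design`.
#' @export
synthetic_design <- function(families, samples, seed = 1L,
                             pool_factor = 2) {
  stopifnot(is.list(families), length(families) >= 1L,
            all(vapply(families, inherits, logical(1), "motif_family")),
            is.list(samples), length(samples) >= 1L)
  for (s in samples) {
    stopifnot(!is.null(s$sample_id), !is.null(s$weights),
              length(s$weights) == length(families), !is.null(s$n_unique))
    if (abs(sum(s$weights) - 1) > 1e-9) {
      stop(sprintf("mixture weights of sample '%s' must sum to 1",
                   s$sample_id), call. = FALSE)
    }
  }
  structure(list(families = families, samples = samples,
                 seed = as.integer(seed), pool_factor = pool_factor),
            class = "synthetic_design")
}

#' Generate repertoires from a synthetic design
#'
#' Deterministic given the design seed. Each sample's unique sequences are
#' allocated to families by a multinomial draw over its mixture weights and
#' sampled without replacement from per-family pools shared across samples
#' (so samples with equal weights overlap partially). Clone counts follow a
#' discrete power law (`floor(u^(-1/(alpha-1)))`, capped at 10,000).
#'
#' @param design a [synthetic_design()].
#' @return List of [repertoire()] objects, with a `truth` attribute: a data
#'   frame (sample, sequence, family) recording the generating family of
#'   every sequence.
#' @export
generate_repertoires <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  withr_seed(design$seed, {
    n_fam <- length(design$families)
    # per-family demand: largest single-sample allocation times pool_factor
    demands <- matrix(0L, length(design$samples), n_fam)
    allocs <- vector("list", length(design$samples))
    for (i in seq_along(design$samples)) {
      s <- design$samples[[i]]
      allocs[[i]] <- as.vector(rmultinom(1L, s$n_unique, s$weights))
      demands[i, ] <- allocs[[i]]
    }
    pools <- lapply(seq_len(n_fam), function(f) {
      need <- max(demands[, f])
      if (need == 0L) return(character(0))
      family_pool(design$families[[f]],
                  target = ceiling(need * design$pool_factor),
                  required = need)
    })
    truth <- list()
    reps <- vector("list", length(design$samples))
    for (i in seq_along(design$samples)) {
      s <- design$samples[[i]]
      seqs <- character(0)
      fams <- character(0)
      for (f in seq_len(n_fam)) {
        k <- allocs[[i]][f]
        if (k == 0L) next
        picked <- sample(pools[[f]], k)
        seqs <- c(seqs, picked)
        fams <- c(fams, rep(design$families[[f]]$name, k))
      }
      # a sequence drawable from two families: keep first occurrence
      keep <- !duplicated(seqs)
      seqs <- seqs[keep]; fams <- fams[keep]
      alpha <- if (is.null(s$count_alpha)) 2.5 else s$count_alpha
      u <- runif(length(seqs))
      counts <- pmin(floor(u^(-1 / (alpha - 1))), 1e4)
      reps[[i]] <- repertoire(seqs, counts, sample_id = s$sample_id)
      truth[[i]] <- data.frame(sample = s$sample_id, sequence = seqs,
                               family = fams, stringsAsFactors = FALSE)
    }
    structure(reps, truth = do.call(rbind, truth))
  })
}

#' Two-sample design with a planted exclusive sub-repertoire
#'
#' Builds a design in which sample `"planted"` draws a fraction
#' `exclusivity` of its sequences from an exclusive family absent from the
#' base samples, while all samples share the base family — the fixture for
#' contributing-sequence recovery. `n_base_samples` base replicates are
#' included (default 2) so that an exchangeable null pair is available
#' alongside the divergent pair.
#'
#' @param base,exclusive [motif_family()] objects.
#' @param exclusivity fraction in (0, 1\] of the planted sample drawn from
#'   the exclusive family.
#' @param n_unique unique sequences per sample (default 200).
#' @param n_base_samples number of base-only samples (default 2).
#' @param seed integer seed.
#' @return A [synthetic_design()].
#' @export
planted_difference_design <- function(base, exclusive, exclusivity,
                                      n_unique = 200L, n_base_samples = 2L,
                                      seed = 1L) {
  stopifnot(inherits(base, "motif_family"),
            inherits(exclusive, "motif_family"))
  if (!(exclusivity > 0 && exclusivity <= 1)) {
    stop("`exclusivity` must be in (0, 1]", call. = FALSE)
  }
  samples <- c(
    list(list(sample_id = "planted",
              weights = c(1 - exclusivity, exclusivity),
              n_unique = n_unique)),
    lapply(seq_len(n_base_samples), function(i) {
      list(sample_id = paste0("base", i), weights = c(1, 0),
           n_unique = n_unique)
    }))
  synthetic_design(list(base, exclusive), samples, seed = seed)
}

#' Eight-sample design with a three-level planted hierarchy
#'
#' Emulates a study of two genetic backgrounds × two T-cell types × two
#' donor sites: backgrounds differ in the conserved C-terminal flank (large
#' divergence), cell types within a background differ in the central
#' consensus (moderate), and the two donor sites of a background/cell-type
#' combination draw from the same family pool (small, sampling-only
#' divergence).
#'
#' @param n_unique unique sequences per sample.
#' @param seed integer seed.
#' @return A [synthetic_design()] with 8 samples and a
#'   `hierarchy` attribute giving the planted partition at 2 and 4 clusters.
#' @export
hierarchical_design <- function(n_unique = 120L, seed = 1L) {
  suffixes <- c(A = "NYQLIWG", B = "SGKLTFG")
  mids <- c(N = "SAY", R = "GTD")
  fams <- list()
  samples <- list()
  for (bg in c("A", "B")) {
    for (ct in c("N", "R")) {
      fam_name <- paste0("bg", bg, "_ct", ct)
      consensus <- paste0("CAAS", mids[ct], suffixes[bg])
      fams[[fam_name]] <- motif_family(consensus,
                                       variable = 2:7,
                                       sub_rate = 0.45, indel_prob = 0.08,
                                       name = fam_name)
    }
  }
  fam_names <- names(fams)
  for (bg in c("A", "B")) {
    for (ct in c("N", "R")) {
      for (site in c("Thy", "Per")) {
        w <- as.numeric(fam_names == paste0("bg", bg, "_ct", ct))
        samples[[length(samples) + 1L]] <-
          list(sample_id = paste0(bg, ct, "_", site), weights = w,
               n_unique = n_unique)
      }
    }
  }
  design <- synthetic_design(unname(fams), samples, seed = seed)
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  attr(design, "hierarchy") <- list(
    level2 = substr(ids, 1, 1),
    level4 = substr(ids, 1, 2),
    sample_ids = ids)
  design
}

#' Serialize and restore a synthetic design
#'
#' @param design a [synthetic_design()].
#' @param path JSON file path.
#' @return `design_to_json` returns `path` invisibly; `design_from_json`
#'   returns the restored [synthetic_design()].
#' @export
design_to_json <- function(design, path) {
  stopifnot(inherits(design, "synthetic_design"))
  payload <- list(
    families = lapply(design$families, function(f) {
      list(consensus = f$consensus, variable = f$variable,
           sub_rate = f$sub_rate, indel_prob = f$indel_prob, name = f$name)
    }),
    samples = design$samples,
    seed = design$seed,
    pool_factor = design$pool_factor)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname design_to_json
#' @export
design_from_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  fams <- lapply(payload$families, function(f) {
    motif_family(f$consensus, variable = as.integer(f$variable),
                 sub_rate = f$sub_rate, indel_prob = f$indel_prob,
                 name = f$name)
  })
  samples <- lapply(payload$samples, function(s) {
    list(sample_id = s$sample_id, weights = as.numeric(s$weights),
         n_unique = as.integer(s$n_unique),
         count_alpha = s$count_alpha)
  })
  synthetic_design(fams, samples, seed = payload$seed,
                   pool_factor = payload$pool_factor)
}
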