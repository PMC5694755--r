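#' Pipeline configuration
#'
#' Collects every tunable of the five-stage analysis with the standard
#' defaults: BLOSUM62 with gap penalties 10/1, MDS embedding in two
#' dimensions (deterministic up to rigid motion), a 400-bin-per-axis grid,
#' 5-fold ML cross-validated bandwidth, top 1% contributing bins, 100
#' bootstrap replicates at the 99th percentile, and Ward linkage.
#'
#' @param matrix substitution matrix name.
#' @param gap_open,gap_extend affine gap penalties.
#' @param method embedding method (`"mds"`, `"tsne"`, `"isomap"`,
#'   `"spectral"`).
#' @param dim embedding dimensionality.
#' @param k_neighbors,perplexity embedding parameters.
#' @param bins grid bins per axis.
#' @param bandwidth fixed bandwidth overriding cross-validation, or `NULL`
#'   (default) to optimize per sample.
#' @param cv_folds bandwidth cross-validation folds.
#' @param weighted logical: weight KDE points by clone read counts.
#' @param top_frac fraction of positive local-JSD bins reported as
#'   contributing.
#' @param n_boot bootstrap replicates.
#' @param percentile bootstrap threshold percentile.
#' @param linkage clustering linkage.
#' @param equalize logical: equalize read depth across samples before
#'   analysis.
#' @param seed master seed; stage sub-seeds are derived from it.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(matrix = "BLOSUM62", gap_open = 10L,
                            gap_extend = 1L, method = "mds", dim = 2L,
                            k_neighbors = 10L, perplexity = 30,
                            bins = 400L, bandwidth = NULL, cv_folds = 5L,
                            weighted = FALSE, top_frac = 0.01,
                            n_boot = 100L, percentile = 99,
                            linkage = "ward", equalize = FALSE, seed = 1L) {
  cfg <- list(matrix = matrix, gap_open = as.integer(gap_open),
              gap_extend = as.integer(gap_extend), method = method,
              dim = as.integer(dim), k_neighbors = as.integer(k_neighbors),
              perplexity = perplexity, bins = as.integer(bins),
              bandwidth = bandwidth, cv_folds = as.integer(cv_folds),
              weighted = isTRUE(weighted), top_frac = top_frac,
              n_boot = as.integer(n_boot), percentile = percentile,
              linkage = linkage, equalize = isTRUE(equalize),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as flat key=value text
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns the restored [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, " = ", if (is.null(v)) "" else as.character(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- lapply(kv, function(x) if (length(x) < 2L) "" else x[2])
  base <- pipeline_config()
  for (i in seq_along(keys)) {
    k <- trimws(keys[i]); v <- trimws(vals[[i]])
    if (!k %in% names(base)) next
    base[k] <- list(
      if (v == "") NULL
      else if (k %in% c("matrix", "method", "linkage")) v
      else if (k %in% c("weighted", "equalize")) as.logical(v)
      else if (k %in% c("perplexity", "top_frac", "percentile", "bandwidth"))
        as.numeric(v)
      else as.integer(v))
  }
  class(base) <- "pipeline_config"
  base
}

#' Run the full repertoire-comparison pipeline
#'
#' Executes the five stages — alignment dissimilarity, embedding, per-sample
#' KDE, pairwise JSD with contributing sequences and bootstrap significance,
#' and Ward clustering — and writes all artifacts to `out_dir`:
#' `dissimilarity.tsv`, `coordinates.tsv`, `density_<sample>.tsv`,
#' `jsd_matrix.tsv`, `local_jsd_<A>__<B>.tsv`, `contributing_<A>__<B>.tsv`,
#' `bootstrap.tsv`, `significance.tsv`, `linkage.tsv`, `tree.nwk`, and a
#' `run_log.txt` with every effective parameter and seed.
#'
#' A sample pair is flagged significant when its naive JSD exceeds the
#' bootstrap thresholds of both of its samples.
#'
#' @param reps list of [repertoire()] objects (or paths readable by
#'   [read_clonotype_table()]).
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if needed; `NULL` skips writing.
#' @param write_local_maps logical; local-JSD grids can be large, so writing
#'   them is optional (default FALSE).
#' @return Invisibly, a list with elements `dissimilarity` (the
#'   [repertoire_dissimilarity()] result), `coords`, `grid`, `pdfs`,
#'   `bandwidths`, `jsd` (pairwise matrix), `jsd_results`, `contributing`,
#'   `bootstrap`, `significant` (logical matrix), `dendrogram`.
#' @export
run_pipeline <- function(reps, config = pipeline_config(), out_dir = NULL,
                         write_local_maps = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(reps)) {
    reps <- lapply(reps, read_clonotype_table)
  }
  stopifnot(is.list(reps), length(reps) >= 2L,
            all(vapply(reps, inherits, logical(1), "repertoire")))
  ids <- vapply(reps, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids", call. = FALSE)

  if (config$equalize) {
    reps <- equalize_read_depth(reps, seed = config$seed)
  }

  params <- alignment_params(config$matrix, config$gap_open,
                             config$gap_extend)
  dis <- repertoire_dissimilarity(reps, params)

  ecfg <- embedding_config(config$method, dim = config$dim,
                           k_neighbors = config$k_neighbors,
                           perplexity = config$perplexity,
                           seed = config$seed)
  coords <- embed_dissimilarity(dis$S, ecfg)

  grid <- make_grid(coords, bins = config$bins)

  pdfs <- vector("list", length(reps))
  bandwidths <- numeric(length(reps))
  sample_points <- vector("list", length(reps))
  for (i in seq_along(reps)) {
    pts <- coords[dis$membership[, i], , drop = FALSE]
    sample_points[[i]] <- pts
    h <- if (is.null(config$bandwidth)) {
      as.numeric(optimize_bandwidth(pts, folds = config$cv_folds,
                                    seed = config$seed + i))
    } else as.numeric(config$bandwidth)
    bandwidths[i] <- h
    w <- if (config$weighted) {
      reps[[i]]$counts[match(rownames(pts), reps[[i]]$sequences)]
    } else NULL
    pdfs[[i]] <- estimate_pdf(pts, grid, h, weights = w,
                              sample_id = ids[i])
  }

  jsd <- pairwise_sample_jsd(pdfs)
  M <- length(reps)
  jsd_results <- list()
  contributing <- list()
  for (i in seq_len(M - 1)) {
    for (j in (i + 1):M) {
      key <- paste0(ids[i], "__", ids[j])
      res <- jensen_shannon(pdfs[[i]], pdfs[[j]])
      jsd_results[[key]] <- res
      contributing[[key]] <- contributing_sequences(
        res, sample_points[[i]], sample_points[[j]], grid,
        top_frac = config$top_frac)
    }
  }

  # the bootstrap must mimic the estimator's own sampling noise: the
  # unweighted KDE is built from one point per unique sequence, the
  # count-weighted KDE from one point per read
  boots <- lapply(seq_along(reps), function(i) {
    n_pts <- if (config$weighted) total_reads(reps[[i]])
             else nrow(sample_points[[i]])
    bootstrap_significance(pdfs[[i]], n_points = n_pts,
                           n_boot = config$n_boot,
                           seed = config$seed + 1000L + i,
                           percentile = config$percentile)
  })
  names(boots) <- ids
  thresholds <- vapply(boots, `[[`, numeric(1), "threshold")
  significant <- jsd > outer(thresholds, thresholds, pmax)
  diag(significant) <- FALSE

  dend <- ward_linkage(jsd, linkage = config$linkage)

  out <- list(dissimilarity = dis, coords = coords, grid = grid,
              pdfs = pdfs, bandwidths = setNames(bandwidths, ids),
              jsd = jsd, jsd_results = jsd_results,
              contributing = contributing, bootstrap = boots,
              significant = significant, dendrogram = dend)

  if (!is.null(out_dir)) {
    write_pipeline_outputs(out, reps, config, out_dir, write_local_maps)
  }
  invisible(out)
}

write_pipeline_outputs <- function(out, reps, config, out_dir,
                                   write_local_maps) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(reps, `[[`, character(1), "sample_id")
  tsv <- function(x, name, rn = TRUE) {
    write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = rn, col.names = NA)
  }
  tsv(round(out$dissimilarity$S, 10), "dissimilarity.tsv")
  coords_tab <- data.frame(sequence = rownames(out$coords),
                           out$coords,
                           out$dissimilarity$membership + 0L,
                           check.names = FALSE)
  write.table(coords_tab, file.path(out_dir, "coordinates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (i in seq_along(out$pdfs)) {
    p <- out$pdfs[[i]]
    write.table(data.frame(bin = seq_along(p$prob), probability = p$prob),
                file.path(out_dir, paste0("density_", ids[i], ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tsv(out$jsd, "jsd_matrix.tsv")
  for (key in names(out$contributing)) {
    cs <- out$contributing[[key]]
    pair <- strsplit(key, "__")[[1]]
    tab <- rbind(
      if (nrow(cs$A)) cbind(sample = pair[1], cs$A) else NULL,
      if (nrow(cs$B)) cbind(sample = pair[2], cs$B) else NULL)
    if (is.null(tab)) {
      tab <- data.frame(sample = character(0), sequence = character(0),
                        bin = integer(0), local_jsd = numeric(0))
    }
    write.table(tab, file.path(out_dir, paste0("contributing_", key, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (write_local_maps) {
      res <- out$jsd_results[[key]]
      write.table(data.frame(bin = seq_along(res$local),
                             local_jsd = res$local),
                  file.path(out_dir, paste0("local_jsd_", key, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  boot_tab <- data.frame(
    sample = names(out$bootstrap),
    threshold = vapply(out$bootstrap, `[[`, numeric(1), "threshold"),
    n_points = vapply(out$bootstrap, `[[`, numeric(1), "n_points"),
    n_boot = vapply(out$bootstrap, `[[`, numeric(1), "n_boot"))
  write.table(boot_tab, file.path(out_dir, "bootstrap.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tsv(out$significant + 0L, "significance.tsv")
  write.table(linkage_table(out$dendrogram),
              file.path(out_dir, "linkage.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  as_newick(out$dendrogram, file.path(out_dir, "tree.nwk"))
  log_lines <- c(
    sprintf("recold %s", as.character(utils::packageVersion("recold"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("date %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("samples %s", paste(ids, collapse = ", ")),
    vapply(names(unclass(config)), function(k) {
      v <- config[[k]]
      sprintf("%s = %s", k, if (is.null(v)) "cross-validated"
              else as.character(v))
    }, character(1)),
    sprintf("bandwidth[%s] = %.8g", names(out$bandwidths), out$bandwidths))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
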