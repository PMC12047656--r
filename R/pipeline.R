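# End-to-end orchestration: count -> test -> mask -> merge -> sample ->
# transform -> embed.  A thin command-line wrapper over these functions is
# installed as exec/kmap.

#' Run configuration
#'
#' Defaults follow the method's standard settings: k from 5 to 16,
#' significance threshold 1e-10 on the Hamming-ball ratio p-value,
#' reverse-complement mode on, 5000 sampled points, 20 smoothing
#' neighbors, and the [embed_config()] defaults for the optimization.
#'
#' @param k_range Integer vector of k-mer lengths (within 1..16).
#' @param alpha Ratio p-value threshold in (0, 1).
#' @param rc_mode Reverse-complement (canonical) mode.
#' @param sample_n Number of sampled points for visualization.
#' @param n_neighbors Neighborhood size for distance smoothing.
#' @param embed An [embed_config()].
#' @param radius_overrides Optional named vector mapping k to a radius.
#' @param null_length,null_repeats Null-model simulation size.
#' @param max_motifs,top_n Per-k discovery loop controls.
#' @param seed Single top-level seed; all randomness (null fits, sampling,
#'   initialization, diffusion) derives from it.
#' @return An object of class `kmap_config`.
#' @export
kmap_config <- function(k_range = 5:16, alpha = 1e-10, rc_mode = TRUE,
                        sample_n = 5000, n_neighbors = 20,
                        embed = embed_config(), radius_overrides = NULL,
                        null_length = 100000, null_repeats = 10,
                        max_motifs = 10, top_n = 10, seed = 1) {
  stopifnot(all(k_range >= 1), all(k_range <= 16), alpha > 0, alpha < 1,
            sample_n > 1, n_neighbors >= 1, inherits(embed, "embed_config"))
  structure(list(k_range = as.integer(k_range), alpha = alpha,
                 rc_mode = isTRUE(rc_mode), sample_n = as.integer(sample_n),
                 n_neighbors = as.integer(n_neighbors), embed = embed,
                 radius_overrides = radius_overrides,
                 null_length = null_length, null_repeats = null_repeats,
                 max_motifs = max_motifs, top_n = top_n,
                 seed = as.integer(seed)),
            class = "kmap_config")
}

#' Full motif discovery run
#'
#' Reads the input, runs per-k discovery with cached null models, merges
#' consensuses across k, and (optionally) writes `motifs.tsv`, a MEME
#' minimal motif file, per-motif ball member tables and a co-occurrence
#' matrix into `out_dir`.
#'
#' @param input Path to a FASTA/FASTQ file (optionally gzipped) or a
#'   sequence set.
#' @param config A [kmap_config()].
#' @param out_dir Optional output directory.
#' @param nulls Optional prefitted null models (named list by k).
#' @param verbose Log per-iteration diagnostics.
#' @return A `kmap_run`: list with `motifs` (a `kmap_motifs`), `seqs` and
#'   `config`.
#' @export
run_discover <- function(input, config = kmap_config(), out_dir = NULL,
                         nulls = NULL, verbose = FALSE) {
  seqs <- if (is.character(input) && length(input) == 1L &&
                is.null(names(input))) {
    if (!file.exists(input)) stop("run_discover: cannot read input: ", input)
    read_sequences(input)
  } else as_sequence_set(input)
  if (length(seqs) == 0L) stop("run_discover: no sequences in input")
  motifs <- discover_motifs(seqs, k_range = config$k_range,
                            alpha = config$alpha, rc_mode = config$rc_mode,
                            radius_overrides = config$radius_overrides,
                            nulls = nulls, null_length = config$null_length,
                            null_repeats = config$null_repeats,
                            seed = config$seed,
                            max_motifs = config$max_motifs,
                            top_n = config$top_n, verbose = verbose)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_motifs_tsv(motifs, file.path(out_dir, "motifs.tsv"))
    if (length(motifs$motifs)) {
      write_meme(motifs, file.path(out_dir, "motifs.meme"))
      write_ball_members(motifs, out_dir)
      if (length(motifs$motifs) >= 2) {
        cons <- vapply(motifs$motifs, function(m) m$consensus, character(1))
        write.table(cooccurrence(seqs, cons, config$rc_mode),
                    file.path(out_dir, "cooccurrence.tsv"), sep = "\t",
                    quote = FALSE)
      }
    }
  }
  structure(list(motifs = motifs, seqs = seqs, config = config),
            class = "kmap_run")
}

#' @export
print.kmap_run <- function(x, ...) {
  cat("Discovery run over", length(x$seqs), "sequences\n")
  print(x$motifs)
  invisible(x)
}

#' Visualize a discovery run or a precomputed distance matrix
#'
#' For a `kmap_run`, takes the k of the most significant motif, samples
#' `sample_n` motif/random k-mers ([sample_supervised()]), and embeds the
#' smoothed + sigmoid-transformed Hamming distance matrix.  For a
#' precomputed distance matrix (the direct path, e.g. aligned
#' gene-editing reads), optionally applies [sample_unsupervised()] and
#' embeds the raw matrix without the k-mer transformations.
#'
#' @param x A `kmap_run` or a square symmetric distance matrix.
#' @param config A [kmap_config()].
#' @param out_dir Optional output directory for `embedding.tsv`.
#' @param sample For the matrix path: run unsupervised sampling first.
#' @param nn Neighbors for unsupervised sampling (matrix path).
#' @param labels Optional labels for the matrix path.
#' @return A `kmap_embedding` (with an `items` attribute on the k-mer
#'   path and a `sampled_indices` attribute on the sampled matrix path).
#' @export
run_visualize <- function(x, config = kmap_config(), out_dir = NULL,
                          sample = FALSE, nn = 600, labels = NULL) {
  ec <- config$embed
  if (is.null(ec$seed)) ec$seed <- config$seed + 2000L
  if (inherits(x, "kmap_run")) {
    ms <- x$motifs$motifs
    if (length(ms) == 0L)
      stop("run_visualize: the discovery run found no motifs")
    k <- ms[[which.min(vapply(ms, function(m) m$pvalue, numeric(1)))]]$k
    ct <- count_kmers(x$seqs, k, config$rc_mode)
    sm <- sample_supervised(x$motifs, ct, n = config$sample_n,
                            seed = config$seed + 3000L)
    D <- hamming_matrix(sm$items)
    D0 <- smooth_distances(D, config$n_neighbors)
    Dt <- repulse_transform(D0, transform_params(k))
    emb <- kmap_embed(Dt, labels = sm$labels, config = ec)
    attr(emb, "items") <- sm$items
  } else {
    D <- as.matrix(x)
    if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
      stop("run_visualize: matrix input must be square and symmetric")
    idx <- seq_len(nrow(D))
    if (sample) {
      idx <- sample_unsupervised(D, nn = min(nn, nrow(D) - 1L))
      D <- D[idx, idx, drop = FALSE]
      labels <- labels[idx]
    }
    emb <- kmap_embed(D, labels = labels, config = ec)
    attr(emb, "sampled_indices") <- idx
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_embedding_tsv(emb, file.path(out_dir, "embedding.tsv"),
                        items = attr(emb, "items"))
  }
  emb
}

#' Minimal density clustering of embedded points
#'
#' A compact DBSCAN on a distance matrix or 2D coordinates: points with at
#' least `min_pts` neighbors within `eps` are core points, connected core
#' neighborhoods grow into clusters, and remaining points are labelled 0
#' (noise).  Used to read off groups from 2D embeddings.
#'
#' @param x n x 2 coordinate matrix (or an n x n distance matrix with
#'   `is_distance = TRUE`).
#' @param eps Neighborhood radius.
#' @param min_pts Minimum neighborhood size (self included) for a core
#'   point.
#' @param is_distance Interpret `x` as a precomputed distance matrix.
#' @return Integer cluster labels (0 = noise).
#' @export
density_cluster <- function(x, eps = 0.5, min_pts = 5, is_distance = FALSE) {
  D <- if (is_distance) as.matrix(x) else as.matrix(dist(x))
  n <- nrow(D)
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      for (q in nbrs[[j]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}
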