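# Selecting the items to embed: supervised motif/random k-mer sampling and
# unsupervised distance-based sampling.

#' Supervised sampling of motif and random k-mers
#'
#' Draws `n/2` k-mers with replacement from the pooled observed members of
#' the motif Hamming balls (probability proportional to observed count)
#' and `n/2` from the remaining ("random") k-mers, likewise count-weighted.
#' Duplicates are intentional: they encode the density that the embedding
#' visualizes.
#'
#' @param motifs A `kmap_motifs` object or list of `kmap_motif`; motifs
#'   whose k differs from `counts$k` are skipped with a warning.
#' @param counts A `kmer_counts` object at the k to visualize.
#' @param n Total sample size (default 5000, half motif / half random).
#' @param seed Optional integer seed.
#' @return A `kmap_sample`: list with parallel `items` and `labels`
#'   (motif consensus or `"random"`), plus the seed.
#' @export
sample_supervised <- function(motifs, counts, n = 5000, seed = NULL) {
  stopifnot(inherits(counts, "kmer_counts"))
  ms <- if (inherits(motifs, "kmap_motifs")) motifs$motifs else motifs
  keep <- vapply(ms, function(m) m$k == counts$k, logical(1))
  if (any(!keep))
    warning("sample_supervised: skipping ", sum(!keep),
            " motif(s) with k != ", counts$k)
  ms <- ms[keep]
  pool_items <- character(0)
  pool_w <- numeric(0)
  pool_lab <- character(0)
  for (m in ms) {
    pool_items <- c(pool_items, names(m$members))
    pool_w <- c(pool_w, unname(m$members))
    pool_lab <- c(pool_lab, rep(m$consensus, length(m$members)))
  }
  member_keys <- unique(if (counts$rc_mode && length(pool_items))
    canonical_kmer(pool_items) else pool_items)
  rand_keys <- setdiff(names(counts$counts), member_keys)
  rand_w <- unname(counts$counts[rand_keys])
  n_motif <- floor(n / 2)
  n_rand <- n - n_motif
  if (length(pool_items) == 0L) {
    warning("sample_supervised: no motifs; returning an all-random sample")
    n_motif <- 0L; n_rand <- n
  }
  if (length(rand_keys) == 0L) {
    if (length(pool_items) == 0L)
      stop("sample_supervised: no motif members and no random k-mers")
    warning("sample_supervised: no random k-mers; returning an all-motif sample")
    n_motif <- n; n_rand <- 0L
  }
  draw <- function() {
    mi <- if (n_motif > 0)
      sample.int(length(pool_items), n_motif, replace = TRUE, prob = pool_w)
    else integer(0)
    ri <- if (n_rand > 0)
      sample.int(length(rand_keys), n_rand, replace = TRUE, prob = rand_w)
    else integer(0)
    list(items = c(pool_items[mi], rand_keys[ri]),
         labels = c(pool_lab[mi], rep("random", length(ri))))
  }
  res <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(list(items = res$items, labels = res$labels, seed = seed),
            class = "kmap_sample")
}

#' @export
print.kmap_sample <- function(x, ...) {
  cat("Sampled items:", length(x$items), "|",
      sum(x$labels != "random"), "motif /", sum(x$labels == "random"),
      "random\n")
  invisible(x)
}

#' Write sampled items and labels as a two-column TSV
#'
#' @param sample A `kmap_sample`.
#' @param path Output path.
#' @export
write_sample_tsv <- function(sample, path) {
  write.table(data.frame(item = sample$items, label = sample$labels),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Unsupervised distance-based sampling
#'
#' Selects items lying in dense neighborhoods of a precomputed distance
#' matrix.  For each pair (i, j) a smoothed value is computed (default
#' `"pooled"` rule: the mean of the `nn` smallest off-diagonal entries of
#' rows i and j pooled; `"cross"` rule: the mean distance between i's and
#' j's `nn` nearest neighbors).  A Normal is fitted to all smoothed
#' off-diagonal values by moments, pairs below `mu - 2*sigma` are kept,
#' and the indices appearing in any kept pair are returned.
#'
#' @param D Square symmetric distance matrix.
#' @param nn Number of nearest neighbors for smoothing (default 600).
#' @param seed Unused (the procedure is deterministic); kept for interface
#'   symmetry with the other samplers.
#' @param rule `"pooled"` (default) or `"cross"` smoothing rule.
#' @return Sorted integer indices, with attributes `mu`, `sigma` and
#'   `n_kept_pairs`.
#' @export
sample_unsupervised <- function(D, nn = 600, seed = NULL,
                                rule = c("pooled", "cross")) {
  rule <- match.arg(rule)
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("sample_unsupervised: 'D' must be square and symmetric")
  if (nn >= n) stop("sample_unsupervised: 'nn' must be smaller than nrow(D)")
  if (rule == "pooled") {
    nn_sums <- vapply(seq_len(n), function(i)
      sum(sort(D[i, -i], partial = nn)[seq_len(nn)]), numeric(1))
    S <- outer(nn_sums, nn_sums, "+") / (2 * nn)
  } else {
    S <- neighbor_smooth(D, nn)
  }
  vals <- S[upper.tri(S)]
  mu <- mean(vals)
  sigma <- sd(vals)
  if (!is.finite(sigma) || sigma < 1e-12) {
    warning("sample_unsupervised: smoothed distances are constant; ",
            "keeping all items")
    out <- seq_len(n)
    attributes(out) <- c(attributes(out),
                         list(mu = mu, sigma = 0, n_kept_pairs = NA))
    return(out)
  }
  keep <- which(S < mu - 2 * sigma & upper.tri(S), arr.ind = TRUE)
  out <- sort(unique(as.integer(keep)))
  attributes(out) <- c(attributes(out),
                       list(mu = mu, sigma = sigma,
                            n_kept_pairs = nrow(keep)))
  out
}
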