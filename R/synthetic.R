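# Seeded generators for every input class the method consumes: implanted
# motif reads, cluster-structured distance matrices, gene-editing reads.

#' Specification of an implanted motif
#'
#' @param consensus Consensus sequence to implant.
#' @param implant_rate Per-read probability of carrying the implant.
#' @param max_mutations Implants receive m ~ Uniform{0..max_mutations}
#'   random substitutions (`< nchar(consensus)`).
#' @param strand_rc_prob Probability of implanting the reverse complement.
#' @return An object of class `implant_spec`.
#' @export
implant_spec <- function(consensus, implant_rate, max_mutations = 0,
                         strand_rc_prob = 0) {
  consensus <- check_kmer(consensus)
  stopifnot(implant_rate >= 0, implant_rate <= 1,
            max_mutations >= 0, max_mutations < nchar(consensus),
            strand_rc_prob >= 0, strand_rc_prob <= 1)
  structure(list(consensus = consensus, implant_rate = implant_rate,
                 max_mutations = as.integer(max_mutations),
                 strand_rc_prob = strand_rc_prob),
            class = "implant_spec")
}

mutate_kmer <- function(chars, m) {
  if (m == 0) return(chars)
  pos <- sample.int(length(chars), m)
  for (p in pos)
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
  chars
}

#' Generate reads with implanted motifs on a uniform background
#'
#' Background reads are i.i.d. uniform over {A,C,G,T}.  Each read
#' independently receives each spec's consensus with probability
#' `implant_rate`, mutated at m ~ Uniform{0..max_mutations} positions,
#' reverse-complemented with probability `strand_rc_prob`, and written
#' over the background at a uniform random offset (so read length is
#' constant).  Overlaps between implants in one read are resolved by
#' redrawing the offset up to 10 times, then skipping.
#'
#' @param n_reads Number of reads.
#' @param read_len Read length (>= the longest consensus).
#' @param specs A single [implant_spec()] or a list of them.
#' @param seed Optional integer seed.
#' @return List with `sequences` (named character vector) and `implants`,
#'   a ground-truth `data.frame` (read, spec, consensus, start, mutations,
#'   strand) sufficient to recompute read support.
#' @export
generate_motif_dataset <- function(n_reads, read_len, specs, seed = NULL) {
  if (inherits(specs, "implant_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "implant_spec")))
  if (any(vapply(specs, function(s) nchar(s$consensus), integer(1)) >
        read_len))
    stop("generate_motif_dataset: read_len shorter than a consensus")
  run <- function() {
    reads <- character(n_reads)
    log_rows <- list()
    for (i in seq_len(n_reads)) {
      chars <- sample(DNA_BASES, read_len, replace = TRUE)
      occupied <- matrix(numeric(0), ncol = 2)
      for (si in seq_along(specs)) {
        sp <- specs[[si]]
        if (runif(1) >= sp$implant_rate) next
        L <- nchar(sp$consensus)
        m <- sample.int(sp$max_mutations + 1L, 1L) - 1L
        imp <- mutate_kmer(strsplit(sp$consensus, "", fixed = TRUE)[[1]], m)
        strand <- "+"
        if (runif(1) < sp$strand_rc_prob) {
          imp <- rev(chartr("ACGT", "TGCA", imp))
          strand <- "-"
        }
        placed <- FALSE
        for (try in 1:10) {
          start <- sample.int(read_len - L + 1L, 1L)
          clash <- nrow(occupied) > 0 &&
            any(start <= occupied[, 2] & start + L - 1 >= occupied[, 1])
          if (!clash) { placed <- TRUE; break }
        }
        if (!placed) next
        chars[start:(start + L - 1L)] <- imp
        occupied <- rbind(occupied, c(start, start + L - 1L))
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(read = i, spec = si, consensus = sp$consensus,
                     start = start, mutations = m, strand = strand,
                     stringsAsFactors = FALSE)
      }
      reads[i] <- paste(chars, collapse = "")
    }
    list(sequences = setNames(reads, sprintf("read_%04d", seq_len(n_reads))),
         implants = if (length(log_rows)) do.call(rbind, log_rows)
           else data.frame(read = integer(0), spec = integer(0),
                           consensus = character(0), start = integer(0),
                           mutations = integer(0), strand = character(0)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a cluster-structured distance matrix
#'
#' Block matrix with within-block entries `within +/- jitter` (uniform)
#' and cross-block entries `between +/- jitter`, symmetrized, negatives
#' clipped to zero and zero diagonal.  A fixture for the embedding and
#' unsupervised-sampling paths.
#'
#' @param n_per_cluster Integer vector of cluster sizes.
#' @param within,between Within/between-cluster base distances
#'   (`between > within >= 0`).
#' @param jitter Half-width of the uniform noise (default 0).
#' @param seed Optional integer seed.
#' @return Distance matrix with a `labels` attribute of cluster indices.
#' @export
generate_cluster_matrix <- function(n_per_cluster, within, between,
                                    jitter = 0, seed = NULL) {
  stopifnot(between > within, within >= 0, jitter >= 0)
  labels <- rep(seq_along(n_per_cluster), n_per_cluster)
  n <- length(labels)
  run <- function() {
    D <- matrix(between, n, n)
    same <- outer(labels, labels, "==")
    D[same] <- within
    if (jitter > 0) {
      noise <- matrix(0, n, n)
      up <- upper.tri(noise)
      noise[up] <- runif(sum(up), -jitter, jitter)
      noise <- noise + t(noise)
      D <- D + noise
    }
    D[D < 0] <- 0
    diag(D) <- 0
    D
  }
  D <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  attr(D, "labels") <- labels
  D
}

#' Generate gene-editing reads from a reference and edit patterns
#'
#' Each read draws one edit pattern (or none) by weight and applies it to
#' the reference: deletions remove `length` bases starting at `position`;
#' insertions insert `payload` before `position`.  Reads are right-padded
#' with the sentinel 'N' to a uniform length so they remain comparable
#' under the Hamming distance.
#'
#' @param n_reads Number of reads.
#' @param reference Reference sequence.
#' @param patterns List of patterns, each a list with fields `op`
#'   (`"deletion"` or `"insertion"`), `position` (1-based), `length`, and
#'   `payload` (insertions only).
#' @param weights Pattern probabilities, `sum(weights) <= 1`; the
#'   remainder of reads stay unedited.
#' @param seed Optional integer seed.
#' @return List with `sequences` (uniform-length, 'N'-padded) and
#'   `labels` (pattern index as character, or `"unedited"`).
#' @export
generate_editing_reads <- function(n_reads, reference, patterns, weights,
                                   seed = NULL) {
  reference <- toupper(reference)
  nref <- nchar(reference)
  stopifnot(length(patterns) == length(weights), all(weights >= 0),
            sum(weights) <= 1 + 1e-9)
  edited <- vapply(patterns, function(p) {
    op <- match.arg(p$op, c("deletion", "insertion"))
    pos <- as.integer(p$position)
    len <- as.integer(p$length)
    if (op == "deletion") {
      if (pos < 1 || pos + len - 1 > nref)
        stop("generate_editing_reads: deletion outside the reference")
      paste0(substr(reference, 1, pos - 1),
             substr(reference, pos + len, nref))
    } else {
      if (pos < 1 || pos > nref + 1)
        stop("generate_editing_reads: insertion outside the reference")
      payload <- toupper(p$payload)
      if (nchar(payload) != len)
        stop("generate_editing_reads: payload length != length")
      paste0(substr(reference, 1, pos - 1), payload,
             substr(reference, pos, nref))
    }
  }, character(1))
  variants <- c(edited, reference)
  probs <- c(weights, max(0, 1 - sum(weights)))
  labs <- c(as.character(seq_along(patterns)), "unedited")
  run <- function() {
    idx <- sample.int(length(variants), n_reads, replace = TRUE,
                      prob = probs)
    maxlen <- max(nchar(variants))
    seqs <- vapply(variants[idx], function(s)
      paste0(s, strrep("N", maxlen - nchar(s))), character(1),
      USE.NAMES = FALSE)
    list(sequences = setNames(seqs, sprintf("read_%04d", seq_len(n_reads))),
         labels = labs[idx])
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
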