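# Iterative Hamming-ball motif discovery, cross-k consensus merging, PWMs,
# consensus comparison, co-occurrence and position scanning.

is_repeat_kmer <- function(x) grepl("^(.)\\1*$", x)

# Observed ball members for a motif: raw ball members are canonicalized
# against the count table (when rc), deduplicated, re-oriented toward the
# consensus, and reduced to the positive-count set.
ball_observed_members <- function(counts, center, radius) {
  k <- counts$k
  raw <- cpp_decode(cpp_ball_members(cpp_encode(center, k), k,
                                     as.integer(radius)), k)
  keys <- if (counts$rc_mode) unique(canonical_kmer(raw)) else raw
  cnt <- counts$counts[match(keys, names(counts$counts))]
  cnt[is.na(cnt)] <- 0
  keep <- cnt > 0
  keys <- keys[keep]
  cnt <- unname(cnt[keep])
  if (length(keys) == 0L) return(setNames(numeric(0), character(0)))
  if (counts$rc_mode) {
    rc <- reverse_complement(keys)
    d_fwd <- vapply(keys, hamming_distance, integer(1), b = center)
    d_rev <- vapply(rc, hamming_distance, integer(1), b = center)
    keys <- ifelse(d_rev < d_fwd, rc, keys)
  }
  setNames(cnt, keys)
}

#' Iterative motif discovery at a fixed k-mer length
#'
#' One round tests the Hamming-ball ratios of the `top_n` most frequent
#' k-mers; if the smallest p-value beats `alpha`, that center's ball is
#' accepted as a motif and all its members are masked from the sequences
#' before the next round.  Discovery stops at the first failing round or
#' after `max_motifs` acceptances.
#'
#' @param seqs Sequence set (or FASTA/FASTQ path).
#' @param k k-mer length.
#' @param null A fitted `kmap_null` for `(k, radius)` with matching
#'   `rc_mode`.
#' @param radius Ball radius (default [default_radius()]).
#' @param alpha Significance threshold on the ratio p-value.
#' @param max_motifs Maximum number of accepted motifs per k.
#' @param top_n Number of top-count candidate centers tested per round.
#' @param rc_mode Canonical (both-strand) counting and masking.
#' @param drop_repeats Drop motifs whose consensus is a single repeated
#'   base (they are masked during iteration but excluded from the output).
#' @param verbose Log each round's best candidate to stderr.
#' @return List of `kmap_motif` objects in discovery order.
#' @export
discover_at_k <- function(seqs, k, null, radius = default_radius(k),
                          alpha = 1e-10, max_motifs = 10, top_n = 10,
                          rc_mode = FALSE, drop_repeats = TRUE,
                          verbose = FALSE) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs) &&
      is.null(names(seqs)))
    seqs <- read_sequences(seqs)
  seqs0 <- as_sequence_set(seqs)
  stopifnot(inherits(null, "kmap_null"))
  if (null$k != k || null$r != radius)
    stop("discover_at_k: null model was fitted for (k = ", null$k, ", r = ",
         null$r, "), not (", k, ", ", radius, ")")
  cur <- seqs0
  motifs <- list()
  accepted <- 0L
  repeat {
    ct <- count_kmers(cur, k, rc_mode)
    if (length(ct$counts) == 0L || ct$total_windows == 0) {
      if (accepted == 0L) warning("discover_at_k: no valid k-windows")
      break
    }
    cand <- head(names(ct$counts), top_n)
    st <- ball_ratio_stats(ct, cand, radius)
    ratios <- setNames(st$ratio, cand)
    pv <- ratio_pvalue(null, ratios, st$size_factor)
    pick <- order(pv, -ct$counts[cand], cand)[1]
    if (verbose)
      message(sprintf("k=%d round %d: top candidate %s ratio=%.3f p=%.3g",
                      k, accepted + 1L, cand[pick], ratios[pick], pv[pick]))
    if (pv[pick] >= alpha) break
    center <- cand[pick]
    members <- ball_observed_members(ct, center, radius)
    ball <- hamming_ball(center, radius, members = members)
    mask_codes <- cpp_ball_members(cpp_encode(center, k), k,
                                   as.integer(radius))
    motif <- structure(
      list(consensus = center, k = as.integer(k),
           radius = as.integer(radius), members = members,
           ratio = unname(ratios[pick]), pvalue = unname(pv[pick]),
           read_support = read_support(seqs0, ball, rc_mode),
           discovery_order = accepted + 1L, merged = NA),
      class = "kmap_motif")
    motifs[[length(motifs) + 1L]] <- motif
    accepted <- accepted + 1L
    cur <- setNames(cpp_mask_members(unname(cur), k, mask_codes,
                                     isTRUE(rc_mode)), names(cur))
    if (accepted >= max_motifs) break
  }
  if (drop_repeats)
    motifs <- Filter(function(m) !is_repeat_kmer(m$consensus), motifs)
  motifs
}

#' @export
print.kmap_motif <- function(x, ...) {
  cat(sprintf("Motif %s (k=%d, r=%d): ratio %.3f, p %.3g, support %.1f%%%s\n",
              x$consensus, x$k, x$radius, x$ratio, x$pvalue,
              100 * x$read_support,
              if (isTRUE(x$merged)) ", merged" else ""))
  invisible(x)
}

#' Merge candidate consensuses across k-mer lengths
#'
#' A consensus chain is three candidates at consecutive lengths k-1, k,
#' k+1, each a substring of the next; every chain collapses to its
#' middle-length sequence and consumes its members.  Longer runs collapse
#' to the middles of all embedded 3-chains; among merged middles that are
#' substrings of one another the longer is kept.  Candidates in no chain
#' are retained and flagged unmerged.
#'
#' @param candidates Named list mapping k (names) to ordered character
#'   vectors of candidate consensuses.
#' @return `data.frame` with columns `consensus`, `k`, `merged`.
#' @examples
#' merge_consensus(list(`10` = "AATCGTAGGA", `11` = "AATCGTAGGAT",
#'                      `12` = "AATCGTAGGATG"))
#' @export
merge_consensus <- function(candidates) {
  candidates <- candidates[lengths(candidates) > 0]
  ks <- sort(as.integer(names(candidates)))
  tag <- function(k, s) paste0(k, ":", s)
  consumed <- character(0)
  middles <- character(0)
  for (k in ks) {
    if (!((k - 1) %in% ks && (k + 1) %in% ks)) next
    lo <- candidates[[as.character(k - 1)]]
    mi <- candidates[[as.character(k)]]
    hi <- candidates[[as.character(k + 1)]]
    for (s1 in mi) {
      subs <- lo[vapply(lo, function(s) grepl(s, s1, fixed = TRUE),
                        logical(1))]
      sups <- hi[vapply(hi, function(s) grepl(s1, s, fixed = TRUE),
                        logical(1))]
      if (length(subs) && length(sups)) {
        middles <- c(middles, s1)
        consumed <- c(consumed, tag(k - 1, subs), tag(k, s1),
                      tag(k + 1, sups))
      }
    }
  }
  middles <- unique(middles)
  if (length(middles) > 1) {
    keep <- vapply(middles, function(m)
      !any(middles != m & nchar(middles) > nchar(m) &
             vapply(middles, function(o) grepl(m, o, fixed = TRUE),
                    logical(1))), logical(1))
    middles <- middles[keep]
  }
  rows <- list()
  if (length(middles))
    rows[[1]] <- data.frame(consensus = middles, k = nchar(middles),
                            merged = TRUE, stringsAsFactors = FALSE)
  for (k in ks) {
    cand <- candidates[[as.character(k)]]
    left <- cand[!(tag(k, cand) %in% consumed)]
    left <- setdiff(left, middles)
    if (length(left))
      rows[[length(rows) + 1L]] <-
        data.frame(consensus = left, k = nchar(left), merged = FALSE,
                   stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(consensus = character(0), k = integer(0),
                    merged = logical(0), stringsAsFactors = FALSE)
  out[!duplicated(out$consensus), , drop = FALSE]
}

#' Discover motifs across a range of k-mer lengths
#'
#' Runs [discover_at_k()] for every k in `k_range` (fitting or reusing a
#' cached null per k), then merges the candidate consensuses across
#' lengths with [merge_consensus()].
#'
#' @inheritParams discover_at_k
#' @param k_range Integer vector of k-mer lengths (default 5:16).
#' @param radius_overrides Optional named vector mapping k to a radius.
#' @param nulls Optional named list (by k) of prefitted `kmap_null`s.
#' @param null_length,null_repeats Null-fit simulation size.
#' @param seed Integer seed; null fits use derived sub-seeds so that the
#'   whole run is reproducible.
#' @return A `kmap_motifs` object: motifs (merged or flagged unmerged)
#'   ordered by p-value, plus the run parameters.
#' @export
discover_motifs <- function(seqs, k_range = 5:16, alpha = 1e-10,
                            rc_mode = TRUE, radius_overrides = NULL,
                            nulls = NULL, null_length = 100000,
                            null_repeats = 10, seed = 1, max_motifs = 10,
                            top_n = 10, drop_repeats = TRUE,
                            verbose = FALSE) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs) &&
      is.null(names(seqs)))
    seqs <- read_sequences(seqs)
  seqs <- as_sequence_set(seqs)
  if (length(seqs) == 0L) stop("discover_motifs: no input sequences")
  per_k <- list()
  for (k in k_range) {
    if (all(nchar(seqs) < k)) next
    r <- if (!is.null(radius_overrides) &&
             as.character(k) %in% names(radius_overrides))
      as.integer(radius_overrides[[as.character(k)]])
    else default_radius(k)
    null <- if (!is.null(nulls) && as.character(k) %in% names(nulls))
      nulls[[as.character(k)]]
    else null_model(k, r, length = null_length, repeats = null_repeats,
                    seed = (seed %||% 0) + 1000L + k, rc_mode = rc_mode)
    per_k[[as.character(k)]] <-
      discover_at_k(seqs, k, null, radius = r, alpha = alpha,
                    max_motifs = max_motifs, top_n = top_n,
                    rc_mode = rc_mode, drop_repeats = drop_repeats,
                    verbose = verbose)
  }
  cand <- lapply(per_k, function(ms)
    vapply(ms, function(m) m$consensus, character(1)))
  merged <- merge_consensus(cand)
  motifs <- lapply(seq_len(nrow(merged)), function(i) {
    k <- merged$k[i]
    ms <- per_k[[as.character(k)]]
    m <- ms[[which(vapply(ms, function(m) m$consensus, character(1)) ==
                     merged$consensus[i])[1]]]
    m$merged <- merged$merged[i]
    m
  })
  if (length(motifs))
    motifs <- motifs[order(vapply(motifs, function(m) m$pvalue, numeric(1)),
                           -vapply(motifs, function(m) m$ratio, numeric(1)))]
  structure(list(motifs = motifs,
                 params = list(k_range = k_range, alpha = alpha,
                               rc_mode = rc_mode,
                               radius_overrides = radius_overrides,
                               null_length = null_length,
                               null_repeats = null_repeats, seed = seed),
                 provenance = paste(length(seqs), "sequences")),
            class = "kmap_motifs")
}

#' @export
print.kmap_motifs <- function(x, ...) {
  cat("Motif set:", length(x$motifs), "motifs from", x$provenance, "\n")
  for (m in x$motifs) print(m)
  invisible(x)
}

#' Position weight matrix of a motif's Hamming ball
#'
#' Count-weighted base frequencies at each position across the observed
#' ball members; each row sums to 1.
#'
#' @param ball A `kmap_motif`, a [hamming_ball()], or a named numeric
#'   vector of member counts.
#' @return Numeric matrix, width x 4, columns A, C, G, T.
#' @examples
#' build_pwm(c(AA = 3, AC = 1))
#' @export
build_pwm <- function(ball) {
  members <- if (inherits(ball, "kmap_motif")) ball$members
    else if (inherits(ball, "hamming_ball")) ball$members
    else ball
  if (!is.numeric(members) || is.null(names(members)))
    stop("build_pwm: expected named member counts")
  members <- members[members > 0]
  if (length(members) == 0L || sum(members) <= 0)
    stop("build_pwm: no members with positive counts")
  width <- nchar(names(members)[1])
  chars <- do.call(rbind, strsplit(names(members), "", fixed = TRUE))
  pwm <- matrix(0, nrow = width, ncol = 4,
                dimnames = list(NULL, DNA_BASES))
  for (b in DNA_BASES)
    pwm[, b] <- colSums((chars == b) * members)
  pwm / rowSums(pwm)
}

#' Precision and recall between two consensus sequences
#'
#' Overlap is the length of the longest common substring under exact
#' character match; precision divides by `nchar(s_K)` and recall by
#' `nchar(s_M)`.
#'
#' @param s_K,s_M Non-empty consensus strings (query and reference).
#' @return Named numeric vector `c(precision, recall)`.
#' @examples
#' compare_consensus("AATCGTAGGA", "TCGTAG")  # 0.6, 1.0
#' @export
compare_consensus <- function(s_K, s_M) {
  a <- strsplit(toupper(s_K), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(s_M), "", fixed = TRUE)[[1]]
  if (length(a) == 0L || length(b) == 0L)
    stop("compare_consensus: empty consensus")
  best <- 0L
  prev <- integer(length(b))
  for (i in seq_along(a)) {
    cur <- integer(length(b))
    match_i <- a[i] == b
    cur[match_i] <- c(0L, prev)[which(match_i)] + 1L
    best <- max(best, cur)
    prev <- cur
  }
  c(precision = best / length(a), recall = best / length(b))
}

#' Motif co-occurrence across reads
#'
#' Entry (a, b) is the number of reads containing both consensuses as
#' exact substrings (either strand when `rc_mode`) divided by the number
#' containing at least one; 0/0 is defined as 0.  The diagonal is 1 for
#' motifs that occur at all.
#'
#' @param seqs Sequence set.
#' @param consensuses Character vector (>= 2) of consensus sequences.
#' @param rc_mode Also match reverse-complement occurrences.
#' @return Symmetric matrix in [0, 1] with consensus dimnames.
#' @export
cooccurrence <- function(seqs, consensuses, rc_mode = FALSE) {
  seqs <- as_sequence_set(seqs)
  if (length(consensuses) < 2L)
    stop("cooccurrence: need at least two consensuses")
  occ <- vapply(consensuses, function(cs) {
    hit <- grepl(cs, seqs, fixed = TRUE)
    if (rc_mode) hit <- hit | grepl(reverse_complement(cs), seqs,
                                    fixed = TRUE)
    hit
  }, logical(length(seqs)))
  occ <- matrix(occ, ncol = length(consensuses))
  m <- length(consensuses)
  out <- matrix(0, m, m, dimnames = list(consensuses, consensuses))
  for (i in seq_len(m)) {
    for (j in i:m) {
      both <- sum(occ[, i] & occ[, j])
      either <- sum(occ[, i] | occ[, j])
      out[i, j] <- out[j, i] <- if (either == 0) 0 else both / either
    }
  }
  out
}

#' Mismatch-tolerant consensus positions in reads
#'
#' Reports every window within Hamming distance `max_mismatch` of the
#' consensus, with the 0-based window start, the offset of the start
#' relative to the read center `floor(read_length/2)`, and the strand
#' ('-' windows match the reverse complement).  Central positioning of
#' genuine binding motifs shows up as offsets concentrated near 0.
#'
#' @param seqs Sequence set.
#' @param consensus Consensus sequence to scan for.
#' @param max_mismatch Maximum allowed mismatches (default 0).
#' @param rc_mode Also scan the reverse-complement orientation.
#' @return `data.frame` with columns `read`, `start`, `offset`,
#'   `mismatches`, `strand`.
#' @export
scan_positions <- function(seqs, consensus, max_mismatch = 0,
                           rc_mode = FALSE) {
  seqs <- as_sequence_set(seqs)
  consensus <- check_kmer(consensus)
  df <- cpp_scan_consensus(unname(seqs), consensus,
                           as.integer(max_mismatch), isTRUE(rc_mode))
  df$offset <- df$start - floor(nchar(seqs)[df$read] / 2)
  df[, c("read", "start", "offset", "mismatches", "strand")]
}

motif_table <- function(motifs) {
  ms <- if (inherits(motifs, "kmap_motifs")) motifs$motifs else motifs
  do.call(rbind, lapply(ms, function(m)
    data.frame(consensus = m$consensus, k = m$k, radius = m$radius,
               count_in_ball = sum(m$members), ratio = m$ratio,
               pvalue = m$pvalue, read_support = m$read_support,
               merged = m$merged, discovery_order = m$discovery_order,
               stringsAsFactors = FALSE)))
}

#' Write a motif set as motifs.tsv
#'
#' One row per motif: consensus, k, radius, count_in_ball, ratio, pvalue,
#' read_support, merged flag and discovery order.
#'
#' @param motifs A `kmap_motifs` object (or list of `kmap_motif`).
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_motifs_tsv <- function(motifs, path) {
  tab <- motif_table(motifs)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write motif PWMs in MEME minimal motif format
#'
#' Letter-probability matrices with `nsites` set to the total ball count,
#' consumable by standard logo and scanning tools.
#'
#' @inheritParams write_motifs_tsv
#' @export
write_meme <- function(motifs, path) {
  ms <- if (inherits(motifs, "kmap_motifs")) motifs$motifs else motifs
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -",
               "", "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (m in ms) {
    pwm <- build_pwm(m)
    writeLines(sprintf("MOTIF %s", m$consensus), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d",
      nrow(pwm), round(sum(m$members))), con)
    writeLines(apply(pwm, 1, function(row)
      paste(sprintf("%.6f", row), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write per-motif ball member tables
#'
#' One TSV per motif (`ball_members_<i>.tsv` under `dir`): member k-mer,
#' observed count and Hamming distance to the consensus.
#'
#' @param motifs A `kmap_motifs` object (or list of `kmap_motif`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_ball_members <- function(motifs, dir) {
  ms <- if (inherits(motifs, "kmap_motifs")) motifs$motifs else motifs
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(ms)) {
    m <- ms[[i]]
    tab <- data.frame(member = names(m$members),
                      count = unname(m$members),
                      distance = vapply(names(m$members), hamming_distance,
                                        integer(1), b = m$consensus),
                      stringsAsFactors = FALSE)
    p <- file.path(dir, sprintf("ball_members_%d.tsv", i))
    write.table(tab[order(tab$distance, -tab$count), ], p, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
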