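# Sequence I/O, k-mer counting, motif masking and read support.

#' Coerce input to a sequence set
#'
#' A sequence set is represented as a named character vector of uppercase
#' sequences.  Accepts a character vector or a `Biostrings::XStringSet`;
#' unnamed records receive identifiers `seq1`, `seq2`, ...
#'
#' @param x Character vector or `XStringSet`.
#' @return Named uppercase character vector.
#' @export
as_sequence_set <- function(x) {
  if (methods::is(x, "XStringSet")) x <- setNames(as.character(x), names(x))
  if (!is.character(x)) stop("expected a character vector or XStringSet")
  x <- toupper(x)
  if (is.null(names(x)) || any(is.na(names(x))) || any(!nzchar(names(x)))) {
    nm <- names(x) %||% rep("", length(x))
    nm[is.na(nm) | !nzchar(nm)] <-
      paste0("seq", seq_along(x))[is.na(nm) | !nzchar(nm)]
    names(x) <- nm
  }
  x
}

#' Read DNA sequences from FASTA or FASTQ
#'
#' Format is auto-detected from the file extension, falling back to the
#' first record character ('>' FASTA, '@' FASTQ).  Gzipped files are
#' supported; FASTQ quality scores are ignored.
#'
#' @param path Path to a FASTA/FASTQ file, optionally gzipped.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return Named character vector of uppercase sequences.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read sequences: no such file: ", path)
  if (format == "auto") {
    base <- sub("\\.(gz|bgz)$", "", path, ignore.case = TRUE)
    ext <- tolower(sub(".*\\.", "", base))
    format <- if (ext %in% c("fastq", "fq")) "fastq"
      else if (ext %in% c("fasta", "fa", "fna", "ffn")) "fasta"
      else {
        con <- gzfile(path, "rt")
        on.exit(close(con))
        first <- substr(readLines(con, n = 1L), 1L, 1L)
        if (identical(first, "@")) "fastq" else "fasta"
      }
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  as_sequence_set(x)
}

#' Write a sequence set as FASTA
#'
#' @param seqs Sequence set (see [as_sequence_set()]).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_sequence_set(seqs)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Construct a k-mer count table
#'
#' Low-level constructor used by [count_kmers()] and by tests; validates
#' the key lengths against `k`.
#'
#' @param counts Named numeric vector of k-mer counts.
#' @param k k-mer length.
#' @param rc_mode Whether keys are canonical (strand-collapsed) k-mers.
#' @param total_windows Number of valid k-windows scanned.
#' @return An object of class `kmer_counts`.
#' @export
kmer_counts <- function(counts, k, rc_mode = FALSE, total_windows = sum(counts)) {
  if (length(counts) && (is.null(names(counts)) ||
      any(nchar(names(counts)) != k)))
    stop("kmer_counts: all keys must be k-mers of length ", k)
  if (any(counts < 0)) stop("kmer_counts: counts must be positive")
  o <- order(-counts, names(counts))
  structure(list(k = as.integer(k), rc_mode = isTRUE(rc_mode),
                 counts = counts[o],
                 total_windows = as.numeric(total_windows)),
            class = "kmer_counts")
}

#' Count k-mers in a sequence set
#'
#' Every length-k window over {A,C,G,T} contributes one count; windows
#' containing any other character (e.g. 'N') are skipped but still advance
#' by one position.  With `rc_mode = TRUE` each window is recorded under
#' its canonical form (lexicographic minimum of the window and its reverse
#' complement), so both strands are pooled.
#'
#' @param seqs Sequence set, file path, or `XStringSet`.
#' @param k k-mer length (1..16).
#' @param rc_mode Canonicalize to the lexicographically smaller strand.
#' @return A `kmer_counts` object; `$counts` is sorted by decreasing count
#'   (ties broken lexicographically) and `$total_windows` counts the
#'   contributing windows.
#' @examples
#' count_kmers(c(r1 = "ACGTACGT"), k = 4)$counts
#' @export
count_kmers <- function(seqs, k, rc_mode = FALSE) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs) &&
      is.null(names(seqs)))
    seqs <- read_sequences(seqs)
  seqs <- as_sequence_set(seqs)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 16L)
    stop("count_kmers: 'k' must be in 1..16")
  if (length(seqs) == 0L) {
    warning("count_kmers: empty input; returning empty counts")
    return(kmer_counts(setNames(numeric(0), character(0)), k, rc_mode, 0))
  }
  if (all(nchar(seqs) < k))
    stop("count_kmers: k = ", k, " exceeds the length of every record")
  res <- cpp_count_kmers(unname(seqs), k, isTRUE(rc_mode))
  kmer_counts(res$counts, k, rc_mode, res$total_windows)
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat("k-mer counts: k =", x$k, if (x$rc_mode) "(canonical)" else "",
      "|", length(x$counts), "distinct k-mers over",
      format(x$total_windows, big.mark = ","), "windows\n")
  print(head(x$counts, 10L))
  invisible(x)
}

ball_member_codes <- function(ball, k) {
  if (inherits(ball, "hamming_ball")) {
    mem <- names(ball$members)
    if (length(mem) == 0L)
      mem <- ball_members(ball$center, ball$radius, allow_large = TRUE)
  } else if (is.character(ball)) {
    mem <- toupper(ball)
  } else stop("expected a 'hamming_ball' or a character vector of members")
  if (any(nchar(mem) != k)) stop("ball members must have length ", k)
  cpp_encode(mem, k)
}

#' Mask all occurrences of a Hamming ball in a sequence set
#'
#' Scans every window of the *original* sequences and overwrites the union
#' of all windows equal to a ball member (in either orientation when
#' `rc_mode = TRUE`) with the sentinel 'N'.  Re-counting afterwards yields
#' zero for every member; masking is idempotent.
#'
#' @param seqs Sequence set.
#' @param ball A [hamming_ball()] (or a character vector of member k-mers).
#' @param rc_mode Also mask reverse-complement occurrences.
#' @return The masked sequence set.
#' @export
mask_ball <- function(seqs, ball, rc_mode = FALSE) {
  seqs <- as_sequence_set(seqs)
  if (length(seqs) == 0L) return(seqs)
  mem1 <- if (inherits(ball, "hamming_ball")) names(ball$members) else ball
  k <- nchar(if (inherits(ball, "hamming_ball")) ball$center else mem1[1])
  codes <- ball_member_codes(ball, k)
  setNames(cpp_mask_members(unname(seqs), k, codes, isTRUE(rc_mode)),
           names(seqs))
}

#' Fraction of reads supporting a motif
#'
#' Proportion of records that contain at least one window matching a ball
#' member (either orientation when `rc_mode = TRUE`).  High read support
#' together with a small p-value is evidence of a genuine motif.
#'
#' @inheritParams mask_ball
#' @return Fraction in [0, 1].
#' @export
read_support <- function(seqs, ball, rc_mode = FALSE) {
  seqs <- as_sequence_set(seqs)
  if (length(seqs) == 0L) stop("read_support: empty sequence set")
  mem1 <- if (inherits(ball, "hamming_ball")) names(ball$members) else ball
  k <- nchar(if (inherits(ball, "hamming_ball")) ball$center else mem1[1])
  codes <- ball_member_codes(ball, k)
  mean(cpp_member_hits(unname(seqs), k, codes, isTRUE(rc_mode)))
}
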