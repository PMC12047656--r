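test_that("count_kmers walks windows, skips non-ACGT, totals correctly", {
  ct <- count_kmers(c(r1 = "ACGTACGT"), 4)
  expect_identical(ct$total_windows, 5)
  expect_equal(ct$counts[c("ACGT", "CGTA", "GTAC", "TACG")],
               c(ACGT = 2, CGTA = 1, GTAC = 1, TACG = 1))
  ct2 <- count_kmers(c(r1 = "ACNGT"), 2)
  expect_identical(ct2$total_windows, 2)
  expect_equal(ct2$counts, c(AC = 1, GT = 1))
  expect_warning(empty <- count_kmers(character(0), 3), "empty")
  expect_identical(empty$total_windows, 0)
  expect_error(count_kmers(c(a = "ACG"), 5), "exceeds")
})

test_that("canonical counting pools both strands", {
  ct <- count_kmers(c(r1 = "AAATTT"), 3, rc_mode = TRUE)
  expect_identical(ct$total_windows, 4)
  expect_equal(ct$counts[c("AAA", "AAT")], c(AAA = 2, AAT = 2))
  # rc-off counts of w and rc(w) sum to the canonical count
  set.seed(21)
  seqs <- simulate_random_dna(4000)
  off <- count_kmers(seqs, 5, rc_mode = FALSE)
  on <- count_kmers(seqs, 5, rc_mode = TRUE)
  expect_identical(off$total_windows, on$total_windows)
  for (w in sample(names(on$counts), 50)) {
    rc <- reverse_complement(w)
    got <- sum(off$counts[unique(c(w, rc))], na.rm = TRUE)
    expect_identical(unname(on$counts[w]), got)
  }
})

test_that("counting conserves windows when records are removed", {
  set.seed(22)
  reads <- setNames(replicate(6, paste(sample(c("A", "C", "G", "T", "N"),
                                              30, replace = TRUE,
                                              prob = c(rep(0.24, 4), 0.04)),
                                       collapse = "")),
                    paste0("r", 1:6))
  full <- count_kmers(reads, 4)
  for (drop in 1:6) {
    rest <- count_kmers(reads[-drop], 4)
    alone <- count_kmers(reads[drop], 4)
    expect_identical(full$total_windows,
                     rest$total_windows + alone$total_windows)
  }
})

test_that("mask_ball blanks matched windows of the original sequence", {
  expect_identical(mask_ball(c(r = "TTACGTTT"), hamming_ball("ACGT", 0))[[1]],
                   "TTNNNNTT")
  seqs <- c(r = "GGGGGGGG")
  expect_identical(mask_ball(seqs, hamming_ball("ACGT", 0)), seqs)
  # overlapping matches are resolved against the original sequence
  expect_identical(mask_ball(c(r = "ACGACG"),
                             hamming_ball("ACGA", 0))[[1]], "NNNNCG")
  # masking is idempotent and kills all member counts
  ds <- three_motif_reads(seed = 3, n_reads = 80)
  ball <- hamming_ball(THREE_MOTIF_CONSENSUS[1], 2)
  once <- mask_ball(ds$sequences, ball, rc_mode = TRUE)
  expect_identical(mask_ball(once, ball, rc_mode = TRUE), once)
  ct <- count_kmers(once, 8, rc_mode = TRUE)
  canon <- unique(canonical_kmer(names(ball$members)))
  expect_identical(sum(ct$counts[canon], na.rm = TRUE), 0)
})

test_that("read_support counts member-bearing reads", {
  seqs <- c(a = "TTACGTTT", b = "ACGTAAAA", c = "GGGGGGGG", d = "AACGTAAA")
  expect_identical(read_support(seqs, hamming_ball("ACGT", 0)), 0.75)
  expect_identical(read_support(seqs, hamming_ball("CCCC", 0)), 0)
  all_hit <- c(a = "AACGTA", b = "TACGTC")
  expect_identical(read_support(all_hit, hamming_ball("ACGT", 0)), 1)
  # rc_mode counts reverse-complement occurrences too
  expect_identical(read_support(c(a = "AAACGTTT"), hamming_ball("ACGT", 0),
                                rc_mode = TRUE), 1)
  expect_identical(read_support(c(a = "TTTTAAAA"), hamming_ball("CCCC", 0),
                                rc_mode = TRUE), 0)
})

test_that("FASTA/FASTQ round-trips preserve sequences", {
  ds <- three_motif_reads(seed = 5, n_reads = 12)
  fa <- file.path(tempdir(), "toy.fasta")
  write_fasta(ds$sequences, fa)
  back <- read_sequences(fa)
  expect_identical(back, ds$sequences)
  # plain FASTQ, gzipped, auto-detected by content
  fq <- file.path(tempdir(), "toy.fastq.gz")
  con <- gzfile(fq, "wt")
  for (i in seq_along(ds$sequences))
    writeLines(c(paste0("@", names(ds$sequences)[i]), ds$sequences[[i]],
                 "+", strrep("I", nchar(ds$sequences[[i]]))), con)
  close(con)
  expect_identical(read_sequences(fq), ds$sequences)
  noext <- file.path(tempdir(), "toyreads")
  file.copy(fa, noext, overwrite = TRUE)
  expect_identical(read_sequences(noext), ds$sequences)
  expect_error(read_sequences(file.path(tempdir(), "absent.fa")), "no such")
})
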