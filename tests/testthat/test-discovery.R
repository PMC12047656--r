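test_that("a saturated input yields exactly one exact-consensus motif", {
  null4 <- null_model(4, 1, length = 20000, repeats = 3, seed = 104)
  seqs <- setNames(rep("TGCA", 50), paste0("r", 1:50))
  ms <- discover_at_k(seqs, 4, null4, radius = 1, rc_mode = FALSE)
  expect_length(ms, 1)
  expect_identical(ms[[1]]$consensus, "TGCA")
  expect_identical(ms[[1]]$read_support, 1)
  expect_equal(ms[[1]]$ratio, 1 / ball_probability(4, 1))
})

test_that("discovery masks accepted balls and orders motifs", {
  null8 <- cached_null(8, 2)
  ds <- three_motif_reads(seed = 2)
  ms <- discover_at_k(ds$sequences, 8, null8, rc_mode = TRUE)
  expect_gte(length(ms), 2)
  expect_identical(vapply(ms, function(m) m$discovery_order, integer(1)),
                   seq_along(ms))
  # mask soundness: no later consensus lies inside an earlier ball
  for (i in seq_along(ms)[-1]) {
    for (j in seq_len(i - 1)) {
      d <- min(hamming_distance(ms[[i]]$consensus, ms[[j]]$consensus),
               hamming_distance(ms[[i]]$consensus,
                                reverse_complement(ms[[j]]$consensus)))
      expect_gt(d, ms[[j]]$radius)
    }
  }
  masked <- ds$sequences
  for (m in ms)
    masked <- mask_ball(masked, hamming_ball(m$consensus, m$radius),
                        rc_mode = TRUE)
  ct <- count_kmers(masked, 8, rc_mode = TRUE)
  for (m in ms) {
    canon <- unique(canonical_kmer(ball_members(m$consensus, m$radius)))
    expect_identical(sum(ct$counts[canon], na.rm = TRUE), 0)
  }
})

test_that("raising alpha never yields fewer motifs", {
  null8 <- cached_null(8, 2)
  ds <- three_motif_reads(seed = 4, n_reads = 1200)
  n_strict <- length(discover_at_k(ds$sequences, 8, null8, alpha = 1e-30,
                                   rc_mode = TRUE))
  n_loose <- length(discover_at_k(ds$sequences, 8, null8, alpha = 1e-10,
                                  rc_mode = TRUE))
  expect_lte(n_strict, n_loose)
})

test_that("single-base repeat motifs are filtered unless kept", {
  null5 <- null_model(5, 1, length = 20000, repeats = 3, seed = 105,
                      rc_mode = FALSE)
  seqs <- c(setNames(rep(strrep("A", 30), 150), paste0("p", 1:150)),
            three_motif_reads(seed = 6, n_reads = 150, read_len = 30)$sequences)
  dropped <- discover_at_k(seqs, 5, null5, rc_mode = FALSE)
  kept <- discover_at_k(seqs, 5, null5, rc_mode = FALSE,
                        drop_repeats = FALSE)
  expect_false("AAAAA" %in% vapply(dropped, `[[`, "", "consensus"))
  expect_true("AAAAA" %in% vapply(kept, `[[`, "", "consensus"))
})

test_that("consensus chains collapse to their middle sequence", {
  got <- merge_consensus(list(`10` = "AATCGTAGGA", `11` = "AATCGTAGGAT",
                              `12` = "AATCGTAGGATG"))
  expect_identical(got$consensus, "AATCGTAGGAT")
  expect_true(got$merged)
  # candidates in no chain are retained, flagged unmerged
  lone <- merge_consensus(list(`6` = "AAACCC"))
  expect_identical(lone$consensus, "AAACCC")
  expect_false(lone$merged)
  # a 4-length chain collapses to the longer of the two middles
  four <- merge_consensus(list(`9` = "AATCGTAGG", `10` = "AATCGTAGGA",
                               `11` = "AATCGTAGGAT", `12` = "AATCGTAGGATG"))
  expect_identical(four$consensus, "AATCGTAGGAT")
  expect_true(four$merged)
  # unrelated candidates survive alongside a chain
  mix <- merge_consensus(list(`10` = c("AATCGTAGGA", "CCCGGGTTTA"),
                              `11` = "AATCGTAGGAT",
                              `12` = "AATCGTAGGATG"))
  expect_setequal(mix$consensus, c("AATCGTAGGAT", "CCCGGGTTTA"))
  expect_identical(mix$merged[mix$consensus == "AATCGTAGGAT"], TRUE)
  expect_identical(mix$merged[mix$consensus == "CCCGGGTTTA"], FALSE)
})

test_that("PWMs are count-weighted base frequencies with unit rows", {
  pwm <- build_pwm(c(ACGT = 1))
  expect_equal(pwm, matrix(c(1, 0, 0, 0,  0, 1, 0, 0,
                             0, 0, 1, 0,  0, 0, 0, 1),
                           4, 4, byrow = TRUE,
                           dimnames = list(NULL, c("A", "C", "G", "T"))))
  pwm2 <- build_pwm(c(AA = 1, AC = 1))
  expect_equal(pwm2[1, ], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(pwm2[2, ], c(A = 0.5, C = 0.5, G = 0, T = 0))
  pwm3 <- build_pwm(c(AA = 3, AC = 1))
  expect_equal(pwm3[2, ], c(A = 0.75, C = 0.25, G = 0, T = 0))
  expect_true(all(abs(rowSums(pwm3) - 1) < 1e-9))
  expect_error(build_pwm(c(AA = 0)), "positive")
})

test_that("consensus comparison uses the longest common substring", {
  expect_equal(compare_consensus("ACGTACGT", "ACGTACGT"),
               c(precision = 1, recall = 1))
  expect_equal(compare_consensus("AATCGTAGGA", "TCGTAG"),
               c(precision = 0.6, recall = 1))
  expect_equal(compare_consensus("AAAA", "CCCC"),
               c(precision = 0, recall = 0))
  # symmetry swaps precision and recall; oracle by substring enumeration
  set.seed(31)
  for (i in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
               collapse = "")
    subs <- unique(unlist(lapply(1:nchar(b), function(i0)
      substring(b, i0, i0:nchar(b)))))
    best <- max(c(0, nchar(subs[vapply(subs, grepl, logical(1), x = a,
                                       fixed = TRUE)])))
    got <- compare_consensus(a, b)
    expect_equal(unname(got), c(best / nchar(a), best / nchar(b)))
    expect_equal(unname(compare_consensus(b, a)), rev(unname(got)))
  }
})

test_that("co-occurrence divides both-hits by either-hits", {
  M <- cooccurrence(c(r1 = "ACGTTT", r2 = "ACGAAA"), c("ACG", "TTT"))
  expect_equal(M["ACG", "TTT"], 0.5)
  expect_equal(diag(M), c(ACG = 1, TTT = 1))
  M2 <- cooccurrence(c(r1 = "AAAA", r2 = "CCCC"), c("AAA", "CCC", "GGG"))
  expect_equal(M2["AAA", "CCC"], 0)
  expect_equal(M2["GGG", "GGG"], 0)  # never occurs: 0/0 -> 0
  M3 <- cooccurrence(c(r1 = "AACCA", r2 = "CCAAG"), c("AA", "CC"))
  expect_equal(M3["AA", "CC"], 1)
  expect_error(cooccurrence(c(r = "ACGT"), "ACG"), "two")
})

test_that("scan_positions reports offsets relative to the read center", {
  hits <- scan_positions(c(r = "AAACGTAAA"), "ACGT")
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 2L)
  expect_identical(hits$offset, -2)
  expect_identical(hits$strand, "+")
  hits1 <- scan_positions(c(r = "AAACGAAAA"), "ACGT", max_mismatch = 1)
  expect_true(any(hits1$start == 2 & hits1$mismatches == 1))
  expect_identical(nrow(scan_positions(c(r = "GGGGGGGG"), "ACTA")), 0L)
  # reverse-complement hits are reported on the minus strand
  minus <- scan_positions(c(r = "TTTTCCAGG"), "CCTGGAA", rc_mode = TRUE)
  expect_identical(minus$strand, "-")
})

test_that("cross-k discovery merges and writes its reports", {
  nulls <- list(`7` = cached_null(7, 2), `8` = cached_null(8, 2),
                `9` = cached_null(9, 2))
  ds <- three_motif_reads(seed = 8)
  ms <- discover_motifs(ds$sequences, k_range = 7:9, nulls = nulls,
                        rc_mode = TRUE, seed = 5)
  expect_s3_class(ms, "kmap_motifs")
  expect_gte(length(ms$motifs), 1)
  pv <- vapply(ms$motifs, function(m) m$pvalue, numeric(1))
  expect_true(all(diff(pv) >= 0))
  out <- file.path(tempdir(), "motifs_out")
  dir.create(out, showWarnings = FALSE)
  write_motifs_tsv(ms, file.path(out, "motifs.tsv"))
  tab <- read.table(file.path(out, "motifs.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  expect_identical(nrow(tab), length(ms$motifs))
  expect_true(all(c("consensus", "ratio", "pvalue", "merged") %in%
                    names(tab)))
  write_meme(ms, file.path(out, "motifs.meme"))
  meme <- readLines(file.path(out, "motifs.meme"))
  expect_identical(meme[1], "MEME version 4")
  expect_identical(sum(grepl("^MOTIF ", meme)), length(ms$motifs))
  expect_identical(sum(grepl("^letter-probability matrix:", meme)),
                   length(ms$motifs))
  paths <- write_ball_members(ms, out)
  expect_true(all(file.exists(paths)))
  bm <- read.table(paths[1], header = TRUE, sep = "\t")
  expect_true(all(bm$distance <= ms$motifs[[1]]$radius))
})
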