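test_that("generators are bit-reproducible under a fixed seed", {
  s1 <- three_motif_reads(seed = 61, n_reads = 50)
  s2 <- three_motif_reads(seed = 61, n_reads = 50)
  expect_identical(s1, s2)
  D1 <- generate_cluster_matrix(c(5, 5), 1, 9, jitter = 1, seed = 62)
  D2 <- generate_cluster_matrix(c(5, 5), 1, 9, jitter = 1, seed = 62)
  expect_identical(D1, D2)
  e1 <- editing_reads(seed = 63, n_reads = 30)
  e2 <- editing_reads(seed = 63, n_reads = 30)
  expect_identical(e1, e2)
})

test_that("implant rate 0 and 1 hit their boundary behavior", {
  none <- generate_motif_dataset(40, 60, implant_spec("ACGTACGTAC", 0),
                                 seed = 64)
  expect_identical(nrow(none$implants), 0L)
  expect_identical(read_support(none$sequences,
                                hamming_ball("ACGTACGTAC", 0)), 0)
  all_in <- generate_motif_dataset(40, 60,
                                   implant_spec("ACGTACGTAC", 1, 0),
                                   seed = 65)
  expect_identical(nrow(all_in$implants), 40L)
  expect_identical(read_support(all_in$sequences,
                                hamming_ball("ACGTACGTAC", 0)), 1)
  expect_true(all(nchar(all_in$sequences) == 60))
})

test_that("the implant log reproduces read support exactly", {
  # exact implants of a 10-mer: background collisions are vanishingly
  # rare, so the log determines support
  ds <- generate_motif_dataset(300, 80, implant_spec("CACGTGACTT", 0.4, 0),
                               seed = 66)
  got <- read_support(ds$sequences, hamming_ball("CACGTGACTT", 0))
  expect_equal(got, length(unique(ds$implants$read)) / 300)
  # mutated implants stay within their declared bounds
  mut <- generate_motif_dataset(200, 80, implant_spec("CACGTGAC", 0.5, 2),
                                seed = 73)
  expect_true(all(mut$implants$mutations <= 2))
  expect_true(all(mut$implants$start >= 1 &
                    mut$implants$start <= 80 - 8 + 1))
  dist_to_cons <- vapply(seq_len(nrow(mut$implants)), function(i) {
    r <- mut$implants[i, ]
    frag <- substr(mut$sequences[[r$read]], r$start, r$start + 7)
    hamming_distance(frag, "CACGTGAC")
  }, integer(1))
  expect_identical(dist_to_cons, mut$implants$mutations)
})

test_that("implants respect strand probability and error on misuse", {
  rc_ds <- generate_motif_dataset(200, 50,
                                  implant_spec("GGATCCTTAG", 1, 0,
                                               strand_rc_prob = 1),
                                  seed = 67)
  expect_true(all(rc_ds$implants$strand == "-"))
  expect_identical(read_support(rc_ds$sequences,
                                hamming_ball("GGATCCTTAG", 0),
                                rc_mode = TRUE), 1)
  expect_identical(read_support(rc_ds$sequences,
                                hamming_ball("GGATCCTTAG", 0),
                                rc_mode = FALSE), 0)
  expect_error(generate_motif_dataset(10, 6, implant_spec("ACGTACGTAC", 1)),
               "shorter")
  expect_error(implant_spec("ACGT", 0.5, max_mutations = 4))
})

test_that("cluster matrices are exact blocks at zero jitter", {
  D <- generate_cluster_matrix(c(2, 3), within = 1, between = 9)
  labels <- attr(D, "labels")
  same <- outer(labels, labels, "==")
  expect_true(all(D[same & !diag(5)] == 1))
  expect_true(all(D[!same] == 9))
  expect_true(all(diag(D) == 0))
  Dj <- generate_cluster_matrix(c(4, 4), within = 0.2, between = 8,
                                jitter = 0.5, seed = 68)
  expect_identical(Dj, t(Dj))
  expect_true(all(Dj >= 0))
})

test_that("editing reads apply the drawn pattern and pad uniformly", {
  ref <- simulate_random_dna(60, seed = 69)[[1]]
  one <- generate_editing_reads(25, ref,
                                list(list(op = "deletion", position = 10,
                                          length = 5)), weights = 1,
                                seed = 70)
  expect_true(all(one$labels == "1"))
  expect_identical(length(unique(one$sequences)), 1L)
  expect_true(all(hamming_matrix(one$sequences) == 0))
  expect_identical(nchar(one$sequences[[1]]), 60L)  # padded to reference
  ins <- generate_editing_reads(5, ref,
                                list(list(op = "insertion", position = 3,
                                          length = 2, payload = "GG")),
                                weights = 1, seed = 71)
  expect_identical(substr(ins$sequences[[1]], 3, 4), "GG")
  expect_identical(nchar(ins$sequences[[1]]), 62L)
  expect_error(generate_editing_reads(5, ref,
                                      list(list(op = "deletion",
                                                position = 58, length = 5)),
                                      weights = 1), "outside")
  # two equal weights give group sizes within binomial bounds
  two <- generate_editing_reads(400, ref,
                                list(list(op = "deletion", position = 10,
                                          length = 3),
                                     list(op = "deletion", position = 30,
                                          length = 6)),
                                weights = c(0.5, 0.5), seed = 72)
  n1 <- sum(two$labels == "1")
  expect_lt(abs(n1 - 200), 2.58 * sqrt(400 * 0.25) + 1)
})
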