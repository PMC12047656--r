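test_that("hamming_distance counts mismatches and is a metric", {
  expect_identical(hamming_distance("ACGT", "ACGT"), 0L)
  expect_identical(hamming_distance("AAAA", "TTTT"), 4L)
  expect_identical(hamming_distance("AATCGTAG", "AATCGTAC"), 1L)
  expect_error(hamming_distance("ACG", "ACGT"), "unequal")
  set.seed(7)
  for (i in 1:25) {
    trio <- sapply(1:3, function(j)
      paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = ""))
    dab <- hamming_distance(trio[1], trio[2])
    dba <- hamming_distance(trio[2], trio[1])
    expect_identical(dab, dba)
    expect_lte(hamming_distance(trio[1], trio[3]),
               dab + hamming_distance(trio[2], trio[3]))
    expect_identical(dab == 0L, trio[1] == trio[2])
  }
})

test_that("reverse_complement is an involution over A<->T, C<->G", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AAAA"), "TTTT")
  expect_identical(reverse_complement("GGAA"), "TTCC")
  expect_error(reverse_complement("ACGN"), "outside")
  set.seed(8)
  words <- replicate(20, paste(sample(c("A", "C", "G", "T"), 11,
                                      replace = TRUE), collapse = ""))
  expect_identical(reverse_complement(reverse_complement(words)), words)
})

test_that("orbit sizes follow C(k,i) 3^i and conserve the 4^k space", {
  expect_identical(orbit_size(8, 0), 1)
  expect_identical(orbit_size(8, 2), 252)
  expect_identical(orbit_size(8, 6), 20412)
  expect_error(orbit_size(8, 9), "0 <= i <= k")
  for (k in 1:8)
    expect_identical(sum(orbit_size(k, 0:k)), 4^k)
})

test_that("orbit sizes match exhaustive enumeration from any center", {
  set.seed(11)
  for (k in 2:5) {
    space <- all_kmers(k)
    center <- sample(space, 1)
    d <- vapply(space, slow_hamming, numeric(1), b = center)
    enum <- tabulate(d + 1, nbins = k + 1)
    expect_equal(enum, orbit_size(k, 0:k), ignore_attr = TRUE)
  }
})

test_that("orbit-size sequence is unimodal with mode near 3k/4", {
  expect_identical(mode_orbit(8), 6L)
  expect_identical(mode_orbit(1), 1L)
  expect_identical(mode_orbit(4), 3L)
  for (k in 1:16) {
    sizes <- orbit_size(k, 0:k)
    dd <- diff(sizes)
    # increases to a single maximum then decreases (one plateau allowed)
    expect_lte(sum(diff(sign(dd)[dd != 0]) != 0), 1)
    expect_lte(abs(mode_orbit(k) - 3 * k / 4), 1)
  }
})

test_that("ball probability is exact, monotone in r, and center-free", {
  expect_identical(ball_probability(8, 2), 277 / 65536)
  expect_lt(abs(100 * ball_probability(8, 2) - 0.42), 0.01)
  expect_identical(ball_probability(6, 1), 19 / 4096)
  for (k in c(3, 8, 12)) expect_identical(ball_probability(k, k), 1)
  for (k in c(5, 9)) {
    p <- vapply(0:k, function(r) ball_probability(k, r), numeric(1))
    expect_true(all(diff(p) > 0))
  }
  expect_error(ball_probability(8, 9), "radius")
})

test_that("ball_members enumerates exactly the r-neighborhood", {
  expect_identical(ball_members("AC", 0), "AC")
  expect_setequal(ball_members("AA", 1),
                  c("AA", "CA", "GA", "TA", "AC", "AG", "AT"))
  expect_length(ball_members("ACGTACGT", 2), 277)
  # oracle: enumeration over the full space, center-independent size
  set.seed(12)
  for (k in 3:5) {
    space <- all_kmers(k)
    center <- sample(space, 1)
    r <- sample(1:2, 1)
    want <- space[vapply(space, slow_hamming, numeric(1), b = center) <= r]
    expect_setequal(ball_members(center, r), want)
  }
  expect_error(ball_members("ACGTACGTACGT", 5), "allow_large")
  expect_length(ball_members("ACGTA", 5, allow_large = TRUE), 4^5)
})

test_that("default_radius reproduces the anchored points", {
  expect_identical(default_radius(c(5, 8, 16)), c(1L, 2L, 4L))
  expect_identical(default_radius(10), 2L)
  expect_true(all(default_radius(1:4) == 1L))
})

test_that("hamming_ball validates members against the radius", {
  b <- hamming_ball("ACG", 1)
  expect_s3_class(b, "hamming_ball")
  expect_length(b$members, 10)
  expect_error(hamming_ball("ACG", 1, members = c(TTT = 2)), "outside")
  b2 <- hamming_ball("ACG", 1, members = c(ACG = 3, ACC = 1))
  expect_identical(unname(b2$members), c(3, 1))
})
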