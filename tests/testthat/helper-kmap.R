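# Shared fixtures: all data is generated in code under fixed seeds.

# Enumerate the full 4^k k-mer space (oracle for small k).
all_kmers <- function(k) {
  grid <- do.call(expand.grid,
                  rep(list(c("A", "C", "G", "T")), k))
  apply(as.matrix(grid), 1, function(r) paste(rev(r), collapse = ""))
}

# Brute-force Hamming distance, independent of the package's C++ path.
slow_hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Three well-separated, non-palindromic 8-mer consensuses used by the
# SELEX-like three-motif instance (2000 x 40 bp reads; implant rates
# 15/10/8%; up to 2 substitutions).
THREE_MOTIF_CONSENSUS <- c("CACGTGAC", "GGATAGCT", "TTCCGGTA")

three_motif_reads <- function(seed, n_reads = 2000, read_len = 40) {
  generate_motif_dataset(n_reads, read_len, list(
    implant_spec(THREE_MOTIF_CONSENSUS[1], 0.15, 2),
    implant_spec(THREE_MOTIF_CONSENSUS[2], 0.10, 2),
    implant_spec(THREE_MOTIF_CONSENSUS[3], 0.08, 2)), seed = seed)
}

# Null models are deterministic given their seed, so fixtures share them
# across tests through the package cache.
cached_null <- function(k, r = default_radius(k), rc_mode = TRUE) {
  null_model(k, r, length = 1e5, repeats = 10, seed = 1000 + k,
             rc_mode = rc_mode)
}

# Small AAVS1-like editing instance: a random 120 bp reference cut by four
# distinct repair outcomes (two MMEJ-style deletions, one templated
# insertion, one 1 nt NHEJ deletion).
editing_patterns <- function() {
  list(list(op = "deletion", position = 50, length = 12),
       list(op = "deletion", position = 55, length = 5),
       list(op = "insertion", position = 57, length = 3, payload = "CAG"),
       list(op = "deletion", position = 58, length = 1))
}

editing_reads <- function(seed, n_reads = 800) {
  ref <- simulate_random_dna(120, seed = 321)[[1]]
  generate_editing_reads(n_reads, ref, editing_patterns(),
                         weights = c(0.3, 0.3, 0.2, 0.2), seed = seed)
}

cluster_purity <- function(cluster, truth) {
  keep <- cluster != 0
  if (!any(keep)) return(0)
  tab <- table(cluster[keep], truth[keep])
  sum(apply(tab, 1, max)) / sum(tab)
}
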