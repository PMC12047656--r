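# Null distribution of the Hamming-ball ratio on random DNA.

#' Simulate uniform random DNA
#'
#' One record of i.i.d. uniform characters over {A,C,G,T}; reproducible
#' under a fixed seed.  This is the background model under which the
#' Hamming-ball ratio has expectation 1.
#'
#' @param length Sequence length (>= 1).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A one-record sequence set named `random_dna`.
#' @export
simulate_random_dna <- function(length, seed = NULL) {
  length <- as.numeric(length)
  if (is.na(length) || length < 1)
    stop("simulate_random_dna: 'length' must be >= 1")
  draw <- function()
    paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
  s <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  c(random_dna = s)
}

# Hamming-ball ratios for several centers at once (vectorized core).
# Returns the ratio plus the per-center size factor s = sqrt(p_ref / p_c):
# under canonical counting the strand-union ball of a (near-)palindromic
# center is up to half the generic size, which inflates the binomial
# sampling spread of its ratio by up to sqrt(2); standardizing deviations
# by s makes ratios of all centers comparable under one null sigma.
ball_ratio_stats <- function(counts, centers, r) {
  stopifnot(inherits(counts, "kmer_counts"))
  k <- counts$k
  if (counts$total_windows == 0)
    stop("ball_ratio: undefined for counts with zero scanned windows")
  key_codes <- cpp_encode(names(counts$counts), k)
  ctr_codes <- cpp_encode(toupper(centers), k)
  if (any(is.na(ctr_codes)))
    stop("ball_ratio: centers must be valid k-mers of length ", k)
  st <- cpp_ball_stats(key_codes, unname(counts$counts), ctr_codes,
                       k, as.integer(r), counts$rc_mode)
  p_c <- st[, 2] / 4^k
  p_ref <- ball_probability(k, r) * (if (counts$rc_mode) 2 else 1)
  data.frame(center = centers,
             ratio = (st[, 1] / counts$total_windows) / p_c,
             size_factor = sqrt(p_ref / p_c), stringsAsFactors = FALSE)
}

ball_ratios <- function(counts, centers, r) {
  st <- ball_ratio_stats(counts, centers, r)
  setNames(st$ratio, centers)
}

#' Hamming-ball ratio of a center in observed counts
#'
#' Ratio between the empirical probability of the ball (count mass of its
#' members over all scanned windows) and its uniform-manifold probability.
#' Values near 1 are expected on random DNA; strong enrichment gives
#' ratios far above 1.  When the counts are canonical (`rc_mode`), the
#' ball is taken as the strand union of the balls around the center and
#' its reverse complement, with the theoretical probability adjusted to
#' the raw size of that union.
#'
#' @param counts A `kmer_counts` object with `counts$k == nchar(center)`.
#' @param center Center (consensus) k-mer.
#' @param r Ball radius.
#' @return Non-negative ratio (0 when no member is observed).
#' @examples
#' ct <- kmer_counts(c(AA = 5), k = 2, total_windows = 20)
#' ball_ratio(ct, "AA", 0)  # (5/20) / (1/16) = 4
#' @export
ball_ratio <- function(counts, center, r) {
  unname(ball_ratios(counts, center, r))
}

# Sigma estimator with the mean fixed at 1 (ML for known mean), floored.
null_sigma <- function(ratios) {
  sigma <- sqrt(mean((ratios - 1)^2))
  if (!is.finite(sigma) || sigma < 1e-12) {
    warning("degenerate null ratios: sigma floored at 1e-12")
    sigma <- 1e-12
  }
  sigma
}

#' Fit the Gaussian null of the Hamming-ball ratio
#'
#' Simulates `repeats` independent random DNA sequences, counts k-mers in
#' each, computes the Hamming-ball ratio of every distinct observed k-mer
#' (capped at `max_centers` sampled centers for k >= 10), and fits a
#' Gaussian with the mean fixed at 1: `sigma = sqrt(mean((x - 1)^2))`.
#'
#' @param k k-mer length.
#' @param r Ball radius (default [default_radius()]).
#' @param length Length of each simulated sequence (default 100000 bp).
#' @param repeats Number of independent simulations (default 10).
#' @param seed Optional integer seed controlling the whole fit.
#' @param rc_mode Match the reverse-complement mode of the query data.
#' @param max_centers Cap on centers per repeat for k >= 10.
#' @return An object of class `kmap_null` with fields `k`, `r`, `sigma`,
#'   `mean` (always 1) and `fit_meta`.
#' @export
fit_null <- function(k, r = default_radius(k), length = 100000, repeats = 10,
                     seed = NULL, rc_mode = FALSE, max_centers = 5000) {
  k <- as.integer(k)
  r <- as.integer(r)
  repeats <- as.integer(repeats)
  if (is.na(repeats) || repeats < 1) stop("fit_null: 'repeats' must be >= 1")
  run <- function() {
    ratios <- vector("list", repeats)
    n_centers <- 0L
    for (rep in seq_len(repeats)) {
      seqs <- simulate_random_dna(length)
      ct <- count_kmers(seqs, k, rc_mode)
      centers <- names(ct$counts)
      if (k >= 10L && base::length(centers) > max_centers)
        centers <- sort(sample(centers, max_centers))
      n_centers <- n_centers + base::length(centers)
      st <- ball_ratio_stats(ct, centers, r)
      # pool size-standardized deviations so that palindromic (half-size)
      # balls do not inflate the fitted spread
      ratios[[rep]] <- 1 + (st$ratio - 1) / st$size_factor
    }
    list(ratios = unlist(ratios, use.names = FALSE), n_centers = n_centers)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(k = k, r = r, sigma = null_sigma(res$ratios), mean = 1,
                 fit_meta = list(sequence_length = length, repeats = repeats,
                                 seed = seed, n_centers_used = res$n_centers,
                                 rc_mode = isTRUE(rc_mode),
                                 max_centers = max_centers)),
            class = "kmap_null")
}

#' @export
print.kmap_null <- function(x, ...) {
  cat(sprintf("Hamming-ball ratio null: k = %d, r = %d, N(1, %.4g^2)\n",
              x$k, x$r, x$sigma))
  cat(sprintf("  fitted on %d x %s bp (rc_mode %s, %d centers)\n",
              x$fit_meta$repeats, format(x$fit_meta$sequence_length),
              x$fit_meta$rc_mode, x$fit_meta$n_centers_used))
  invisible(x)
}

#' Upper-tail p-value of an observed Hamming-ball ratio
#'
#' One-sided (enrichment-only) tail probability of `Normal(1, sigma^2)` at
#' the observed ratio; ratios below 1 (depletion) give p > 0.5 and are
#' never significant.  `size_factor` standardizes the ratio deviation for
#' centers whose strand-union ball is smaller than the generic size under
#' canonical counting (near-palindromic centers); the default 1 applies to
#' plain-strand counting.
#'
#' @param model A `kmap_null` model.
#' @param ratio Observed ratio(s).
#' @param size_factor Per-center spread scaling `sqrt(p_ref / p_center)`
#'   (default 1).
#' @return p-value(s) in (0, 1), strictly decreasing in the ratio.
#' @export
ratio_pvalue <- function(model, ratio, size_factor = 1) {
  stopifnot(inherits(model, "kmap_null"))
  p <- pnorm(1 + (ratio - 1) / size_factor, mean = 1, sd = model$sigma,
             lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
}

# In-memory cache of fitted nulls keyed by the full parameter set.
.null_cache <- new.env(parent = emptyenv())

#' Fetch (or fit and cache) a null model
#'
#' Null models depend only on `(k, r, length, repeats, seed, rc_mode)`, not
#' on the query data, so they are cached in memory and reused across
#' discovery iterations and runs.
#'
#' @inheritParams fit_null
#' @return A `kmap_null` model.
#' @export
null_model <- function(k, r = default_radius(k), length = 100000,
                       repeats = 10, seed = NULL, rc_mode = FALSE,
                       max_centers = 5000) {
  key <- paste(k, r, length, repeats, seed %||% "NULL", rc_mode, max_centers,
               sep = "_")
  if (!is.null(seed) && exists(key, envir = .null_cache))
    return(get(key, envir = .null_cache))
  model <- fit_null(k, r, length, repeats, seed, rc_mode, max_centers)
  if (!is.null(seed)) assign(key, model, envir = .null_cache)
  model
}

#' Write / read a null model as a small key-value text file
#'
#' @param model A `kmap_null` model.
#' @param path File path.
#' @return `write_null` returns the path invisibly; `read_null` returns the
#'   model.
#' @export
write_null <- function(model, path) {
  stopifnot(inherits(model, "kmap_null"))
  meta <- model$fit_meta
  lines <- c(paste0("k=", model$k), paste0("r=", model$r),
             paste0("sigma=", format(model$sigma, digits = 17)),
             paste0("mean=", model$mean),
             paste0("sequence_length=", meta$sequence_length),
             paste0("repeats=", meta$repeats),
             paste0("seed=", meta$seed %||% "NA"),
             paste0("n_centers_used=", meta$n_centers_used),
             paste0("rc_mode=", meta$rc_mode),
             paste0("max_centers=", meta$max_centers))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_null
#' @export
read_null <- function(path) {
  kv <- read.table(path, sep = "=", col.names = c("key", "value"),
                   colClasses = "character")
  val <- setNames(kv$value, kv$key)
  num <- function(x) suppressWarnings(as.numeric(x))
  structure(list(k = as.integer(val[["k"]]), r = as.integer(val[["r"]]),
                 sigma = num(val[["sigma"]]), mean = 1,
                 fit_meta = list(sequence_length = num(val[["sequence_length"]]),
                                 repeats = as.integer(val[["repeats"]]),
                                 seed = if (val[["seed"]] == "NA") NULL
                                        else as.integer(val[["seed"]]),
                                 n_centers_used = as.integer(val[["n_centers_used"]]),
                                 rc_mode = as.logical(val[["rc_mode"]]),
                                 max_centers = num(val[["max_centers"]]))),
            class = "kmap_null")
}
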