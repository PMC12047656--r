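# Cross-entropy 2D embedding with a diffusion escape for coincident points.

#' Embedding configuration
#'
#' @param learning_rate Gradient-descent step size (default 0.01).
#' @param iterations Number of full-batch iterations (default 2500).
#' @param sigma Global kernel scale of the high-dimensional similarities;
#'   one value for all points (no point-specific scaling, which preserves
#'   the global structure of the manifold and leaves random k-mers in the
#'   peripheral space).
#' @param diffusion_threshold Pairs closer than this in 2D receive
#'   diffusion noise before each gradient evaluation (default 0.1).
#' @param diffusion_sd Standard deviation of the diffusion noise
#'   (default 0.01).
#' @param seed Optional integer seed for initialization and diffusion.
#' @param init_range Half-width of the uniform initialization box.
#' @param clip Per-point gradient-norm clip (0 disables; default 4).
#' @param squared_kernel Use `exp(-d^2/(2 sigma^2))` instead of the
#'   default `exp(-d/(2 sigma^2))` for the input similarities.
#' @return An object of class `embed_config`.
#' @export
embed_config <- function(learning_rate = 0.01, iterations = 2500, sigma = 1,
                         diffusion_threshold = 0.1, diffusion_sd = 0.01,
                         seed = NULL, init_range = 10, clip = 4,
                         squared_kernel = FALSE) {
  stopifnot(learning_rate > 0, iterations > 0, sigma > 0,
            diffusion_threshold > 0, diffusion_sd > 0, init_range > 0,
            clip >= 0)
  structure(list(learning_rate = learning_rate,
                 iterations = as.integer(iterations), sigma = sigma,
                 diffusion_threshold = diffusion_threshold,
                 diffusion_sd = diffusion_sd, seed = seed,
                 init_range = init_range, clip = clip,
                 squared_kernel = isTRUE(squared_kernel)),
            class = "embed_config")
}

#' High-dimensional similarity probabilities
#'
#' `p_ij = exp(-d(x_i, x_j) / (2 sigma^2))` with a single global sigma
#' (set `squared = TRUE` for the Gaussian-kernel variant on d^2).
#'
#' @param D Distance matrix (finite, non-negative).
#' @param sigma Global kernel scale (> 0).
#' @param squared Exponentiate the squared distance instead.
#' @return Symmetric matrix in (0, 1] with unit diagonal.
#' @export
similarity_p <- function(D, sigma = 1, squared = FALSE) {
  if (sigma <= 0) stop("similarity_p: 'sigma' must be positive")
  D <- as.matrix(D)
  if (!all(is.finite(D))) stop("similarity_p: 'D' must be finite")
  x <- if (squared) D^2 else D
  P <- exp(-x / (2 * sigma^2))
  diag(P) <- 1
  P
}

#' Low-dimensional similarity probabilities
#'
#' Student-type kernel `q_ij = 1 / (1 + ||w_i - w_j||^2)` on 2D
#' coordinates.
#'
#' @param W n x 2 coordinate matrix.
#' @return Symmetric matrix in (0, 1].
#' @export
similarity_q <- function(W) {
  W <- as.matrix(W)
  if (!all(is.finite(W))) stop("similarity_q: coordinates must be finite")
  1 / (1 + as.matrix(dist(W))^2)
}

#' Cross-entropy loss between similarity matrices
#'
#' `sum_{i != j} p log(p/q) + (1-p) log((1-p)/(1-q))`, with the
#' `0 * log 0 = 0` convention for p in {0, 1} and q clamped to
#' `[1e-12, 1 - 1e-12]`.  Non-negative; zero iff P = Q off-diagonal.
#'
#' @param P,Q Similarity matrices of equal dimension.
#' @return Scalar loss.
#' @export
cross_entropy_loss <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(all(dim(P) == dim(Q)))
  qc <- pmin(pmax(Q, 1e-12), 1 - 1e-12)
  t1 <- ifelse(P > 0, P * log(P / qc), 0)
  t2 <- ifelse(P < 1, (1 - P) * log((1 - P) / (1 - qc)), 0)
  M <- t1 + t2
  diag(M) <- 0
  sum(M)
}

#' 2D embedding of a distance matrix by cross-entropy descent
#'
#' Initializes coordinates uniformly in the seeded box
#' `[-init_range, init_range]^2`, then runs exactly
#' `config$iterations` full-batch gradient steps on the cross-entropy
#' loss between `p_ij` (from `D` via [similarity_p()]) and
#' `q_ij = 1/(1 + ||w_i - w_j||^2)`, using the gradient
#' `4 (p_ij - q_ij) (w_i - w_j) / ||w_i - w_j||^2`.  Before each gradient
#' evaluation, every ordered pair closer than `diffusion_threshold`
#' receives independent `N(0, diffusion_sd^2)` noise on `w_j` -- the
#' diffusion escape that keeps the gradient denominator away from zero
#' when many input items are exact duplicates.  Per-point gradient norms
#' are clipped at `config$clip`.
#'
#' @param D Square symmetric distance matrix.
#' @param labels Optional item labels carried into the result.
#' @param config An [embed_config()].
#' @return A `kmap_embedding`: `coordinates` (n x 2), `labels`,
#'   `loss_trace` (one loss per iteration) and the config.
#' @export
kmap_embed <- function(D, labels = NULL, config = embed_config()) {
  stopifnot(inherits(config, "embed_config"))
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("kmap_embed: 'D' must be square and symmetric")
  if (!is.null(labels) && length(labels) != n)
    stop("kmap_embed: 'labels' must match nrow(D)")
  P <- similarity_p(D, config$sigma, config$squared_kernel)
  run <- function() {
    W0 <- matrix(runif(2 * n, -config$init_range, config$init_range),
                 ncol = 2)
    cpp_embed(P, W0, config$iterations, config$learning_rate,
              config$diffusion_threshold, config$diffusion_sd, config$clip)
  }
  res <- if (is.null(config$seed)) run()
    else withr::with_seed(config$seed, run())
  if (!all(is.finite(res$W)) || !all(is.finite(res$loss)))
    stop("kmap_embed: non-finite coordinates or loss encountered")
  structure(list(coordinates = res$W, labels = labels,
                 loss_trace = as.numeric(res$loss), config = config),
            class = "kmap_embedding")
}

#' @export
print.kmap_embedding <- function(x, ...) {
  n <- nrow(x$coordinates)
  cat(sprintf("2D embedding of %d items (%d iterations, final loss %.4g)\n",
              n, length(x$loss_trace), tail(x$loss_trace, 1)))
  invisible(x)
}

#' Write an embedding as item/label/x/y TSV
#'
#' @param embedding A `kmap_embedding`.
#' @param path Output path.
#' @param items Optional item strings (same length as the embedding).
#' @export
write_embedding_tsv <- function(embedding, path, items = NULL) {
  n <- nrow(embedding$coordinates)
  tab <- data.frame(item = items %||% seq_len(n),
                    label = embedding$labels %||% rep(NA, n),
                    x = embedding$coordinates[, 1],
                    y = embedding$coordinates[, 2])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scatter plot of an embedding
#'
#' Motif items are colored by label and random items drawn in gray.
#' Requires ggplot2.
#'
#' @param embedding A `kmap_embedding`.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_embedding requires the ggplot2 package")
  df <- data.frame(x = embedding$coordinates[, 1],
                   y = embedding$coordinates[, 2],
                   label = embedding$labels %||%
                     rep("item", nrow(embedding$coordinates)))
  df$is_random <- df$label == "random"
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point(data = df[df$is_random, ], color = "grey70",
                        size = 0.6) +
    ggplot2::geom_point(data = df[!df$is_random, ],
                        ggplot2::aes(color = label), size = 0.8) +
    ggplot2::labs(x = "dim 1", y = "dim 2", color = "motif") +
    ggplot2::theme_minimal()
}
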