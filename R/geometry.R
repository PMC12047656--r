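# Pairwise Hamming distance matrices and the two manifold-aware distance
# transformations: neighbor smoothing and sigmoid repulsion.

#' Transformation parameters for a given item length
#'
#' The sigmoid repulsion uses curvature `gamma = 0.2*k - 0.2` and change
#' point `x0 = k/2` -- the rough boundary between a Hamming ball and the
#' outer orbits, given that two random k-mers sit at expected distance
#' 3k/4.  Neighbor smoothing uses `n_neighbors` nearest items.
#'
#' @param k Item length (k-mer length, or the aligned read length for
#'   non-k-mer inputs).
#' @param gamma,x0 Optional overrides of the defaults above.
#' @param n_neighbors Neighborhood size for smoothing (default 20).
#' @return An object of class `transform_params`.
#' @examples
#' transform_params(8)  # gamma 1.4, x0 4
#' @export
transform_params <- function(k, gamma = NULL, x0 = NULL, n_neighbors = 20) {
  k <- as.integer(k)
  gamma <- gamma %||% (0.2 * k - 0.2)
  x0 <- x0 %||% (k / 2)
  if (gamma <= 0)
    stop("transform_params: gamma must be positive (k >= 2 for the default)")
  structure(list(k = k, gamma = gamma, x0 = x0,
                 n_neighbors = as.integer(n_neighbors)),
            class = "transform_params")
}

#' Pairwise Hamming distance matrix
#'
#' @param items Character vector of equal-length strings (k-mers or
#'   aligned reads; duplicates allowed and give exact zeros).
#' @return Symmetric integer matrix with zero diagonal.
#' @export
hamming_matrix <- function(items) {
  items <- toupper(as.character(items))
  if (length(items) < 2L) stop("hamming_matrix: need at least two items")
  if (length(unique(nchar(items))) != 1L)
    stop("hamming_matrix: items have mixed lengths")
  D <- cpp_hamming_matrix(items)
  storage.mode(D) <- "double"
  D
}

# Neighborhoods exclude the item itself; ties in the k-NN cut break by
# item index, which makes duplicated items deterministic mutual neighbors.
neighbor_sets <- function(D, nn) {
  n <- nrow(D)
  vapply(seq_len(n), function(i) {
    ord <- order(D[i, ], seq_len(n))
    ord <- ord[ord != i]
    ord[seq_len(nn)]
  }, integer(nn))
}

# Mean pairwise distance between the neighborhoods of i and j, computed as
# A D A' with A the row-normalized sparse neighbor indicator.
neighbor_smooth <- function(D, nn) {
  n <- nrow(D)
  nbr <- neighbor_sets(D, nn)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = nn),
                            j = as.integer(nbr), x = 1 / nn,
                            dims = c(n, n))
  S <- as.matrix(A %*% D %*% Matrix::t(A))
  (S + t(S)) / 2
}

#' Neighbor smoothing of a distance matrix
#'
#' Entry (i, j) becomes the mean Hamming distance over all pairs drawn
#' from the `n_neighbors` nearest items to i and to j (self excluded).
#' Pulls members of a dense cluster together: neighbors of one motif
#' k-mer are typically neighbors of another, while distances to random
#' k-mers stay near 3k/4.  The diagonal is recomputed by the same rule and
#' then zeroed.
#'
#' @param D Square symmetric distance matrix.
#' @param n_neighbors Neighborhood size (must be `< nrow(D)`).
#' @return Smoothed symmetric matrix with zero diagonal.
#' @export
smooth_distances <- function(D, n_neighbors = 20) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D)) stop("smooth_distances: 'D' must be square")
  if (n_neighbors >= n)
    stop("smooth_distances: 'n_neighbors' must be smaller than nrow(D)")
  S <- neighbor_smooth(D, as.integer(n_neighbors))
  diag(S) <- 0
  S
}

#' Sigmoid repulsion of smoothed distances
#'
#' Entrywise `f(x) = 16 / (1 + exp(-gamma * (x - x0)))`: a strictly
#' increasing map onto (0, 16) with midpoint value 8 at `x0`.  Distances
#' beyond the ball boundary are pushed toward 16 while within-ball
#' distances collapse toward 0, mitigating the conflict between Hamming
#' and Euclidean geometry.  The diagonal is forced back to 0.
#'
#' @param D0 Smoothed distance matrix (entries >= 0).
#' @param params A [transform_params()] object.
#' @return Transformed matrix with zero diagonal.
#' @export
repulse_transform <- function(D0, params) {
  stopifnot(inherits(params, "transform_params"))
  D0 <- as.matrix(D0)
  if (any(D0 < 0)) stop("repulse_transform: distances must be >= 0")
  out <- 16 / (1 + exp(-params$gamma * (D0 - params$x0)))
  diag(out) <- 0
  out
}

#' Read / write a distance matrix as headerless TSV
#'
#' @param path File path.
#' @param D Numeric matrix (for writing).
#' @return `read_distance_matrix` returns a numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  D <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  dimnames(D) <- NULL
  if (!is.numeric(D)) stop("read_distance_matrix: non-numeric entries")
  D
}

#' @rdname read_distance_matrix
#' @export
write_distance_matrix <- function(D, path) {
  write.table(as.matrix(D), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
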