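# Exact combinatorics and geometry of the k-mer space: orbits, Hamming
# balls, reverse complements.

DNA_BASES <- c("A", "C", "G", "T")

check_kmer <- function(x, arg = deparse(substitute(x))) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) < 1L)
    stop(sprintf("'%s' must be a single non-empty DNA string", arg))
  x <- toupper(x)
  if (grepl("[^ACGT]", x))
    stop(sprintf("'%s' contains characters outside {A,C,G,T}", arg))
  x
}

#' Hamming distance between two equal-length DNA words
#'
#' Number of positions at which `a` and `b` differ.  The Hamming distance is
#' the metric of the k-mer manifold: a k-mer at distance i from a chosen
#' origin lies in the origin's i-th orbit.
#'
#' @param a,b Single DNA strings of equal length.
#' @return Non-negative integer count of mismatching positions.
#' @examples
#' hamming_distance("ACGT", "ACGT")  # 0
#' hamming_distance("AAAA", "TTTT")  # 4
#' @export
hamming_distance <- function(a, b) {
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  if (nchar(a) != nchar(b))
    stop("hamming_distance: sequences have unequal lengths (",
         nchar(a), " vs ", nchar(b), ")")
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over the alphabet A<->T, C<->G.  Applying
#' the function twice returns the input (involution).
#'
#' @param x Character vector of DNA strings (A, C, G, T only).
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("GGAA")  # "TTCC"
#' @export
reverse_complement <- function(x) {
  x <- toupper(as.character(x))
  if (any(grepl("[^ACGT]", x)))
    stop("reverse_complement: input contains characters outside {A,C,G,T}")
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Map k-mers to their canonical (strand-collapsed) form
#'
#' The canonical form of a k-mer is the lexicographic minimum of the k-mer
#' and its reverse complement, so both strands share one representative.
#'
#' @param x Character vector of DNA k-mers.
#' @return Character vector of canonical k-mers.
#' @export
canonical_kmer <- function(x) {
  pmin(toupper(as.character(x)), reverse_complement(x))
}

#' Size of an orbit of the k-mer manifold
#'
#' The i-th orbit around any origin k-mer contains all k-mers at exact
#' Hamming distance i; its size is `choose(k, i) * 3^i`, independent of the
#' chosen origin (the manifold is isotropic).  Orbit sizes sum to 4^k.
#'
#' @param k k-mer length (1..16).
#' @param i Orbit index, `0 <= i <= k`.  May be a vector.
#' @return Exact orbit size(s) as doubles (integral for k <= 16).
#' @examples
#' orbit_size(8, 2)              # 252
#' sum(orbit_size(8, 0:8))       # 4^8
#' @export
orbit_size <- function(k, i) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("orbit_size: 'k' must be a positive integer")
  if (any(is.na(i)) || any(i < 0) || any(i > k))
    stop("orbit_size: orbit index 'i' must satisfy 0 <= i <= k")
  choose(k, i) * 3^i
}

#' Index of the densest orbit
#'
#' Returns the orbit index maximizing [orbit_size()]; the orbit-size
#' sequence is unimodal with its mode near 3k/4.  Ties break toward the
#' smaller index.
#'
#' @param k k-mer length.
#' @return Integer orbit index.
#' @examples
#' mode_orbit(8)  # 6
#' @export
mode_orbit <- function(k) {
  sizes <- orbit_size(k, 0:k)
  which.max(sizes) - 1L
}

#' Uniform probability of a Hamming ball
#'
#' Probability that a uniformly random k-mer lies within Hamming distance r
#' of a fixed center: `sum_{i<=r} orbit_size(k, i) / 4^k`.  Independent of
#' the center and strictly increasing in r; equals 1 at r = k.
#'
#' @param k k-mer length.
#' @param r Ball radius, `0 <= r <= k`.
#' @return Probability in (0, 1].
#' @examples
#' ball_probability(8, 2)  # 277/65536, about 0.4%
#' @export
ball_probability <- function(k, r) {
  k <- as.integer(k)
  r <- as.integer(r)
  if (length(r) != 1L || is.na(r) || r < 0L || r > k)
    stop("ball_probability: radius 'r' must satisfy 0 <= r <= k")
  sum(orbit_size(k, 0:r)) / 4^k
}

#' Enumerate the members of a Hamming ball
#'
#' All k-mers within Hamming distance `r` of `center`, including the center
#' itself.  The member count is `sum_{i<=r} choose(k, i) * 3^i`, which
#' explodes with r, so radii of 5 or more require `allow_large = TRUE`.
#'
#' @param center Center (consensus) k-mer.
#' @param r Ball radius.
#' @param allow_large Override the capacity guard on `r >= 5`.
#' @return Character vector of member k-mers in lexicographic order.
#' @examples
#' ball_members("AA", 1)  # 7 members
#' @export
ball_members <- function(center, r, allow_large = FALSE) {
  center <- check_kmer(center)
  k <- nchar(center)
  r <- as.integer(r)
  if (is.na(r) || r < 0L || r > k)
    stop("ball_members: radius 'r' must satisfy 0 <= r <= k")
  if (r >= 5L && !allow_large)
    stop("ball_members: radius ", r, " enumerates ",
         format(sum(orbit_size(k, 0:r)), big.mark = ","),
         " k-mers; pass allow_large = TRUE to proceed")
  codes <- cpp_ball_members(cpp_encode(center, k), k, r)
  sort(cpp_decode(codes, k))
}

#' Default Hamming-ball radius for a given k
#'
#' Radius rule `max(1, round(k/4))`, anchored so that k = 8 yields radius
#' 2 and the ball stays a small fraction of the 4^k manifold across the
#' default k range (about 0.09% at k = 10, 0.04% at k = 12).  Overridable
#' wherever a radius argument is accepted.
#'
#' @param k k-mer length (vectorized).
#' @return Integer radius per k.
#' @examples
#' default_radius(c(5, 8, 16))  # 1 2 4
#' @export
default_radius <- function(k) {
  pmax(1L, as.integer(round(k / 4)))
}

#' Construct a Hamming ball
#'
#' A Hamming ball is the method's unit of motif: a center (consensus)
#' k-mer, a radius, and a member table.  When `members` is omitted the full
#' ball is enumerated (subject to the [ball_members()] capacity guard) with
#' zero counts, ready to be attached to data.
#'
#' @param center Center k-mer.
#' @param radius Ball radius.
#' @param members Optional named numeric vector of member counts (names are
#'   member k-mers, each within `radius` of `center`).
#' @param allow_large Passed to [ball_members()] when enumerating.
#' @return An object of class `hamming_ball`.
#' @export
hamming_ball <- function(center, radius, members = NULL, allow_large = FALSE) {
  center <- check_kmer(center)
  radius <- as.integer(radius)
  if (is.null(members)) {
    mem <- ball_members(center, radius, allow_large = allow_large)
    members <- setNames(numeric(length(mem)), mem)
  } else {
    if (is.null(names(members)) && is.character(members))
      members <- setNames(numeric(length(members)), members)
    nm <- toupper(names(members))
    if (any(nchar(nm) != nchar(center)))
      stop("hamming_ball: members must have the same length as the center")
    d <- vapply(nm, hamming_distance, integer(1), b = center)
    if (any(d > radius))
      stop("hamming_ball: member(s) ", paste(nm[d > radius], collapse = ", "),
           " lie outside radius ", radius)
    names(members) <- nm
    if (any(members < 0)) stop("hamming_ball: member counts must be >= 0")
  }
  structure(list(center = center, radius = radius, members = members),
            class = "hamming_ball")
}

#' @export
print.hamming_ball <- function(x, ...) {
  cat("Hamming ball: center", x$center, "radius", x$radius, "with",
      length(x$members), "members (", sum(x$members > 0), "observed )\n")
  invisible(x)
}
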