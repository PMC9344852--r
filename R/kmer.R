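#' Hamming distance between two equal-length sequences
#'
#' Counts positions at which the two sequences differ. With `cap` set, the
#' scan stops as soon as the running count exceeds `cap` and returns
#' `cap + 1` as a sentinel (a truncated distance): callers that only need to
#' know whether the distance is within a threshold can avoid scanning full
#' sequences that are clearly far apart.
#'
#' @param a,b sequences of equal length over A/C/G/T.
#' @param cap optional non-negative integer; when given, any true distance
#'   greater than `cap` is reported as `cap + 1`.
#' @return Integer distance (or the `cap + 1` sentinel).
#' @examples
#' hamming_distance("ACGT", "ACGA")
#' hamming_distance("AAAA", "TTTT", cap = 2) # sentinel 3
#' @export
hamming_distance <- function(a, b, cap = NULL) {
  cpp_hamming(a, b, if (is.null(cap)) -1L else as.integer(cap))
}

#' k-mer partition scheme for fixed-length barcodes
#'
#' Tiles a barcode of length `l` into `p` non-overlapping partitions:
#' `floor(l / k)` partitions of length `k` plus, when `k` does not divide
#' `l`, one remainder partition of length `r = l %% k`. Two sequences within
#' Hamming distance `epsilon` must agree on at least `p - epsilon` whole
#' partitions (pigeonhole principle), so the scheme also enumerates all
#' `choose(p, p - epsilon)` partition subsets of size `p - epsilon` ("k-mer
#' combinations"); a feasible scheme requires `p - epsilon >= 1`.
#'
#' When `k` is omitted it is chosen automatically: among feasible values the
#' cost `choose(p, p - epsilon) + sum_c n / 4^(nucleotides in combination c)`
#' is minimized (hash lookups per query plus expected spurious bucket
#' collisions among `n` random sequences), ties going to the larger `k`.
#'
#' @param l barcode length (nucleotides).
#' @param epsilon Hamming distance threshold (>= 1).
#' @param k substring length; `NULL` to choose automatically.
#' @param n expected number of unique sequences to be indexed (used only by
#'   the automatic choice of `k`).
#' @return An object of class `"shepherd_scheme"`.
#' @examples
#' kmer_scheme(8, epsilon = 2, k = 2)   # p = 4, six 2-mer pairs
#' kmer_scheme(26, epsilon = 2, k = 3)  # eight 3-mers + one 2-mer
#' @export
kmer_scheme <- function(l, epsilon, k = NULL, n = 1e5) {
  l <- as.integer(l); epsilon <- as.integer(epsilon)
  if (l < 1L || epsilon < 1L) stop("need l >= 1 and epsilon >= 1")
  if (is.null(k)) {
    feasible <- Filter(function(kk) scheme_feasible(l, epsilon, kk), seq_len(l))
    if (length(feasible) == 0L)
      stop("no substring length k gives p - epsilon > 0 for l = ", l,
           ", epsilon = ", epsilon)
    cost <- vapply(feasible, function(kk) scheme_cost(l, epsilon, kk, n),
                   numeric(1))
    # ties -> larger k
    k <- max(feasible[cost <= min(cost) * (1 + 1e-12)])
  } else {
    k <- as.integer(k)
    if (!scheme_feasible(l, epsilon, k))
      stop("infeasible scheme: l = ", l, ", k = ", k, ", epsilon = ", epsilon,
           " leaves p - epsilon <= 0 (or the combination ID space exceeds ",
           "64-bit integers)")
  }
  build_scheme(l, epsilon, k)
}

partition_bounds <- function(l, k) {
  nfull <- l %/% k
  r <- l %% k
  lens <- c(rep.int(k, nfull), if (r > 0L) r)
  starts <- cumsum(c(0L, lens[-length(lens)]))
  list(starts = as.integer(starts), lens = as.integer(lens),
       p = length(lens), r = as.integer(r))
}

scheme_feasible <- function(l, epsilon, k) {
  if (k < 1L || k > l) return(FALSE)
  pb <- partition_bounds(l, k)
  m <- pb$p - epsilon
  if (m < 1L) return(FALSE)
  # combination IDs must fit in a 64-bit signed integer
  max_nt <- k * m # a subset of m full-length partitions always exists
  log2_span <- lchoose(pb$p, m) / log(2) + 2 * max_nt
  log2_span < 62
}

scheme_cost <- function(l, epsilon, k, n) {
  pb <- partition_bounds(l, k)
  m <- pb$p - epsilon
  subs <- utils::combn(pb$p, m)
  nt <- colSums(matrix(pb$lens[subs], nrow = m))
  ncol(subs) + sum(n / 4^nt)
}

build_scheme <- function(l, epsilon, k) {
  pb <- partition_bounds(l, k)
  m <- pb$p - epsilon
  subs <- utils::combn(pb$p, m) # lexicographic subset order
  structure(list(
    l = l, k = as.integer(k), epsilon = epsilon,
    p = pb$p, r = pb$r,
    starts0 = pb$starts, lens = pb$lens,
    partition_bounds = cbind(start = pb$starts, end = pb$starts + pb$lens),
    subsets0 = subs - 1L,
    n_combinations = ncol(subs),
    max_nt = as.integer(k * m)
  ), class = "shepherd_scheme")
}

#' @export
print.shepherd_scheme <- function(x, ...) {
  cat("k-mer scheme: l =", x$l, "| k =", x$k, "| epsilon =", x$epsilon,
      "| p =", x$p, if (x$r > 0) paste0("(remainder ", x$r, " nt)"),
      "|", x$n_combinations, "combinations per sequence\n")
  invisible(x)
}

#' Combination IDs of a sequence
#'
#' Encodes each of the scheme's `choose(p, p - epsilon)` k-mer combinations
#' of a sequence as an integer ID: the lexicographic rank of the partition
#' subset shifted by `4^max_nt`, plus the base-4 value of the concatenated
#' partition contents (A=0, C=1, G=2, T=3). The mapping (subset, contents)
#' -> ID is injective, so two sequences emit a common ID if and only if they
#' agree on every position of some `p - epsilon` partition subset. IDs are
#' returned as decimal strings because they can exceed R's exact double
#' integer range.
#'
#' @param seq a sequence of length `scheme$l`.
#' @param scheme a [kmer_scheme()].
#' @return Character vector of `choose(p, p - epsilon)` decimal integer IDs.
#' @export
combination_ids <- function(seq, scheme) {
  stopifnot(inherits(scheme, "shepherd_scheme"))
  cpp_combination_ids(seq, scheme)
}

#' Build the k-mer index of a ReadSet
#'
#' Single pass over the unique sequences: each sequence's combination IDs
#' are inserted into a hash table mapping ID -> set of sequences containing
#' that combination. The index answers [kmer_neighborhood()] and
#' [epsilon_neighborhood()] queries.
#'
#' @param reads a [read_set()] (or character vector of unique sequences).
#' @param scheme a [kmer_scheme()] with matching `l`.
#' @return An object of class `"shepherd_index"`.
#' @export
build_kmer_index <- function(reads, scheme) {
  stopifnot(inherits(scheme, "shepherd_scheme"))
  if (is.character(reads)) reads <- read_set(reads, rep(1, length(reads)))
  stopifnot(inherits(reads, "shepherd_reads"))
  if (reads$length != scheme$l)
    stop("read length ", reads$length, " does not match scheme l = ", scheme$l)
  ptr <- cpp_index_build(reads$sequences, unclass(scheme))
  structure(list(ptr = ptr, scheme = scheme, sequences = reads$sequences,
                 counts = reads$counts),
            class = "shepherd_index")
}

#' @export
print.shepherd_index <- function(x, ...) {
  cat("k-mer index over", length(x$sequences), "sequences |")
  print(x$scheme)
  invisible(x)
}

#' k-mer neighborhood of a sequence
#'
#' All indexed sequences sharing at least one combination ID with the query
#' (the query itself excluded). By the pigeonhole principle this is a
#' superset of the epsilon-neighborhood; when `l` is a multiple of `k` no
#' member lies beyond Hamming distance `k * epsilon`.
#'
#' @param seq query sequence of length `l`.
#' @param index a [build_kmer_index()] result.
#' @return Integer indices into `index$sequences`.
#' @export
kmer_neighborhood <- function(seq, index) {
  stopifnot(inherits(index, "shepherd_index"))
  cpp_kmer_neighborhood(index$ptr, seq)
}

#' Exact epsilon-neighborhood of a sequence
#'
#' Filters the k-mer neighborhood down to the sequences within Hamming
#' distance `epsilon` of the query, using the truncated distance. The result
#' is exactly the set an all-pairs Hamming scan would produce, ordered by
#' distance (ascending) then read count (descending) then sequence, the
#' order in which downstream tie-breaking consumes it.
#'
#' @inheritParams kmer_neighborhood
#' @return A data frame with columns `idx` (index into `index$sequences`)
#'   and `dist`.
#' @export
epsilon_neighborhood <- function(seq, index) {
  stopifnot(inherits(index, "shepherd_index"))
  res <- cpp_eps_neighborhood(index$ptr, seq, as.numeric(index$counts))
  data.frame(idx = res$idx, dist = res$dist)
}
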