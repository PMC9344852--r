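#' Cluster barcode reads at a single timepoint
#'
#' The main error correction procedure. Unique sequences are visited in
#' descending read-count order (count ties broken lexicographically, so
#' results are bit-reproducible). The highest-count sequence is always a
#' putative barcode. Each subsequent sequence either (a) has no putative
#' barcode within Hamming distance epsilon and becomes a putative barcode
#' itself, or (b) is tested against its closest putative barcode (distance
#' ties go to the higher-count one) with the Bayesian log-Bayes-factor
#' test: an `ERROR_SEQUENCE` verdict joins it to that barcode's cluster, a
#' `TRUE_BARCODE` verdict opens a new cluster. A sequence whose count
#' exceeds `skip_frac * f_max` is unambiguously a true barcode and bypasses
#' the test (`skip_test = TRUE`, the default).
#'
#' When `rho` is missing it is estimated from the data with
#' [estimate_rho()]; when `epsilon` is missing it is chosen with
#' [choose_epsilon()]; when `k` is missing the scheme picks it
#' automatically (see [kmer_scheme()]).
#'
#' @param reads a [read_set()].
#' @param rho per-nucleotide substitution rate; `NULL` to estimate.
#' @param epsilon Hamming distance threshold; `NULL` to choose.
#' @param k substring length; `NULL` for automatic.
#' @param log_bf_threshold ln K decision threshold (default -4).
#' @param skip_test bypass the Bayes test for counts above
#'   `skip_frac * f_max` (default TRUE).
#' @param skip_frac fraction of `f_max` above which the test is skipped.
#' @param max_epsilon clamp ceiling for the automatic epsilon choice (see
#'   [choose_epsilon()]); ignored when `epsilon` is given.
#' @return An object of class `"shepherd_clusters"`: sequences (in
#'   processing order) with their counts, per-sequence cluster assignment
#'   and distance to center, the center indices, accumulated cluster
#'   totals, and the parameters used.
#' @examples
#' rs <- read_set(c("ACGTACGTAC", "ACGTACGTAA", "ACGTACGTAG"), c(500, 3, 2))
#' res <- cluster_reads(rs, rho = 0.005, epsilon = 2)
#' clusters(res)
#' @export
cluster_reads <- function(reads, rho = NULL, epsilon = NULL, k = NULL,
                          log_bf_threshold = -4, skip_test = TRUE,
                          skip_frac = 0.05, max_epsilon = 3L) {
  stopifnot(inherits(reads, "shepherd_reads"))
  ord <- order(-reads$counts, reads$sequences, method = "radix")
  reads <- read_set(reads$sequences[ord], reads$counts[ord])

  if (is.null(rho)) {
    # rho is needed to choose epsilon, and estimating it only requires
    # distance-1 neighbors: estimate from a provisional epsilon = 1 index
    scheme1 <- kmer_scheme(reads$length, 1L, n = length(reads$sequences))
    idx1 <- build_kmer_index(reads, scheme1)
    rho <- estimate_rho(reads, idx1)
  }
  if (is.null(epsilon)) epsilon <- choose_epsilon(reads, rho, max_epsilon)
  scheme <- kmer_scheme(reads$length, epsilon, k = k,
                        n = length(reads$sequences))
  index <- build_kmer_index(reads, scheme)
  model <- error_model(rho, reads$length, f_max = max(reads$counts),
                       log_bf_threshold = log_bf_threshold)

  res <- cpp_cluster(index$ptr, as.numeric(reads$counts), rho,
                     log_bf_threshold, skip_frac, isTRUE(skip_test))
  structure(list(
    sequences = reads$sequences,
    counts = reads$counts,
    assignment = res$assign,
    distance = res$dist,
    centers = which(res$is_center),
    cluster_totals = res$cluster_total,
    indel = NULL,
    dropped_indel = 0,
    scheme = scheme,
    model = model,
    index = index
  ), class = "shepherd_clusters")
}

#' Cluster membership table
#'
#' @param result a [cluster_reads()] result.
#' @return A data frame with one row per cluster: `center_sequence`,
#'   `total_count`, `n_members` (members beyond the center, indel-corrected
#'   reads included), sorted by total count (descending) then sequence.
#' @export
clusters <- function(result) {
  stopifnot(inherits(result, "shepherd_clusters"))
  ctr <- result$centers
  n_members <- tabulate(result$assignment, nbins = length(result$sequences))[ctr] - 1L
  if (!is.null(result$indel) && nrow(result$indel) > 0) {
    extra <- table(factor(result$indel$center, levels = ctr))
    n_members <- n_members + as.integer(extra)
  }
  out <- data.frame(center_sequence = result$sequences[ctr],
                    total_count = result$cluster_totals[ctr],
                    n_members = n_members,
                    stringsAsFactors = FALSE)
  out[order(-out$total_count, out$center_sequence, method = "radix"), ,
      drop = FALSE]
}

#' Per-sequence assignment table
#'
#' @param result a [cluster_reads()] result.
#' @return A data frame: `sequence`, `count`, `center_sequence`, `distance`
#'   for every length-l input sequence (indel-corrected off-length reads,
#'   if any, are appended with their center and `distance = NA`).
#' @export
assignments <- function(result) {
  stopifnot(inherits(result, "shepherd_clusters"))
  out <- data.frame(sequence = result$sequences,
                    count = result$counts,
                    center_sequence = result$sequences[result$assignment],
                    distance = result$distance,
                    stringsAsFactors = FALSE)
  if (!is.null(result$indel) && nrow(result$indel) > 0) {
    out <- rbind(out, data.frame(sequence = result$indel$sequence,
                                 count = result$indel$count,
                                 center_sequence = result$sequences[result$indel$center],
                                 distance = NA_integer_,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' @export
print.shepherd_clusters <- function(x, ...) {
  cat("clustering:", length(x$centers), "putative barcodes from",
      length(x$sequences), "unique sequences (",
      format(sum(x$counts), big.mark = ","), "reads )\n")
  print(x$model)
  print(x$scheme)
  invisible(x)
}

#' Fold single insertion/deletion reads into existing clusters
#'
#' Post-processing for reads one nucleotide longer or shorter than the
#' barcode length l. Each length l+1 sequence is reduced by every one of
#' its l+1 single deletions; each length l-1 sequence is expanded by every
#' single insertion (l positions x 4 bases). If any variant equals a
#' putative barcode, the read count is added to that barcode's cluster;
#' when several putative barcodes are reachable, the one with the higher
#' cluster total wins (then lexicographic order). Unmatched off-length
#' reads are dropped and counted. Cluster membership decisions made by the
#' main pass are not revisited.
#'
#' @param result a [cluster_reads()] result.
#' @param off_length data frame of `sequence`, `count` with lengths
#'   `l + 1` or `l - 1` (others are ignored and counted as dropped).
#' @return The updated `"shepherd_clusters"` object.
#' @export
correct_indels <- function(result, off_length) {
  stopifnot(inherits(result, "shepherd_clusters"))
  if (is.null(off_length) || nrow(off_length) == 0L) return(result)
  l <- result$scheme$l
  centers <- result$centers
  center_seq <- result$sequences[centers]
  center_lookup <- seq_along(centers)
  names(center_lookup) <- center_seq

  rows <- vector("list", nrow(off_length))
  dropped <- 0
  for (i in seq_len(nrow(off_length))) {
    s <- off_length$sequence[i]
    len <- nchar(s)
    if (len == l + 1L) {
      vars <- del_variants(s)
    } else if (len == l - 1L) {
      vars <- ins_variants(s)
    } else {
      dropped <- dropped + off_length$count[i]
      next
    }
    hit <- center_lookup[unique(vars)]
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0L) {
      dropped <- dropped + off_length$count[i]
      next
    }
    tot <- result$cluster_totals[centers[hit]]
    best <- hit[order(-tot, center_seq[hit], method = "radix")][1L]
    rows[[i]] <- data.frame(sequence = s, count = off_length$count[i],
                            center = centers[best], stringsAsFactors = FALSE)
  }
  added <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (!is.null(added)) {
    agg <- tapply(added$count, added$center, sum)
    at <- as.integer(names(agg))
    result$cluster_totals[at] <- result$cluster_totals[at] + as.numeric(agg)
    result$indel <- rbind(result$indel, added)
  }
  result$dropped_indel <- result$dropped_indel + dropped
  result
}

# all sequences obtainable by deleting one position
del_variants <- function(s) {
  n <- nchar(s)
  vapply(seq_len(n), function(i) paste0(substr(s, 1L, i - 1L),
                                        substr(s, i + 1L, n)),
         character(1))
}

# all sequences obtainable by inserting one base at any position
ins_variants <- function(s) {
  n <- nchar(s)
  out <- character(4L * (n + 1L))
  bases <- c("A", "C", "G", "T")
  idx <- 1L
  for (i in 0:n) {
    pre <- substr(s, 1L, i)
    post <- substr(s, i + 1L, n)
    for (b in bases) {
      out[idx] <- paste0(pre, b, post)
      idx <- idx + 1L
    }
  }
  unique(out)
}
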