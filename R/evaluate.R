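#' False positive cluster count
#'
#' Number of identified cluster centers that are not true barcodes — each
#' one is a spurious lineage. A cluster corresponds to a true barcode iff
#' its center sequence is exactly a true barcode.
#'
#' @param result a [cluster_reads()] result.
#' @param true_barcodes character vector of true barcode sequences.
#' @return Integer count.
#' @export
false_positive_count <- function(result, true_barcodes) {
  stopifnot(inherits(result, "shepherd_clusters"))
  sum(!(result$sequences[result$centers] %in% true_barcodes))
}

#' False negative cluster count
#'
#' Number of true barcodes that appear in the data but were absorbed as a
#' member of a cluster centered on another sequence, i.e. incorrectly
#' classified as error sequences. A true barcode absorbed into a cluster
#' centered on an error sequence counts as a false negative too (it was
#' still misclassified).
#'
#' @inheritParams false_positive_count
#' @return Integer count.
#' @export
false_negative_count <- function(result, true_barcodes) {
  stopifnot(inherits(result, "shepherd_clusters"))
  pos <- match(true_barcodes, result$sequences)
  pos <- pos[!is.na(pos)]
  sum(result$assignment[pos] != pos)
}

#' Effective cluster radius
#'
#' Cluster compactness: for each cluster with at least two sequences, the
#' mean Hamming distance between the cluster's highest-count sequence
#' (count ties broken by lexicographically smallest sequence) and every
#' other member. Singleton clusters are excluded. Values near 1 indicate
#' tight clusters dominated by single-error sequences.
#'
#' @param result a [cluster_reads()] result.
#' @return Named numeric vector, one radius per multi-member cluster
#'   (names are the cluster center sequences).
#' @export
effective_cluster_radius <- function(result) {
  stopifnot(inherits(result, "shepherd_clusters"))
  out <- numeric(0)
  nm <- character(0)
  for (ci in result$centers) {
    members <- which(result$assignment == ci)
    if (length(members) < 2L) next
    sq <- result$sequences[members]
    cn <- result$counts[members]
    hub <- sq[order(-cn, sq, method = "radix")][1L]
    rest <- setdiff(sq, hub)
    out <- c(out, mean(vapply(rest, function(s) cpp_hamming(hub, s, -1L),
                              numeric(1))))
    nm <- c(nm, result$sequences[ci])
  }
  names(out) <- nm
  out
}

#' Per-timepoint mean absolute count error
#'
#' Mean of `|estimated - true|` over the barcodes identified by the method
#' (matched to the truth by exact sequence), at each timepoint.
#'
#' @param table a [track_lineages()] result (or a [cluster_reads()] result,
#'   treated as one timepoint).
#' @param truth list with `barcodes` and `counts` (vector or matrix) as
#'   produced by the simulators.
#' @return Numeric vector of MAE values, one per timepoint.
#' @export
count_mae <- function(table, truth) {
  if (inherits(table, "shepherd_clusters")) {
    est_bc <- table$sequences[table$centers]
    est <- matrix(table$cluster_totals[table$centers], ncol = 1L)
  } else {
    stopifnot(inherits(table, "shepherd_lineages"))
    est_bc <- table$barcodes
    est <- table$counts
  }
  tc <- truth$counts
  if (is.null(dim(tc))) tc <- matrix(tc, ncol = 1L)
  m <- match(truth$barcodes, est_bc)
  ok <- !is.na(m)
  if (!any(ok)) stop("no true barcode matched an identified barcode")
  colMeans(abs(est[m[ok], , drop = FALSE] - tc[ok, , drop = FALSE]))
}

#' Score a clustering against simulation ground truth
#'
#' @inheritParams false_positive_count
#' @param truth list with `barcodes` and `counts` from the simulator.
#' @return A list of class `"shepherd_eval"`: `fpc`, `fnc`, `n_true`,
#'   `n_clusters`, `n_matched` (centers that are true barcodes),
#'   `exact_count_fraction` (matched barcodes whose estimated count equals
#'   the true count exactly), `mae`, and the effective-radius vector `r_e`.
#' @export
evaluate_clustering <- function(result, truth) {
  stopifnot(inherits(result, "shepherd_clusters"))
  centers_seq <- result$sequences[result$centers]
  m <- match(truth$barcodes, centers_seq)
  ok <- !is.na(m)
  est <- result$cluster_totals[result$centers][m[ok]]
  structure(list(
    fpc = false_positive_count(result, truth$barcodes),
    fnc = false_negative_count(result, truth$barcodes),
    n_true = length(truth$barcodes),
    n_clusters = length(result$centers),
    n_matched = sum(ok),
    exact_count_fraction = mean(est == truth$counts[ok]),
    mae = mean(abs(est - truth$counts[ok])),
    r_e = effective_cluster_radius(result)
  ), class = "shepherd_eval")
}

#' @export
print.shepherd_eval <- function(x, ...) {
  cat(sprintf(paste0(
    "evaluation: %d clusters vs %d true barcodes\n",
    "  FPC %d | FNC %d | matched %d\n",
    "  exact-count fraction %.4f | MAE %.4f\n",
    "  r_e: %d multi-member clusters, range [%.3f, %.3f]\n"),
    x$n_clusters, x$n_true, x$fpc, x$fnc, x$n_matched,
    x$exact_count_fraction, x$mae, length(x$r_e),
    if (length(x$r_e)) min(x$r_e) else NA, if (length(x$r_e)) max(x$r_e) else NA))
  invisible(x)
}
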