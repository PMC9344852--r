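#' Track barcode lineages across timepoints
#'
#' Full clustering is performed only on the first timepoint. Every later
#' timepoint is treated as a classification problem: each sequence is
#' assigned to its closest putative barcode within distance epsilon
#' (distance ties go to the barcode whose cluster has the higher count at
#' this timepoint), unless the Bayesian test declares the sequence a true
#' barcode, in which case it is promoted to a new lineage. Promotion of a
#' sequence that was previously absorbed as a cluster member corrects a
#' first-timepoint false negative (two merged barcodes separate once their
#' count discrepancy grows); such lineages carry provenance
#' `"split-corrected"`, all other promotions `"emerging"`. Sequences with
#' no putative barcode within epsilon are buffered and clustered among
#' themselves with the same scheme; their cluster centers become new
#' lineages with `emerged_at` set to the current timepoint.
#'
#' `f_max` and the cluster-count de-bias are recomputed per timepoint from
#' that timepoint's data; `rho` is estimated once from the first timepoint
#' unless supplied.
#'
#' @param timepoints list of [read_set()] objects, one per timepoint, all
#'   with the same barcode length.
#' @inheritParams cluster_reads
#' @return An object of class `"shepherd_lineages"`: `barcodes`, a
#'   `barcode x timepoint` matrix `counts` of corrected read counts,
#'   per-barcode `emerged_at` and `provenance`
#'   (initial / emerging / split-corrected), and the parameters used.
#' @export
track_lineages <- function(timepoints, rho = NULL, epsilon = NULL, k = NULL,
                           log_bf_threshold = -4, skip_test = TRUE,
                           skip_frac = 0.05) {
  stopifnot(is.list(timepoints), length(timepoints) >= 1L)
  for (tp in timepoints) stopifnot(inherits(tp, "shepherd_reads"))
  l <- unique(vapply(timepoints, function(x) x$length, integer(1)))
  if (length(l) != 1L) stop("all timepoints must share the same barcode length")
  n_tp <- length(timepoints)

  first <- cluster_reads(timepoints[[1L]], rho = rho, epsilon = epsilon,
                         k = k, log_bf_threshold = log_bf_threshold,
                         skip_test = skip_test, skip_frac = skip_frac)
  rho <- first$model$rho
  scheme <- first$scheme

  barcodes <- first$sequences[first$centers]
  counts <- matrix(0, nrow = length(barcodes), ncol = n_tp)
  counts[, 1L] <- first$cluster_totals[first$centers]
  emerged_at <- rep.int(1L, length(barcodes))
  provenance <- rep.int("initial", length(barcodes))

  # sequences ever absorbed as members (candidates for split-correction)
  member_seen <- new.env(hash = TRUE, parent = emptyenv())
  mem <- which(first$assignment != seq_along(first$sequences))
  for (s in first$sequences[mem]) assign(s, TRUE, envir = member_seen)

  if (n_tp >= 2L) {
    cindex <- cpp_index_build(barcodes, unclass(scheme))
    for (t in 2L:n_tp) {
      rs <- timepoints[[t]]
      ord <- order(-rs$counts, rs$sequences, method = "radix")
      seqs <- rs$sequences[ord]
      cnts <- as.numeric(rs$counts[ord])
      f_max_t <- cnts[1L]

      n_before <- length(barcodes)
      ft0 <- numeric(n_before)
      exact <- match(seqs, barcodes)
      hit <- !is.na(exact)
      ft0[exact[hit]] <- cnts[hit]

      res <- cpp_classify_timepoint(cindex, ft0, seqs[!hit], cnts[!hit],
                                    rho, log_bf_threshold, f_max_t)
      rest_seqs <- seqs[!hit]
      rest_cnts <- cnts[!hit]

      promoted <- which(res$promoted)
      if (length(promoted)) {
        # cpp assigns promoted sequences ids n_before+1, ... in pass order
        promo_seqs <- rest_seqs[promoted]
        barcodes <- c(barcodes, promo_seqs)
        emerged_at <- c(emerged_at, rep.int(t, length(promo_seqs)))
        was_member <- vapply(promo_seqs,
                             function(s) exists(s, envir = member_seen),
                             logical(1), USE.NAMES = FALSE)
        provenance <- c(provenance,
                        ifelse(was_member, "split-corrected", "emerging"))
        counts <- rbind(counts, matrix(0, length(promo_seqs), n_tp))
      }
      ft <- res$ft

      # members first seen at this timepoint
      absorbed <- rest_seqs[res$assign > 0L & !res$promoted]
      for (s in absorbed) assign(s, TRUE, envir = member_seen)

      # unassigned sequences: cluster among themselves with the same scheme
      un <- which(res$assign == 0L)
      if (length(un)) {
        sub <- cluster_reads(read_set(rest_seqs[un], rest_cnts[un]),
                             rho = rho, epsilon = scheme$epsilon,
                             k = scheme$k,
                             log_bf_threshold = log_bf_threshold,
                             skip_test = skip_test, skip_frac = skip_frac)
        new_centers <- sub$sequences[sub$centers]
        cpp_index_insert(cindex, new_centers)
        barcodes <- c(barcodes, new_centers)
        emerged_at <- c(emerged_at, rep.int(t, length(new_centers)))
        provenance <- c(provenance, rep.int("emerging", length(new_centers)))
        counts <- rbind(counts, matrix(0, length(new_centers), n_tp))
        ft <- c(ft, sub$cluster_totals[sub$centers])
        submem <- sub$sequences[sub$assignment != seq_along(sub$sequences)]
        for (s in submem) assign(s, TRUE, envir = member_seen)
      }
      counts[, t] <- ft
    }
  }

  structure(list(barcodes = barcodes, counts = counts,
                 emerged_at = emerged_at, provenance = provenance,
                 scheme = scheme, rho = rho,
                 log_bf_threshold = log_bf_threshold),
            class = "shepherd_lineages")
}

#' @export
print.shepherd_lineages <- function(x, ...) {
  cat("lineage table:", length(x$barcodes), "barcodes x", ncol(x$counts),
      "timepoints |", sum(x$provenance == "emerging"), "emerging,",
      sum(x$provenance == "split-corrected"), "split-corrected\n")
  invisible(x)
}

#' Lineage table as a data frame
#'
#' @param x a [track_lineages()] result.
#' @param ... unused.
#' @return One row per barcode: `barcode`, `emerged_at`, `provenance`, and
#'   one `count_t<i>` column per timepoint.
#' @export
as.data.frame.shepherd_lineages <- function(x, ...) {
  cnt <- as.data.frame(x$counts)
  names(cnt) <- paste0("count_t", seq_len(ncol(x$counts)))
  cbind(data.frame(barcode = x$barcodes, emerged_at = x$emerged_at,
                   provenance = x$provenance, stringsAsFactors = FALSE),
        cnt)
}
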