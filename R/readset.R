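#' Deduplicated fixed-length barcode reads
#'
#' A `ReadSet` is the universal input of the clustering routines: a set of
#' unique sequences over the alphabet A/C/G/T, all of the same length, each
#' with a positive integer read count. Use [tally_reads()] to build one from
#' raw (possibly repeated) reads, or [read_reads()] to ingest a file.
#'
#' @param sequences character vector of unique A/C/G/T sequences, all of the
#'   same length.
#' @param counts positive integer read counts, one per sequence.
#' @return An object of class `"shepherd_reads"`: a list with elements
#'   `sequences`, `counts` and `length` (the common sequence length `l`).
#' @examples
#' rs <- read_set(c("ACGTACGT", "ACGTACGA"), c(10, 2))
#' rs$length
#' @export
read_set <- function(sequences, counts) {
  sequences <- as.character(sequences)
  if (length(sequences) == 0L) stop("empty read set")
  if (length(counts) != length(sequences))
    stop("`sequences` and `counts` must have the same length")
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != floor(counts)))
    stop("counts must be positive integers")
  if (anyDuplicated(sequences))
    stop("sequences must be unique; tally duplicates first (see tally_reads)")
  l <- unique(nchar(sequences))
  if (length(l) != 1L)
    stop("all sequences must have the same length; route off-length reads ",
         "to indel correction instead")
  if (any(grepl("[^ACGT]", sequences)))
    stop("sequences contain non-ACGT characters")
  structure(list(sequences = sequences, counts = counts, length = as.integer(l)),
            class = "shepherd_reads")
}

#' Tally raw reads into a ReadSet
#'
#' Collapses identical reads, drops reads containing non-ACGT characters,
#' and separates reads whose length differs from the (modal or supplied)
#' barcode length: lengths `l + 1` and `l - 1` are kept aside for single
#' indel correction, any other length is dropped.
#'
#' @param reads character vector of raw reads (repeats allowed), or a
#'   two-column data frame of (sequence, count).
#' @param length barcode length `l`; defaults to the modal read length.
#' @return A list with elements `reads` (a [read_set()]), `off_length`
#'   (data frame of sequence/count at length `l +- 1`) and `dropped`
#'   (named counts of discarded reads).
#' @export
tally_reads <- function(reads, length = NULL) {
  if (is.data.frame(reads)) {
    dt <- data.table::data.table(sequence = as.character(reads[[1]]),
                                 count = as.numeric(reads[[2]]))
  } else {
    dt <- data.table::data.table(sequence = as.character(reads), count = 1)
  }
  dt <- dt[, list(count = sum(count)), by = "sequence"]
  bad <- grepl("[^ACGT]", dt$sequence)
  n_bad <- sum(dt$count[bad])
  dt <- dt[!bad]
  if (nrow(dt) == 0L) stop("no valid ACGT reads")
  len <- nchar(dt$sequence)
  if (is.null(length)) {
    tab <- tapply(dt$count, len, sum)
    length <- as.integer(names(tab)[which.max(tab)])
  }
  main <- len == length
  indel <- len == length + 1L | len == length - 1L
  n_len <- sum(dt$count[!main & !indel])
  if (!any(main)) stop("no reads at barcode length ", length)
  list(reads = read_set(dt$sequence[main], dt$count[main]),
       off_length = data.frame(sequence = dt$sequence[indel],
                               count = dt$count[indel],
                               stringsAsFactors = FALSE),
       dropped = c(non_acgt = n_bad, off_length = n_len))
}

#' @export
print.shepherd_reads <- function(x, ...) {
  cat("ReadSet:", length(x$sequences), "unique sequences of length",
      x$length, "|", format(sum(x$counts), big.mark = ","), "reads\n")
  invisible(x)
}
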