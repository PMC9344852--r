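#' Read barcode reads from TSV, FASTA or FASTQ
#'
#' A TSV input is headerless `sequence<TAB>count` (duplicate sequence lines
#' have their counts summed); FASTA/FASTQ records are tallied one read per
#' record via Biostrings. Reads containing non-ACGT characters are dropped
#' (counted), reads of length `l + 1` or `l - 1` are routed to the indel
#' buffer, other lengths are dropped (counted). The barcode length defaults
#' to the modal read length.
#'
#' @param path input file.
#' @param format `"auto"` (sniffed from extension, then content), `"tsv"`,
#'   `"fasta"` or `"fastq"`.
#' @param length barcode length override.
#' @return As [tally_reads()]: list of `reads`, `off_length`, `dropped`.
#' @export
read_reads <- function(path, format = c("auto", "tsv", "fasta", "fastq"),
                       length = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- sniff_format(path)
  if (format == "tsv") {
    dt <- tryCatch(
      data.table::fread(path, header = FALSE, sep = "\t",
                        colClasses = list(character = 1), data.table = TRUE),
      error = function(e) stop("cannot parse TSV ", path, ": ",
                               conditionMessage(e)))
    if (ncol(dt) < 2L)
      stop("TSV must have two columns: sequence<TAB>count (", path, ")")
    bad <- which(!grepl("^[0-9]+$", as.character(dt[[2L]])))
    if (length(bad))
      stop("non-integer count in ", path, " at line ", bad[1L])
    df <- data.frame(sequence = toupper(dt[[1L]]),
                     count = as.numeric(dt[[2L]]), stringsAsFactors = FALSE)
    tally_reads(df, length = length)
  } else {
    ss <- Biostrings::readDNAStringSet(path, format = format)
    tally_reads(toupper(as.character(ss)), length = length)
  }
}

sniff_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.(fq|fastq)(\\.gz)?$", lower)) return("fastq")
  if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", lower)) return("fasta")
  if (grepl("\\.(tsv|txt)(\\.gz)?$", lower)) return("tsv")
  first <- substr(readLines(path, n = 1L), 1L, 1L)
  if (identical(first, ">")) "fasta" else if (identical(first, "@")) "fastq"
  else "tsv"
}

#' Write cluster and assignment tables
#'
#' `write_clusters()` writes one row per cluster
#' (`center_sequence`, `total_count`, `n_members`), sorted by total count
#' descending then sequence; `write_assignments()` writes the per-sequence
#' table (`sequence`, `count`, `center_sequence`, `distance`). Both are
#' tab-separated with a header and round-trip through [data.table::fread()].
#'
#' @param result a [cluster_reads()] result.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_clusters <- function(result, path) {
  data.table::fwrite(clusters(result), path, sep = "\t")
  invisible(path)
}

#' @rdname write_clusters
#' @export
write_assignments <- function(result, path) {
  a <- assignments(result)
  a <- a[order(-a$count, a$sequence, method = "radix"), , drop = FALSE]
  data.table::fwrite(a, path, sep = "\t")
  invisible(path)
}

#' Write a lineage table
#'
#' One row per barcode: `barcode`, `emerged_at`, `provenance`, and one
#' count column per timepoint; sorted by final-timepoint count descending
#' then barcode.
#'
#' @param table a [track_lineages()] result.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_lineages <- function(table, path) {
  df <- as.data.frame(table)
  last <- df[[ncol(df)]]
  df <- df[order(-last, df$barcode, method = "radix"), , drop = FALSE]
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Machine-readable run metadata
#'
#' Collects the parameters a run actually used (including auto-chosen
#' epsilon, k and estimated rho) into a JSON string, for logging alongside
#' outputs.
#'
#' @param result a [cluster_reads()] or [track_lineages()] result.
#' @return A JSON string.
#' @export
run_metadata <- function(result) {
  scheme <- result$scheme
  model <- if (inherits(result, "shepherd_clusters")) result$model else NULL
  jsonlite::toJSON(list(
    package_version = as.character(utils::packageVersion("shepherd")),
    l = scheme$l, k = scheme$k, epsilon = scheme$epsilon, p = scheme$p,
    rho = if (!is.null(model)) model$rho else result$rho,
    log_bf_threshold = if (!is.null(model)) model$log_bf_threshold
                       else result$log_bf_threshold
  ), auto_unbox = TRUE, digits = NA)
}
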