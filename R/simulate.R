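#' Generate a library of random barcode sequences
#'
#' Each barcode is `l_random` i.i.d. uniform nucleotides followed by a
#' constant flanking sequence (the flank mimics the fixed context around
#' the random region in real lineage-tracking constructs; its placement is
#' irrelevant to the algorithms and fixed as a suffix for
#' reproducibility). Duplicates are redrawn until all barcodes are unique.
#'
#' @param n_barcodes number of barcodes.
#' @param l_random number of random nucleotides (default 20).
#' @param flank constant suffix (default `"ACGTAC"`, giving total length 26).
#' @return Character vector of `n_barcodes` unique sequences.
#' @export
generate_barcodes <- function(n_barcodes, l_random = 20L, flank = "ACGTAC") {
  if (n_barcodes > 4^l_random)
    stop("cannot draw ", n_barcodes, " unique barcodes from 4^", l_random,
         " possibilities")
  draw <- function(n) {
    m <- matrix(sample(c("A", "C", "G", "T"), n * l_random, replace = TRUE),
                nrow = n)
    paste0(do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE)), flank)
  }
  bc <- unique(draw(n_barcodes))
  while (length(bc) < n_barcodes)
    bc <- unique(c(bc, draw(n_barcodes - length(bc))))
  bc
}

#' Draw true barcode counts
#'
#' Counts are the ceiling of an Exponential variate with the given mean, so
#' every barcode has at least one copy; the resulting mean is
#' `1 / (1 - exp(-1/mean_count))` (~ 100.5 for `mean_count = 100`).
#'
#' @param n_barcodes number of barcodes.
#' @param mean_count mean of the underlying Exponential (default 100).
#' @return Integer counts, all `>= 1`.
#' @export
assign_counts <- function(n_barcodes, mean_count = 100) {
  as.integer(ceiling(stats::rexp(n_barcodes, rate = 1 / mean_count)))
}

#' Apply per-nucleotide substitution errors to reads
#'
#' Every read (a barcode repeated `counts` times) independently mutates
#' each of its `l` positions with probability `rho`; a mutated position is
#' replaced by one of the three other bases uniformly. Reads are tallied
#' into a [read_set()] and full provenance (observed sequence, source
#' barcode, read count) is recorded.
#'
#' @param barcodes character vector of barcode sequences.
#' @param counts integer true counts, one per barcode.
#' @param rho substitution probability per nucleotide, in `[0, 1)`.
#' @return A list: `reads` (a [read_set()]) and `truth` with
#'   `barcodes`, `counts`, and a `provenance` data table
#'   (sequence, source index, n_reads).
#' @export
apply_errors <- function(barcodes, counts, rho) {
  stopifnot(length(barcodes) == length(counts), rho >= 0, rho < 1)
  l <- nchar(barcodes[1L])
  n <- length(barcodes)
  total <- sum(counts)
  src <- rep.int(seq_len(n), counts)
  k <- stats::rbinom(total, l, rho)
  err <- which(k > 0L)

  err_src <- src[err]
  err_seqs <- mutate_reads(barcodes[err_src], k[err], l)

  clean <- counts - tabulate(err_src, nbins = n)
  keep <- clean > 0L
  dt <- data.table::data.table(
    sequence = c(barcodes[keep], err_seqs),
    source = c(which(keep), err_src),
    n_reads = c(clean[keep], rep.int(1L, length(err_seqs))))
  prov <- dt[, list(n_reads = sum(n_reads)), by = c("sequence", "source")]
  obs <- prov[, list(count = sum(n_reads)), by = "sequence"]
  list(reads = read_set(obs$sequence, obs$count),
       truth = list(barcodes = barcodes, counts = counts, provenance = prov))
}

# mutate each read at `k[i]` distinct positions, uniformly chosen; the
# position set of a Binomial(l, rho) error draw is uniform over k-subsets
mutate_reads <- function(x, k, l) {
  out <- x
  for (kk in sort(unique(k))) {
    sel <- which(k == kk)
    pos <- distinct_positions(length(sel), kk, l)
    for (j in seq_len(kk)) out[sel] <- substitute_at(out[sel], pos[, j])
  }
  out
}

# n x k matrix of distinct positions in 1..l, uniform over k-subsets;
# k <= 3 via the vectorized sequential-shift construction, rare larger k
# per read
distinct_positions <- function(n, k, l) {
  if (n == 0L) return(matrix(integer(0), 0L, k))
  if (k == 1L) return(matrix(sample.int(l, n, replace = TRUE), ncol = 1L))
  if (k == 2L) {
    a <- sample.int(l, n, replace = TRUE)
    b <- sample.int(l - 1L, n, replace = TRUE)
    b <- b + (b >= a)
    return(cbind(a, b))
  }
  if (k == 3L) {
    a <- sample.int(l, n, replace = TRUE)
    b <- sample.int(l - 1L, n, replace = TRUE)
    b <- b + (b >= a)
    m1 <- pmin(a, b); m2 <- pmax(a, b)
    cc <- sample.int(l - 2L, n, replace = TRUE)
    cc <- cc + (cc >= m1)
    cc <- cc + (cc >= m2)
    return(cbind(a, b, cc))
  }
  pos <- matrix(0L, n, k)
  for (i in seq_len(n)) pos[i, ] <- sample.int(l, k)
  pos
}

# vectorized single-position substitution to a uniformly chosen other base
substitute_at <- function(x, pos) {
  bases <- c("A", "C", "G", "T")
  oi <- match(substring(x, pos, pos), bases)
  ni <- ((oi - 1L + sample.int(3L, length(x), replace = TRUE)) %% 4L) + 1L
  substring(x, pos, pos) <- bases[ni]
  x
}

#' Simulate a single-timepoint barcode sequencing dataset
#'
#' Convenience wrapper: draws barcodes ([generate_barcodes()]), true counts
#' ([assign_counts()]), applies substitution errors ([apply_errors()]).
#'
#' @inheritParams generate_barcodes
#' @inheritParams assign_counts
#' @param rho substitution probability per nucleotide.
#' @param seed optional RNG seed for reproducibility.
#' @return As [apply_errors()].
#' @examples
#' sim <- simulate_reads(200, rho = 0.005, seed = 1)
#' sim$reads
#' @export
simulate_reads <- function(n_barcodes, rho, mean_count = 100, l_random = 20L,
                           flank = "ACGTAC", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bc <- generate_barcodes(n_barcodes, l_random, flank)
  cnt <- assign_counts(n_barcodes, mean_count)
  apply_errors(bc, cnt, rho)
}

#' Simulate a multi-timepoint lineage-tracking experiment
#'
#' Lineages receive i.i.d. Exponential base abundances; a random subset of
#' `n_advantaged` lineages grows by a factor `advantage` per timepoint
#' relative to the neutral ones (serial-transfer abstraction). At each
#' timepoint lineage frequencies are renormalized, `depth` reads are drawn
#' multinomially, and substitution errors are applied independently.
#'
#' @inheritParams simulate_reads
#' @param n_timepoints number of timepoints (>= 2).
#' @param n_advantaged number of lineages with a growth advantage
#'   (default 1% of `n_barcodes`).
#' @param advantage per-timepoint growth-rate multiplier of advantaged
#'   lineages (default 1.5).
#' @param depth sequencing depth (reads per timepoint); default
#'   `n_barcodes * mean_count`.
#' @return A list: `timepoints` (list of [read_set()]), `truth` with
#'   `barcodes`, the true `counts` matrix (barcode x timepoint), and the
#'   advantaged indices.
#' @export
simulate_lineage_series <- function(n_barcodes, rho, n_timepoints = 4L,
                                    n_advantaged = round(0.01 * n_barcodes),
                                    advantage = 1.5, mean_count = 100,
                                    depth = NULL, l_random = 20L,
                                    flank = "ACGTAC", seed = NULL) {
  stopifnot(n_timepoints >= 2L, n_advantaged <= n_barcodes)
  if (!is.null(seed)) set.seed(seed)
  depth <- depth %||% (n_barcodes * mean_count)
  bc <- generate_barcodes(n_barcodes, l_random, flank)
  base_w <- stats::rexp(n_barcodes, rate = 1 / mean_count)
  adv <- sample.int(n_barcodes, n_advantaged)
  growth <- rep.int(1, n_barcodes)
  growth[adv] <- advantage

  true_counts <- matrix(0L, n_barcodes, n_timepoints)
  tps <- vector("list", n_timepoints)
  for (t in seq_len(n_timepoints)) {
    w <- base_w * growth^(t - 1L)
    ct <- as.integer(stats::rmultinom(1L, depth, w / sum(w)))
    true_counts[, t] <- ct
    present <- ct > 0L
    tps[[t]] <- apply_errors(bc[present], ct[present], rho)$reads
  }
  list(timepoints = tps,
       truth = list(barcodes = bc, counts = true_counts, advantaged = adv))
}

#' Benchmark dataset presets
#'
#' Named single-timepoint simulation settings spanning low to high error
#' rates on the 20+6 nt barcode design: `A` (rho = 0.33%, 500k barcodes),
#' `B` (rho = 0.66%, 500k barcodes), `C` (rho = 2%, 100k barcodes).
#' `scale` multiplies the number of barcodes, e.g. `scale = 0.02` for a
#' desk-sized analogue of preset A.
#'
#' @param preset `"A"`, `"B"` or `"C"`.
#' @param scale multiplier on the number of barcodes (default 1).
#' @return A named list of arguments for [simulate_reads()].
#' @export
dataset_preset <- function(preset = c("A", "B", "C"), scale = 1) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
                A = list(n_barcodes = 500000L, rho = 0.0033),
                B = list(n_barcodes = 500000L, rho = 0.0066),
                C = list(n_barcodes = 100000L, rho = 0.02))
  cfg$n_barcodes <- as.integer(round(cfg$n_barcodes * scale))
  cfg$mean_count <- 100
  cfg
}
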