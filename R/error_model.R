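#' Substitution error model
#'
#' Holds the per-nucleotide substitution probability `rho`, the barcode
#' length `l`, the log-Bayes-factor decision threshold, and the highest
#' observed read count `f_max`. These four numbers drive the Bayesian test
#' that decides whether a sequence near a putative barcode is an error
#' sequence (model M1) or a true barcode in its own right (model M2).
#'
#' The default threshold -4 means the likelihood of M2 must exceed that of
#' M1 by a factor of about exp(4) ~ 55 before a sequence is promoted to a
#' true barcode; the asymmetry deliberately favors M1, because a spurious
#' new lineage is more disruptive to lineage tracking than a mildly
#' distorted count.
#'
#' @param rho per-nucleotide substitution probability, in (0, 1).
#' @param l barcode length.
#' @param f_max highest read count observed in the data.
#' @param log_bf_threshold decision threshold for ln K (default -4).
#' @return An object of class `"shepherd_model"`.
#' @export
error_model <- function(rho, l, f_max, log_bf_threshold = -4) {
  if (!is.finite(rho) || rho <= 0 || rho >= 1)
    stop("rho must lie strictly between 0 and 1")
  if (f_max < 1) stop("f_max must be >= 1")
  if (!is.finite(log_bf_threshold)) stop("threshold must be finite")
  structure(list(rho = rho, l = as.integer(l), f_max = as.numeric(f_max),
                 log_bf_threshold = log_bf_threshold),
            class = "shepherd_model")
}

#' @export
print.shepherd_model <- function(x, ...) {
  cat(sprintf("error model: rho = %.6g | l = %d | f_max = %g | lnK threshold = %g\n",
              x$rho, x$l, x$f_max, x$log_bf_threshold))
  invisible(x)
}

#' A single classification case
#'
#' Bundles the quantities the Bayesian test consumes: the Hamming distance
#' `d` between the candidate and its closest putative barcode, the candidate
#' read count `f_c`, and `n_hat`, the estimated true copy number of the
#' putative barcode. `n_hat` may be supplied directly or derived from the
#' putative barcode's accumulated cluster read count `f_p` via
#' [n_hat_estimate()].
#'
#' @param d Hamming distance, `>= 1`.
#' @param f_c candidate read count, `>= 1`.
#' @param n_hat estimated true count of the putative barcode, `>= 1`.
#' @return A list of class `"shepherd_case"`.
#' @export
test_case <- function(d, f_c, n_hat) {
  if (d < 1) stop("d must be >= 1 (a distance-0 pair is the same sequence)")
  if (f_c < 1) stop("f_c must be >= 1")
  if (n_hat < 1) stop("n_hat must be >= 1")
  structure(list(d = as.integer(d), f_c = as.numeric(f_c),
                 n_hat = as.numeric(n_hat)), class = "shepherd_case")
}

#' De-biased estimate of a putative barcode's true count
#'
#' A copy of a barcode is read error-free with probability `(1 - rho)^l`,
#' so the observed accumulated count `f_p` underestimates the true copy
#' number; `round(f_p / (1 - rho)^l)` undoes that bias.
#'
#' @param f_p accumulated cluster read count of the putative barcode.
#' @param model an [error_model()].
#' @export
n_hat_estimate <- function(f_p, model) {
  round(f_p / (1 - model$rho)^model$l)
}

#' Probability of converting one sequence into another by substitutions
#'
#' The probability that sequencing errors turn a source barcode into one
#' specific sequence at Hamming distance `d`: each of the `d` mismatched
#' positions must err to the one observed alternative (probability `rho/3`,
#' all three alternatives being equally likely) and the remaining `l - d`
#' positions must be read correctly, giving `(rho/3)^d * (1 - rho)^(l - d)`.
#' Computed in log space.
#'
#' @param d Hamming distance, `0 <= d <= l`.
#' @param model an [error_model()].
#' @export
p_conversion <- function(d, model) {
  if (any(d < 0 | d > model$l)) stop("d must lie in [0, l]")
  exp(d * log(model$rho / 3) + (model$l - d) * log1p(-model$rho))
}

#' Log-Bayes factor for error sequence vs true barcode
#'
#' The log ratio ln K of the likelihood that the candidate is an error
#' sequence of its closest putative barcode (M1) to the likelihood that it
#' is a true barcode (M2):
#'
#' \deqn{\ln K = \ln\left[\binom{\hat n}{f_c} \hat p^{f_c}
#'   (1-\hat p)^{\hat n - f_c}\right] + \ln \hat p + l \ln 4 + \ln f_{max}}
#'
#' with \eqn{\hat p} the conversion probability [p_conversion()] at distance
#' `d`. All probability arithmetic is done in log space; when
#' `f_c > n_hat` the binomial mass is zero and `-Inf` is returned (an error
#' child cannot outnumber its source's estimated copies, so the candidate
#' must be a true barcode).
#'
#' @param case a [test_case()].
#' @param model an [error_model()].
#' @return ln K, possibly `-Inf`.
#' @export
log_bayes_factor <- function(case, model) {
  stopifnot(inherits(case, "shepherd_case"), inherits(model, "shepherd_model"))
  cpp_log_bf(case$d, case$f_c, case$n_hat, model$rho, model$l, model$f_max)
}

#' Classify a candidate as error sequence or true barcode
#'
#' `TRUE_BARCODE` iff `ln K` falls strictly below the model threshold
#' (default -4); ties at the threshold favor M1 and return
#' `ERROR_SEQUENCE`.
#'
#' @inheritParams log_bayes_factor
#' @return `"TRUE_BARCODE"` or `"ERROR_SEQUENCE"`.
#' @export
classify_sequence <- function(case, model) {
  lnK <- log_bayes_factor(case, model)
  if (lnK < model$log_bf_threshold) "TRUE_BARCODE" else "ERROR_SEQUENCE"
}

#' Estimate the per-nucleotide substitution rate from the data
#'
#' Anchor sequences -- sequences whose count exceeds the
#' `anchor_quantile` count percentile and that have no higher-count
#' sequence within the index's epsilon -- are taken to be unambiguous true
#' barcodes. Around each anchor, the error-free read mass is the anchor's
#' own count (E0) and the single-error mass is the summed count of its
#' distance-1 neighbors (E1). Under the model, a read of an anchor is
#' error-free with probability `(1 - rho)^l` and carries exactly one error
#' with probability `l * rho * (1 - rho)^(l - 1)`, so
#' `E1 / (E0 + E1) = l * rho / (l * rho + 1 - rho)`; pooling counts over all
#' anchors and inverting this relation (exactly:
#' `rho = q / (l * (1 - q) + q)` with `q = E1 / (E0 + E1)`) yields the
#' estimate.
#'
#' Anchors are ranked and selected on `s = E0 + E1` rather than on `E0`
#' alone: conditionally on `s`, the split of a barcode's (<= 1)-error reads
#' between error-free and single-error is exactly Binomial(s, q), so a
#' selection that is a function of `s` leaves the pooled ratio unbiased,
#' whereas selecting directly on the observed count `E0` favors anchors
#' whose error-free count fluctuated upward and biases the rate downward.
#'
#' The number of anchors is scale-aware: the count-percentile rule alone
#' would leave only a few dozen anchors on small datasets, whose pooled
#' read mass is too small for the stated accuracy, so at least
#' `min(min_anchors, 10% of unique sequences)` anchors are used. On
#' datasets of millions of unique sequences the percentile rule dominates
#' and the floor is inactive.
#'
#' @param reads a [read_set()].
#' @param index a [build_kmer_index()] over the same reads.
#' @param anchor_quantile count percentile above which sequences qualify as
#'   anchors (default 0.999).
#' @param min_anchors floor on the number of anchors pooled (subject to the
#'   10%-of-unique-sequences cap).
#' @param floor smallest reportable rate; an estimate below it (e.g. on
#'   error-free data) is floored with a warning.
#' @return Estimated rho in (0, 1).
#' @export
estimate_rho <- function(reads, index, anchor_quantile = 0.999,
                         min_anchors = 1000L, floor = 1e-6) {
  stopifnot(inherits(reads, "shepherd_reads"), inherits(index, "shepherd_index"))
  counts <- reads$counts
  l <- reads$length
  n <- length(counts)
  thr <- stats::quantile(counts, anchor_quantile, names = FALSE)
  m <- max(sum(counts > thr),
           min(as.integer(min_anchors), floor(0.1 * n)), 1L)
  ord <- order(-counts, reads$sequences, method = "radix")
  cand <- ord[seq_len(min(n, 2L * m))]
  e0 <- numeric(length(cand)); e1 <- numeric(length(cand))
  ok <- logical(length(cand))
  for (i in seq_along(cand)) {
    a <- cand[i]
    nb <- cpp_eps_neighborhood(index$ptr, reads$sequences[a],
                               as.numeric(counts))
    if (length(nb$idx) && any(counts[nb$idx] > counts[a])) next
    ok[i] <- TRUE
    e0[i] <- counts[a]
    e1[i] <- sum(counts[nb$idx][nb$dist == 1L])
  }
  if (!any(ok))
    stop("no admissible anchor sequences (all have a higher-count neighbor ",
         "within epsilon); supply rho manually")
  s <- e0 + e1
  s[!ok] <- -Inf
  keep <- ok & rank(-s, ties.method = "first") <= m
  if (!any(keep)) keep <- ok
  q <- sum(e1[keep]) / sum(s[keep])
  rho <- q / (l * (1 - q) + q)
  if (rho < floor) {
    warning("estimated substitution rate below ", floor,
            "; data appear (nearly) error free")
    rho <- floor
  }
  rho
}

#' Choose the Hamming distance threshold epsilon
#'
#' Selects the smallest epsilon such that the expected number of reads in
#' the whole dataset carrying more than epsilon substitution errors is
#' below one: with `T` the total read count and the number of errors per
#' read distributed Binomial(l, rho), the criterion is
#' `T * P(Bin(l, rho) > epsilon) < 1`. Reads beyond epsilon escape their
#' source's neighborhood and seed spurious clusters, so this bounds the
#' expected number of such escapes. The result is clamped to
#' `[1, max_epsilon]` (larger epsilon grows the index and the neighborhood
#' searches faster than it buys accuracy).
#'
#' @param reads a [read_set()].
#' @param rho per-nucleotide substitution rate.
#' @param max_epsilon clamp ceiling (default 3).
#' @return Integer epsilon.
#' @export
choose_epsilon <- function(reads, rho, max_epsilon = 3L) {
  stopifnot(inherits(reads, "shepherd_reads"))
  l <- reads$length
  total <- sum(reads$counts)
  eps <- 1L
  while (eps < l && total * stats::pbinom(eps, l, rho, lower.tail = FALSE) >= 1)
    eps <- eps + 1L
  min(max(eps, 1L), as.integer(max_epsilon))
}
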