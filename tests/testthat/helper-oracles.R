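# Independent reference implementations used as oracles. These deliberately
# avoid the package's C++ code paths: distances come from character-level
# comparison, neighborhoods from all-pairs scans, and the log-Bayes factor
# either from arbitrary-precision arithmetic (mpmath via the system python)
# or an lgamma-based formula.

BASES <- c("A", "C", "G", "T")

rand_seqs <- function(n, l) {
  repeat {
    s <- apply(matrix(sample(BASES, n * l, replace = TRUE), n), 1, paste,
               collapse = "")
    if (!anyDuplicated(s)) return(s)
  }
}

# plant a mutant at exactly distance d
mutate_seq <- function(seq, d) {
  l <- nchar(seq)
  pos <- sample.int(l, d)
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

ham_oracle <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

char_matrix <- function(seqs) do.call(rbind, strsplit(seqs, ""))

# distances from every row of `mat` to query sequence `q`
dist_to_all <- function(mat, q) {
  qm <- matrix(strsplit(q, "")[[1]], nrow(mat), ncol(mat), byrow = TRUE)
  rowSums(mat != qm)
}

# all-pairs epsilon-neighborhood of seqs[i] (indices, excluding i)
brute_eps_neighbors <- function(mat, i, eps) {
  d <- rowSums(mat != matrix(mat[i, ], nrow(mat), ncol(mat), byrow = TRUE))
  setdiff(which(d <= eps), i)
}

# arbitrary-precision log-Bayes factor via mpmath (50 significant digits)
mp_log_bf <- function(d, fc, nhat, rho, l, fmax) {
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "import mpmath as mp",
    "mp.mp.dps = 50",
    "for line in sys.stdin:",
    "    d, fc, nhat, rho, l, fmax = line.split()",
    "    d = int(d); l = int(l)",
    "    fc = mp.mpf(fc); nhat = mp.mpf(nhat)",
    "    rho = mp.mpf(rho); fmax = mp.mpf(fmax)",
    "    p = (rho / 3) ** d * (1 - rho) ** (l - d)",
    "    if fc > nhat:",
    "        print('-inf')",
    "        continue",
    "    lb = (mp.log(mp.binomial(nhat, fc)) + fc * mp.log(p)",
    "          + (nhat - fc) * mp.log(1 - p))",
    "    print(mp.nstr(lb + mp.log(p) + l * mp.log(4) + mp.log(fmax), 17))"
  ), script)
  lines <- sprintf("%d %.17g %.17g %.17g %d %.17g", d, fc, nhat, rho, l, fmax)
  out <- system2("python", script, input = lines, stdout = TRUE)
  unlink(script)
  as.numeric(out)
}

# lgamma-route log-Bayes factor (independent of the dbinom code path)
lgamma_log_bf <- function(d, fc, nhat, rho, l, fmax) {
  lp <- d * log(rho / 3) + (l - d) * log1p(-rho)
  if (fc > nhat) return(-Inf)
  lpmf <- lgamma(nhat + 1) - lgamma(fc + 1) - lgamma(nhat - fc + 1) +
    fc * lp + (nhat - fc) * log1p(-exp(lp))
  lpmf + lp + l * log(4) + log(fmax)
}

# reference clustering: same algorithm, but neighborhoods from an all-pairs
# distance matrix and the Bayes factor from the lgamma route
brute_cluster <- function(sequences, counts, rho, eps, thresh = -4,
                          skip_frac = 0.05, use_skip = TRUE) {
  ord <- order(-counts, sequences, method = "radix")
  sq <- sequences[ord]
  cn <- counts[ord]
  n <- length(sq)
  l <- nchar(sq[1])
  mat <- char_matrix(sq)
  D <- matrix(0L, n, n)
  for (i in seq_len(n))
    D[i, ] <- rowSums(mat != matrix(mat[i, ], n, l, byrow = TRUE))
  fmax <- cn[1]
  is_center <- logical(n)
  assign <- integer(n)
  ctot <- numeric(n)
  for (i in seq_len(n)) {
    make <- FALSE
    if (i == 1L || (use_skip && cn[i] > skip_frac * fmax)) {
      make <- TRUE
    } else {
      cand <- which(is_center & D[i, ] <= eps)
      if (!length(cand)) {
        make <- TRUE
      } else {
        best <- cand[order(D[i, cand], -cn[cand], sq[cand],
                           method = "radix")][1L]
        nhat <- round(ctot[best] / (1 - rho)^l)
        lnK <- lgamma_log_bf(D[i, best], cn[i], nhat, rho, l, fmax)
        if (lnK < thresh) {
          make <- TRUE
        } else {
          assign[i] <- best
          ctot[best] <- ctot[best] + cn[i]
        }
      }
    }
    if (make) {
      is_center[i] <- TRUE
      assign[i] <- i
      ctot[i] <- cn[i]
    }
  }
  list(sequences = sq, counts = cn, assignment = assign,
       centers = which(is_center), cluster_totals = ctot)
}
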