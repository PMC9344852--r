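# shepherd

Error correction and clustering of DNA barcode sequencing reads, for
lineage-tracking experiments: recover the true barcodes and their read
counts from noisy fixed-length reads, at one timepoint or across a time
series.

Sequencing a barcoded population yields millions of unique sequences of
which only a fraction are real barcodes; the rest are substitution-error
corruptions of them. `shepherd` treats error correction as clustering:

* **Exact neighborhood search without all-pairs distances.** Each
  length-`l` sequence is tiled into `p` non-overlapping k-mers. Two
  sequences within Hamming distance ε must share at least `p − ε` whole
  k-mers (pigeonhole principle), so indexing every sequence under its
  `choose(p, p−ε)` k-mer combinations — each encoded as an integer ID in
  a hash table — retrieves a small superset of the ε-neighborhood in one
  lookup pass, which a truncated Hamming filter then makes exact.
* **A Bayesian test for ambiguous sequences.** Sequences are processed in
  descending count order; a sequence near an established (putative)
  barcode is absorbed as an error sequence or promoted to a new barcode
  by the log-Bayes factor

  ```
  ln K = ln[ C(n̂, f_c) p̂^f_c (1 − p̂)^(n̂ − f_c) ] + ln p̂ + l ln 4 + ln f_max,
  p̂ = (ρ/3)^d (1 − ρ)^(l − d),
  ```

  comparing "error child of the neighbor" against "true barcode"; it is
  promoted iff `ln K < −4` (a ~55-fold likelihood demand). The
  per-nucleotide substitution rate ρ is estimated from the data when not
  supplied.
* **Lineage tracking with emerging-barcode detection.** Later timepoints
  are classified against the known barcodes; sequences that outgrow the
  error model are promoted as emerging lineages, which also repairs
  first-timepoint merges once counts diverge.
* **A synthetic benchmark generator with full ground truth** (barcodes of
  20 random + 6 constant nt, ceiling-exponential counts, per-read
  substitution errors, multi-timepoint selection dynamics) and evaluation
  metrics (false positive/negative cluster counts, count MAE, effective
  cluster radius).

## Worked example

```r
library(shepherd)

sim <- simulate_reads(2000, rho = 0.0066, seed = 42)  # 2,000 true barcodes
sim$reads
#> ReadSet: 29286 unique sequences of length 26 | 200,599 reads

res <- cluster_reads(sim$reads)   # rho, epsilon and k chosen from the data
res
#> clustering: 2004 putative barcodes from 29286 unique sequences ( 200,599 reads )
#> error model: rho = 0.006616 | l = 26 | f_max = 715 | lnK threshold = -4
#> k-mer scheme: l = 26 | k = 6 | epsilon = 3 | p = 5 (remainder 2 nt) | 10 combinations per sequence

head(clusters(res), 3)
#>              center_sequence total_count n_members
#> 1 GTAATGTAGGGGAATACGTCACGTAC         837        70
#> 2 GCCCAGAAAGCACGTCCACTACGTAC         833        71
#> 3 ACGGATTCACTTTGGGAGAGACGTAC         776        76

evaluate_clustering(res, sim$truth)
#> evaluation: 2004 clusters vs 2000 true barcodes
#>   FPC 7 | FNC 3 | matched 1997
#>   exact-count fraction 0.9980 | MAE 0.0020
#>   r_e: 1892 multi-member clusters, range [1.000, 3.000]
```

The 29,286 unique sequences collapse to 2,004 clusters. The estimated
error rate (0.66% per nucleotide) matches the simulated one to 0.2%;
1,997 of 2,000 true barcodes are recovered as cluster centers, 99.8% of
them with *exactly* their true read count. The 7 spurious clusters are
dominated by barcodes whose single read was corrupted — an
irreducible-floor case discussed in the vignette. The effective cluster
radius (mean distance from each cluster center to its members) stays in
`[1, 3]` because members are error sequences at most ε = 3 substitutions
away.

For a time series:

```r
ser <- simulate_lineage_series(3000, rho = 0.0033, n_timepoints = 4, seed = 1)
lt  <- track_lineages(ser$timepoints)
count_mae(lt, ser$truth)   # per-timepoint mean absolute count error
```

A command-line front end with `cluster`, `track`, `simulate` and
`evaluate` subcommands is installed at `inst/cli/shepherd.R` (run it with
`Rscript`); it reads headerless `sequence<TAB>count` TSV, FASTA or FASTQ.

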