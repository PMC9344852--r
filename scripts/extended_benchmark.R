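#!/usr/bin/env Rscript

# Extended benchmark tier: regenerate a full-size (or scaled) synthetic
# dataset, cluster it, and report FPC / FNC / count fidelity. The full-size
# presets (A/B: 500k barcodes, ~50M reads; C: 100k barcodes, ~10M reads)
# need tens of gigabyte-minutes; use --scale to shrink.
#
# Usage:
#   Rscript scripts/extended_benchmark.R --preset A --scale 1 --seed 1 \
#       [--max-epsilon 5] [--out results/benchmark_A.json]

suppressPackageStartupMessages(library(shepherd))

args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1L]
}
preset <- arg_val("--preset", "A")
scale <- as.numeric(arg_val("--scale", "1"))
seed <- as.integer(arg_val("--seed", "1"))
max_eps <- as.integer(arg_val("--max-epsilon", "5"))
out <- arg_val("--out", sprintf("results/benchmark_%s.json", preset))
dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)

cfg <- dataset_preset(preset, scale = scale)
message(sprintf("simulating preset %s at scale %g: %d barcodes, rho = %g",
                preset, scale, cfg$n_barcodes, cfg$rho))
sim <- simulate_reads(cfg$n_barcodes, rho = cfg$rho, seed = seed)
message(sprintf("%d unique sequences, %s reads",
                length(sim$reads$sequences),
                format(sum(sim$reads$counts), big.mark = ",")))

t0 <- Sys.time()
res <- cluster_reads(sim$reads, max_epsilon = max_eps)
message(sprintf("clustered in %s (epsilon = %d, k = %d, rho_hat = %.5g)",
                format(Sys.time() - t0), res$scheme$epsilon, res$scheme$k,
                res$model$rho))

ev <- evaluate_clustering(res, sim$truth)
print(ev)
jsonlite::write_json(list(
  preset = preset, scale = scale, seed = seed,
  n_true_barcodes = ev$n_true, n_unique_sequences = length(sim$reads$sequences),
  total_reads = sum(sim$reads$counts),
  epsilon = res$scheme$epsilon, k = res$scheme$k, rho_hat = res$model$rho,
  n_clusters = ev$n_clusters, fpc = ev$fpc, fnc = ev$fnc,
  exact_count_fraction = ev$exact_count_fraction, mae = ev$mae
), out, auto_unbox = TRUE, digits = NA)
message("wrote ", out)
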