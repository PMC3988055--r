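#!/usr/bin/env Rscript

# Stage 1: build the simulated study dataset.
#
# Twenty multi-exon genes with 2-4 isoforms each (alternative isoforms by
# internal exon skipping) on two 100 kb chromosomes; 5-20 long reads per
# isoform with realistic 5'/3' truncation; a 10% donor-shift alignment
# artifact; complete short-read junction evidence. Five genes and four
# non-primary isoforms are withheld from the emitted annotation so the
# downstream stages have genuine novelty to find.

suppressPackageStartupMessages(library(isocurate))

cfg <- sim_config(seed = 1L, n_genes = 20L,
                  n_hidden_genes = 5L, n_hidden_isoforms = 4L)
ds <- simulate_dataset(cfg)
paths <- write_simulation(ds, "results/sim")

cat(sprintf("simulated %d long reads from %d isoforms of %d genes\n",
            nrow(ds$reads), nrow(ds$sim$isoforms), nrow(ds$sim$genes)))
cat(sprintf("short-read evidence: %d junctions\n", nrow(ds$junctions)))
cat(sprintf("hidden from the emitted annotation: %d genes (%s), %d isoforms\n",
            length(ds$truth$hidden_genes),
            paste(ds$truth$hidden_genes, collapse = ", "),
            length(ds$truth$hidden_isoforms)))
cat(sprintf("reads carrying a donor-shift artifact: %d (%.1f%%)\n",
            sum(ds$read_truth$n_shift_applied > 0),
            100 * mean(ds$read_truth$n_shift_applied > 0)))
cat(sprintf("reads expected to survive validation: %d of %d\n",
            sum(ds$truth$expected_retained), nrow(ds$reads)))
cat("files:\n")
for (p in paths) cat("  ", p, "\n")
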