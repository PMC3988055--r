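#!/usr/bin/env Rscript

# Stage 2: junction validation of the simulated long reads.
#
# Each junction must (1) carry a canonical GT-AG splice motif in the genome
# and (2) appear in the short-read junction database. Only multi-exon reads
# in which every junction passes both checks are retained; this is what
# removes the donor-shift artifacts, whose shifted positions still look
# canonical but never have short-read support.

suppressPackageStartupMessages(library(isocurate))

genome <- read_fasta("results/sim/genome.fa")
reads <- read_bed12("results/sim/reads.bed12")
jrec <- read_junction_bed("results/sim/junctions.tab", dialect = "plain_tab")
db <- build_junction_db(jrec, min_support = 1L)

v <- validate_alignments(reads, genome, db)
dir.create("results", showWarnings = FALSE)
write.table(v$report, "results/validation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
ret <- retained_alignments(reads, v)
write_bed12(ret, "results/validated.bed12")

rep <- v$report
cat(sprintf("reads in: %d (%d multi-exon, %d single-exon)\n",
            nrow(rep), sum(rep$n_exons >= 2), sum(rep$n_exons < 2)))
cat(sprintf("retained: %d (%.1f%% of multi-exon reads)\n",
            sum(rep$retained), 100 * mean(rep$retained[rep$n_exons >= 2])))
cat(sprintf("failures: %d motif-only, %d evidence-only, %d both\n",
            sum(rep$n_motif_fail > 0 & rep$n_evidence_fail == 0),
            sum(rep$n_motif_fail == 0 & rep$n_evidence_fail > 0),
            sum(rep$n_motif_fail > 0 & rep$n_evidence_fail > 0)))
cat(sprintf("strand inferred from motifs for %d unstranded reads\n",
            sum(rep$retained & rep$strand != "*")))
cat("wrote results/validation.tsv, results/validated.bed12\n")
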