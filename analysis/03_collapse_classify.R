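#!/usr/bin/env Rscript

# Stage 3: collapse retained reads into isoform models and classify them
# against the emitted (deliberately incomplete) annotation.
#
# Reads sharing an intron chain merge into one model spanning the furthest
# observed start and end. Models whose chain matches an annotated transcript
# are "annotated"; unannotated chains overlapping a known gene are novel
# isoforms; the rest cluster into new gene regions.

suppressPackageStartupMessages(library(isocurate))

genome <- read_fasta("results/sim/genome.fa")
reads <- read_bed12("results/sim/reads.bed12")
jrec <- read_junction_bed("results/sim/junctions.tab", dialect = "plain_tab")
annot <- read_gtf("results/sim/emitted.gtf")

cur <- curate_isoforms(reads, genome, jrec, annot)
m <- cur$models
cl <- cur$classification

write_bed12(m, "results/models.bed12")
write_bed12(m[cl$category != "annotated", ], "results/novel_isoforms.bed12")
write_bed12(m[cl$category == "novel_gene", ],
            "results/new_gene_isoforms.bed12")
write.table(cur$summary, "results/summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cur$regions$regions, "results/new_gene_regions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d retained reads collapsed into %d isoform models\n",
            sum(cur$validation$report$retained), nrow(m)))
cat(sprintf("categories: %d annotated, %d novel isoforms of known genes, %d isoforms in new gene regions\n",
            sum(cl$category == "annotated"),
            sum(cl$category == "novel_isoform_known_gene"),
            sum(cl$category == "novel_gene")))
cat(sprintf("new gene regions found: %d\n", nrow(cur$regions$regions)))
cat("summary table (results/summary.tsv):\n")
print(cur$summary, row.names = FALSE)
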