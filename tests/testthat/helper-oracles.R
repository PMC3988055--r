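# Independent brute-force oracles and tiny fixture builders. These
# deliberately avoid the package's own code paths: motifs are checked by
# character slicing, interval work by per-base logical vectors.

toy_genome <- function(...) {
  s <- toupper(unlist(list(...)))
  structure(s, class = "genome_seq")
}

# Direct genome-text slicing: is the intron canonical, and on which strand?
oracle_motif <- function(seqtext, start, end, strand = "*") {
  first2 <- substring(seqtext, start + 1, start + 2)
  last2 <- substring(seqtext, end - 1, end)
  plus <- (first2 == "GT") && (last2 == "AG")
  minus <- (first2 == "CT") && (last2 == "AC")
  if (strand == "+") list(valid = plus, strand = "+")
  else if (strand == "-") list(valid = minus, strand = "-")
  else list(valid = plus || minus,
            strand = if (plus && !minus) "+"
            else if (minus && !plus) "-" else "*")
}

# Per-base occupancy vector of a set of spans on one chromosome of length L
# (0-based half-open in, 1-based logical vector out).
base_mask <- function(starts, ends, L) {
  m <- logical(L)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) m[(starts[i] + 1):ends[i]] <- TRUE
  }
  m
}

# Brute-force any-overlap percentage: fraction of row spans sharing >= 1
# base with any column span, per chromosome, on toy data.
oracle_overlap_pct <- function(row_df, col_df, L = 10000) {
  if (nrow(row_df) == 0) return(NA_real_)
  hit <- vapply(seq_len(nrow(row_df)), function(i) {
    cols <- col_df[col_df$chrom == row_df$chrom[i], , drop = FALSE]
    if (nrow(cols) == 0) return(FALSE)
    m <- base_mask(cols$start, cols$end, L)
    any(m[(row_df$start[i] + 1):row_df$end[i]])
  }, logical(1))
  100 * mean(hit)
}

# Brute-force exonic coverage of one transcript by a pile of read exons.
oracle_covered_bases <- function(tx_exons, read_exons, L = 10000) {
  rm <- base_mask(read_exons[, 1], read_exons[, 2], L)
  tm <- base_mask(tx_exons[, 1], tx_exons[, 2], L)
  sum(rm & tm)
}

# Shortcut constructor for toy alignments.
ts1 <- function(id, chrom, strand, exons, source = "long_read") {
  transcript_set(id, chrom, strand, list(exons), source = source)
}

# Is `frag` a contiguous sub-chain of `long` with compatible extent?
# (independent re-derivation used to cross-check subset_collapse)
oracle_absorbable <- function(long_introns, long_start, long_end,
                              frag_introns, frag_start, frag_end) {
  K <- nrow(long_introns); m <- nrow(frag_introns)
  if (m >= K) return(FALSE)
  for (q in 1:(K - m + 1)) {
    win <- long_introns[q:(q + m - 1), , drop = FALSE]
    if (!isTRUE(all.equal(unname(win), unname(frag_introns)))) next
    lo <- if (q == 1) long_start else long_introns[q - 1, 2]
    hi <- if (q + m - 1 == K) long_end else long_introns[q + m, 1]
    if (frag_start >= lo && frag_end <= hi) return(TRUE)
  }
  FALSE
}

# A small annotation built in code: two genes on one chromosome.
toy_annotation <- function() {
  ts <- transcript_set(
    id = c("t1", "t2", "t3"),
    chrom = "chr1",
    strand = c("+", "+", "-"),
    exons = list(cbind(c(100, 300), c(200, 400)),
                 cbind(c(100, 300, 500), c(200, 400, 650)),
                 cbind(c(2000, 2500), c(2200, 2700))),
    source = "annotation")
  annotation_set(ts, c(t1 = "g1", t2 = "g1", t3 = "g2"))
}
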