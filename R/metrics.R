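#' Any-overlap percentage matrix between feature sets
#'
#' For every ordered pair of sets, the percentage of the row set's elements
#' whose span is overlapped by at least 1 bp by some element of the column
#' set. Spans (not exon structures) are compared, strand-agnostic — the bulk
#' gene-level convention. The matrix is asymmetric in general; the diagonal
#' is 100 for any non-empty set; an empty set's row is `NA`.
#'
#' @param feature_sets named list of [transcript_set()] objects
#' @return list of class `overlap_matrix`: `set_names`, `counts` (elements
#'   per set), `percent` (square numeric matrix)
#' @export
overlap_matrix <- function(feature_sets) {
  stopifnot(length(feature_sets) >= 1L, !is.null(names(feature_sets)))
  nm <- names(feature_sets)
  spans <- lapply(feature_sets, spans_to_granges)
  counts <- vapply(feature_sets, nrow, integer(1))
  pct <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (r in seq_along(nm)) {
    if (counts[r] == 0L) next
    for (c in seq_along(nm)) {
      if (counts[c] == 0L) { pct[r, c] <- 0; next }
      h <- harmonize_seqlevels(spans[[r]], spans[[c]])
      hit <- GenomicRanges::countOverlaps(h[[1L]], h[[2L]],
                                          minoverlap = 1L,
                                          ignore.strand = TRUE) > 0L
      pct[r, c] <- 100 * mean(hit)
    }
  }
  structure(list(set_names = nm, counts = counts, percent = pct),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("overlap_matrix (% of row overlapped by column, any amount):\n")
  print(round(x$percent, 1))
  invisible(x)
}

#' Per-transcript read coverage and length-binned histograms
#'
#' For each annotated transcript, the fraction of its exonic bases covered by
#' the union of read exons. Three histograms over transcript exonic length
#' are reported: all transcripts, transcripts overlapped by any amount
#' (covered_bases > 0), and transcripts covered by more than 90% of their
#' length (strictly greater; exactly 0.90 does not qualify).
#'
#' @param annot_ts annotated transcripts (a `transcript_set`, e.g.
#'   `annot$transcripts`)
#' @param reads a `transcript_set` of read alignments
#' @param breaks increasing numeric vector of length-bin edges (default
#'   `seq(0, 6000, by = 250)`); lengths at or past the last edge fall into a
#'   final overflow bin
#' @return list of class `coverage_profile`: `per_transcript` (`data.frame`
#'   with `id`, `length`, `covered_bases`, `fraction`) and `histogram`
#'   (`data.frame` with `bin_lo`, `bin_hi`, `n_all`, `n_any`, `n_gt90`)
#' @export
coverage_profile <- function(annot_ts, reads,
                             breaks = seq(0, 6000, by = 250)) {
  stopifnot(length(breaks) >= 2L, !is.unsorted(breaks, strictly = TRUE))
  read_ex <- GenomicRanges::reduce(exons_to_granges(reads),
                                   ignore.strand = TRUE)
  len <- vapply(annot_ts$exons, function(m) sum(m[, 2L] - m[, 1L]),
                integer(1))
  covered <- integer(nrow(annot_ts))
  if (nrow(annot_ts) > 0L && length(read_ex) > 0L) {
    h <- harmonize_seqlevels(exons_to_granges(annot_ts), read_ex)
    tex <- h[[1L]]; read_ex <- h[[2L]]
    hits <- GenomicRanges::findOverlaps(tex, read_ex, ignore.strand = TRUE)
    if (length(hits) > 0L) {
      q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
      # read_ex is disjoint (reduced), so intersections never double-count
      w <- pmin(GenomicRanges::end(tex)[q], GenomicRanges::end(read_ex)[s]) -
        pmax(GenomicRanges::start(tex)[q], GenomicRanges::start(read_ex)[s]) +
        1L
      cv <- rowsum(w, S4Vectors::mcols(tex)$id[q])
      covered[match(rownames(cv), annot_ts$id)] <- as.integer(cv[, 1L])
    }
  }
  per <- data.frame(id = annot_ts$id, length = len, covered_bases = covered,
                    fraction = ifelse(len > 0L, covered / len, 0),
                    stringsAsFactors = FALSE)
  edges <- c(breaks, Inf)
  bin <- findInterval(per$length, edges, rightmost.closed = FALSE)
  bin[bin < 1L] <- 1L
  nb <- length(edges) - 1L
  tab <- function(sel) as.integer(table(factor(bin[sel], levels = seq_len(nb))))
  hist <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
                     n_all = tab(rep(TRUE, nrow(per))),
                     n_any = tab(per$covered_bases > 0L),
                     n_gt90 = tab(per$fraction > 0.9))
  structure(list(per_transcript = per, histogram = hist),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  p <- x$per_transcript
  cat(sprintf(
    "coverage_profile: %d transcript(s); %.1f%% any overlap, %.1f%% >90%% covered\n",
    nrow(p), 100 * mean(p$covered_bases > 0), 100 * mean(p$fraction > 0.9)))
  invisible(x)
}

#' Distances from observed splice sites to the nearest annotated site
#'
#' For each observed splice donor (the intron start on the plus strand, the
#' intron end on the minus strand) and acceptor (the converse), the signed
#' distance to the nearest annotated site of the same kind on the same
#' chromosome and strand. The sign is orientation-corrected: positive means
#' downstream in the transcript's direction, so donor-shift alignment
#' artifacts appear as a positive-side peak. Sites farther than `window`
#' from every annotated site (or with no same-kind site available) are
#' tallied in an overflow bucket. Observed junctions of unknown strand are
#' dropped with a warning, since donor and acceptor cannot be told apart.
#'
#' @param observed junction `data.frame` (`chrom`, `strand`, `start`, `end`),
#'   e.g. from [extract_junctions()]; strands may be motif-inferred first
#' @param annotated junction `data.frame` of the reference's introns
#' @param window half-width W of the reported distance range (default 50)
#' @return `data.frame` of class `splice_distance_profile`: columns
#'   `site_kind` (`donor`/`acceptor`), `distance` (integer in `[-W, W]`, or
#'   `NA` for the overflow bucket) and `count`
#' @export
splice_distance_profile <- function(observed, annotated, window = 50L) {
  stopifnot(window >= 1L)
  unk <- observed$strand == "*"
  if (any(unk)) {
    warning(sum(unk), " observed junction(s) of unknown strand dropped")
    observed <- observed[!unk, , drop = FALSE]
  }
  annotated <- annotated[annotated$strand %in% c("+", "-"), , drop = FALSE]
  site_of <- function(j, kind) {
    pos <- if (kind == "donor") ifelse(j$strand == "+", j$start, j$end)
    else ifelse(j$strand == "+", j$end, j$start)
    data.frame(chrom = j$chrom, strand = j$strand, pos = pos,
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (kind in c("donor", "acceptor")) {
    obs <- site_of(observed, kind)
    ann <- site_of(annotated, kind)
    d <- rep(NA_integer_, nrow(obs))
    for (grp in split(seq_len(nrow(obs)), paste(obs$chrom, obs$strand))) {
      ch <- obs$chrom[grp[1L]]; st <- obs$strand[grp[1L]]
      apos <- sort(unique(ann$pos[ann$chrom == ch & ann$strand == st]))
      if (length(apos) == 0L) next
      for (i in grp) {
        nearest <- apos[which.min(abs(apos - obs$pos[i]))]
        delta <- obs$pos[i] - nearest
        if (st == "-") delta <- -delta  # downstream = decreasing coordinate
        if (abs(delta) <= window) d[i] <- delta
      }
    }
    counts <- table(factor(d, levels = seq(-window, window)), useNA = "no")
    out[[kind]] <- data.frame(
      site_kind = kind,
      distance = c(seq(-window, window), NA_integer_),
      count = c(as.integer(counts), sum(is.na(d))),
      stringsAsFactors = FALSE)
  }
  res <- rbind(out$donor, out$acceptor)
  rownames(res) <- NULL
  class(res) <- c("splice_distance_profile", "data.frame")
  res
}

#' @export
print.splice_distance_profile <- function(x, ...) {
  for (k in unique(x$site_kind)) {
    s <- x[x$site_kind == k & !is.na(x$distance), ]
    tot <- sum(s$count)
    at0 <- s$count[s$distance == 0]
    cat(sprintf("%s: %d site(s) in window, %.1f%% at distance 0\n",
                k, tot, if (tot > 0) 100 * at0 / tot else NA_real_))
  }
  invisible(x)
}
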