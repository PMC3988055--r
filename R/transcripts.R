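#' @title Transcript alignment sets
#'
#' @description A `transcript_set` is the package's central container: a plain
#' `data.frame` with one row per spliced alignment (a mapped long read, an
#' annotated transcript, or an assembled contig) and a list column `exons`
#' holding, for each row, an integer matrix of exon blocks. All genomic
#' coordinates inside the package are 0-based half-open; GTF input is
#' converted at the boundary.
#'
#' Columns: `id` (character), `chrom` (character), `strand` (one of
#' `"+"`, `"-"`, `"*"` where `"*"` means unknown), `source` (one of
#' `"long_read"`, `"annotation"`, `"assembly"`), `start`/`end` (the span,
#' derived from the exon blocks), `n_exons`, and the `exons` list column
#' (matrices with columns `start`, `end`, rows sorted, non-overlapping,
#' separated by at least one intronic base).
#'
#' @param id character vector of alignment identifiers (must be unique)
#' @param chrom character vector of chromosome names
#' @param strand character vector over `{+,-,*}`
#' @param exons list of 2-column integer matrices (0-based half-open blocks)
#' @param source alignment provenance label, recycled to length
#' @return a `data.frame` of class `transcript_set`
#' @examples
#' ts <- transcript_set("r1", "chr1", "+", list(cbind(c(100, 300), c(200, 400))))
#' ts$n_exons
#' @export
transcript_set <- function(id, chrom, strand, exons,
                           source = "long_read") {
  n <- length(id)
  if (n == 0) {
    ts <- data.frame(id = character(), chrom = character(),
                     strand = character(), source = character(),
                     start = integer(), end = integer(),
                     n_exons = integer(), stringsAsFactors = FALSE)
    ts$exons <- list()
    class(ts) <- c("transcript_set", "data.frame")
    return(ts)
  }
  stopifnot(length(exons) == n)
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(as.character(strand), n)
  source <- rep_len(as.character(source), n)
  if (anyDuplicated(id)) stop("alignment ids must be unique")
  if (!all(strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  if (!all(source %in% c("long_read", "annotation", "assembly")))
    stop("unknown source label")
  exons <- lapply(exons, validate_exons)
  ts <- data.frame(id = as.character(id), chrom = as.character(chrom),
                   strand = strand, source = source,
                   start = vapply(exons, function(m) m[1L, 1L], integer(1)),
                   end = vapply(exons, function(m) m[nrow(m), 2L], integer(1)),
                   n_exons = vapply(exons, nrow, integer(1)),
                   stringsAsFactors = FALSE)
  ts$exons <- exons
  rownames(ts) <- NULL
  class(ts) <- c("transcript_set", "data.frame")
  ts
}

# Enforce the exon-block invariants: integer storage, end > start, sorted,
# and a gap of >= 1 base (the intron) between consecutive blocks.
validate_exons <- function(m) {
  m <- matrix(as.integer(m), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  if (nrow(m) == 0L) stop("alignment must have at least one exon")
  if (any(m[, 2L] <= m[, 1L])) stop("exon end must exceed exon start")
  if (nrow(m) > 1L) {
    gaps <- m[-1L, 1L] - m[-nrow(m), 2L]
    if (any(gaps < 1L))
      stop("exons must be sorted with a gap of >= 1 base (zero-length intron)")
  }
  m
}

#' Combine transcript sets
#' @param ... `transcript_set` objects
#' @return a single `transcript_set`
#' @export
bind_transcripts <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, nrow, integer(1)) > 0L]
  if (length(parts) == 0L)
    return(transcript_set(character(), character(), character(), list()))
  transcript_set(
    id = unlist(lapply(parts, `[[`, "id")),
    chrom = unlist(lapply(parts, `[[`, "chrom")),
    strand = unlist(lapply(parts, `[[`, "strand")),
    exons = do.call(c, lapply(parts, `[[`, "exons")),
    source = unlist(lapply(parts, `[[`, "source")))
}

# Spans of a transcript_set (or any df with chrom/start/end) as GRanges.
# Internal 0-based half-open -> 1-based closed at the boundary.
spans_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*"))
}

# Give two GRanges a shared seqlevel universe so overlap queries between
# objects from different chromosome sets stay silent.
harmonize_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a, b)
}

# All exon blocks of a transcript_set as one flat GRanges (id in mcols).
exons_to_granges <- function(ts) {
  nex <- vapply(ts$exons, nrow, integer(1))
  if (sum(nex) == 0L) return(GenomicRanges::GRanges())
  ex <- do.call(rbind, ts$exons)
  GenomicRanges::GRanges(
    seqnames = rep(ts$chrom, nex),
    ranges = IRanges::IRanges(start = ex[, 1L] + 1L, end = ex[, 2L]),
    strand = rep(ifelse(ts$strand %in% c("+", "-"), ts$strand, "*"), nex),
    id = rep(ts$id, nex))
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set with %d alignment(s) on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x) > 0L)
    print.data.frame(utils::head(x[, setdiff(names(x), "exons")], 10L))
  invisible(x)
}

#' Annotation set
#'
#' Bundles the annotated transcripts with their gene assignment and the
#' per-gene genic regions (the union of each gene's transcript spans,
#' introns included).
#'
#' @param transcripts a `transcript_set` with `source = "annotation"`
#' @param gene_of named character vector mapping transcript id to gene id;
#'   every transcript id must be present exactly once
#' @return an object of class `annotation_set`: a list with elements
#'   `transcripts`, `gene_of`, and `genic_regions` (a `data.frame` with
#'   columns `gene_id`, `chrom`, `strand`, `start`, `end`)
#' @export
annotation_set <- function(transcripts, gene_of) {
  if (!all(transcripts$id %in% names(gene_of)))
    stop("every transcript id must map to a gene id")
  gene_of <- gene_of[transcripts$id]
  if (anyNA(gene_of)) stop("every transcript id must map to a gene id")
  if (nrow(transcripts) == 0L) {
    gr <- data.frame(gene_id = character(), chrom = character(),
                     strand = character(), start = integer(),
                     end = integer(), stringsAsFactors = FALSE)
  } else {
    sp <- split(seq_len(nrow(transcripts)), gene_of)
    gr <- do.call(rbind, lapply(names(sp), function(g) {
      i <- sp[[g]]
      chroms <- unique(transcripts$chrom[i])
      do.call(rbind, lapply(chroms, function(ch) {
        j <- i[transcripts$chrom[i] == ch]
        st <- unique(transcripts$strand[j])
        data.frame(gene_id = g, chrom = ch,
                   strand = if (length(st) == 1L) st else "*",
                   start = min(transcripts$start[j]),
                   end = max(transcripts$end[j]),
                   stringsAsFactors = FALSE)
      }))
    }))
    gr <- gr[order(gr$chrom, gr$start, gr$gene_id), , drop = FALSE]
    rownames(gr) <- NULL
  }
  structure(list(transcripts = transcripts, gene_of = gene_of,
                 genic_regions = gr),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d transcripts, %d genes\n",
              nrow(x$transcripts), length(unique(x$gene_of))))
  invisible(x)
}
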