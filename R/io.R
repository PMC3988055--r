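#' Read a genome FASTA file
#'
#' Reads one or more chromosome records into a named character vector of
#' uppercase sequences. IUPAC ambiguity codes other than N are collapsed to N
#' with a warning: real assemblies contain them, and N can never satisfy a
#' splice-motif check, which is the conservative behaviour.
#'
#' @param path path to a FASTA file
#' @return named character vector of class `genome_seq`; names are the first
#'   whitespace-delimited token of each header
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no records in FASTA file: ", path)
  s <- toupper(as.character(seqs))
  names(s) <- sub("\\s.*$", "", names(seqs))
  if (any(nchar(s) == 0L)) stop("empty FASTA record in ", path)
  odd <- grepl("[^ACGTN]", s)
  if (any(odd)) {
    warning(sum(odd), " record(s) contained IUPAC ambiguity codes; ",
            "collapsed to N")
    s[odd] <- gsub("[^ACGTN]", "N", s[odd])
  }
  structure(s, class = "genome_seq")
}

#' Write a genome to FASTA
#' @param genome named character vector of sequences
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read spliced alignments from BED12
#'
#' Parses a 12-column BED file of spliced alignments into a
#' [transcript_set()]. Block offsets are resolved against `chromStart` into
#' absolute 0-based half-open exon coordinates. Strand `"."` becomes the
#' unknown strand `"*"`. `thickStart`/`thickEnd` are ignored.
#'
#' @param path path to a BED12 file
#' @param source provenance label for the resulting alignments
#' @return a `transcript_set`
#' @export
read_bed12 <- function(path, source = "long_read") {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L)
    return(transcript_set(character(), character(), character(), list(),
                          source = source))
  check_bed12_blocks(lines, path)
  gr <- rtracklayer::import(path, format = "bed")
  blk <- rtracklayer::blocks(gr)  # absolute, 1-based closed
  exons <- lapply(seq_along(blk), function(i) {
    b <- blk[[i]]
    m <- cbind(start = GenomicRanges::start(b) - 1L,
               end = GenomicRanges::end(b))
    if (is.unsorted(m[, 1L], strictly = TRUE) && nrow(m) > 1L)
      stop("BED12 blocks out of order for record ",
           S4Vectors::mcols(gr)$name[i])
    m
  })
  ids <- S4Vectors::mcols(gr)$name
  if (is.null(ids) || anyNA(ids)) ids <- paste0("rec", seq_along(gr))
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_dup")
  transcript_set(id = ids,
                 chrom = as.character(GenomicRanges::seqnames(gr)),
                 strand = sub("^\\*$", "*",
                              as.character(GenomicRanges::strand(gr))),
                 exons = exons, source = source)
}

# BED12 structural validation with actionable messages: rtracklayer fails on
# these too, but opaquely.
check_bed12_blocks <- function(lines, path) {
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 12L))
    stop("expected 12 BED columns, found ", min(nf), " in ", path)
  for (i in seq_along(f)) {
    n <- as.integer(f[[i]][10L])
    sizes <- strsplit(sub(",$", "", f[[i]][11L]), ",", fixed = TRUE)[[1L]]
    starts <- strsplit(sub(",$", "", f[[i]][12L]), ",", fixed = TRUE)[[1L]]
    if (length(sizes) != n || length(starts) != n)
      stop("blockCount (", n, ") does not match blockSizes/blockStarts ",
           "lengths on line ", i, " of ", path)
  }
  invisible(TRUE)
}

#' Read a reference annotation from GTF
#'
#' Groups `exon` features by `transcript_id` into annotated transcripts,
#' converting from GTF's 1-based closed coordinates to the package's 0-based
#' half-open convention, and computes per-gene genic regions (span unions).
#'
#' @param path path to a GTF file with exon features carrying `gene_id` and
#'   `transcript_id` attributes
#' @return an [annotation_set()]
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in GTF file: ", path)
  tid <- S4Vectors::mcols(gr)$transcript_id
  gid <- S4Vectors::mcols(gr)$gene_id
  if (is.null(tid) || anyNA(tid) || any(!nzchar(tid)))
    stop("exon feature missing transcript_id attribute in ", path)
  if (is.null(gid) || anyNA(gid))
    stop("exon feature missing gene_id attribute in ", path)
  ord <- order(tid, GenomicRanges::start(gr))
  gr <- gr[ord]; tid <- tid[ord]; gid <- gid[ord]
  idx <- split(seq_along(gr), tid)
  ids <- names(idx)
  exons <- vector("list", length(idx))
  chrom <- character(length(idx))
  strand <- character(length(idx))
  gene <- character(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    m <- cbind(start = GenomicRanges::start(gr)[i] - 1L,
               end = GenomicRanges::end(gr)[i])
    if (nrow(m) > 1L && any(m[-1L, 1L] - m[-nrow(m), 2L] < 1L))
      stop("overlapping or abutting exons within transcript ", ids[k],
           ": malformed model")
    exons[[k]] <- m
    chrom[k] <- as.character(GenomicRanges::seqnames(gr))[i[1L]]
    strand[k] <- as.character(GenomicRanges::strand(gr))[i[1L]]
    g <- unique(gid[i])
    if (length(g) != 1L)
      stop("transcript ", ids[k], " maps to more than one gene_id")
    gene[k] <- g
  }
  strand[!strand %in% c("+", "-")] <- "*"
  ts <- transcript_set(ids, chrom, strand, exons, source = "annotation")
  annotation_set(ts, stats::setNames(gene, ids))
}

#' Read short-read junction evidence
#'
#' Two dialects are supported. `tophat_bed` is the junctions.bed flavour
#' written by short-read spliced aligners: BED12-like records with exactly two
#' blocks, the intron being the gap between them, and the score column holding
#' the supporting read count. `plain_tab` is a headerless five-column table:
#' chrom, intron start (0-based), intron end (exclusive), strand, count.
#' Duplicate junctions have their counts summed.
#'
#' @param path input path
#' @param dialect `"tophat_bed"` or `"plain_tab"`
#' @return `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `count`, one row per distinct junction, sorted by coordinate
#' @export
read_junction_bed <- function(path, dialect = c("tophat_bed", "plain_tab")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("junction file not found: ", path)
  if (dialect == "tophat_bed") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines)]
    if (length(lines) == 0L)
      return(empty_junction_records())
    check_bed12_blocks(lines, path)
    gr <- rtracklayer::import(path, format = "bed")
    blk <- rtracklayer::blocks(gr)
    if (any(lengths(blk) != 2L))
      stop("tophat_bed junction record must have exactly 2 blocks")
    j <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = vapply(seq_along(blk),
                     function(i) GenomicRanges::end(blk[[i]])[1L], integer(1)),
      end = vapply(seq_along(blk),
                   function(i) GenomicRanges::start(blk[[i]])[2L] - 1L,
                   integer(1)),
      strand = as.character(GenomicRanges::strand(gr)),
      count = as.integer(S4Vectors::mcols(gr)$score),
      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = c("character", "integer", "integer",
                                            "character", "integer"))
    names(tab) <- c("chrom", "start", "end", "strand", "count")
    j <- tab
  }
  if (any(j$count < 0L)) stop("negative junction read count")
  j$strand[!j$strand %in% c("+", "-")] <- "*"
  aggregate_junction_records(j)
}

empty_junction_records <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), count = integer(), stringsAsFactors = FALSE)
}

# Sum counts over identical (chrom, start, end); strand is kept when all
# contributing records agree, "*" otherwise.
aggregate_junction_records <- function(j) {
  if (nrow(j) == 0L) return(empty_junction_records())
  key <- paste(j$chrom, j$start, j$end, sep = "\r")
  agg <- rowsum(j$count, key)
  strands <- vapply(split(j$strand, key),
                    function(s) if (length(unique(s)) == 1L) s[[1L]] else "*",
                    character(1))
  u <- j[!duplicated(key), , drop = FALSE]
  ukey <- key[!duplicated(key)]
  out <- data.frame(chrom = u$chrom, start = u$start, end = u$end,
                    strand = unname(strands[ukey]),
                    count = as.integer(agg[ukey, 1L]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write isoform models (or any multi-exon alignments) to BED12
#'
#' The name column carries the model/alignment id and the score column the
#' supporting-read count capped at 1000 (BED's score ceiling). Reading the
#' file back with [read_bed12()] reproduces the exon structure exactly.
#'
#' @param x an isoform model table from [collapse_isoforms()] or a
#'   `transcript_set`; every record must have at least 2 exons unless
#'   `allow_single_exon = TRUE` (used when writing raw simulated reads)
#' @param path output path
#' @param allow_single_exon permit single-block records
#' @return `path`, invisibly
#' @export
write_bed12 <- function(x, path, allow_single_exon = FALSE) {
  if (nrow(x) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  exons <- if ("exons" %in% names(x)) x$exons else model_exons(x)
  nex <- vapply(exons, nrow, integer(1))
  if (!allow_single_exon && any(nex < 2L))
    stop("every record written to BED12 must have >= 2 exons")
  score <- if ("support" %in% names(x)) pmin(x$support, 1000L) else 0L
  span_start <- vapply(exons, function(m) m[1L, 1L], integer(1))
  span_end <- vapply(exons, function(m) m[nrow(m), 2L], integer(1))
  blocks <- IRanges::IRangesList(lapply(seq_along(exons), function(i) {
    m <- exons[[i]]
    IRanges::IRanges(start = m[, 1L] - span_start[i] + 1L,
                     end = m[, 2L] - span_start[i])
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = span_start + 1L, end = span_end),
    strand = ifelse(x$strand %in% c("+", "-"), x$strand, "*"),
    name = x$id, score = score,
    thick = IRanges::IRanges(start = span_start + 1L, end = span_end),
    blocks = blocks)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write an annotation (or simulated gene models) to GTF
#'
#' Emits one `exon` feature per exon block with `gene_id` and `transcript_id`
#' attributes, converting back to GTF's 1-based closed coordinates.
#'
#' @param annot an [annotation_set()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gtf <- function(annot, path) {
  ts <- annot$transcripts
  if (nrow(ts) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  nex <- vapply(ts$exons, nrow, integer(1))
  ex <- do.call(rbind, ts$exons)
  tid <- rep(ts$id, nex)
  lines <- sprintf(
    "%s\tisocurate\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    rep(ts$chrom, nex), ex[, 1L] + 1L, ex[, 2L],
    rep(ifelse(ts$strand %in% c("+", "-"), ts$strand, "."), nex),
    as.character(annot$gene_of[tid]), tid)
  writeLines(lines, path)
  invisible(path)
}
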