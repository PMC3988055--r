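#' Extract splice junctions (introns) from spliced alignments
#'
#' Each pair of consecutive exon blocks implies one intron spanning
#' `[exon_i.end, exon_{i+1}.start)`. Single-exon alignments contribute no
#' junctions.
#'
#' @param ts a [transcript_set()]
#' @return `data.frame` with columns `id`, `index` (junction position within
#'   the alignment, 5' to 3' in genomic order), `chrom`, `strand`, `start`,
#'   `end`
#' @export
extract_junctions <- function(ts) {
  nj <- pmax(ts$n_exons - 1L, 0L)
  if (nrow(ts) == 0L || sum(nj) == 0L)
    return(data.frame(id = character(), index = integer(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  introns <- lapply(ts$exons, introns_of)
  data.frame(id = rep(ts$id, nj),
             index = unlist(lapply(nj, seq_len)),
             chrom = rep(ts$chrom, nj),
             strand = rep(ts$strand, nj),
             start = unlist(lapply(introns, function(m) m[, 1L])),
             end = unlist(lapply(introns, function(m) m[, 2L])),
             stringsAsFactors = FALSE)
}

# Intron matrix of one exon matrix (0 rows for single-exon input).
introns_of <- function(m) {
  m <- validate_exons(m)
  if (nrow(m) < 2L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = m[-nrow(m), 2L], end = m[-1L, 1L])
}

#' Check splice junctions for canonical splice motifs
#'
#' Tests whether an intron carries the canonical donor/acceptor dinucleotides:
#' on the plus strand the first two intronic bases must read `GT` (donor) and
#' the last two `AG` (acceptor); on the minus strand the genomic sequence must
#' read `CT`...`AC` (the reverse complement). For junctions of unknown strand
#' (`"*"`) both orientations are tried and the passing one is reported as the
#' inferred strand; if both pass the junction is flagged valid but the strand
#' stays unknown, with a warning.
#'
#' Only the GT-AG class (and its reverse complement) validates; the minor
#' GC-AG and AT-AC spliceosomal classes fail by design — the filter is
#' deliberately conservative, trading a small loss of genuine minor-class
#' introns for protection against alignment artifacts.
#'
#' @param junctions `data.frame` with columns `chrom`, `strand`, `start`,
#'   `end` (0-based half-open intron coordinates), e.g. from
#'   [extract_junctions()]
#' @param genome a `genome_seq` from [read_fasta()] (or any named character
#'   vector of uppercase sequences)
#' @param oob how to treat junctions outside their chromosome: `"error"`
#'   (default) or `"warn"` (motif_valid becomes `FALSE`)
#' @return the input with columns `motif_valid` (logical) and
#'   `inferred_strand` (`"+"`, `"-"`, or `"*"`) appended
#' @export
check_splice_motifs <- function(junctions, genome, oob = c("error", "warn")) {
  oob <- match.arg(oob)
  j <- junctions
  if (nrow(j) == 0L) {
    j$motif_valid <- logical(0)
    j$inferred_strand <- character(0)
    return(j)
  }
  if (any(j$end - j$start < 4L))
    stop("intron shorter than 4 bases cannot carry donor and acceptor motifs")
  seqlen <- stats::setNames(nchar(genome), names(genome))
  known <- j$chrom %in% names(genome)
  inb <- known & j$start >= 0L & j$end <= seqlen[j$chrom] & !is.na(j$start)
  if (any(!inb)) {
    msg <- sprintf("%d junction(s) outside chromosome bounds", sum(!inb))
    if (oob == "error") stop(msg) else warning(msg)
  }
  don <- acc <- rep(NA_character_, nrow(j))
  don[inb] <- substr(genome[j$chrom[inb]], j$start[inb] + 1L, j$start[inb] + 2L)
  acc[inb] <- substr(genome[j$chrom[inb]], j$end[inb] - 1L, j$end[inb])
  plus <- !is.na(don) & don == "GT" & acc == "AG"
  minus <- !is.na(don) & don == "CT" & acc == "AC"
  valid <- ifelse(j$strand == "+", plus,
                  ifelse(j$strand == "-", minus, plus | minus))
  inferred <- j$strand
  unk <- j$strand == "*"
  inferred[unk & plus & !minus] <- "+"
  inferred[unk & minus & !plus] <- "-"
  amb <- unk & plus & minus
  if (any(amb))
    warning(sum(amb), " junction(s) match canonical motifs on both strands; ",
            "strand left unknown")
  j$motif_valid <- valid & inb
  j$inferred_strand <- inferred
  j
}

#' Build the short-read junction database
#'
#' Aggregates junction evidence records and retains junctions whose summed
#' read count reaches `min_support`. Lookup is strand-agnostic on
#' (chrom, start, end) by default: short-read aligners themselves infer
#' junction strand from the splice motif, so the coordinates alone identify
#' the intron.
#'
#' @param records `data.frame` of junction evidence with columns `chrom`,
#'   `start`, `end`, `count` (e.g. from [read_junction_bed()])
#' @param min_support minimum summed read count for a junction to count as
#'   evidence (default 1: any short-read support validates)
#' @param strand_aware if `TRUE`, lookups also require matching strand
#' @return an object of class `junction_db`
#' @export
build_junction_db <- function(records, min_support = 1L,
                              strand_aware = FALSE) {
  if (min_support < 1L) stop("min_support must be >= 1")
  if (nrow(records) > 0L && any(records$count < 0L))
    stop("negative junction read count")
  if (is.null(records$strand)) records$strand <- "*"
  agg <- aggregate_junction_records(records)
  agg <- agg[agg$count >= min_support & agg$count >= 1L, , drop = FALSE]
  keys <- if (strand_aware)
    paste(agg$chrom, agg$start, agg$end, agg$strand, sep = "\r")
  else paste(agg$chrom, agg$start, agg$end, sep = "\r")
  structure(list(entries = agg,
                 counts = stats::setNames(agg$count, keys),
                 min_support = as.integer(min_support),
                 strand_aware = strand_aware),
            class = "junction_db")
}

#' Query the junction database
#' @param db a [build_junction_db()] object
#' @param junctions `data.frame` with columns `chrom`, `start`, `end` (and
#'   `strand` if the database is strand-aware)
#' @return logical vector: is each junction supported by short-read evidence?
#' @export
db_supported <- function(db, junctions) {
  if (nrow(junctions) == 0L) return(logical(0))
  keys <- if (db$strand_aware)
    paste(junctions$chrom, junctions$start, junctions$end, junctions$strand,
          sep = "\r")
  else paste(junctions$chrom, junctions$start, junctions$end, sep = "\r")
  unname(!is.na(db$counts[keys]))
}

#' @export
print.junction_db <- function(x, ...) {
  cat(sprintf("junction_db: %d junction(s), min_support = %d%s\n",
              nrow(x$entries), x$min_support,
              if (x$strand_aware) ", strand-aware" else ""))
  invisible(x)
}

#' Validate spliced alignments by motif and short-read evidence
#'
#' Applies the two-step junction validation to every alignment: each junction
#' must carry a canonical splice motif and be present in the short-read
#' junction database. Only multi-exon alignments in which every junction
#' passes both checks are retained. Alignments of unknown strand whose
#' junctions all infer the same orientation from the motif have that strand
#' assigned in the returned report.
#'
#' @param ts a [transcript_set()] of spliced alignments
#' @param genome a `genome_seq`
#' @param db a `junction_db`
#' @return list of class `validation_result` with elements:
#'   \describe{
#'     \item{report}{per-alignment `data.frame`: `id`, `n_exons`,
#'       `n_junctions`, `n_motif_fail`, `n_evidence_fail`, `retained`,
#'       `strand` (after motif inference)}
#'     \item{junctions}{per-junction `data.frame` with `motif_valid`,
#'       `evidence_valid`, `inferred_strand` flags}
#'   }
#' @export
validate_alignments <- function(ts, genome, db) {
  j <- extract_junctions(ts)
  j <- check_splice_motifs(j, genome, oob = "warn")
  j$evidence_valid <- db_supported(db, j)
  nm <- tapply(!j$motif_valid, factor(j$id, levels = ts$id), sum,
               default = 0L)
  ne <- tapply(!j$evidence_valid, factor(j$id, levels = ts$id), sum,
               default = 0L)
  inf <- vapply(split(j$inferred_strand, factor(j$id, levels = ts$id)),
                function(s) {
                  u <- unique(s)
                  if (length(u) == 1L && u %in% c("+", "-")) u else "*"
                }, character(1))
  strand <- ts$strand
  strand[strand == "*" & inf[ts$id] != "*"] <-
    inf[ts$id][strand == "*" & inf[ts$id] != "*"]
  report <- data.frame(
    id = ts$id, n_exons = ts$n_exons,
    n_junctions = pmax(ts$n_exons - 1L, 0L),
    n_motif_fail = as.integer(nm[ts$id]),
    n_evidence_fail = as.integer(ne[ts$id]),
    strand = strand,
    stringsAsFactors = FALSE)
  report$retained <- report$n_exons >= 2L & report$n_motif_fail == 0L &
    report$n_evidence_fail == 0L
  rownames(report) <- NULL
  structure(list(report = report, junctions = j),
            class = "validation_result")
}

#' Validate a single alignment
#' @param aln a one-row `transcript_set`
#' @inheritParams validate_alignments
#' @return one-row validation report (see [validate_alignments()])
#' @export
validate_alignment <- function(aln, genome, db) {
  stopifnot(nrow(aln) == 1L)
  validate_alignments(aln, genome, db)$report
}

#' Subset alignments to those passing validation
#'
#' @param ts the `transcript_set` given to [validate_alignments()]
#' @param validation its result
#' @return the retained alignments, with motif-inferred strands applied
#' @export
retained_alignments <- function(ts, validation) {
  keep <- validation$report$retained[match(ts$id, validation$report$id)]
  out <- ts[keep, , drop = FALSE]
  out$strand <- validation$report$strand[match(out$id, validation$report$id)]
  class(out) <- c("transcript_set", "data.frame")
  out
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("validation_result: %d/%d alignment(s) retained\n",
              sum(x$report$retained), nrow(x$report)))
  invisible(x)
}
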