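#' Junction codes: intron-chain identity of an isoform
#'
#' The junction code of a multi-exon alignment is the ordered chain of its
#' intron coordinates, rendered as `"chrom:strand:s1-e1,s2-e2,..."`. Two reads
#' with the same code represent the same isoform regardless of how far their
#' 5'/3' ends reach — the variability the collapse step is built to absorb.
#'
#' @param ts a [transcript_set()]; every alignment must have >= 2 exons
#' @return character vector of codes, one per alignment
#' @export
make_code <- function(ts) {
  if (any(ts$n_exons < 2L))
    stop("junction codes are defined only for multi-exon alignments")
  vapply(seq_len(nrow(ts)), function(i) {
    m <- introns_of(ts$exons[[i]])
    paste0(ts$chrom[i], ":", ts$strand[i], ":",
           paste(m[, 1L], m[, 2L], sep = "-", collapse = ","))
  }, character(1))
}

#' Parse a junction code back into its parts
#' @param code character vector of codes from [make_code()]
#' @return list with one element per code: `chrom`, `strand`, `introns`
#'   (2-column matrix)
#' @export
parse_code <- function(code) {
  lapply(strsplit(code, ":", fixed = TRUE), function(p) {
    if (length(p) != 3L) stop("malformed junction code")
    pairs <- do.call(rbind, strsplit(strsplit(p[3L], ",", fixed = TRUE)[[1L]],
                                     "-", fixed = TRUE))
    list(chrom = p[1L], strand = p[2L],
         introns = matrix(as.integer(pairs), ncol = 2L,
                          dimnames = list(NULL, c("start", "end"))))
  })
}

#' Collapse validated alignments into isoform models
#'
#' Groups alignments by junction code and merges each group into one isoform
#' model: the furthest observed transcription start and end over the members
#' become the model's extent, and the member count its support. Exact-code
#' matching is used — a read whose chain differs in a single intron
#' coordinate founds its own model. Output order is deterministic
#' (chrom, start, code).
#'
#' @param ts a [transcript_set()] of retained multi-exon alignments (see
#'   [retained_alignments()])
#' @return `data.frame` of class `isoform_models`: columns `id`, `code`,
#'   `chrom`, `strand`, `start`, `end`, `support`, plus list columns
#'   `introns`, `exons` (implied by start/introns/end) and `member_ids`
#' @export
collapse_isoforms <- function(ts) {
  if (nrow(ts) == 0L) return(empty_models())
  if (any(ts$n_exons < 2L))
    stop("collapse requires multi-exon alignments; filter with validation first")
  code <- make_code(ts)
  groups <- split(seq_len(nrow(ts)), code)
  models <- data.frame(
    code = names(groups),
    chrom = vapply(groups, function(i) ts$chrom[i[1L]], character(1)),
    strand = vapply(groups, function(i) ts$strand[i[1L]], character(1)),
    start = vapply(groups, function(i) min(ts$start[i]), integer(1)),
    end = vapply(groups, function(i) max(ts$end[i]), integer(1)),
    support = vapply(groups, length, integer(1)),
    stringsAsFactors = FALSE)
  models$introns <- lapply(groups, function(i) introns_of(ts$exons[[i[1L]]]))
  models$member_ids <- lapply(groups, function(i) sort(ts$id[i]))
  finalize_models(models)
}

# Sort deterministically, assign ids, recompute implied exon structure.
finalize_models <- function(models) {
  ord <- order(models$chrom, models$start, models$code)
  models <- models[ord, , drop = FALSE]
  models$id <- sprintf("ISO%05d", seq_len(nrow(models)))
  models$exons <- lapply(seq_len(nrow(models)), function(i) {
    implied_exons(models$start[i], models$introns[[i]], models$end[i])
  })
  cols <- c("id", "code", "chrom", "strand", "start", "end", "support",
            "introns", "exons", "member_ids")
  models <- models[, cols]
  rownames(models) <- NULL
  class(models) <- c("isoform_models", "data.frame")
  models
}

empty_models <- function() {
  m <- data.frame(id = character(), code = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  support = integer(), stringsAsFactors = FALSE)
  m$introns <- list(); m$exons <- list(); m$member_ids <- list()
  class(m) <- c("isoform_models", "data.frame")
  m
}

# Exon blocks implied by an extent and an intron chain.
implied_exons <- function(start, introns, end) {
  if (start >= introns[1L, 1L] || end <= introns[nrow(introns), 2L])
    stop("model extent must flank its intron chain")
  validate_exons(cbind(start = c(start, introns[, 2L]),
                       end = c(introns[, 1L], end)))
}

#' Exon structures of isoform models
#' @param models an `isoform_models` table
#' @return list of exon matrices (0-based half-open)
#' @export
model_exons <- function(models) models$exons

#' Absorb truncated sub-chain models into longer models
#'
#' With `enabled = TRUE`, a model whose intron chain is a contiguous
#' sub-chain of a longer model's chain on the same chromosome and strand, and
#' whose extent fits inside the longer model's exon structure (its ends do
#' not run past the flanking introns of the matched window), is merged into
#' the longer model, summing support. This treats 5'/3'-truncated fragments
#' as redundant observations of the longer isoform. With `enabled = FALSE`
#' (the default throughout the package) the input is returned unchanged:
#' exact-code identity is the conservative reading of duplicate removal.
#'
#' Fragments are processed in ascending chain length and absorbed into the
#' longest compatible model (ties broken by code order), so support flows
#' transitively up nested chains.
#'
#' @param models an `isoform_models` table from [collapse_isoforms()]
#' @param enabled apply the absorption (default `FALSE`)
#' @return an `isoform_models` table
#' @export
subset_collapse <- function(models, enabled = FALSE) {
  if (!enabled || nrow(models) < 2L) return(models)
  n <- nrow(models)
  clen <- vapply(models$introns, nrow, integer(1))
  ord <- order(clen, models$code)  # fragments first
  absorbed_into <- rep(NA_integer_, n)
  live_support <- models$support
  live_members <- models$member_ids
  for (f in ord) {
    cands <- which(clen > clen[f] & models$chrom == models$chrom[f] &
                     models$strand == models$strand[f])
    cands <- cands[vapply(cands, function(l)
      chain_absorbs(models$introns[[l]], models$start[l], models$end[l],
                    models$introns[[f]], models$start[f], models$end[f]),
      logical(1))]
    if (length(cands) == 0L) next
    best <- cands[order(-clen[cands], models$code[cands])][1L]
    absorbed_into[f] <- best
    live_support[best] <- live_support[best] + live_support[f]
    live_members[[best]] <- sort(c(live_members[[best]], live_members[[f]]))
  }
  keep <- is.na(absorbed_into)
  out <- models[keep, , drop = FALSE]
  out$support <- live_support[keep]
  out$member_ids <- live_members[keep]
  finalize_models(out[, setdiff(names(out), c("id", "exons"))])
}

# Is the fragment chain a contiguous window of the long chain, with the
# fragment's extent contained in the long model's exon structure there?
chain_absorbs <- function(long_introns, long_start, long_end,
                          frag_introns, frag_start, frag_end) {
  K <- nrow(long_introns); m <- nrow(frag_introns)
  if (m >= K) return(FALSE)
  key_frag <- paste(frag_introns[, 1L], frag_introns[, 2L])
  key_long <- paste(long_introns[, 1L], long_introns[, 2L])
  for (q in seq_len(K - m + 1L)) {
    if (!all(key_long[q:(q + m - 1L)] == key_frag)) next
    lower <- if (q == 1L) long_start else long_introns[q - 1L, 2L]
    upper <- if (q + m - 1L == K) long_end else long_introns[q + m, 1L]
    if (frag_start >= lower && frag_end <= upper) return(TRUE)
  }
  FALSE
}

#' @export
print.isoform_models <- function(x, ...) {
  cat(sprintf("isoform_models: %d model(s), total support %d\n",
              nrow(x), sum(x$support)))
  if (nrow(x) > 0L)
    print.data.frame(utils::head(
      x[, c("id", "chrom", "strand", "start", "end", "support")], 10L))
  invisible(x)
}
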