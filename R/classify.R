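#' Junction codes present in a reference annotation
#'
#' One code per multi-exon annotated transcript; single-exon transcripts have
#' no intron chain and contribute nothing (they can never match a collapsed
#' model, which is multi-exon by construction).
#'
#' @param annot an [annotation_set()]
#' @return character vector of distinct codes
#' @export
annotation_code_set <- function(annot) {
  ts <- annot$transcripts
  multi <- ts[ts$n_exons >= 2L, , drop = FALSE]
  if (nrow(multi) == 0L) return(character(0))
  unique(make_code(multi))
}

#' Classify isoform models against a reference annotation
#'
#' Each model falls into exactly one category:
#' \describe{
#'   \item{`annotated`}{its junction code equals that of some annotated
#'     transcript}
#'   \item{`novel_isoform_known_gene`}{code unannotated, but the model span
#'     overlaps (>= 1 bp) at least one genic region}
#'   \item{`novel_gene`}{code unannotated and no genic overlap}
#' }
#' Genic overlap is strand-agnostic by default, mirroring a plain
#' bedtools-style intersection of model spans with gene spans.
#'
#' @param models an `isoform_models` table
#' @param annot an [annotation_set()]
#' @param strict_strand require matching strand for genic overlap
#' @return `data.frame` of class `classification`: `id`, `code`, `category`,
#'   list column `overlapping_genes`, `n_novel_exons`, list column
#'   `novel_exons`
#' @export
classify_models <- function(models, annot, strict_strand = FALSE) {
  cats <- c("annotated", "novel_isoform_known_gene", "novel_gene")
  if (nrow(models) == 0L) {
    cl <- data.frame(id = character(), code = character(),
                     category = character(), stringsAsFactors = FALSE)
    cl$overlapping_genes <- list()
    cl$n_novel_exons <- integer(0)
    cl$novel_exons <- list()
    class(cl) <- c("classification", "data.frame")
    return(cl)
  }
  known_codes <- annotation_code_set(annot)
  annotated <- models$code %in% known_codes
  genes <- overlapping_genes(models, annot, strict_strand)
  category <- ifelse(annotated, "annotated",
                     ifelse(lengths(genes) > 0L,
                            "novel_isoform_known_gene", "novel_gene"))
  nov <- find_novel_exons(models, annot, strict_strand = FALSE)
  cl <- data.frame(id = models$id, code = models$code,
                   category = factor(category, levels = cats),
                   stringsAsFactors = FALSE)
  cl$category <- as.character(cl$category)
  cl$overlapping_genes <- genes
  cl$novel_exons <- nov
  cl$n_novel_exons <- vapply(nov, nrow, integer(1))
  rownames(cl) <- NULL
  class(cl) <- c("classification", "data.frame")
  cl
}

# Gene ids whose genic region overlaps each model span by >= 1 bp.
overlapping_genes <- function(models, annot, strict_strand = FALSE) {
  gr <- annot$genic_regions
  if (nrow(gr) == 0L) return(rep(list(character(0)), nrow(models)))
  h <- harmonize_seqlevels(
    spans_to_granges(models),
    spans_to_granges(data.frame(chrom = gr$chrom, start = gr$start,
                                end = gr$end, strand = gr$strand)))
  mspan <- h[[1L]]; gspan <- h[[2L]]
  hits <- GenomicRanges::findOverlaps(mspan, gspan, minoverlap = 1L,
                                      ignore.strand = !strict_strand)
  out <- rep(list(character(0)), nrow(models))
  if (length(hits) > 0L) {
    byq <- split(gr$gene_id[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits))
    for (q in names(byq)) out[[as.integer(q)]] <- sort(unique(byq[[q]]))
  }
  out
}

#' Find model exons absent from the annotation
#'
#' A model exon is novel when it shares zero bases with every annotated exon
#' on its chromosome (any overlap at all, even 1 bp, makes it known — the
#' same any-overlap convention used throughout the bulk comparisons).
#'
#' @param models an `isoform_models` table
#' @param annot an [annotation_set()]
#' @param strict_strand restrict the comparison to same-strand annotated
#'   exons
#' @return list of exon matrices, one per model (possibly 0-row)
#' @export
find_novel_exons <- function(models, annot, strict_strand = FALSE) {
  if (nrow(models) == 0L) return(list())
  aex <- exons_to_granges(annot$transcripts)
  out <- vector("list", nrow(models))
  for (i in seq_len(nrow(models))) {
    m <- models$exons[[i]]
    mex <- GenomicRanges::GRanges(
      seqnames = models$chrom[i],
      ranges = IRanges::IRanges(start = m[, 1L] + 1L, end = m[, 2L]),
      strand = if (models$strand[i] %in% c("+", "-")) models$strand[i] else "*")
    h <- harmonize_seqlevels(mex, aex)
    hit <- GenomicRanges::countOverlaps(h[[1L]], h[[2L]], minoverlap = 1L,
                                        ignore.strand = !strict_strand) > 0L
    out[[i]] <- m[!hit, , drop = FALSE]
  }
  out
}

#' Cluster novel-gene models into new gene regions
#'
#' Single-linkage clustering of model spans by any overlap (>= 1 bp) on the
#' same chromosome, strand-agnostic: each connected cluster becomes one new
#' gene region, with its member isoforms and the number of distinct exons
#' (exact coordinates) it contains.
#'
#' @param models an `isoform_models` table restricted to models classified
#'   `novel_gene` (rows of other categories are rejected if a classification
#'   is attached via `classification`)
#' @param classification optional [classify_models()] output used to select
#'   the `novel_gene` rows of `models`
#' @return list of class `new_gene_regions`: `regions` (`data.frame` with
#'   `region_id`, `chrom`, `start`, `end`, `n_isoforms`, `n_exons`) and
#'   `members` (`data.frame` mapping `region_id` to model `id`)
#' @export
cluster_new_gene_regions <- function(models, classification = NULL) {
  if (!is.null(classification)) {
    keep <- classification$category[match(models$id, classification$id)] ==
      "novel_gene"
    models <- models[keep, , drop = FALSE]
  }
  if (nrow(models) == 0L) {
    return(structure(list(
      regions = data.frame(region_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           n_isoforms = integer(), n_exons = integer(),
                           stringsAsFactors = FALSE),
      members = data.frame(region_id = character(), id = character(),
                           stringsAsFactors = FALSE)),
      class = "new_gene_regions"))
  }
  span <- spans_to_granges(models)
  # min.gapwidth = 0L: merge only true overlaps, never book-ended spans
  red <- GenomicRanges::reduce(span, min.gapwidth = 0L, ignore.strand = TRUE)
  red <- GenomicRanges::sort(red, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(span, red, ignore.strand = TRUE)
  stopifnot(length(hits) == nrow(models))
  cluster <- S4Vectors::subjectHits(hits)
  region_id <- sprintf("NEWGENE%04d", seq_along(red))
  n_exons <- vapply(seq_along(red), function(k) {
    i <- which(cluster == k)
    keys <- unlist(lapply(i, function(m) {
      ex <- models$exons[[m]]
      paste(models$chrom[m], ex[, 1L], ex[, 2L])
    }))
    length(unique(keys))
  }, integer(1))
  regions <- data.frame(
    region_id = region_id,
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    n_isoforms = as.integer(table(factor(cluster, levels = seq_along(red)))),
    n_exons = n_exons,
    stringsAsFactors = FALSE)
  members <- data.frame(region_id = region_id[cluster], id = models$id,
                        stringsAsFactors = FALSE)
  members <- members[order(members$region_id, members$id), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(regions = regions, members = members),
            class = "new_gene_regions")
}

#' @export
print.new_gene_regions <- function(x, ...) {
  cat(sprintf("new_gene_regions: %d region(s), %d isoform(s)\n",
              nrow(x$regions), nrow(x$members)))
  invisible(x)
}

#' Summarise novelty bookkeeping
#'
#' Produces the headline counts of the curation: all new annotations, genes
#' carrying them (known genes with novel isoforms plus new gene regions), new
#' genes, isoforms and distinct exons for new genes, and distinct new exons
#' inside known genes. Distinct exons are counted by exact (chrom, start,
#' end) coordinates.
#'
#' @param classification from [classify_models()]
#' @param models the classified `isoform_models`
#' @param regions from [cluster_new_gene_regions()]
#' @return one-row `data.frame` with columns `n_new_annotations`,
#'   `n_genes_with_new_annotations`, `n_new_genes`,
#'   `n_isoforms_for_new_genes`, `n_exons_in_new_genes`,
#'   `n_new_exons_in_known_genes`
#' @export
novelty_summary <- function(classification, models, regions) {
  stopifnot(identical(classification$id, models$id))
  novel_iso <- classification$category == "novel_isoform_known_gene"
  novel_gene <- classification$category == "novel_gene"
  known_genes_hit <- unique(unlist(
    classification$overlapping_genes[novel_iso]))
  exon_key <- function(i) {
    if (length(i) == 0L) return(character(0))
    unlist(lapply(i, function(k) {
      m <- models$exons[[k]]
      if (nrow(m) == 0L) return(character(0))
      paste(models$chrom[k], m[, 1L], m[, 2L])
    }))
  }
  novel_exon_key <- unlist(lapply(which(novel_iso), function(k) {
    m <- classification$novel_exons[[k]]
    if (nrow(m) == 0L) return(character(0))
    paste(models$chrom[k], m[, 1L], m[, 2L])
  }))
  data.frame(
    n_new_annotations = sum(novel_iso) + sum(novel_gene),
    n_genes_with_new_annotations = length(known_genes_hit) +
      nrow(regions$regions),
    n_new_genes = nrow(regions$regions),
    n_isoforms_for_new_genes = sum(novel_gene),
    n_exons_in_new_genes = length(unique(exon_key(which(novel_gene)))),
    n_new_exons_in_known_genes = length(unique(novel_exon_key)))
}
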