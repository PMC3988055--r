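#' In-memory isoform curation: validate, collapse, classify
#'
#' The core analysis chain on loaded objects. Junctions of each multi-exon
#' alignment are validated by canonical splice motif and short-read
#' evidence; retained alignments are collapsed by junction code into isoform
#' models with furthest-extent starts/ends; models are classified against
#' the annotation and novel-gene models clustered into new gene regions.
#'
#' @param reads a [transcript_set()] of long-read alignments
#' @param genome a `genome_seq` from [read_fasta()]
#' @param junction_records junction evidence `data.frame` (see
#'   [read_junction_bed()])
#' @param annot an [annotation_set()]
#' @param min_support minimum short-read count for a junction to validate
#' @param use_subset_collapse absorb truncated sub-chain models into longer
#'   models (see [subset_collapse()])
#' @param strict_strand strand-aware genic overlap in classification
#' @return list of class `curation`: `validation`, `models`,
#'   `classification`, `regions`, `summary`
#' @export
curate_isoforms <- function(reads, genome, junction_records, annot,
                            min_support = 1L, use_subset_collapse = FALSE,
                            strict_strand = FALSE) {
  db <- build_junction_db(junction_records, min_support = min_support)
  validation <- validate_alignments(reads, genome, db)
  retained <- retained_alignments(reads, validation)
  models <- collapse_isoforms(retained)
  models <- subset_collapse(models, enabled = use_subset_collapse)
  classification <- classify_models(models, annot,
                                    strict_strand = strict_strand)
  regions <- cluster_new_gene_regions(models, classification)
  summary <- novelty_summary(classification, models, regions)
  structure(list(validation = validation, models = models,
                 classification = classification, regions = regions,
                 summary = summary),
            class = "curation")
}

#' @export
print.curation <- function(x, ...) {
  cat(sprintf(
    "curation: %d/%d read(s) retained -> %d model(s); %d annotated, %d novel isoform(s), %d novel-gene isoform(s) in %d region(s)\n",
    sum(x$validation$report$retained), nrow(x$validation$report),
    nrow(x$models), sum(x$classification$category == "annotated"),
    sum(x$classification$category == "novel_isoform_known_gene"),
    sum(x$classification$category == "novel_gene"), nrow(x$regions$regions)))
  invisible(x)
}

#' Run the full curation pipeline on files
#'
#' Reads the genome, long-read alignments, short-read junction evidence and
#' reference annotation, runs [curate_isoforms()] plus the descriptive
#' metrics, and writes all outputs with a manifest. Rerunning with identical
#' inputs produces byte-identical outputs (the manifest carries no
#' timestamps and every table is deterministically ordered).
#'
#' Outputs in `outdir`: `validation.tsv`, `models.bed12`,
#' `novel_isoforms.bed12` (all models not matching an annotated code),
#' `new_gene_isoforms.bed12` (models in unannotated gene regions),
#' `summary.tsv`, `matrix.tsv` (reads vs annotation any-overlap),
#' `covhist.tsv`, `dist.tsv`, `manifest.json`.
#'
#' @param config named list (or path to a JSON file holding one) with
#'   entries: `genome`, `reads`, `junctions`, `annotation` (input paths),
#'   `outdir`, and optionally `junction_dialect` (`"plain_tab"` default or
#'   `"tophat_bed"`), `min_support` (1), `subset_collapse` (FALSE),
#'   `strict_strand` (FALSE), `window` (50), `bins` (length-histogram edges,
#'   default `seq(0, 6000, 250)`)
#' @return the manifest list, invisibly
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- list(junction_dialect = "plain_tab", min_support = 1L,
                   subset_collapse = FALSE, strict_strand = FALSE,
                   window = 50L, bins = seq(0, 6000, by = 250))
  for (f in names(defaults))
    if (is.null(config[[f]])) config[[f]] <- defaults[[f]]
  needed <- c("genome", "reads", "junctions", "annotation", "outdir")
  missing_fields <- setdiff(needed, names(config))
  if (length(missing_fields) > 0L)
    stop("config error: missing field(s) ",
         paste(missing_fields, collapse = ", "))
  for (f in c("genome", "reads", "junctions", "annotation"))
    if (!file.exists(config[[f]]))
      stop("config error: input file not found: ", config[[f]])
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  genome <- stage("load_genome", read_fasta(config$genome))
  reads <- stage("load_reads", read_bed12(config$reads))
  jrec <- stage("load_junctions",
                read_junction_bed(config$junctions,
                                  dialect = config$junction_dialect))
  annot <- stage("load_annotation", read_gtf(config$annotation))

  cur <- stage("curate",
               curate_isoforms(reads, genome, jrec, annot,
                               min_support = config$min_support,
                               use_subset_collapse = config$subset_collapse,
                               strict_strand = config$strict_strand))

  out <- function(f) file.path(config$outdir, f)
  utils::write.table(cur$validation$report, out("validation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(cur$models) > 0L) write_bed12(cur$models, out("models.bed12"))
  else writeLines(character(0), out("models.bed12"))
  novel <- cur$models[cur$classification$category != "annotated", ,
                      drop = FALSE]
  newg <- cur$models[cur$classification$category == "novel_gene", ,
                     drop = FALSE]
  write_bed12(novel, out("novel_isoforms.bed12"))
  write_bed12(newg, out("new_gene_isoforms.bed12"))
  utils::write.table(cur$summary, out("summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  om <- stage("overlap_matrix",
              overlap_matrix(list(reads = reads,
                                  annotation = annot$transcripts)))
  mat <- data.frame(set = om$set_names, n = om$counts,
                    round(om$percent, 4), check.names = FALSE)
  utils::write.table(mat, out("matrix.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cov <- stage("coverage",
               coverage_profile(annot$transcripts, reads,
                                breaks = config$bins))
  utils::write.table(cov$histogram, out("covhist.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  obs <- cur$validation$junctions
  obs$strand <- obs$inferred_strand
  dist <- stage("splice_distance",
                splice_distance_profile(
                  obs[obs$strand %in% c("+", "-"), , drop = FALSE],
                  extract_junctions(annot$transcripts),
                  window = config$window))
  utils::write.table(as.data.frame(dist), out("dist.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(
    tool = "isocurate",
    version = as.character(utils::packageVersion("isocurate")),
    config = config[order(names(config))],
    input_md5 = stats::setNames(
      as.list(unname(tools::md5sum(c(config$genome, config$reads,
                                     config$junctions, config$annotation)))),
      c("genome", "reads", "junctions", "annotation")),
    counts = list(
      reads_in = nrow(reads),
      reads_multi_exon = sum(reads$n_exons >= 2L),
      reads_retained = sum(cur$validation$report$retained),
      reads_not_retained = sum(!cur$validation$report$retained),
      junction_db_size = nrow(jrec),
      models = nrow(cur$models),
      annotated = sum(cur$classification$category == "annotated"),
      novel_isoform_known_gene =
        sum(cur$classification$category == "novel_isoform_known_gene"),
      novel_gene_isoforms =
        sum(cur$classification$category == "novel_gene"),
      new_gene_regions = nrow(cur$regions$regions)),
    summary = as.list(cur$summary),
    outputs = c("validation.tsv", "models.bed12", "novel_isoforms.bed12",
                "new_gene_isoforms.bed12", "summary.tsv", "matrix.tsv",
                "covhist.tsv", "dist.tsv"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
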