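#' Simulation configuration
#'
#' Parameters of the synthetic transcriptome used to exercise the pipeline
#' with known ground truth. The defaults describe a desk-scale transcriptome
#' with the error modes long-read cDNA data exhibits: frequent 5'/3'
#' truncation of reads (RNA degradation, shearing, incomplete amplification),
#' a donor-shift alignment artifact that moves a splice donor to a nearby
#' downstream GT at a rate of about 10% of junction observations, and
#' short-read junction evidence that is clean but may miss a fraction of
#' true junctions.
#'
#' Genes are multi-exon with alternative isoforms produced by skipping of
#' single internal exons, so isoforms of one gene share most junctions but
#' have distinct intron chains. Every planted intron starts with the donor
#' consensus `GTAAGT` and ends `...TTTCAG` in transcript orientation; the
#' second GT inside the donor consensus is the natural decoy the donor-shift
#' artifact latches onto (at +4 bp), mirroring misalignment near sites with
#' multiple plausible donors.
#'
#' @param seed integer random seed controlling every draw
#' @param n_chroms,chrom_length chromosome count and length (bp)
#' @param n_genes genes to plant (round-robin across chromosomes)
#' @param isoforms_per_gene,exons_per_isoform,exon_length,intron_length,intergenic_length inclusive integer ranges `c(lo, hi)`
#' @param n_hidden_genes genes excluded from the emitted annotation (their
#'   reads should classify as novel genes)
#' @param n_hidden_isoforms non-primary isoforms of visible genes excluded
#'   from the emitted annotation (novel isoforms of known genes)
#' @param reads_per_isoform range of long reads simulated per isoform
#' @param p_truncate_5p,p_truncate_3p probability a read is truncated at the
#'   5'/3' end (whole terminal exons dropped and/or terminal exon trimmed)
#' @param truncate_max_exons at most this many whole exons dropped per end
#' @param p_donor_shift probability each junction observation has its donor
#'   shifted to the nearest downstream GT within `max_shift` bases
#' @param max_shift donor-shift search window (bp)
#' @param short_read_coverage_per_junction range of short-read counts per
#'   true junction
#' @param p_junction_unsupported probability a true junction is omitted from
#'   the short-read evidence
#' @return a validated list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 100000L,
                       n_genes = 20L,
                       isoforms_per_gene = c(2L, 4L),
                       exons_per_isoform = c(4L, 8L),
                       exon_length = c(80L, 300L),
                       intron_length = c(60L, 400L),
                       intergenic_length = c(300L, 1500L),
                       n_hidden_genes = 0L,
                       n_hidden_isoforms = 0L,
                       reads_per_isoform = c(5L, 20L),
                       p_truncate_5p = 0.3,
                       p_truncate_3p = 0.2,
                       truncate_max_exons = 2L,
                       p_donor_shift = 0.1,
                       max_shift = 10L,
                       short_read_coverage_per_junction = c(3L, 30L),
                       p_junction_unsupported = 0) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              isoforms_per_gene = as.integer(isoforms_per_gene),
              exons_per_isoform = as.integer(exons_per_isoform),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              intergenic_length = as.integer(intergenic_length),
              n_hidden_genes = as.integer(n_hidden_genes),
              n_hidden_isoforms = as.integer(n_hidden_isoforms),
              reads_per_isoform = as.integer(reads_per_isoform),
              p_truncate_5p = p_truncate_5p, p_truncate_3p = p_truncate_3p,
              truncate_max_exons = as.integer(truncate_max_exons),
              p_donor_shift = p_donor_shift, max_shift = as.integer(max_shift),
              short_read_coverage_per_junction =
                as.integer(short_read_coverage_per_junction),
              p_junction_unsupported = p_junction_unsupported)
  probs <- c(cfg$p_truncate_5p, cfg$p_truncate_3p, cfg$p_donor_shift,
             cfg$p_junction_unsupported)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  for (f in c("isoforms_per_gene", "exons_per_isoform", "exon_length",
              "intron_length", "intergenic_length", "reads_per_isoform",
              "short_read_coverage_per_junction")) {
    r <- cfg[[f]]
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 1L)
      stop("range '", f, "' must be c(lo, hi) with 1 <= lo <= hi")
  }
  if (cfg$n_hidden_genes > cfg$n_genes)
    stop("hidden genes must be a subset of generated genes")
  if (cfg$intron_length[1L] < 2L * cfg$max_shift + 8L)
    stop("introns must be long enough to host motifs and donor shifts")
  if (cfg$exon_length[1L] < 40L)
    stop("minimum exon length below 40 bp leaves no room for end trimming")
  structure(cfg, class = "sim_config")
}

rand_int <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(range[1L]:range[2L], n, replace = TRUE)
}

#' Generate a toy genome with planted gene models
#'
#' Plants `n_genes` multi-exon genes on random background sequence. Each gene
#' has a backbone exon chain; isoform 1 uses all exons and each further
#' isoform skips one distinct internal exon (its flanking donor/acceptor are
#' shared with the backbone, so skip junctions are canonical by
#' construction). Every intron carries canonical splice motifs in gene
#' orientation. Deterministic given the seed.
#'
#' @param config a [sim_config()]
#' @return list of class `sim_genome`: `genome` (a `genome_seq`), `genes`
#'   (`data.frame` with `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `hidden`), `isoforms` (a `transcript_set` of all true isoforms),
#'   `gene_of` (named vector), `hidden_genes`, `hidden_isoforms`, `config`
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  cursor <- stats::setNames(rand_int(config$n_chroms,
                                     config$intergenic_length), chroms)
  plant <- list()   # motif replacements per chrom: list of (pos0, text)
  gene_rows <- list(); iso_ids <- character(0); iso_chrom <- character(0)
  iso_strand <- character(0); iso_exons <- list(); iso_gene <- character(0)
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("G%03d", g)
    chrom <- chroms[((g - 1L) %% config$n_chroms) + 1L]
    n_iso <- rand_int(1L, config$isoforms_per_gene)
    E <- max(rand_int(1L, config$exons_per_isoform), n_iso + 2L)
    exlen <- rand_int(E, config$exon_length)
    inlen <- rand_int(E - 1L, config$intron_length)
    glen <- sum(exlen) + sum(inlen)
    gstart <- cursor[chrom]
    if (gstart + glen > config$chrom_length)
      stop("gene geometry infeasible: gene ", gid, " does not fit on ",
           chrom, " (need ", gstart + glen, " bp of ",
           config$chrom_length, "); reduce n_genes or enlarge chromosomes")
    cursor[chrom] <- gstart + glen + rand_int(1L, config$intergenic_length)
    strand <- sample(c("+", "-"), 1L)
    # backbone exon coordinates
    starts <- gstart + cumsum(c(0L, exlen[-E] + inlen))
    backbone <- cbind(start = starts, end = starts + exlen)
    introns <- cbind(start = backbone[-E, 2L], end = backbone[-1L, 1L])
    # plant canonical motifs (consensus GTAAGT donor, TTTCAG acceptor,
    # in gene orientation)
    for (k in seq_len(E - 1L)) {
      s <- introns[k, 1L]; e <- introns[k, 2L]
      if (strand == "+") {
        plant[[chrom]] <- c(plant[[chrom]], list(list(s, "GTAAGT"),
                                                 list(e - 6L, "TTTCAG")))
      } else {
        plant[[chrom]] <- c(plant[[chrom]], list(list(e - 6L, "ACTTAC"),
                                                 list(s, "CTGAAA")))
      }
    }
    for (t in seq_len(n_iso)) {
      keep <- if (t == 1L) seq_len(E) else setdiff(seq_len(E), t)
      iso_ids <- c(iso_ids, sprintf("%s.T%d", gid, t))
      iso_chrom <- c(iso_chrom, chrom)
      iso_strand <- c(iso_strand, strand)
      iso_exons <- c(iso_exons, list(backbone[keep, , drop = FALSE]))
      iso_gene <- c(iso_gene, gid)
    }
    gene_rows[[g]] <- data.frame(gene_id = gid, chrom = chrom,
                                 strand = strand, start = gstart,
                                 end = gstart + glen,
                                 stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_rows)
  # random background, then overwrite planted motifs
  genome <- vapply(chroms, function(ch) {
    s <- paste(sample(c("A", "C", "G", "T"), config$chrom_length,
                      replace = TRUE), collapse = "")
    for (p in plant[[ch]])
      substr(s, p[[1L]] + 1L, p[[1L]] + nchar(p[[2L]])) <- p[[2L]]
    s
  }, character(1))
  names(genome) <- chroms
  class(genome) <- "genome_seq"
  hidden_genes <- if (config$n_hidden_genes > 0L)
    sort(sample(genes$gene_id, config$n_hidden_genes)) else character(0)
  genes$hidden <- genes$gene_id %in% hidden_genes
  # hidden isoforms: non-primary isoforms of visible genes
  eligible <- iso_ids[!(iso_gene %in% hidden_genes) &
                        !grepl("\\.T1$", iso_ids)]
  if (config$n_hidden_isoforms > length(eligible))
    stop("not enough non-primary isoforms of visible genes to hide")
  hidden_isoforms <- if (config$n_hidden_isoforms > 0L)
    sort(sample(eligible, config$n_hidden_isoforms)) else character(0)
  isoforms <- transcript_set(iso_ids, iso_chrom, iso_strand, iso_exons,
                             source = "annotation")
  structure(list(genome = genome, genes = genes, isoforms = isoforms,
                 gene_of = stats::setNames(iso_gene, iso_ids),
                 hidden_genes = hidden_genes,
                 hidden_isoforms = hidden_isoforms, config = config),
            class = "sim_genome")
}

#' True and emitted annotations of a simulated genome
#'
#' The true annotation contains every planted isoform; the emitted annotation
#' drops hidden genes and hidden isoforms, emulating an incomplete reference.
#'
#' @param sim a `sim_genome`
#' @return an [annotation_set()]
#' @export
truth_annotation <- function(sim) {
  annotation_set(sim$isoforms, sim$gene_of)
}

#' @rdname truth_annotation
#' @export
emitted_annotation <- function(sim) {
  keep <- !(sim$gene_of %in% sim$hidden_genes) &
    !(sim$isoforms$id %in% sim$hidden_isoforms)
  ts <- sim$isoforms[keep, , drop = FALSE]
  class(ts) <- c("transcript_set", "data.frame")
  annotation_set(ts, sim$gene_of[ts$id])
}

#' Simulate long-read alignments with truncation and donor shifts
#'
#' Each read is a copy of its source isoform's exon chain, optionally
#' truncated at the 5' and/or 3' end (whole terminal exons dropped, then the
#' new terminal exon trimmed from its outer edge — internal junction
#' coordinates are never touched, so truncated reads remain exact sub-chains
#' of the true code) and optionally carrying donor-shift artifacts: with
#' probability `p_donor_shift` per junction the donor is moved to the
#' nearest downstream GT (transcript orientation) within `max_shift` bases;
#' if no such GT exists the junction is left alone and the failed attempt
#' recorded. Reads are emitted unstranded (`"*"`), as unoriented cDNA
#' alignments would be; validation recovers strand from the splice motifs.
#'
#' @param sim a `sim_genome` from [generate_genome()]
#' @return list: `reads` (a `transcript_set`), `read_truth` (`data.frame`
#'   with per-read provenance: `read_id`, `isoform_id`, `gene_id`, `strand`,
#'   `n_exons`, `drop5`, `drop3`, `trim5`, `trim3`, `n_shift_applied`,
#'   `n_shift_failed`, `code` (post-modification, `NA` for single-exon
#'   reads), `true_code`)
#' @export
simulate_long_reads <- function(sim) {
  config <- sim$config
  set.seed((config$seed + 1001L) %% .Machine$integer.max)
  iso <- sim$isoforms
  rows <- list(); k <- 0L
  read_ids <- character(0); read_exons <- list(); read_chrom <- character(0)
  for (i in seq_len(nrow(iso))) {
    n_reads <- rand_int(1L, config$reads_per_isoform)
    true_code <- make_code(iso[i, , drop = FALSE])
    strand <- iso$strand[i]
    for (r in seq_len(n_reads)) {
      k <- k + 1L
      rid <- sprintf("read%05d_%s", k, iso$id[i])
      ex <- iso$exons[[i]]
      n <- nrow(ex)
      drop5 <- drop3 <- trim5 <- trim3 <- 0L
      if (stats::runif(1) < config$p_truncate_5p)
        drop5 <- sample(0:min(config$truncate_max_exons, n - 1L), 1L)
      if (stats::runif(1) < config$p_truncate_3p)
        drop3 <- sample(0:min(config$truncate_max_exons, n - 1L - drop5), 1L)
      # transcript 5' end is the genomic left end on +, right end on -
      gdrop_left <- if (strand == "+") drop5 else drop3
      gdrop_right <- if (strand == "+") drop3 else drop5
      ex <- ex[(1L + gdrop_left):(n - gdrop_right), , drop = FALSE]
      do_trim5 <- stats::runif(1) < config$p_truncate_5p
      do_trim3 <- stats::runif(1) < config$p_truncate_3p
      tl <- if ((strand == "+" && do_trim5) || (strand == "-" && do_trim3)) {
        sample(0:max(0L, (ex[1L, 2L] - ex[1L, 1L]) - 20L), 1L)
      } else 0L
      tr <- if ((strand == "+" && do_trim3) || (strand == "-" && do_trim5)) {
        # a single-exon read shares its only exon between both trims
        avail <- (ex[nrow(ex), 2L] - ex[nrow(ex), 1L]) - 20L -
          (if (nrow(ex) == 1L) tl else 0L)
        sample(0:max(0L, avail), 1L)
      } else 0L
      ex[1L, 1L] <- ex[1L, 1L] + tl
      ex[nrow(ex), 2L] <- ex[nrow(ex), 2L] - tr
      trim5 <- if (strand == "+") tl else tr
      trim3 <- if (strand == "+") tr else tl
      # donor-shift artifact per junction
      n_applied <- 0L; n_failed <- 0L
      if (nrow(ex) > 1L && config$p_donor_shift > 0) {
        seq <- sim$genome[[iso$chrom[i]]]
        for (j in seq_len(nrow(ex) - 1L)) {
          if (stats::runif(1) >= config$p_donor_shift) next
          s <- ex[j, 2L]; e <- ex[j + 1L, 1L]
          shifted <- FALSE
          for (kk in seq_len(config$max_shift)) {
            if (strand == "+") {
              if (substr(seq, s + kk + 1L, s + kk + 2L) == "GT" &&
                  (e - (s + kk)) >= 4L) {
                ex[j, 2L] <- s + kk; shifted <- TRUE; break
              }
            } else {
              if (substr(seq, e - kk - 1L, e - kk) == "AC" &&
                  ((e - kk) - s) >= 4L) {
                ex[j + 1L, 1L] <- e - kk; shifted <- TRUE; break
              }
            }
          }
          if (shifted) n_applied <- n_applied + 1L
          else n_failed <- n_failed + 1L
        }
      }
      code <- if (nrow(ex) >= 2L) {
        intr <- introns_of(ex)
        paste0(iso$chrom[i], ":", strand, ":",
               paste(intr[, 1L], intr[, 2L], sep = "-", collapse = ","))
      } else NA_character_
      read_ids <- c(read_ids, rid)
      read_chrom <- c(read_chrom, iso$chrom[i])
      read_exons <- c(read_exons, list(ex))
      rows[[k]] <- data.frame(
        read_id = rid, isoform_id = iso$id[i],
        gene_id = unname(sim$gene_of[iso$id[i]]), strand = strand,
        n_exons = nrow(ex), drop5 = drop5, drop3 = drop3,
        trim5 = trim5, trim3 = trim3,
        n_shift_applied = n_applied, n_shift_failed = n_failed,
        code = code, true_code = true_code, stringsAsFactors = FALSE)
    }
  }
  reads <- transcript_set(read_ids, read_chrom, "*", read_exons,
                          source = "long_read")
  read_truth <- do.call(rbind, rows)
  rownames(read_truth) <- NULL
  list(reads = reads, read_truth = read_truth)
}

#' Simulate short-read junction evidence
#'
#' Emits every true junction of the simulated transcriptome (backbone introns
#' and exon-skip introns of all genes, hidden ones included — short reads
#' sample expression regardless of annotation) with a read count drawn from
#' the configured range, except that each junction is independently omitted
#' with probability `p_junction_unsupported`. Artifact junctions are never
#' emitted: the short-read evidence is the clean orthogonal oracle.
#'
#' @param sim a `sim_genome`
#' @return list: `records` (`data.frame` `chrom`, `start`, `end`, `strand`,
#'   `count` in the plain_tab dialect), `omitted` (the withheld junctions)
#' @export
simulate_short_read_junctions <- function(sim) {
  config <- sim$config
  set.seed((config$seed + 2002L) %% .Machine$integer.max)
  j <- extract_junctions(sim$isoforms)
  j <- j[!duplicated(paste(j$chrom, j$start, j$end)), , drop = FALSE]
  j <- j[order(j$chrom, j$start, j$end), , drop = FALSE]
  omit <- stats::runif(nrow(j)) < config$p_junction_unsupported
  counts <- rand_int(nrow(j), config$short_read_coverage_per_junction)
  records <- data.frame(chrom = j$chrom[!omit], start = j$start[!omit],
                        end = j$end[!omit], strand = j$strand[!omit],
                        count = counts[!omit], stringsAsFactors = FALSE)
  omitted <- j[omit, c("chrom", "start", "end", "strand"), drop = FALSE]
  rownames(records) <- rownames(omitted) <- NULL
  list(records = records, omitted = omitted)
}

#' Simulate a complete dataset with ground truth
#'
#' Runs [generate_genome()], [simulate_long_reads()] and
#' [simulate_short_read_junctions()] and derives the expected downstream
#' outcomes: which reads should survive validation (multi-exon, no shifted
#' junction, every junction present in the emitted evidence), the resulting
#' expected retained code set, and the expected novelty category of each
#' retained code against the emitted annotation.
#'
#' @param config a [sim_config()]
#' @return list of class `sim_dataset`: `sim`, `reads`, `read_truth`,
#'   `junctions` (evidence records), `omitted_junctions`, `truth` (list with
#'   `expected_retained` per read, `expected_codes`, `expected_category`
#'   named by code, `hidden_genes`, `hidden_isoforms`)
#' @export
simulate_dataset <- function(config) {
  sim <- generate_genome(config)
  lr <- simulate_long_reads(sim)
  srj <- simulate_short_read_junctions(sim)
  evidence_key <- paste(srj$records$chrom, srj$records$start,
                        srj$records$end)
  jr <- extract_junctions(lr$reads)
  jr$shifted_or_unsupported <- !(paste(jr$chrom, jr$start, jr$end) %in%
                                   evidence_key)
  bad <- tapply(jr$shifted_or_unsupported,
                factor(jr$id, levels = lr$reads$id), any, default = FALSE)
  expected_retained <- lr$read_truth$n_exons >= 2L &
    lr$read_truth$n_shift_applied == 0L &
    !as.logical(bad[lr$read_truth$read_id])
  expected_codes <- sort(unique(lr$read_truth$code[expected_retained]))
  emitted_codes <- annotation_code_set(emitted_annotation(sim))
  gene_by_code <- tapply(lr$read_truth$gene_id, lr$read_truth$code,
                         function(g) g[[1L]])
  expected_category <- vapply(expected_codes, function(cd) {
    if (cd %in% emitted_codes) "annotated"
    else if (gene_by_code[[cd]] %in% sim$hidden_genes) "novel_gene"
    else "novel_isoform_known_gene"
  }, character(1))
  structure(list(
    sim = sim, reads = lr$reads, read_truth = lr$read_truth,
    junctions = srj$records, omitted_junctions = srj$omitted,
    truth = list(expected_retained = stats::setNames(expected_retained,
                                                     lr$read_truth$read_id),
                 expected_codes = expected_codes,
                 expected_category = expected_category,
                 hidden_genes = sim$hidden_genes,
                 hidden_isoforms = sim$hidden_isoforms)),
    class = "sim_dataset")
}

#' Write a simulated dataset to disk
#'
#' Produces the file set a real run would start from: `genome.fa`,
#' `truth.gtf` (all genes), `emitted.gtf` (hidden genes/isoforms removed),
#' `reads.bed12`, `junctions.tab` (plain_tab dialect) and `truth.json`.
#' All outputs are plain text and byte-stable for a given config.
#'
#' @param ds a `sim_dataset`
#' @param dir output directory (created if needed)
#' @return named vector of paths, invisibly
#' @export
write_simulation <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             truth_gtf = file.path(dir, "truth.gtf"),
             emitted_gtf = file.path(dir, "emitted.gtf"),
             reads = file.path(dir, "reads.bed12"),
             junctions = file.path(dir, "junctions.tab"),
             truth = file.path(dir, "truth.json"))
  write_fasta(ds$sim$genome, paths["genome"])
  write_gtf(truth_annotation(ds$sim), paths["truth_gtf"])
  write_gtf(emitted_annotation(ds$sim), paths["emitted_gtf"])
  write_bed12(ds$reads, paths["reads"], allow_single_exon = TRUE)
  utils::write.table(ds$junctions, paths["junctions"], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(read_truth = ds$read_truth,
         expected_retained = as.list(ds$truth$expected_retained),
         expected_codes = ds$truth$expected_codes,
         expected_category = as.list(ds$truth$expected_category),
         hidden_genes = ds$truth$hidden_genes,
         hidden_isoforms = ds$truth$hidden_isoforms),
    paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
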