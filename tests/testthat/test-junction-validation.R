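test_that("junctions are the gaps between exon blocks", {
  ts <- ts1("r1", "chr1", "+", cbind(c(100, 300, 500), c(200, 400, 600)))
  j <- extract_junctions(ts)
  expect_equal(j$start, c(200, 400))
  expect_equal(j$end, c(300, 500))
  expect_equal(j$index, 1:2)
  single <- ts1("r2", "chr1", "+", cbind(100, 600))
  expect_equal(nrow(extract_junctions(single)), 0L)
  # a zero-length intron violates the container invariant outright
  expect_error(ts1("r3", "chr1", "+", cbind(c(100, 200), c(200, 300))),
               "zero-length intron")
})

test_that("canonical motifs validate on the stated strand", {
  # intron (200, 300): bases 200-201 GT ... 298-299 AG (0-based)
  g <- toy_genome(chr1 = paste0(strrep("A", 200), "GTAAGT",
                                strrep("C", 90), "TTAG",
                                strrep("A", 100)))
  j <- data.frame(chrom = "chr1", strand = "+", start = 200L, end = 300L)
  r <- check_splice_motifs(j, g)
  expect_true(r$motif_valid)
  # non-canonical donor GC fails
  g2 <- toy_genome(chr1 = sub("^(.{200})GT", "\\1GC", unclass(g)[[1]]))
  expect_false(check_splice_motifs(j, g2)$motif_valid)
  # wrong-strand request fails even though the plus test would pass
  jm <- transform(j, strand = "-")
  expect_false(check_splice_motifs(jm, g)$motif_valid)
})

test_that("unknown-strand junctions infer orientation from the motif", {
  g <- toy_genome(chr1 = paste0(strrep("A", 200), "CT",
                                strrep("G", 96), "AC", strrep("A", 100)))
  j <- data.frame(chrom = "chr1", strand = "*", start = 200L, end = 300L)
  r <- check_splice_motifs(j, g)
  expect_true(r$motif_valid)
  expect_equal(r$inferred_strand, "-")
})

test_that("out-of-bounds junctions error, or warn-and-fail when asked", {
  g <- toy_genome(chr1 = strrep("A", 100))
  j <- data.frame(chrom = "chr1", strand = "+", start = 90L, end = 150L)
  expect_error(check_splice_motifs(j, g), "bounds")
  expect_warning(r <- check_splice_motifs(j, g, oob = "warn"), "bounds")
  expect_false(r$motif_valid)
  expect_error(
    check_splice_motifs(data.frame(chrom = "chr1", strand = "+",
                                   start = 10L, end = 13L), g),
    "shorter than 4")
})

test_that("motif check agrees with direct genome slicing on random junctions", {
  set.seed(901)
  L <- 20000
  seqtext <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                   collapse = "")
  g <- toy_genome(chr1 = seqtext)
  n <- 300
  start <- sample.int(L - 200, n)
  end <- start + sample(4:150, n, replace = TRUE)
  strand <- sample(c("+", "-", "*"), n, replace = TRUE)
  j <- data.frame(chrom = "chr1", strand = strand, start = start, end = end)
  r <- suppressWarnings(check_splice_motifs(j, g))
  for (i in seq_len(n)) {
    o <- oracle_motif(seqtext, start[i], end[i], strand[i])
    expect_identical(r$motif_valid[i], o$valid)
    expect_identical(r$inferred_strand[i], o$strand)
  }
})

test_that("junction DB aggregates, thresholds, and answers lookups", {
  rec <- data.frame(chrom = "chr1", start = c(200L, 200L, 700L),
                    end = c(400L, 400L, 900L), strand = "+",
                    count = c(3L, 4L, 2L))
  db <- build_junction_db(rec, min_support = 5L)
  expect_equal(nrow(db$entries), 1L)
  expect_equal(db$entries$count, 7L)
  q <- data.frame(chrom = "chr1", start = c(200L, 700L), end = c(400L, 900L))
  expect_equal(db_supported(db, q), c(TRUE, FALSE))
  empty <- build_junction_db(rec[0, ])
  expect_equal(db_supported(empty, q), c(FALSE, FALSE))
  expect_error(build_junction_db(transform(rec, count = -1L)), "negative")
})

test_that("retention requires multi-exon, all motifs, and all evidence", {
  g <- toy_genome(chr1 = paste0(
    strrep("A", 200), "GT", strrep("C", 96), "AG",   # intron (200,300)
    strrep("A", 100), "GT", strrep("C", 96), "AG",   # intron (400,500)
    strrep("A", 100)))
  exons <- cbind(c(100, 300, 500), c(200, 400, 600))
  reads <- bind_transcripts(
    ts1("full", "chr1", "+", exons),
    ts1("mono", "chr1", "+", cbind(100, 600)))
  both <- data.frame(chrom = "chr1", start = c(200L, 400L),
                     end = c(300L, 500L), strand = "+", count = 5L)
  v <- validate_alignments(reads, g, build_junction_db(both))
  expect_equal(v$report$retained, c(TRUE, FALSE))
  # evidence for only one junction: canonical motifs alone do not retain
  v2 <- validate_alignments(reads, g, build_junction_db(both[1, ]))
  expect_false(v2$report$retained[1])
  expect_equal(v2$report$n_evidence_fail[1], 1L)
  expect_equal(v2$report$n_motif_fail[1], 0L)
})

test_that("raising min_support never rescues an alignment (monotonicity)", {
  ds <- simulate_dataset(sim_config(seed = 33, n_genes = 8,
                                    p_donor_shift = 0.15))
  retained_at <- function(ms) {
    db <- build_junction_db(ds$junctions, min_support = ms)
    v <- validate_alignments(ds$reads, ds$sim$genome, db)
    v$report$id[v$report$retained]
  }
  prev <- retained_at(1L)
  for (ms in c(5L, 15L, 40L)) {
    cur <- retained_at(ms)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("motif inference recovers the true strand of simulated genes", {
  ds <- simulate_dataset(sim_config(seed = 12, n_genes = 10,
                                    p_donor_shift = 0))
  db <- build_junction_db(ds$junctions)
  v <- validate_alignments(ds$reads, ds$sim$genome, db)
  rep <- v$report[v$report$retained, ]
  truth <- ds$read_truth$strand[match(rep$id, ds$read_truth$read_id)]
  expect_true(any(truth == "-"))  # both orientations exercised
  expect_equal(rep$strand, truth)
})
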