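test_that("annotation code set counts multi-exon chains once each", {
  a <- toy_annotation()
  expect_equal(length(annotation_code_set(a)), 3L)
  # duplicate chains collapse to one code; single-exon contribute none
  dup <- transcript_set(c("t1", "t1b", "s1"), "chr1", "+",
                        list(cbind(c(100, 300), c(200, 400)),
                             cbind(c(90, 300), c(200, 410)),
                             cbind(500, 900)),
                        source = "annotation")
  a2 <- annotation_set(dup, c(t1 = "g1", t1b = "g1", s1 = "g2"))
  expect_equal(length(annotation_code_set(a2)), 1L)
})

test_that("models partition into annotated / novel isoform / novel gene", {
  annot <- toy_annotation()
  reads <- bind_transcripts(
    ts1("r1", "chr1", "+", cbind(c(100, 300), c(200, 400))),     # = t1 code
    ts1("r2", "chr1", "+", cbind(c(120, 350), c(200, 550))),     # new chain, g1
    ts1("r3", "chr1", "+", cbind(c(5000, 5300), c(5100, 5400)))) # empty region
  m <- collapse_isoforms(reads)
  cl <- classify_models(m, annot)
  cat_of <- function(id) cl$category[match(
    m$id[vapply(m$member_ids, function(x) id %in% x, logical(1))], cl$id)]
  expect_equal(cat_of("r1"), "annotated")
  expect_equal(cat_of("r2"), "novel_isoform_known_gene")
  expect_equal(cat_of("r3"), "novel_gene")
  i_r2 <- which(vapply(m$member_ids, function(x) "r2" %in% x, logical(1)))
  expect_equal(cl$overlapping_genes[[i_r2]], "g1")
  expect_setequal(cl$category, c("annotated", "novel_isoform_known_gene",
                                 "novel_gene"))
})

test_that("novel exons are those sharing zero bases with annotation", {
  annot <- toy_annotation()  # annotated exons at (100,200),(300,400),(500,650)...
  reads <- ts1("r", "chr1", "+", cbind(c(300, 395, 800), c(390, 420, 900)))
  m <- collapse_isoforms(reads)
  nov <- find_novel_exons(m, annot)[[1]]
  # (300,390) overlaps; (395,420) overlaps by 5 bp -> known; (800,900) novel
  expect_equal(unname(nov), unname(cbind(800, 900)))
})

test_that("new gene regions form by single-linkage any-overlap", {
  reads <- bind_transcripts(
    ts1("a", "chr3", "+", cbind(c(100, 300), c(200, 500))),
    ts1("b", "chr3", "+", cbind(c(400, 700), c(450, 900))),
    ts1("c", "chr3", "+", cbind(c(1000, 1200), c(1100, 1300))))
  m <- collapse_isoforms(reads)
  reg <- cluster_new_gene_regions(m)
  expect_equal(nrow(reg$regions), 2L)
  expect_equal(reg$regions$start, c(100L, 1000L))
  expect_equal(reg$regions$end, c(900L, 1300L))
  expect_equal(reg$regions$n_isoforms, c(2L, 1L))
  # book-ended spans (end == start) do not merge
  reads2 <- bind_transcripts(
    ts1("a", "chr3", "+", cbind(c(100, 300), c(200, 500))),
    ts1("b", "chr3", "+", cbind(c(500, 700), c(600, 900))))
  expect_equal(nrow(cluster_new_gene_regions(collapse_isoforms(reads2))$regions),
               2L)
})

test_that("distinct exons are counted by exact coordinates", {
  reads <- bind_transcripts(
    ts1("a", "chr3", "+", cbind(c(100, 300), c(200, 500))),
    ts1("b", "chr3", "+", cbind(c(100, 300), c(250, 500))))
  m <- collapse_isoforms(reads)
  reg <- cluster_new_gene_regions(m)
  expect_equal(reg$regions$n_exons, 3L)  # (100,200),(100,250),(300,500)
})

test_that("novelty summary counts follow the bookkeeping rules", {
  annot <- toy_annotation()
  reads <- bind_transcripts(
    ts1("n1", "chr1", "+", cbind(c(120, 350), c(200, 560))),
    ts1("n2", "chr1", "+", cbind(c(120, 360), c(200, 580))),
    ts1("n3", "chr1", "-", cbind(c(2000, 2500), c(2100, 2700))),
    ts1("g1a", "chr5", "+", cbind(c(100, 300), c(200, 500))),
    ts1("g1b", "chr5", "+", cbind(c(400, 700), c(450, 900))))
  m <- collapse_isoforms(reads)
  cl <- classify_models(m, annot)
  reg <- cluster_new_gene_regions(m, cl)
  s <- novelty_summary(cl, m, reg)
  expect_equal(s$n_new_annotations, 5L)
  expect_equal(s$n_new_genes, 1L)
  expect_equal(s$n_isoforms_for_new_genes, 2L)
  expect_equal(s$n_genes_with_new_annotations, 3L)  # g1, g2 + 1 new region
  # invariant: new annotations split between new genes and known genes
  expect_equal(s$n_new_annotations,
               s$n_isoforms_for_new_genes +
                 sum(cl$category == "novel_isoform_known_gene"))
})

test_that("no novel models yields an all-zero summary", {
  annot <- toy_annotation()
  m <- collapse_isoforms(annot$transcripts)
  cl <- classify_models(m, annot)
  reg <- cluster_new_gene_regions(m, cl)
  s <- novelty_summary(cl, m, reg)
  expect_true(all(unlist(s) == 0L))
})

test_that("collapsing an annotation against itself is 100% annotated", {
  ds <- simulate_dataset(sim_config(seed = 3, n_genes = 12))
  annot <- truth_annotation(ds$sim)
  m <- collapse_isoforms(annot$transcripts)
  cl <- classify_models(m, annot)
  expect_true(all(cl$category == "annotated"))
})

test_that("hiding genes moves exactly their models to novel_gene", {
  ds <- simulate_dataset(sim_config(seed = 19, n_genes = 12,
                                    n_hidden_genes = 3, p_donor_shift = 0))
  cur <- curate_isoforms(ds$reads, ds$sim$genome, ds$junctions,
                         emitted_annotation(ds$sim))
  gene_of_code <- ds$read_truth$gene_id[match(cur$models$code,
                                              ds$read_truth$code)]
  hidden <- gene_of_code %in% ds$truth$hidden_genes
  expect_equal(cur$classification$category == "novel_gene", hidden)
  expect_equal(nrow(cur$regions$regions), 3L)
  # partition invariant
  expect_equal(sum(table(cur$classification$category)), nrow(cur$models))
})
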