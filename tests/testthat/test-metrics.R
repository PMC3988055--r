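test_that("overlap matrix: diagonal, disjoint sets, empty sets", {
  a <- transcript_set(c("a1", "a2"), "chr1", "+",
                      list(cbind(c(100, 300), c(200, 400)),
                           cbind(c(900, 1100), c(1000, 1200))))
  b <- ts1("b1", "chr2", "+", cbind(c(100, 300), c(200, 400)))
  e <- transcript_set(character(), character(), character(), list())
  om <- overlap_matrix(list(A = a, B = b, E = e))
  expect_equal(om$percent["A", "A"], 100)
  expect_equal(om$percent["B", "B"], 100)
  expect_equal(om$percent["A", "B"], 0)   # different chromosomes
  expect_true(all(is.na(om$percent["E", ])))
  expect_equal(unname(om$counts), c(2L, 1L, 0L))
})

test_that("overlap matrix agrees with the per-base oracle on random toys", {
  set.seed(404)
  rand_set <- function(n, tag) {
    starts <- sort(sample.int(9000, n))
    transcript_set(paste0(tag, seq_len(n)),
                   sample(c("c1", "c2"), n, replace = TRUE), "+",
                   lapply(starts, function(s) cbind(s, s + sample(50:800, 1))))
  }
  for (rep in 1:5) {
    A <- rand_set(sample(3:40, 1), "a")
    B <- rand_set(sample(3:40, 1), "b")
    om <- overlap_matrix(list(A = A, B = B))
    for (ch_pair in list(c("A", "B"), c("B", "A"))) {
      row <- if (ch_pair[1] == "A") A else B
      col <- if (ch_pair[2] == "A") A else B
      expect_equal(om$percent[ch_pair[1], ch_pair[2]],
                   oracle_overlap_pct(row, col))
    }
  }
})

test_that("coverage fractions match the per-base oracle; >90% is strict", {
  annot <- transcript_set(
    c("t1", "t2"), "c1", "+",
    list(cbind(c(100, 400), c(300, 700)),   # exonic length 500
         cbind(c(2000, 2600), c(2400, 2800))),
    source = "annotation")
  # reads covering exactly 450/500 of t1 and only the intron of t2
  reads <- bind_transcripts(
    ts1("r1", "c1", "+", cbind(100, 300)),            # 200
    ts1("r2", "c1", "+", cbind(400, 650)),            # 250
    ts1("r3", "c1", "+", cbind(2400, 2600)))          # intron of t2 only
  cov <- coverage_profile(annot, reads, breaks = c(0, 600, 1200))
  p <- cov$per_transcript
  expect_equal(p$covered_bases[p$id == "t1"], 450L)
  expect_equal(p$fraction[p$id == "t1"], 0.9)
  expect_equal(p$covered_bases[p$id == "t2"], 0L)
  # exactly 0.90 is NOT "more than 90%"
  expect_equal(sum(cov$histogram$n_gt90), 0L)
  expect_equal(sum(cov$histogram$n_any), 1L)
  for (id in p$id) {
    i <- which(annot$id == id)
    expect_equal(p$covered_bases[p$id == id],
                 oracle_covered_bases(annot$exons[[i]],
                                      do.call(rbind, reads$exons)))
  }
})

test_that("coverage histograms are nested and robust to zero reads", {
  ds <- simulate_dataset(sim_config(seed = 21, n_genes = 10))
  annot <- truth_annotation(ds$sim)$transcripts
  cov <- coverage_profile(annot, ds$reads, breaks = seq(0, 4000, 500))
  h <- cov$histogram
  expect_true(all(h$n_gt90 <= h$n_any))
  expect_true(all(h$n_any <= h$n_all))
  expect_equal(sum(h$n_all), nrow(annot))
  none <- coverage_profile(
    annot, transcript_set(character(), character(), character(), list()),
    breaks = seq(0, 4000, 500))
  expect_true(all(none$histogram$n_any == 0L))
  expect_equal(none$histogram$n_all, h$n_all)
})

test_that("splice distances are zero for perfect reads, signed downstream", {
  annot_j <- data.frame(chrom = "c1", strand = c("+", "-"),
                        start = c(200L, 1200L), end = c(300L, 1300L))
  obs <- data.frame(chrom = "c1", strand = c("+", "-", "+"),
                    start = c(200L, 1200L, 204L), end = c(300L, 1296L, 300L))
  prof <- splice_distance_profile(obs, annot_j, window = 50)
  don <- prof[prof$site_kind == "donor" & !is.na(prof$distance), ]
  acc <- prof[prof$site_kind == "acceptor" & !is.na(prof$distance), ]
  # donors: 0 (r1), +4 (minus-strand read, end moved upstream in genome
  # = downstream in transcript), +4 (plus-strand read start moved right)
  expect_equal(don$count[don$distance == 0], 1L)
  expect_equal(don$count[don$distance == 4], 2L)
  expect_equal(sum(don$count), 3L)
  # acceptors unaffected
  expect_equal(acc$count[acc$distance == 0], 3L)
  expect_equal(sum(acc$count), 3L)
})

test_that("splice sites with no annotated neighbour fall in the overflow", {
  annot_j <- data.frame(chrom = "c1", strand = "+",
                        start = 200L, end = 300L)
  obs <- data.frame(chrom = "c1", strand = "+", start = 800L, end = 900L)
  prof <- splice_distance_profile(obs, annot_j, window = 50)
  ov <- prof[is.na(prof$distance), ]
  expect_equal(ov$count, c(1L, 1L))
  expect_warning(
    splice_distance_profile(transform(obs, strand = "*"), annot_j, 50),
    "unknown strand")
})
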