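test_that("simulated datasets are byte-identical for a fixed seed", {
  cfg <- sim_config(seed = 8, n_genes = 6, n_hidden_genes = 1)
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  write_simulation(simulate_dataset(cfg), d1)
  write_simulation(simulate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     info = f)
  }
  # and a different seed changes the data
  d3 <- file.path(withr::local_tempdir(), "c")
  write_simulation(simulate_dataset(sim_config(seed = 9, n_genes = 6,
                                               n_hidden_genes = 1)), d3)
  expect_false(identical(readLines(file.path(d1, "reads.bed12")),
                         readLines(file.path(d3, "reads.bed12"))))
})

test_that("every planted junction carries a canonical motif", {
  sim <- generate_genome(sim_config(seed = 14, n_genes = 8))
  j <- extract_junctions(sim$isoforms)
  r <- check_splice_motifs(j, sim$genome)
  expect_true(all(r$motif_valid))
  # and motif orientation matches the planted gene strand
  expect_equal(r$inferred_strand, j$strand)
})

test_that("error-free reads reproduce their source isoform's code", {
  ds <- simulate_dataset(sim_config(seed = 25, n_genes = 8,
                                    p_truncate_5p = 0, p_truncate_3p = 0,
                                    p_donor_shift = 0))
  expect_true(all(ds$read_truth$code == ds$read_truth$true_code))
  expect_true(all(ds$truth$expected_retained))
})

test_that("truncation keeps internal junctions: read chains are sub-chains", {
  ds <- simulate_dataset(sim_config(seed = 26, n_genes = 8,
                                    p_truncate_5p = 0.8, p_truncate_3p = 0.8,
                                    p_donor_shift = 0))
  tr <- ds$read_truth
  expect_true(any(tr$drop5 > 0 | tr$drop3 > 0))  # truncation actually occurs
  iso_introns <- lapply(parse_code(tr$true_code), `[[`, "introns")
  multi <- which(tr$n_exons >= 2)
  for (i in multi) {
    ri <- parse_code(tr$code[i])[[1]]$introns
    key_r <- paste(ri[, 1], ri[, 2])
    key_t <- paste(iso_introns[[i]][, 1], iso_introns[[i]][, 2])
    hit <- which(key_t == key_r[1])
    expect_length(hit, 1)
    expect_equal(key_t[hit:(hit + length(key_r) - 1)], key_r)
  }
  # single-exon truncations are never retained downstream
  cur <- curate_isoforms(ds$reads, ds$sim$genome, ds$junctions,
                         emitted_annotation(ds$sim))
  mono <- tr$read_id[tr$n_exons == 1]
  if (length(mono) > 0) {
    rep <- cur$validation$report
    expect_true(all(!rep$retained[rep$id %in% mono]))
  }
})

test_that("donor shifts are applied, recorded, and bounded by max_shift", {
  ds <- simulate_dataset(sim_config(seed = 27, n_genes = 8,
                                    p_truncate_5p = 0, p_truncate_3p = 0,
                                    p_donor_shift = 1))
  tr <- ds$read_truth
  expect_true(all(tr$n_shift_applied + tr$n_shift_failed ==
                    tr$n_exons - 1L))
  expect_true(all(tr$n_shift_applied > 0))
  # every shifted donor moved downstream by at most max_shift, and the code
  # changed iff a shift was applied
  expect_true(all((tr$code != tr$true_code) == (tr$n_shift_applied > 0)))
  for (i in seq_len(min(nrow(tr), 50))) {
    obs <- parse_code(tr$code[i])[[1]]
    tru <- parse_code(tr$true_code[i])[[1]]
    if (nrow(obs$introns) != nrow(tru$introns)) next
    donor_obs <- if (obs$strand == "+") obs$introns[, 1] else obs$introns[, 2]
    donor_tru <- if (tru$strand == "+") tru$introns[, 1] else tru$introns[, 2]
    delta <- if (obs$strand == "+") donor_obs - donor_tru
    else donor_tru - donor_obs
    expect_true(all(delta >= 0 & delta <= 10))
    # acceptors untouched
    acc_obs <- if (obs$strand == "+") obs$introns[, 2] else obs$introns[, 1]
    acc_tru <- if (tru$strand == "+") tru$introns[, 2] else tru$introns[, 1]
    expect_equal(acc_obs, acc_tru)
  }
})

test_that("short-read evidence covers true junctions within the count range", {
  cfg <- sim_config(seed = 28, n_genes = 8,
                    short_read_coverage_per_junction = c(4L, 9L))
  sim <- generate_genome(cfg)
  srj <- simulate_short_read_junctions(sim)
  expect_true(all(srj$records$count >= 4L & srj$records$count <= 9L))
  truth_j <- extract_junctions(sim$isoforms)
  key_t <- unique(paste(truth_j$chrom, truth_j$start, truth_j$end))
  key_r <- paste(srj$records$chrom, srj$records$start, srj$records$end)
  expect_setequal(key_r, key_t)  # p_junction_unsupported = 0: nothing omitted
})

test_that("withholding all junction evidence retains nothing", {
  ds <- simulate_dataset(sim_config(seed = 29, n_genes = 5,
                                    p_junction_unsupported = 1))
  expect_equal(nrow(ds$junctions), 0L)
  cur <- curate_isoforms(ds$reads, ds$sim$genome, ds$junctions,
                         emitted_annotation(ds$sim))
  expect_equal(sum(cur$validation$report$retained), 0L)
  expect_equal(nrow(cur$models), 0L)
})

test_that("infeasible gene geometry fails with an explanation", {
  expect_error(generate_genome(sim_config(seed = 1, n_genes = 100,
                                          chrom_length = 20000L)),
               "infeasible")
  expect_error(sim_config(p_donor_shift = 1.5), "probabilities")
  expect_error(sim_config(n_hidden_genes = 30, n_genes = 20), "subset")
})
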