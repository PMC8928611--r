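test_that("reference generation is deterministic and primer-flanked", {
  r1 <- generate_reference_db(1, 6)
  r2 <- generate_reference_db(1, 6)
  expect_identical(r1, r2)
  f1 <- tempfile(); f2 <- tempfile()
  write_reference_fasta(r1, f1); write_reference_fasta(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # forward-primer pattern matches the first 20 nt of every record
  expect_true(all(vapply(r1$seq, match_primer, logical(1),
                         pattern = fwd_primer_default(), end = "5prime")))
  expect_true(all(vapply(r1$seq, match_primer, logical(1),
                         pattern = rev_primer_default(), end = "3prime")))
  expect_true(all(nzchar(r1$genus)))
  back <- read_reference_fasta(f1)
  expect_equal(back, r1)
  unlink(c(f1, f2))
})

test_that("all pairwise reference distances respect the floor", {
  refs <- generate_reference_db(1, 20, min_pairwise_dist = 0.08)
  d <- combn(20, 2, function(ij) {
    pairwise_distance(refs$seq[ij[1]], refs$seq[ij[2]])
  })
  expect_true(all(d >= 0.08))
})

test_that("read simulation is deterministic and fully provenance-tracked", {
  refs <- generate_reference_db(2, 6)
  cfg <- sim_config(seed = 3, n_taxa = 6, samples_per_group = 1,
                    reads_per_sample = 300)
  s1 <- simulate_samples(cfg, refs)
  s2 <- simulate_samples(cfg, refs)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$truth$provenance), nrow(s1$reads))
  expect_true(all(s1$reads$read_id == s1$truth$provenance$read_id))
  expect_equal(unname(colSums(s1$truth$abundance)), rep(1, ncol(s1$truth$abundance)),
               tolerance = 1e-9)
})

test_that("noise-free reads reconstruct reference amplicons exactly", {
  refs <- generate_reference_db(4, 8)
  cfg <- sim_config(seed = 4, n_taxa = 8, samples_per_group = 1,
                    groups = data.frame(treatment = "Con", phase = "PII"),
                    reads_per_sample = 300, base_error_rate = 0,
                    chimera_rate = 0, artifact_rate = 0, offlen_rate = 0,
                    effect_map = list())
  sim <- simulate_samples(cfg, refs)
  fwd <- data.frame(id = sim$reads$read_id, seq = sim$reads$fwd_seq,
                    qual = sim$reads$fwd_qual, sample_id = sim$reads$sample_id,
                    stringsAsFactors = FALSE)
  rev <- data.frame(id = sim$reads$read_id, seq = sim$reads$rev_seq,
                    qual = sim$reads$rev_qual, sample_id = sim$reads$sample_id,
                    stringsAsFactors = FALSE)
  mg <- merge_pairs(fwd, rev)
  expect_equal(mg$stats$failed, 0L)
  src <- sim$truth$provenance$source[match(mg$contigs$id,
                                           sim$truth$provenance$read_id)]
  expect_identical(mg$contigs$seq, refs$seq[match(src, refs$ref_id)])
})

test_that("chimera injection rate is binomial around its nominal value", {
  refs <- generate_reference_db(5, 10)
  cfg <- sim_config(seed = 6, n_taxa = 10, samples_per_group = 1,
                    groups = data.frame(treatment = "Con", phase = "PII"),
                    reads_per_sample = 10000, chimera_rate = 0.05,
                    effect_map = list())
  sim <- simulate_samples(cfg, refs)
  n_chim <- sum(sim$truth$provenance$type == "chimera")
  sigma <- sqrt(10000 * 0.05 * 0.95)
  expect_lt(abs(n_chim - 500), 3 * sigma)
  # every chimera has two distinct parents and a mid-range breakpoint
  chim <- sim$truth$provenance[sim$truth$provenance$type == "chimera", ]
  expect_true(all(chim$source != chim$parent_b))
  expect_true(all(chim$breakpoint_frac >= 0.2 & chim$breakpoint_frac <= 0.8))
  art <- sim$truth$provenance[sim$truth$provenance$type == "artifact", ]
  expect_true(all(art$trunc_len >= 6 & art$trunc_len <= 30))
})

test_that("a 4-fold group multiplier raises mean abundance in nearly all seeds", {
  refs <- generate_reference_db(6, 8)
  groups <- data.frame(treatment = c("Con", "Trt"), phase = "PII")
  hit <- vapply(1:50, function(s) {
    cfg <- sim_config(seed = s, n_taxa = 8, samples_per_group = 6,
                      groups = groups, reads_per_sample = 10,
                      effect_map = list("Ref-004" = c(Trt.PII = 4)))
    ab <- simulate_samples(cfg, refs)$truth$abundance
    grp <- rep(c("Con", "Trt"), each = 6)
    mean(ab["Ref-004", grp == "Trt"]) > mean(ab["Ref-004", grp == "Con"])
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("off-length amplicons straddle the length window", {
  refs <- generate_reference_db(7, 6)
  cfg <- sim_config(seed = 8, n_taxa = 6, samples_per_group = 1,
                    groups = data.frame(treatment = "Con", phase = "PII"),
                    reads_per_sample = 4000, offlen_rate = 0.2,
                    base_error_rate = 0, chimera_rate = 0, artifact_rate = 0,
                    effect_map = list())
  sim <- simulate_samples(cfg, refs)
  fwd <- data.frame(id = sim$reads$read_id, seq = sim$reads$fwd_seq,
                    qual = sim$reads$fwd_qual, sample_id = sim$reads$sample_id,
                    stringsAsFactors = FALSE)
  rev <- data.frame(id = sim$reads$read_id, seq = sim$reads$rev_seq,
                    qual = sim$reads$rev_qual, sample_id = sim$reads$sample_id,
                    stringsAsFactors = FALSE)
  mg <- merge_pairs(fwd, rev)
  sc <- screen_contigs(mg$contigs, qc_params(min_mean_q = 0))
  type <- sim$truth$provenance$type[match(mg$contigs$id,
                                          sim$truth$provenance$read_id)]
  expect_true(all(sc$verdicts[type == "offlen"] == "fail_length"))
  expect_true(all(sc$verdicts[type == "regular"] == "pass"))
})
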