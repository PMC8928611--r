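p_default <- qc_params()
FWD <- "AGAGTTTGATCCTGGCTCAG"                 # 27F with M -> C
REV_RC <- revcomp("GAATTACCGCGGCGGCTG")       # 519R with W -> A, K -> G

make_contig <- function(core_len, q = 36L) {
  core <- rand_seq(core_len)
  seq <- paste0(FWD, core, REV_RC)
  list(seq = seq, qual = rep(as.integer(q), nchar(seq)))
}

test_that("intact primers are end-anchored zero-mismatch IUPAC matches", {
  seq <- paste0("AGAGTTTGATCCTGGCTCAG", rand_seq(100, seed = 61))
  expect_true(match_primer(seq, p_default$fwd_primer, "5prime"))
  seq2 <- paste0("C", substr(seq, 2, nchar(seq)))
  expect_false(match_primer(seq2, p_default$fwd_primer, "5prime"))
  seq3 <- paste0(rand_seq(100), revcomp("GAATTACCGCGGCGGCTG"))
  expect_true(match_primer(seq3, p_default$rev_primer, "3prime"))
  expect_false(match_primer("ACGT", p_default$fwd_primer, "5prime"))
})

test_that("mean Phred is the arithmetic mean of integer scores", {
  expect_equal(mean_phred(c(33L, 33L, 33L)), 33)
  expect_equal(mean_phred(c(rep(40L, 10), rep(20L, 10))), 30)
  expect_equal(mean_phred(40L), 40)
  expect_equal(mean_phred(qual_encode(c(33, 33, 33))), 33)
  expect_error(mean_phred(integer(0)), "empty")
})

test_that("contig screening applies checks in order and trims primers on pass", {
  c500 <- make_contig(500 - 38)       # total length 500 with primers
  r <- screen_contig(c500, p_default)
  expect_equal(r$verdict, "pass")
  expect_equal(nchar(r$contig$seq), 500 - 20 - 18)
  expect_equal(length(r$contig$qual), 462)

  c399 <- make_contig(399 - 38, q = 40L)
  expect_equal(screen_contig(c399, p_default)$verdict, "fail_length")
  c400 <- make_contig(400 - 38, q = 40L)
  expect_equal(screen_contig(c400, p_default)$verdict, "pass")
  c580 <- make_contig(580 - 38, q = 40L)
  expect_equal(screen_contig(c580, p_default)$verdict, "pass")
  c581 <- make_contig(581 - 38, q = 40L)
  expect_equal(screen_contig(c581, p_default)$verdict, "fail_length")

  # mean quality just below the threshold fails; at threshold passes
  cq <- make_contig(450 - 38)
  cq$qual <- rep(c(32L, 34L), length.out = nchar(cq$seq))
  expect_equal(screen_contig(cq, p_default)$verdict, "pass")
  cq$qual[1] <- 30L   # mean drops below 33
  expect_equal(screen_contig(cq, p_default)$verdict, "fail_quality")

  # first failing check wins: broken fwd primer on a short low-quality contig
  bad <- list(seq = rand_seq(100, seed = 62), qual = rep(10L, 100))
  expect_equal(screen_contig(bad, p_default)$verdict, "fail_primer_fwd")
  # intact fwd, broken rev, bad length -> primer_rev reported
  bad2 <- list(seq = paste0(FWD, rand_seq(100)), qual = rep(10L, 120))
  expect_equal(screen_contig(bad2, p_default)$verdict, "fail_primer_rev")
})

test_that("bulk screening partitions contigs and matches screen_contig", {
  set.seed(63)
  contigs <- do.call(rbind, lapply(1:40, function(i) {
    len <- sample(c(350, 450, 500, 600), 1) - 38
    cc <- make_contig(len, q = sample(c(30L, 36L), 1))
    if (i %% 7 == 0) cc$seq <- paste0("C", substr(cc$seq, 2, nchar(cc$seq)))
    data.frame(id = paste0("c", i), seq = cc$seq,
               qual = qual_encode(cc$qual),
               sample_id = sample(c("s1", "s2"), 1), stringsAsFactors = FALSE)
  }))
  res <- screen_contigs(contigs, p_default)
  single <- vapply(seq_len(nrow(contigs)), function(i) {
    screen_contig(list(seq = contigs$seq[i],
                       qual = qual_decode(contigs$qual[i])), p_default)$verdict
  }, character(1))
  expect_equal(res$verdicts, single)
  # tallies partition the input
  tal <- res$tallies
  expect_equal(sum(tal[, -1]), nrow(contigs))
  expect_equal(tal$pass, as.integer(table(contigs$sample_id[res$verdicts == "pass"])[tal$sample_id]))
})

test_that("screening a passed contig again passes (idempotence)", {
  p_notrim <- qc_params(trim_primers = FALSE)
  cc <- make_contig(470 - 38)
  r1 <- screen_contig(cc, p_notrim)
  expect_equal(r1$verdict, "pass")
  expect_equal(screen_contig(r1$contig, p_notrim)$verdict, "pass")
  # trimmed contig passes again with empty primer patterns + shifted bounds
  r2 <- screen_contig(cc, p_default)
  p_shift <- qc_params(fwd_primer = "", rev_primer = "",
                       min_len = p_default$min_len - 38,
                       max_len = p_default$max_len - 38,
                       trim_primers = FALSE)
  expect_equal(screen_contig(r2$contig, p_shift)$verdict, "pass")
})

test_that("samples below the sufficiency threshold are excluded", {
  tal <- data.frame(sample_id = sprintf("S%02d", 1:60),
                    pass = c(rep(999L, 5), rep(500L, 3), rep(1000L, 10),
                             rep(2500L, 42)), stringsAsFactors = FALSE)
  res <- screen_sample(tal, qc_params())
  expect_equal(length(res$included), 52)
  expect_equal(length(res$excluded), 8)
  expect_true(all(tal$pass[tal$sample_id %in% res$included] >= 1000))
})
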