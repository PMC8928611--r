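# Construct two divergent parents and chimeric/truncated queries.
make_parents <- function(seed = 71, len = 400, n_diff = 10) {
  P1 <- rand_seq(len, seed = seed)
  pos <- c(40, 80, 120, 160, 199, 201, 240, 280, 320, 360)[seq_len(n_diff)]
  P2 <- mutate_at(P1, pos)
  list(P1 = P1, P2 = P2, pos = pos)
}

cand_set <- function(seqs, ids = NULL, counts = 100L) {
  n <- length(seqs)
  if (is.null(ids)) ids <- sprintf("Otu-%05d", seq_len(n))
  list(otu_id = ids, rep_seq = seqs,
       counts = matrix(rep(counts, n), ncol = 1))
}

test_that("a mid-point chimera of two parents is flagged with the right parents", {
  pp <- make_parents()
  query <- paste0(substr(pp$P1, 1, 200), substr(pp$P2, 201, 400))
  v <- detect_chimera(list(rep_seq = query, otu_id = "Otu-09999"),
                      cand_set(c(pp$P1, pp$P2)))
  expect_true(v$is_chimera)
  expect_equal(sort(c(v$parent_a, v$parent_b)), c("Otu-00001", "Otu-00002"))
  expect_equal(v$diff_model_best, 0)
  expect_equal(v$diff_single_best, 5)
  # breakpoint lies between the flanking diagnostic sites (199 and 201)
  expect_gte(v$breakpoint, 199)
  expect_lte(v$breakpoint, 201)
  expect_gte(v$votes_left, 2)
  expect_gte(v$votes_right, 2)
})

test_that("a near-copy of one parent is not a chimera (gain below threshold)", {
  pp <- make_parents()
  query <- mutate_at(pp$P1, 57)
  v <- detect_chimera(list(rep_seq = query), cand_set(c(pp$P1, pp$P2)))
  expect_false(v$is_chimera)
  expect_lte(v$diff_single_best - v$diff_model_best, 1)
})

test_that("chimera verdicts need candidates and ignore their input order", {
  pp <- make_parents()
  query <- paste0(substr(pp$P1, 1, 200), substr(pp$P2, 201, 400))
  empty <- list(otu_id = character(), rep_seq = character(),
                counts = matrix(0L, 0, 1))
  expect_false(detect_chimera(list(rep_seq = query), empty)$is_chimera)
  extra <- mutate_at(pp$P1, c(10, 50, 90, 130, 170, 210, 250, 290, 330, 370))
  v1 <- detect_chimera(list(rep_seq = query),
                       cand_set(c(pp$P1, pp$P2, extra),
                                c("Otu-00001", "Otu-00002", "Otu-00003")))
  v2 <- detect_chimera(list(rep_seq = query),
                       cand_set(c(extra, pp$P2, pp$P1),
                                c("Otu-00003", "Otu-00002", "Otu-00001")))
  expect_equal(v1[c("is_chimera", "parent_a", "parent_b", "breakpoint",
                    "diff_single_best", "diff_model_best")],
               v2[c("is_chimera", "parent_a", "parent_b", "breakpoint",
                    "diff_single_best", "diff_model_best")])
})

test_that("end-integrity keeps overhangs of at most five nucleotides", {
  set.seed(72)
  refdb <- mini_refdb(c(rand_seq(420), rand_seq(430)))
  q_id <- substr(refdb$seq[1], 1, 410)
  v <- end_integrity_check(list(rep_seq = q_id), refdb)
  expect_true(v$keep)
  expect_equal(v$unaligned_5p + v$unaligned_3p, 0)
  expect_equal(v$ref_id, "Ref-001")

  q6 <- paste0("GTGTGT", substr(refdb$seq[1], 1, 414))   # 6 novel 5' bases
  v6 <- end_integrity_check(list(rep_seq = q6), refdb)
  expect_equal(v6$unaligned_5p, 6)
  expect_false(v6$keep)

  # 5 novel 3' bases guaranteed to mismatch the reference tail
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  tail5 <- strsplit(substr(refdb$seq[1], 416, 420), "")[[1]]
  q5 <- paste0(substr(refdb$seq[1], 1, 415),
               paste(flip[tail5], collapse = ""))
  v5 <- end_integrity_check(list(rep_seq = q5), refdb)
  expect_equal(v5$unaligned_3p, 5)
  expect_true(v5$keep)

  # no reference of sufficient length
  vno <- end_integrity_check(list(rep_seq = paste0(refdb$seq[2], "ACGTACGT")),
                             refdb)
  expect_false(vno$keep)
  expect_equal(vno$reason, "no_eligible_reference")
})

test_that("rare OTUs need a full-span near-perfect match (1% inclusive)", {
  set.seed(73)
  refdb <- mini_refdb(c(rand_seq(400), rand_seq(410)))
  q4 <- mutate_at(refdb$seq[1], c(50, 150, 250, 350))
  expect_equal(rare_otu_check(list(rep_seq = q4), refdb), "keep")
  q5 <- mutate_at(refdb$seq[1], c(50, 150, 250, 350, 380))
  expect_equal(rare_otu_check(list(rep_seq = q5), refdb), "discard")
  expect_equal(rare_otu_check(list(rep_seq = refdb$seq[1]), refdb), "keep")
  # a novel overhang breaks the full-span requirement (query-side semantics:
  # a merely shorter query still spans itself and is kept)
  qo <- paste0("GG", mutate_at(refdb$seq[1], c(50, 150)))
  expect_equal(rare_otu_check(list(rep_seq = qo), refdb), "discard")
  qt <- substr(refdb$seq[1], 8, 400)
  expect_equal(rare_otu_check(list(rep_seq = qt), refdb), "keep")
})

test_that("curation is an identity on clean, abundant, full-length OTUs", {
  refs <- generate_reference_db(7, 6)
  otus <- greedy_cluster(refs$seq, rep(50L, 6), cutoff = 0.04)
  cur <- curate_otus(otus, refs)
  expect_equal(cur$otus$otu_id, otus$otu_id)
  expect_true(all(cur$report$stage == "kept"))
  expect_true(all(cur$otus$status == "curated"))
})

test_that("an OTU failing chimera and integrity is reported at the chimera stage", {
  set.seed(74)
  P1 <- rand_seq(420)
  P2 <- mutate_at(P1, seq(20, 400, by = 20))   # 20 diffs, both halves
  refdb <- mini_refdb(c(P1, P2, rand_seq(430)))
  novel <- strrep("GT", 6)
  # chimera of shifted parent halves with a 12 nt novel 5' overhang:
  # flagged as chimera AND >5 nt unaligned at the 5' end
  cb <- paste0(novel, substr(P1, 1, 198), substr(P2, 199, 408))
  cur <- curate_otus(make_otus(c(P1, P2, cb), c(100, 90, 3)), refdb)
  expect_equal(cur$report$stage, c("kept", "kept", "chimera"))
  # same overhang without chimeric structure fails at integrity instead
  to <- paste0(novel, substr(P1, 1, 408))
  cur2 <- curate_otus(make_otus(c(P1, P2, to), c(100, 90, 3)), refdb)
  expect_equal(cur2$report$stage, c("kept", "kept", "integrity"))
})

test_that("the rare-OTU rule only ever touches OTUs with at most two reads", {
  set.seed(75)
  refdb <- mini_refdb(c(rand_seq(400), rand_seq(405)))
  # 3% divergent from the nearest reference, full length
  q <- mutate_at(refdb$seq[1], seq(10, 400, by = 33))
  cur3 <- curate_otus(make_otus(c(refdb$seq[1], q), c(50, 3)), refdb)
  expect_true(all(cur3$report$stage == "kept"))    # >= 3 reads: rare bypassed
  cur2 <- curate_otus(make_otus(c(refdb$seq[1], q), c(50, 2)), refdb)
  expect_equal(cur2$report$stage[cur2$report$total == 2], "rare")
})
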