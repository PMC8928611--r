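# Shared fixture builders. All fixtures are generated in code.

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute bases at given 1-based positions (cycling A->C->G->T->A)
mutate_at <- function(seq, pos) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  nxt <- c(A = "C", C = "G", G = "T", T = "A")
  ch[pos] <- nxt[ch[pos]]
  paste(ch, collapse = "")
}

# tiny reference data.frame from raw sequences
mini_refdb <- function(seqs, genera = NULL) {
  n <- length(seqs)
  if (is.null(genera)) genera <- sprintf("Genus%02d", seq_len(n))
  data.frame(ref_id = sprintf("Ref-%03d", seq_len(n)), seq = seqs,
             phylum = "PhylumA", class = "ClassA", order = "OrderA",
             family = rep(sprintf("Family%02d", seq_len(ceiling(n / 2))),
                          each = 2)[seq_len(n)],
             genus = genera, stringsAsFactors = FALSE)
}

# independent greedy-clustering oracle from a full distance matrix
brute_greedy <- function(seqs, totals, cutoff) {
  ord <- order(-totals, seqs, method = "radix")
  seqs <- seqs[ord]
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d[i, j] <- pairwise_distance(seqs[i], seqs[j])
    }
  }
  reps <- integer(0)
  assign <- integer(n)
  for (i in seq_len(n)) {
    hit <- 0L
    for (r in seq_along(reps)) {
      if (d[i, reps[r]] <= cutoff + 1e-12) { hit <- r; break }
    }
    if (hit == 0L) { reps <- c(reps, i); hit <- length(reps) }
    assign[i] <- hit
  }
  list(rep_seqs = seqs[reps], assign = assign, sorted_seqs = seqs)
}

# exact two-sided rank-sum p-value by enumeration of group labelings
wilcox_exact_enum <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  combos <- utils::combn(n, length(x))
  W <- apply(combos, 2, function(idx) sum(r[idx])) - length(x) * (length(x) + 1) / 2
  w_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  mu <- length(x) * length(y) / 2
  if (w_obs > mu) {
    p <- 2 * mean(W >= w_obs)
  } else if (w_obs < mu) {
    p <- 2 * mean(W <= w_obs)
  } else {
    p <- 1
  }
  min(p, 1)
}

# Kruskal-Wallis H from first principles (mid-ranks, tie correction)
kw_H_oracle <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  gs <- split(r, groups)
  H <- 12 / (N * (N + 1)) * sum(vapply(gs, function(ri) sum(ri)^2 / length(ri),
                                       numeric(1))) - 3 * (N + 1)
  t <- table(values)
  C <- 1 - sum(t^3 - t) / (N^3 - N)
  H / C
}

# hand-built otu_set (bypasses clustering)
make_otus <- function(seqs, counts) {
  structure(list(otu_id = sprintf("Otu-%05d", seq_along(seqs)),
                 rep_seq = seqs, status = rep("raw", length(seqs)),
                 counts = matrix(as.integer(counts), ncol = 1),
                 members = as.list(seq_along(seqs)), uniq_seq = seqs),
            class = "otu_set")
}
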