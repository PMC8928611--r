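#' Train the naive-Bayes genus classifier
#'
#' Word-presence (set) semantics over `word_len`-mers: for genus g and word
#' w, `P(w|g) = (n_g(w) + P_prior(w)) / (N_g + 1)` where `n_g(w)` is the
#' number of g's sequences containing w, `N_g` the sequence count of g, and
#' `P_prior(w) = (n(w) + 0.5) / (N + 1)` over all training sequences.
#'
#' @param refdb reference data.frame with `seq` and lineage columns
#'   `phylum`, `class`, `order`, `family`, `genus` (all non-empty).
#' @param word_len word length (default 8).
#' @return a `nb_model` list: `logp` (vocabulary x genus log-probability
#'   matrix), `genera` (per-genus lineage data.frame), `word_len`,
#'   `in_vocab` (logical: word occurs in at least one training sequence).
#' @export
train_classifier <- function(refdb, word_len = 8) {
  if (nrow(refdb) == 0) stop("empty reference database")
  stopifnot(!anyNA(refdb$genus), all(nzchar(refdb$genus)))
  sets <- cpp_kmer_sets(refdb$seq, as.integer(word_len))
  vocab_n <- 4L^word_len
  nw <- integer(vocab_n)                       # n(w) over all sequences
  for (s in sets) nw[s + 1L] <- nw[s + 1L] + 1L
  N <- nrow(refdb)
  prior <- (nw + 0.5) / (N + 1)
  genera <- unique(refdb[, c("phylum", "class", "order", "family", "genus")])
  genera <- genera[order(genera$genus), , drop = FALSE]
  rownames(genera) <- NULL
  logp <- matrix(0, vocab_n, nrow(genera),
                 dimnames = list(NULL, genera$genus))
  for (gi in seq_len(nrow(genera))) {
    rows <- which(refdb$genus == genera$genus[gi])
    ng <- integer(vocab_n)
    for (s in sets[rows]) ng[s + 1L] <- ng[s + 1L] + 1L
    logp[, gi] <- log((ng + prior) / (length(rows) + 1))
  }
  structure(list(logp = logp, genera = genera, word_len = word_len,
                 in_vocab = nw > 0L), class = "nb_model")
}

#' Bootstrap naive-Bayes classification of a query sequence
#'
#' Extracts the query's distinct word set; in each of `n_boot` trials,
#' samples one eighth of the words with replacement and assigns the genus
#' maximising the summed log word probabilities. Per-rank confidence is the
#' fraction of trials agreeing with the modal taxon at that rank
#' (aggregated up the lineage and made non-increasing with depth); the
#' lineage is reported down to the deepest rank with confidence at least
#' `threshold` and `"unclassified"` below.
#'
#' @param query nucleotide string (length >= `word_len`).
#' @param model an `nb_model` from [train_classifier()].
#' @param n_boot bootstrap trials (default 100).
#' @param threshold per-rank confidence cutoff (default 0.80).
#' @param seed RNG seed; classification is deterministic per seed.
#' @return a `tax_assignment` list: `lineage` (named character,
#'   phylum..genus), `confidence` (named numeric), `classified_rank`.
#' @export
classify_bootstrap <- function(query, model, n_boot = 100, threshold = 0.80,
                               seed = 1) {
  ranks <- c("phylum", "class", "order", "family", "genus")
  unclassified <- structure(
    list(lineage = setNames(rep("unclassified", 5), ranks),
         confidence = setNames(rep(0, 5), ranks),
         classified_rank = NA_character_), class = "tax_assignment")
  stopifnot(nchar(query) >= model$word_len)
  words <- cpp_kmer_sets(query, as.integer(model$word_len))[[1]] + 1L
  words <- words[model$in_vocab[words]]
  V <- length(words)
  if (V == 0) return(unclassified)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  nsub <- max(1L, V %/% 8L)
  lp <- model$logp[words, , drop = FALSE]
  winners <- integer(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(V, nsub, replace = TRUE)
    sc <- colSums(lp[idx, , drop = FALSE])
    winners[b] <- which.max(sc)               # ties: first (lex genus order)
  }
  lineage <- setNames(rep(NA_character_, 5), ranks)
  conf <- setNames(numeric(5), ranks)
  for (r in ranks) {
    taxa <- model$genera[[r]][winners]
    tab <- sort(table(taxa), decreasing = TRUE)
    lineage[r] <- names(tab)[1]
    conf[r] <- tab[1] / n_boot
  }
  conf <- rev(cummax(rev(conf)))              # non-increasing with depth
  deepest <- if (any(conf >= threshold)) max(which(conf >= threshold)) else 0L
  if (deepest < 5L && deepest >= 0L) {
    lineage[seq(deepest + 1L, 5L)] <- "unclassified"
  }
  structure(list(lineage = lineage, confidence = conf,
                 classified_rank = if (deepest > 0) ranks[deepest] else
                   NA_character_), class = "tax_assignment")
}

#' Closest reference by semi-global alignment
#'
#' Best alignment score over the reference database (ties: higher percent
#' identity, then lexicographic `ref_id`). Percent identity counts each
#' internal gap run as one difference over aligned columns, matching
#' [pairwise_distance()]; coverage is the aligned fraction of the query.
#'
#' @param query nucleotide string.
#' @param refdb reference data.frame.
#' @return a `nearest_hit` list: `ref_id`, `pct_identity` (full precision),
#'   `pct_identity_int` (reporting style), `query_coverage`.
#' @export
nearest_reference <- function(query, refdb) {
  stopifnot(nrow(refdb) > 0)
  best <- NULL
  for (i in order(refdb$ref_id, method = "radix")) {
    a <- align_pair(query, refdb$seq[i], ends_free = TRUE)
    pid <- 100 * (1 - (a$n_mismatch + a$n_internal_gap_runs) / a$aligned_cols)
    if (is.null(best) || a$score > best$score ||
        (a$score == best$score && pid > best$pid)) {
      ends <- query_end_overhangs(a)
      best <- list(score = a$score, pid = pid, ref = refdb$ref_id[i],
                   cov = (nchar(query) - sum(ends)) / nchar(query))
    }
  }
  structure(list(ref_id = best$ref, pct_identity = best$pid,
                 pct_identity_int = as.integer(round(best$pid)),
                 query_coverage = best$cov), class = "nearest_hit")
}

#' Classify every OTU in a set
#'
#' Runs [classify_bootstrap()] and [nearest_reference()] for each curated
#' OTU representative.
#'
#' @param otus an `otu_set`.
#' @param model an `nb_model`.
#' @param refdb reference data.frame.
#' @param n_boot,threshold,seed see [classify_bootstrap()].
#' @return data.frame: `otu_id`, lineage ranks, per-rank confidence columns
#'   (`conf_*`), `classified_rank`, `nearest_ref`, `pct_identity`.
#' @export
classify_otus <- function(otus, model, refdb, n_boot = 100, threshold = 0.80,
                          seed = 1) {
  n <- length(otus$otu_id)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    ta <- classify_bootstrap(otus$rep_seq[k], model, n_boot = n_boot,
                             threshold = threshold, seed = seed + k)
    nh <- nearest_reference(otus$rep_seq[k], refdb)
    rows[[k]] <- data.frame(
      otu_id = otus$otu_id[k], t(ta$lineage),
      t(setNames(ta$confidence, paste0("conf_", names(ta$confidence)))),
      classified_rank = ta$classified_rank, nearest_ref = nh$ref_id,
      pct_identity = nh$pct_identity_int, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
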