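#' Dereplicate sequences into unique sequences with per-sample counts
#'
#' @param seqs character vector of sequences (one per read).
#' @param sample_ids sample of each read.
#' @return list with `seq` (unique sequences) and `counts` (unique x sample
#'   integer matrix).
#' @export
dereplicate <- function(seqs, sample_ids) {
  samples <- sort(unique(sample_ids))
  f <- factor(seqs)
  counts <- table(f, factor(sample_ids, levels = samples))
  m <- matrix(as.integer(counts), nrow = nlevels(f),
              dimnames = list(NULL, samples))
  list(seq = levels(f), counts = m)
}

#' Greedy abundance-sorted centroid clustering into OTUs
#'
#' Unique sequences are processed in decreasing total-count order (ties
#' broken lexicographically by sequence). Each sequence joins the first
#' existing OTU (in founding order) whose representative is within `cutoff`
#' of it under [pairwise_distance()]; otherwise it founds a new OTU with
#' itself as representative. OTU ids are assigned in founding order.
#'
#' The 8-mer prescreen (`prescreen = TRUE`) skips representative alignments
#' that cannot be within the cutoff; its skip bound is conservative for
#' substitution-dominated divergence (the regime of amplicon data at a 4%
#' cutoff). Set `prescreen = FALSE` for the exact, alignment-only contract.
#'
#' @param seqs unique sequences (dereplicated).
#' @param counts integer matrix (length(seqs) x samples) or vector of total
#'   counts.
#' @param cutoff dissimilarity cutoff in (0, 0.5); default 0.04, the
#'   justified choice for the V1-V3 region.
#' @param prescreen use the 8-mer prescreen and equal-length Hamming
#'   fast path.
#' @param id_prefix prefix for zero-padded OTU ids.
#' @return an `otu_set`: list with `otu_id`, `rep_seq`, `status` (all
#'   `"raw"`), `counts` (OTU x sample matrix), `members` (list of indices
#'   into the *sorted* unique sequences, also returned as `uniq_seq`).
#' @export
greedy_cluster <- function(seqs, counts, cutoff = 0.04, prescreen = TRUE,
                           id_prefix = "Otu") {
  stopifnot(cutoff > 0, cutoff < 0.5)
  if (length(seqs) == 0) {
    return(structure(list(otu_id = character(), rep_seq = character(),
                          status = character(),
                          counts = matrix(0L, 0, 0), members = list(),
                          uniq_seq = character()), class = "otu_set"))
  }
  if (is.null(dim(counts))) {
    counts <- matrix(as.integer(counts), ncol = 1,
                     dimnames = list(NULL, "all"))
  }
  tot <- rowSums(counts)
  ord <- order(-tot, seqs, method = "radix")
  seqs <- seqs[ord]
  counts <- counts[ord, , drop = FALSE]
  assign <- cpp_greedy_cluster(seqs, cutoff, prescreen)
  n_otu <- max(assign)
  members <- split(seq_along(seqs), assign)
  rep_idx <- vapply(members, `[`, integer(1), 1L)  # founder = first member
  cm <- matrix(0L, n_otu, ncol(counts),
               dimnames = list(NULL, colnames(counts)))
  for (k in seq_len(n_otu)) {
    cm[k, ] <- as.integer(colSums(counts[members[[k]], , drop = FALSE]))
  }
  structure(list(
    otu_id = sprintf("%s-%05d", id_prefix, seq_len(n_otu)),
    rep_seq = seqs[rep_idx], status = rep("raw", n_otu), counts = cm,
    members = unname(members), uniq_seq = seqs), class = "otu_set")
}

#' @export
print.otu_set <- function(x, ...) {
  cat(sprintf("otu_set: %d OTUs, %d samples, %d reads\n", length(x$otu_id),
              ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Total read count per OTU
#' @param otus an `otu_set`.
#' @return integer vector.
#' @export
otu_totals <- function(otus) as.integer(rowSums(otus$counts))

# subset an otu_set by logical/integer index, keeping all parallel fields
otu_subset <- function(otus, keep) {
  structure(list(otu_id = otus$otu_id[keep], rep_seq = otus$rep_seq[keep],
                 status = otus$status[keep],
                 counts = otus$counts[keep, , drop = FALSE],
                 members = otus$members[keep], uniq_seq = otus$uniq_seq),
            class = "otu_set")
}
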