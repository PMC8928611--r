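#' De novo two-parent chimera detection
#'
#' Aligns the query representative to every candidate representative,
#' projects the differences onto query coordinates, and scans every ordered
#' candidate pair (A, B) and breakpoint k for the two-parent model
#' `diff_model(k) = diffs(query[1..k] vs A) + diffs(query[(k+1)..] vs B)`.
#' The query is flagged as a chimera iff the best model beats the best
#' single candidate by at least `min_diff_gain` differences and each side
#' has at least `min_votes` positions where the query matches its assigned
#' parent while mismatching the other. Ties are broken deterministically:
#' smallest breakpoint, then lexicographic parent ids. Specificity rests on
#' the abundance-skew candidate rule: callers supply only candidates with at
#' least `min_skew` times the query's total count.
#'
#' @param query list with `rep_seq` and optionally `otu_id`.
#' @param candidates an `otu_set` (or list with `otu_id`, `rep_seq`) of
#'   candidate parents; may be empty.
#' @param min_skew documented candidate abundance-skew factor (enforced by
#'   the caller; recorded in the verdict).
#' @param min_diff_gain minimum difference gain of the model over the best
#'   single parent.
#' @param min_votes minimum diagnostic positions supporting each side.
#' @return a `chimera_verdict` list: `is_chimera`, `parent_a`, `parent_b`,
#'   `breakpoint`, `diff_single_best`, `diff_model_best`, `votes_left`,
#'   `votes_right`.
#' @export
detect_chimera <- function(query, candidates, min_skew = 2,
                           min_diff_gain = 4, min_votes = 2) {
  empty <- list(is_chimera = FALSE, parent_a = NA_character_,
                parent_b = NA_character_, breakpoint = NA_integer_,
                diff_single_best = NA_integer_, diff_model_best = NA_integer_,
                votes_left = NA_integer_, votes_right = NA_integer_)
  nc <- length(candidates$otu_id)
  if (nc == 0) return(structure(empty, class = "chimera_verdict"))
  ord <- order(candidates$otu_id, method = "radix")
  ids <- candidates$otu_id[ord]
  reps <- candidates$rep_seq[ord]
  diffmat <- cpp_diff_profiles(query$rep_seq, reps)
  sc <- cpp_chimera_scan(diffmat)
  if (nc < 2 || is.na(sc$model_best)) {
    out <- empty
    out$diff_single_best <- sc$single_best
    return(structure(out, class = "chimera_verdict"))
  }
  is_chi <- (sc$model_best <= sc$single_best - min_diff_gain) &&
    sc$votes_left >= min_votes && sc$votes_right >= min_votes
  structure(list(
    is_chimera = is_chi,
    parent_a = if (is_chi) ids[sc$a] else NA_character_,
    parent_b = if (is_chi) ids[sc$b] else NA_character_,
    breakpoint = if (is_chi) sc$breakpoint else NA_integer_,
    diff_single_best = sc$single_best, diff_model_best = sc$model_best,
    votes_left = sc$votes_left, votes_right = sc$votes_right),
    class = "chimera_verdict")
}

#' Alignment-based 5'/3' end-integrity check
#'
#' The query is compared to its closest match of equal or longer length in
#' the reference database (highest semi-global alignment score; ties broken
#' by higher percent identity, then lexicographic `ref_id`). Query bases
#' left unaligned at either end (including bases opposite terminal subject
#' gaps) count as missing; the OTU is kept iff at most `max_missing` bases
#' are missing from each end ("more than five nucleotides missing" is
#' discarded).
#'
#' @param query list with `rep_seq`.
#' @param refdb reference data.frame (`ref_id`, `seq`).
#' @param max_missing maximum tolerated unaligned bases per end.
#' @return an `integrity_verdict` list: `ref_id`, `unaligned_5p`,
#'   `unaligned_3p`, `pct_identity`, `keep`; or a verdict with
#'   `ref_id = NA` and `keep = FALSE` (reason `no_eligible_reference`) when
#'   no reference is long enough.
#' @export
end_integrity_check <- function(query, refdb, max_missing = 5) {
  lq <- nchar(query$rep_seq)
  elig <- which(nchar(refdb$seq) >= lq)
  if (length(elig) == 0) {
    return(structure(list(ref_id = NA_character_, unaligned_5p = NA_integer_,
                          unaligned_3p = NA_integer_,
                          pct_identity = NA_real_, keep = FALSE,
                          reason = "no_eligible_reference"),
                     class = "integrity_verdict"))
  }
  best <- NULL
  for (i in elig[order(refdb$ref_id[elig], method = "radix")]) {
    a <- align_pair(query$rep_seq, refdb$seq[i], ends_free = TRUE)
    pid <- 100 * (1 - (a$n_mismatch + a$n_internal_gap_runs) / a$aligned_cols)
    if (is.null(best) || a$score > best$score ||
        (a$score == best$score && pid > best$pid)) {
      best <- list(score = a$score, pid = pid, aln = a, ref = refdb$ref_id[i])
    }
  }
  ends <- query_end_overhangs(best$aln)
  keep <- ends[1] <= max_missing && ends[2] <= max_missing
  structure(list(ref_id = best$ref, unaligned_5p = ends[1],
                 unaligned_3p = ends[2], pct_identity = best$pid,
                 keep = keep, reason = if (keep) "ok" else "end_missing"),
            class = "integrity_verdict")
}

# count query bases inside terminal gap columns (query base opposite a
# terminal subject gap) at each end of an alignment
query_end_overhangs <- function(aln) {
  qa <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  sa <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  n <- length(qa)
  term <- qa == "-" | sa == "-"
  lead <- if (n && term[1]) which.min(term) - 1L else 0L
  if (all(term)) lead <- n
  trail <- if (n && term[n]) which.min(rev(term)) - 1L else 0L
  c(sum(qa[seq_len(lead)] != "-"),
    sum(qa[seq(n - trail + 1L, length.out = trail)] != "-"))
}

#' Retention check for one- and two-read OTUs
#'
#' OTUs with only one or two assigned reads are kept only with a perfect or
#' near-perfect reference match: the best alignment must span the entire
#' query (no unaligned bases at either end) with at most `max_dissim`
#' dissimilar positions (mismatches plus internal gap runs over aligned
#' columns; 1% default, inclusive).
#'
#' @param query list with `rep_seq` (caller restricts to OTUs with <= 2
#'   reads).
#' @param refdb reference data.frame.
#' @param max_dissim maximum tolerated dissimilarity fraction.
#' @return `"keep"` or `"discard"`.
#' @export
rare_otu_check <- function(query, refdb, max_dissim = 0.01) {
  best <- NULL
  for (i in order(refdb$ref_id, method = "radix")) {
    a <- align_pair(query$rep_seq, refdb$seq[i], ends_free = TRUE)
    d <- (a$n_mismatch + a$n_internal_gap_runs) / a$aligned_cols
    if (is.null(best) || a$score > best$score ||
        (a$score == best$score && d < best$d)) {
      best <- list(score = a$score, d = d, aln = a)
    }
  }
  ends <- query_end_overhangs(best$aln)
  if (ends[1] == 0 && ends[2] == 0 && best$d <= max_dissim + 1e-12) {
    "keep"
  } else {
    "discard"
  }
}

#' Three-stage OTU curation
#'
#' Applies, in order: (1) de novo chimera detection with candidate parents
#' drawn from the OTU set itself, (2) the 5'/3' end-integrity filter
#' against the reference database, (3) the retention rule for OTUs with at
#' most two reads. Each removed OTU is tagged with the first stage that
#' failed it; reads of removed OTUs are dropped, not reassigned.
#'
#' The chimera stage follows the standard abundance-skew algorithm of de
#' novo detectors: OTUs are processed in decreasing total-count order and
#' each query's candidate parents are the OTUs already accepted as
#' non-chimeric whose total count is at least `min_skew` times the
#' query's - a chimera is expected to be rarer than both of its parents,
#' and sequences already flagged as chimeric cannot serve as parents.
#'
#' @param otus an `otu_set` from [greedy_cluster()].
#' @param refdb reference data.frame.
#' @param min_skew,min_diff_gain,min_votes see [detect_chimera()].
#' @param max_missing see [end_integrity_check()].
#' @param max_dissim see [rare_otu_check()].
#' @return list with `otus` (curated `otu_set`, status `"curated"`) and
#'   `report` (per-OTU data.frame: `otu_id`, `total`, `stage`, `verdict`,
#'   plus chimera/integrity fields).
#' @export
curate_otus <- function(otus, refdb, min_skew = 2, min_diff_gain = 4,
                        min_votes = 2, max_missing = 5, max_dissim = 0.01) {
  n <- length(otus$otu_id)
  tot <- otu_totals(otus)
  stage <- rep("kept", n)
  detail <- character(n)
  nonchimeric <- logical(n)
  for (k in order(-tot, otus$otu_id, method = "radix")) {
    cand <- which(nonchimeric & tot >= min_skew * tot[k])
    cand <- setdiff(cand, k)
    cv <- detect_chimera(list(rep_seq = otus$rep_seq[k],
                              otu_id = otus$otu_id[k]),
                         otu_subset(otus, cand), min_skew = min_skew,
                         min_diff_gain = min_diff_gain, min_votes = min_votes)
    if (!isTRUE(cv$is_chimera)) nonchimeric[k] <- TRUE
    if (isTRUE(cv$is_chimera)) {
      stage[k] <- "chimera"
      detail[k] <- sprintf("parents=%s,%s bp=%d gain=%d", cv$parent_a,
                           cv$parent_b, cv$breakpoint,
                           cv$diff_single_best - cv$diff_model_best)
      next
    }
    iv <- end_integrity_check(list(rep_seq = otus$rep_seq[k]), refdb,
                              max_missing = max_missing)
    if (!iv$keep) {
      stage[k] <- "integrity"
      detail[k] <- sprintf("ref=%s un5=%s un3=%s", iv$ref_id,
                           iv$unaligned_5p, iv$unaligned_3p)
      next
    }
    if (tot[k] <= 2) {
      rv <- rare_otu_check(list(rep_seq = otus$rep_seq[k]), refdb,
                           max_dissim = max_dissim)
      if (rv == "discard") {
        stage[k] <- "rare"
        detail[k] <- "no full-span near-perfect reference match"
      }
    }
  }
  keep <- stage == "kept"
  out <- otu_subset(otus, keep)
  out$status <- rep("curated", sum(keep))
  report <- data.frame(otu_id = otus$otu_id, total = tot, stage = stage,
                       verdict = ifelse(keep, "keep", "discard"),
                       detail = detail, stringsAsFactors = FALSE)
  list(otus = out, report = report)
}
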