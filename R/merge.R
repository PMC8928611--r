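#' Merge one read pair into a contig
#'
#' Finds the highest-scoring ungapped overlap (score = matches - mismatches)
#' between the forward read and the reverse complement of the reverse read.
#' Admissible overlaps are at least `min_overlap` long with a mismatch
#' fraction at most `max_overlap_mismatch_frac`; score ties go to the longest
#' overlap. In the overlap, agreeing bases keep the higher Phred score;
#' disagreeing bases take the higher-quality base with quality `|q_f - q_r|`,
#' and equal-quality disagreements become `N` at quality 0.
#'
#' @param fwd,rev reads as lists/one-row data.frames with `seq` and `qual`
#'   (integer vector or Phred+33 string); `rev` is the raw reverse read and
#'   is reverse-complemented internally.
#' @param min_overlap minimum admissible overlap length (nt).
#' @param max_overlap_mismatch_frac maximum mismatch fraction in the overlap.
#' @return a contig list with `id`, `seq`, `qual` (integer), `sample_id`,
#'   `overlap_len`, or `NULL` if no admissible overlap exists.
#' @export
merge_read_pair <- function(fwd, rev, min_overlap = 10,
                            max_overlap_mismatch_frac = 0.10) {
  stopifnot(min_overlap >= 1)
  fq <- if (is.character(fwd$qual)) qual_decode(fwd$qual) else as.integer(fwd$qual)
  rq <- if (is.character(rev$qual)) qual_decode(rev$qual) else as.integer(rev$qual)
  stopifnot(nchar(fwd$seq) == length(fq), nchar(rev$seq) == length(rq))
  res <- cpp_merge_pair(fwd$seq, fq, rev$seq, rq, as.integer(min_overlap),
                        max_overlap_mismatch_frac)
  if (!res$ok) return(NULL)
  list(id = if (!is.null(fwd$id)) fwd$id else NA_character_,
       seq = res$seq, qual = res$qual,
       sample_id = if (!is.null(fwd$sample_id)) fwd$sample_id else NA_character_,
       overlap_len = res$overlap_len)
}

#' Merge paired reads in bulk
#'
#' Vectorised version of [merge_read_pair()] over read data.frames (as from
#' [parse_fastq()]). Pairs are matched by row.
#'
#' @param fwd,rev data.frames with `id`, `seq`, `qual` (Phred+33 string),
#'   `sample_id`.
#' @inheritParams merge_read_pair
#' @return list with `contigs` (data.frame: `id`, `seq`, `qual`, `sample_id`,
#'   `overlap_len`, `mean_q`) and `stats` (per-sample `pairs_in`, `merged`,
#'   `failed`).
#' @export
merge_pairs <- function(fwd, rev, min_overlap = 10,
                        max_overlap_mismatch_frac = 0.10) {
  stopifnot(nrow(fwd) == nrow(rev))
  res <- cpp_merge_batch(fwd$seq, fwd$qual, rev$seq, rev$qual,
                         as.integer(min_overlap), max_overlap_mismatch_frac)
  ok <- res$ok
  contigs <- data.frame(
    id = fwd$id[ok], seq = res$seq[ok], qual = res$qual[ok],
    sample_id = fwd$sample_id[ok], overlap_len = res$overlap_len[ok],
    mean_q = res$mean_q[ok], stringsAsFactors = FALSE)
  sid <- fwd$sample_id
  stats <- data.frame(
    sample_id = sort(unique(sid)),
    pairs_in = as.integer(table(sid)[sort(unique(sid))]),
    merged = as.integer(table(factor(sid[ok], levels = sort(unique(sid))))),
    stringsAsFactors = FALSE)
  stats$failed <- stats$pairs_in - stats$merged
  list(contigs = contigs, stats = stats)
}
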