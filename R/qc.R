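#' Quality-control parameters for contig screening
#'
#' Contigs must carry both intact primer sites (zero-mismatch, end-anchored
#' IUPAC match), fall within the length window measured on the untrimmed
#' contig, and have a mean Phred score of at least `min_mean_q`. Samples
#' with fewer than `min_contigs_per_sample` passing contigs are excluded.
#'
#' @param fwd_primer,rev_primer IUPAC primer patterns (27F / 519R V1-V3
#'   defaults). The reverse primer is matched as its reverse complement at
#'   the 3' end.
#' @param min_len,max_len inclusive contig length window (nt).
#' @param min_mean_q minimum mean Phred score.
#' @param min_contigs_per_sample per-sample sufficiency threshold.
#' @param trim_primers remove both primer regions from passing contigs.
#' @return a `qc_params` list.
#' @export
qc_params <- function(fwd_primer = fwd_primer_default(),
                      rev_primer = rev_primer_default(),
                      min_len = 400, max_len = 580, min_mean_q = 33,
                      min_contigs_per_sample = 1000, trim_primers = TRUE) {
  stopifnot(min_len <= max_len, min_mean_q >= 0)
  structure(list(fwd_primer = fwd_primer, rev_primer = rev_primer,
                 min_len = min_len, max_len = max_len,
                 min_mean_q = min_mean_q,
                 min_contigs_per_sample = min_contigs_per_sample,
                 trim_primers = trim_primers), class = "qc_params")
}

#' Test for an intact, end-anchored primer site
#'
#' A primer is intact when every pattern position is IUPAC-compatible with
#' the corresponding contig base, anchored exactly at the contig end, with
#' zero mismatches. For `end = "3prime"` the pattern is matched as its
#' reverse complement against the 3' terminus.
#'
#' @param seq contig sequence.
#' @param pattern IUPAC primer pattern.
#' @param end `"5prime"` or `"3prime"`.
#' @return logical.
#' @export
match_primer <- function(seq, pattern, end = c("5prime", "3prime")) {
  end <- match.arg(end)
  if (end == "3prime") pattern <- revcomp(pattern)
  np <- nchar(pattern)
  if (np > nchar(seq)) return(FALSE)
  target <- if (end == "5prime") substr(seq, 1L, np) else
    substr(seq, nchar(seq) - np + 1L, nchar(seq))
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  tc <- strsplit(target, "", fixed = TRUE)[[1]]
  all(mapply(function(p, t) t %in% .iupac[[p]], pc, tc))
}

# IUPAC pattern -> anchored regex character classes
iupac_regex <- function(pattern) {
  ch <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(vapply(ch, function(c) {
    opts <- .iupac[[c]]
    if (length(opts) == 1) opts else paste0("[", paste(opts, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Mean Phred score
#' @param qual integer Phred vector or Phred+33 string.
#' @return arithmetic mean.
#' @export
mean_phred <- function(qual) {
  if (is.character(qual)) qual <- qual_decode(qual)
  if (length(qual) == 0) stop("empty quality vector")
  mean(qual)
}

#' Screen a single contig
#'
#' Checks, in order: intact forward primer, intact reverse primer, length
#' window (on the untrimmed contig), mean quality. The first failing check
#' determines the verdict. On pass with `trim_primers`, both primer regions
#' are removed from sequence and quality.
#'
#' @param contig list with `seq` and `qual` (integer vector or Phred+33
#'   string); other fields are passed through.
#' @param p a [qc_params()].
#' @return list with `verdict` (one of `pass`, `fail_primer_fwd`,
#'   `fail_primer_rev`, `fail_length`, `fail_quality`) and, on pass,
#'   `contig` (possibly trimmed).
#' @export
screen_contig <- function(contig, p = qc_params()) {
  if (!match_primer(contig$seq, p$fwd_primer, "5prime")) {
    return(list(verdict = "fail_primer_fwd"))
  }
  if (!match_primer(contig$seq, p$rev_primer, "3prime")) {
    return(list(verdict = "fail_primer_rev"))
  }
  len <- nchar(contig$seq)
  if (len < p$min_len || len > p$max_len) {
    return(list(verdict = "fail_length"))
  }
  if (mean_phred(contig$qual) < p$min_mean_q) {
    return(list(verdict = "fail_quality"))
  }
  out <- contig
  if (p$trim_primers) {
    nf <- nchar(p$fwd_primer)
    nr <- nchar(p$rev_primer)
    out$seq <- substr(contig$seq, nf + 1L, len - nr)
    if (is.character(contig$qual)) {
      out$qual <- substr(contig$qual, nf + 1L, len - nr)
    } else {
      out$qual <- contig$qual[(nf + 1L):(len - nr)]
    }
  }
  list(verdict = "pass", contig = out)
}

#' Screen contigs in bulk
#'
#' Vectorised [screen_contig()] over a contig data.frame (as produced by
#' [merge_pairs()]).
#'
#' @param contigs data.frame with `seq`, `qual` (Phred+33), `sample_id`, and
#'   optionally `mean_q` (computed if absent).
#' @param p a [qc_params()].
#' @return list with `passed` (trimmed contigs data.frame), `verdicts`
#'   (character per input contig), and `tallies` (per-sample verdict
#'   counts with a `pass` column).
#' @export
screen_contigs <- function(contigs, p = qc_params()) {
  n <- nrow(contigs)
  verdict <- rep("pass", n)
  fwd_ok <- grepl(paste0("^", iupac_regex(p$fwd_primer)), contigs$seq)
  rev_ok <- grepl(paste0(iupac_regex(revcomp(p$rev_primer)), "$"), contigs$seq)
  len <- nchar(contigs$seq)
  len_ok <- len >= p$min_len & len <= p$max_len
  mq <- if ("mean_q" %in% names(contigs)) contigs$mean_q else
    vapply(contigs$qual, mean_phred, numeric(1), USE.NAMES = FALSE)
  q_ok <- mq >= p$min_mean_q
  verdict[!q_ok] <- "fail_quality"
  verdict[!len_ok] <- "fail_length"
  verdict[!rev_ok] <- "fail_primer_rev"
  verdict[!fwd_ok] <- "fail_primer_fwd"
  passed <- contigs[verdict == "pass", , drop = FALSE]
  if (p$trim_primers && nrow(passed)) {
    nf <- nchar(p$fwd_primer)
    nr <- nchar(p$rev_primer)
    pl <- nchar(passed$seq)
    passed$seq <- substr(passed$seq, nf + 1L, pl - nr)
    passed$qual <- substr(passed$qual, nf + 1L, pl - nr)
  }
  lv <- c("pass", "fail_primer_fwd", "fail_primer_rev", "fail_length",
          "fail_quality")
  tal <- as.data.frame.matrix(table(contigs$sample_id,
                                    factor(verdict, levels = lv)))
  tal <- cbind(sample_id = rownames(tal), tal, stringsAsFactors = FALSE)
  rownames(tal) <- NULL
  list(passed = passed, verdicts = verdict, tallies = tal)
}

#' Apply the per-sample sufficiency screen
#'
#' Samples whose passing-contig count falls below
#' `p$min_contigs_per_sample` are excluded (threshold inclusive: exactly the
#' threshold passes).
#'
#' @param tallies per-sample tallies from [screen_contigs()] (needs
#'   `sample_id` and `pass` columns).
#' @param p a [qc_params()].
#' @return list with `included` and `excluded` sample id vectors.
#' @export
screen_sample <- function(tallies, p = qc_params()) {
  drop <- tallies$pass < p$min_contigs_per_sample
  list(included = tallies$sample_id[!drop],
       excluded = tallies$sample_id[drop])
}
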