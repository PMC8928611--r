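#' Parse FASTQ records from text lines
#'
#' Strict 4-line-per-record FASTQ with Phred+33 quality encoding. Quality is
#' kept as the raw Phred+33 string; decode with [qual_decode()].
#'
#' @param lines character vector of FASTQ lines.
#' @param sample_id sample identifier attached to every read.
#' @return data.frame with columns `id`, `seq`, `qual` (Phred+33 string) and
#'   `sample_id`, one row per record, in input order.
#' @export
parse_fastq <- function(lines, sample_id = NA_character_) {
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0L) {
    return(data.frame(id = character(), seq = character(),
                      qual = character(), sample_id = character(),
                      stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("truncated FASTQ: record %d is incomplete",
                 length(lines) %/% 4L + 1L))
  }
  n <- length(lines) %/% 4L
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  ql <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hd, "@"))
  if (length(bad)) stop(sprintf("malformed FASTQ header at record %d", bad[1]))
  bad <- which(!startsWith(pl, "+"))
  if (length(bad)) stop(sprintf("malformed FASTQ separator at record %d", bad[1]))
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad)) {
    stop(sprintf("sequence/quality length mismatch at record %d", bad[1]))
  }
  bad <- which(nchar(sq) == 0L)
  if (length(bad)) stop(sprintf("empty sequence at record %d", bad[1]))
  qmin <- vapply(ql, function(s) min(utf8ToInt(s)), integer(1), USE.NAMES = FALSE)
  if (any(qmin < 33L)) {
    stop(sprintf("quality character below Phred+33 range at record %d",
                 which(qmin < 33L)[1]))
  }
  data.frame(id = sub("^@", "", hd), seq = sq, qual = ql,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

#' Read a FASTQ file
#' @param path file path.
#' @inheritParams parse_fastq
#' @return as [parse_fastq()].
#' @export
read_fastq <- function(path, sample_id = NA_character_) {
  parse_fastq(readLines(path), sample_id = sample_id)
}

#' Write reads to a FASTQ file
#' @param reads data.frame with `id`, `seq`, `qual` (Phred+33).
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual)),
             con)
  invisible(path)
}

#' Write sequences to a FASTA file
#' @param seqs named character vector (names become headers), or a data.frame
#'   with `id` and `seq` columns.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), con)
  invisible(path)
}

#' Read a FASTA file
#'
#' Uses Biostrings when available (the usual case); falls back to a plain
#' reader for headerless environments.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    return(setNames(as.character(x), names(x)))
  }
  lines <- readLines(path)
  hd <- grepl("^>", lines)
  idx <- cumsum(hd)
  seqs <- vapply(split(lines[!hd], idx[!hd]), paste, character(1), collapse = "")
  setNames(toupper(unname(seqs)), sub("^>", "", lines[hd]))
}

#' Read a reference database FASTA with tab-delimited lineage headers
#'
#' Headers have the form
#' `ref_id<TAB>p__Phylum;c__Class;o__Order;f__Family;g__Genus`.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `ref_id`, `seq`, `phylum`, `class`,
#'   `order`, `family`, `genus`.
#' @export
read_reference_fasta <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "\t", fixed = TRUE)
  ref_id <- vapply(parts, `[`, character(1), 1L)
  lineage <- vapply(parts, function(p) if (length(p) > 1) p[2] else "", character(1))
  ranks <- strsplit(lineage, ";", fixed = TRUE)
  get_rank <- function(prefix) {
    vapply(ranks, function(r) {
      hit <- r[startsWith(r, prefix)]
      if (length(hit)) sub(prefix, "", hit[1], fixed = TRUE) else NA_character_
    }, character(1))
  }
  data.frame(ref_id = ref_id, seq = unname(seqs),
             phylum = get_rank("p__"), class = get_rank("c__"),
             order = get_rank("o__"), family = get_rank("f__"),
             genus = get_rank("g__"), stringsAsFactors = FALSE)
}

#' Write a reference database with lineage headers
#' @param refdb data.frame as produced by [generate_reference_db()].
#' @param path output FASTA path.
#' @return invisibly, the path.
#' @export
write_reference_fasta <- function(refdb, path) {
  hdr <- sprintf("%s\tp__%s;c__%s;o__%s;f__%s;g__%s", refdb$ref_id,
                 refdb$phylum, refdb$class, refdb$order, refdb$family,
                 refdb$genus)
  write_fasta(setNames(refdb$seq, hdr), path)
}

#' Write a table as TSV
#' @param x data.frame.
#' @param path output path.
#' @param comment optional header comment lines (written with a leading `#`).
#' @return invisibly, the path.
#' @export
write_tsv <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
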