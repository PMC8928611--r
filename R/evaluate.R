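#' Score a synthetic pipeline run against its ground truth
#'
#' Labels every raw OTU by the provenance of its representative's reads and
#' summarises what the curation stages did to chimera-derived, artifact and
#' clean OTUs, plus read-level survival of truncation artifacts.
#'
#' @param result output of [run_synthetic_pipeline()] (needs `otus_raw`,
#'   `curation_report`, `passed`, `truth`).
#' @return list with per-class OTU counts and removal fractions
#'   (`chimera_otus`, `chimera_removed_frac`, `clean_otus`,
#'   `clean_lost_frac`, `artifact_otus`, `artifact_removed_frac`,
#'   `artifact_reads_emitted`, `artifact_reads_final`) and the per-OTU
#'   label vector.
#' @export
evaluate_curation <- function(result) {
  otus <- result$otus_raw
  report <- result$curation_report
  passed <- result$passed
  prov <- result$truth$provenance
  label <- otu_provenance(otus, passed, prov)
  removed <- report$verdict[match(otus$otu_id, report$otu_id)] == "discard"
  uniq_idx <- match(passed$seq, otus$uniq_seq)
  otu_of <- integer(length(otus$uniq_seq))
  for (k in seq_along(otus$members)) otu_of[otus$members[[k]]] <- k
  read_otu <- otu_of[uniq_idx]
  read_kept <- !removed[read_otu]
  read_type <- prov$type[match(passed$id, prov$read_id)]
  n_art_emitted <- sum(prov$type == "artifact")
  n_art_final <- sum(read_type == "artifact" & read_kept, na.rm = TRUE)
  frac <- function(x) if (length(x)) mean(x) else NA_real_
  list(
    label = setNames(label, otus$otu_id),
    chimera_otus = sum(label == "chimera"),
    chimera_removed_frac = frac(removed[label == "chimera"]),
    clean_otus = sum(label == "clean"),
    clean_lost_frac = frac(removed[label == "clean"]),
    artifact_otus = sum(label == "artifact"),
    artifact_removed_frac = if (any(label == "artifact"))
      frac(removed[label == "artifact"]) else 1,
    artifact_reads_emitted = n_art_emitted,
    artifact_reads_final = n_art_final)
}
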