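#' Pipeline configuration
#'
#' Bundles the per-stage parameters of the full workflow (merge -> QC ->
#' cluster -> curate -> classify -> stats) with a single master seed from
#' which stage seeds are derived deterministically.
#'
#' @param seed master seed.
#' @param min_overlap,max_overlap_mismatch_frac merge parameters.
#' @param qc a [qc_params()].
#' @param cutoff OTU clustering dissimilarity cutoff.
#' @param min_skew,min_diff_gain,min_votes,max_missing,max_dissim curation
#'   parameters (see [curate_otus()]).
#' @param n_boot,tax_threshold taxonomy parameters.
#' @param alpha significance level for the testing layer.
#' @param abundance_cutoff percent cutoff for abundant-feature selection.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, min_overlap = 10,
                            max_overlap_mismatch_frac = 0.10,
                            qc = qc_params(), cutoff = 0.04, min_skew = 2,
                            min_diff_gain = 4, min_votes = 2,
                            max_missing = 5, max_dissim = 0.01,
                            n_boot = 100, tax_threshold = 0.80,
                            alpha = 0.05, abundance_cutoff = 1.0) {
  stopifnot(cutoff > 0, cutoff < 0.5, alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full amplicon workflow on paired reads
#'
#' Executes merge -> primer/length/quality QC -> sample sufficiency ->
#' dereplication -> greedy OTU clustering -> three-stage curation ->
#' taxonomy -> community statistics, and assembles a manifest with
#' per-stage counts and a per-sample read-conservation ledger
#' (`reads_in = merge_failed + qc_failed + sample_excluded +
#' curation_dropped + reads_final`).
#'
#' @param reads paired reads data.frame (`sample_id`, `read_id`, `fwd_seq`,
#'   `fwd_qual`, `rev_seq`, `rev_qual`), e.g. from [simulate_samples()].
#' @param refdb reference data.frame (lineage-annotated).
#' @param design data.frame with `sample_id`, `group`.
#' @param cfg a [pipeline_config()].
#' @param classify run the taxonomy stage (skippable for speed when only
#'   curation output is needed).
#' @return list with `merge_stats`, `qc` (tallies + excluded samples),
#'   `otus_raw`, `otus` (curated), `curation_report`, `taxonomy`,
#'   `counts` (samples x OTUs), `stats` (alpha table, Bray-Curtis matrix,
#'   PCoA, per-OTU tests), `manifest`.
#' @export
run_pipeline <- function(reads, refdb, design, cfg = pipeline_config(),
                         classify = TRUE) {
  t0 <- Sys.time()
  fwd <- data.frame(id = reads$read_id, seq = reads$fwd_seq,
                    qual = reads$fwd_qual, sample_id = reads$sample_id,
                    stringsAsFactors = FALSE)
  rev <- data.frame(id = reads$read_id, seq = reads$rev_seq,
                    qual = reads$rev_qual, sample_id = reads$sample_id,
                    stringsAsFactors = FALSE)
  mg <- merge_pairs(fwd, rev, cfg$min_overlap, cfg$max_overlap_mismatch_frac)
  sc <- screen_contigs(mg$contigs, cfg$qc)
  ss <- screen_sample(sc$tallies, cfg$qc)
  passed <- sc$passed[sc$passed$sample_id %in% ss$included, , drop = FALSE]
  if (nrow(passed) == 0) stop("no contigs passed QC in any included sample")
  der <- dereplicate(passed$seq, passed$sample_id)
  otus_raw <- greedy_cluster(der$seq, der$counts, cutoff = cfg$cutoff)
  cur <- curate_otus(otus_raw, refdb, min_skew = cfg$min_skew,
                     min_diff_gain = cfg$min_diff_gain,
                     min_votes = cfg$min_votes,
                     max_missing = cfg$max_missing,
                     max_dissim = cfg$max_dissim)
  otus <- cur$otus
  counts <- t(otus$counts)                       # samples x OTUs
  colnames(counts) <- otus$otu_id
  tax <- NULL
  if (classify && length(otus$otu_id)) {
    model <- train_classifier(refdb)
    tax <- classify_otus(otus, model, refdb, n_boot = cfg$n_boot,
                         threshold = cfg$tax_threshold, seed = cfg$seed)
  }
  stats_out <- NULL
  design_used <- design[design$sample_id %in% rownames(counts), , drop = FALSE]
  if (nrow(counts) >= 2 && ncol(counts) >= 1 && all(rowSums(counts) > 0)) {
    pct <- relative_abundance(counts)
    gm <- group_means(pct, design_used)
    abundant <- select_abundant_otus(gm, cfg$abundance_cutoff)
    tests <- if (length(abundant) && length(unique(design_used$group)) >= 2) {
      test_features(pct[, abundant, drop = FALSE], design_used,
                    alpha = cfg$alpha)
    } else NULL
    bc <- bray_curtis_matrix(pct)
    stats_out <- list(pct = pct, group_means = gm, abundant = abundant,
                      alpha = alpha_table(counts), bray_curtis = bc,
                      pcoa = pcoa_ord(bc), tests = tests)
  }
  # read-conservation ledger
  samples <- sort(unique(reads$sample_id))
  tal <- sc$tallies[match(samples, sc$tallies$sample_id), , drop = FALSE]
  merged <- mg$stats$merged[match(samples, mg$stats$sample_id)]
  pairs_in <- mg$stats$pairs_in[match(samples, mg$stats$sample_id)]
  qc_failed <- merged - ifelse(is.na(tal$pass), 0L, tal$pass)
  excluded <- !(samples %in% ss$included)
  final_counts <- integer(length(samples))
  present <- match(samples, rownames(counts))
  final_counts[!is.na(present)] <- as.integer(rowSums(counts))[present[!is.na(present)]]
  sample_excluded <- ifelse(excluded, ifelse(is.na(tal$pass), 0L, tal$pass), 0L)
  kept_pass <- ifelse(excluded, 0L, ifelse(is.na(tal$pass), 0L, tal$pass))
  ledger <- data.frame(
    sample_id = samples, reads_in = pairs_in, merge_failed = pairs_in - merged,
    qc_failed = qc_failed, sample_excluded = sample_excluded,
    curation_dropped = kept_pass - final_counts, reads_final = final_counts,
    stringsAsFactors = FALSE)
  conserved <- with(ledger, all(reads_in == merge_failed + qc_failed +
                                  sample_excluded + curation_dropped +
                                  reads_final))
  if (!conserved) stop("read-conservation ledger does not balance")
  manifest <- list(
    package_version = as.character(utils::packageVersion("ampliclean")),
    seed = cfg$seed, config_hash = config_hash(cfg),
    n_reads_in = nrow(reads), n_merged = sum(merged),
    n_qc_passed = sum(tal$pass, na.rm = TRUE),
    samples_excluded = ss$excluded,
    n_otus_raw = length(otus_raw$otu_id), n_otus_curated = length(otus$otu_id),
    curation_stage_counts = table(cur$report$stage),
    ledger = ledger, runtime_s = as.numeric(difftime(Sys.time(), t0, "secs")))
  list(merge_stats = mg$stats, qc = list(tallies = sc$tallies,
                                         excluded = ss$excluded),
       passed = passed, otus_raw = otus_raw, otus = otus,
       curation_report = cur$report, taxonomy = tax, counts = counts,
       stats = stats_out, manifest = manifest)
}

# order-invariant cheap hash of the configuration for the manifest
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

#' Simulate a community and run the full workflow
#'
#' Convenience wrapper: generates a reference database, simulates reads
#' under `sim_cfg`, and runs [run_pipeline()]. Ground truth is carried
#' through for validation.
#'
#' @param sim_cfg a [sim_config()].
#' @param pipe_cfg a [pipeline_config()].
#' @param refs optional pre-built reference database.
#' @param classify see [run_pipeline()].
#' @return the [run_pipeline()] result plus `truth`, `design`, `refs`.
#' @export
run_synthetic_pipeline <- function(sim_cfg = sim_config(),
                                   pipe_cfg = pipeline_config(seed = sim_cfg$seed),
                                   refs = NULL, classify = TRUE) {
  if (is.null(refs)) {
    refs <- generate_reference_db(sim_cfg$seed, sim_cfg$n_taxa)
  }
  sim <- simulate_samples(sim_cfg, refs)
  out <- run_pipeline(sim$reads, refs, sim$design, pipe_cfg,
                      classify = classify)
  out$truth <- sim$truth
  out$design <- sim$design
  out$refs <- refs
  out
}

#' Trace curated OTUs back to simulation ground truth
#'
#' Labels each raw OTU by the provenance of its reads: `clean` if the
#' representative's reads are regular, `chimera` / `artifact` / `offlen`
#' otherwise (majority type of the representative unique sequence's reads).
#'
#' @param otus raw `otu_set` (with `uniq_seq` and `members`).
#' @param passed_reads data.frame of QC-passing contigs (`id`, `seq`).
#' @param provenance truth provenance data.frame from [simulate_samples()].
#' @return character vector: provenance label per OTU.
#' @export
otu_provenance <- function(otus, passed_reads, provenance) {
  type_of <- provenance$type[match(passed_reads$id, provenance$read_id)]
  # majority read type of the representative unique sequence
  f <- factor(passed_reads$seq, levels = otus$uniq_seq)
  seq_type <- vapply(split(as.character(type_of), f),
                     function(tt) {
                       if (!length(tt)) return(NA_character_)
                       names(sort(table(tt), decreasing = TRUE))[1]
                     }, character(1))
  lab <- unname(seq_type[match(otus$rep_seq, otus$uniq_seq)])
  lab[is.na(lab)] <- "unknown"
  ifelse(lab == "regular", "clean", lab)
}
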