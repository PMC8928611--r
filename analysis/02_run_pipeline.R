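#!/usr/bin/env Rscript
# Step 2: run the full curation pipeline on the simulated cohort from step
# 01 - merge pairs, screen contigs (primers, 400-580 nt, mean Q33), cluster
# at 4% dissimilarity, curate (chimera / end-integrity / rare-OTU screens),
# classify - then compare the curated OTU set against the simulation truth.

suppressPackageStartupMessages(library(ampliclean))

sim_dir <- "results/sim"
out <- "results/pipeline"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
if (!file.exists(file.path(sim_dir, "design.tsv"))) {
  stop("run analysis/01_simulate_community.R first")
}

refs <- read_reference_fasta(file.path(sim_dir, "reference_db.fasta"))
design <- read.delim(file.path(sim_dir, "design.tsv"))
reads <- do.call(rbind, lapply(design$sample_id, function(s) {
  r1 <- read_fastq(file.path(sim_dir, sprintf("%s_R1.fastq", s)), s)
  r2 <- read_fastq(file.path(sim_dir, sprintf("%s_R2.fastq", s)), s)
  data.frame(sample_id = s, read_id = r1$id, fwd_seq = r1$seq,
             fwd_qual = r1$qual, rev_seq = r2$seq, rev_qual = r2$qual,
             stringsAsFactors = FALSE)
}))

cfg <- pipeline_config(seed = 7, qc = qc_params(min_contigs_per_sample = 300))
res <- run_pipeline(reads, refs, design, cfg, classify = TRUE)

write_tsv(res$merge_stats, file.path(out, "merge_stats.tsv"))
write_tsv(res$qc$tallies, file.path(out, "qc_tallies.tsv"))
write_tsv(res$curation_report, file.path(out, "curation_report.tsv"))
write_tsv(res$taxonomy, file.path(out, "taxonomy.tsv"))
write_tsv(cbind(sample_id = rownames(res$counts), as.data.frame(res$counts)),
          file.path(out, "otu_counts.tsv"),
          comment = "curated samples x OTUs read counts")
write_fasta(setNames(res$otus$rep_seq, res$otus$otu_id),
            file.path(out, "otu_representatives.fasta"))
write_tsv(res$manifest$ledger, file.path(out, "read_ledger.tsv"))

cat(sprintf("merged %d/%d pairs; %d contigs passed QC\n",
            res$manifest$n_merged, res$manifest$n_reads_in,
            res$manifest$n_qc_passed))
cat(sprintf("OTUs: %d raw -> %d curated (stages: %s)\n",
            res$manifest$n_otus_raw, res$manifest$n_otus_curated,
            paste(names(res$manifest$curation_stage_counts),
                  res$manifest$curation_stage_counts,
                  sep = "=", collapse = ", ")))

prov <- read.delim(file.path(sim_dir, "truth_provenance.tsv"))
ev <- evaluate_curation(c(res, list(truth = list(provenance = prov))))
cat(sprintf("vs truth: %d/%d chimera-derived OTUs removed, %d/%d clean kept, %d artifact reads in final table\n",
            round(ev$chimera_removed_frac * ev$chimera_otus), ev$chimera_otus,
            round((1 - ev$clean_lost_frac) * ev$clean_otus), ev$clean_otus,
            ev$artifact_reads_final))
if (ev$clean_lost_frac > 0) {
  cat("note: clean-OTU false flags concentrate in small cohorts, where OTU\n",
      "totals spread beyond the 2x abundance-skew envelope the chimera\n",
      "detector assumes; see the methods vignette. The acceptance checks\n",
      "run the full 48-sample design.\n", sep = "")
}
cat(sprintf("tables written under %s/\n", out))
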