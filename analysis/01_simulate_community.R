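#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs - a genus-resolved reference
# database and paired-end V1-V3 amplicon reads for a demonstration cohort
# (six diet-by-phase groups, four samples each, 2,500 read pairs per sample;
# the full study design of 8 samples/group x 10,000 pairs is what the
# acceptance checks run). Writes FASTA/FASTQ/TSV inputs under results/sim/.

suppressPackageStartupMessages(library(ampliclean))

seed <- 7
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

refs <- generate_reference_db(seed, n_taxa = 20, min_pairwise_dist = 0.08)
write_reference_fasta(refs, file.path(out, "reference_db.fasta"))
cat(sprintf("reference database: %d taxa, amplicons %d-%d nt\n",
            nrow(refs), min(nchar(refs$seq)), max(nchar(refs$seq))))

cfg <- sim_config(seed = seed, samples_per_group = 4, reads_per_sample = 2500)
sim <- simulate_samples(cfg, refs)
write_tsv(sim$design, file.path(out, "design.tsv"))
write_tsv(sim$truth$provenance, file.path(out, "truth_provenance.tsv"))
write_tsv(as.data.frame(sim$truth$abundance),
          file.path(out, "truth_abundance.tsv"),
          comment = "true relative abundances (taxa x samples)")
for (s in unique(sim$reads$sample_id)) {
  rr <- sim$reads[sim$reads$sample_id == s, ]
  write_fastq(data.frame(id = rr$read_id, seq = rr$fwd_seq,
                         qual = rr$fwd_qual),
              file.path(out, sprintf("%s_R1.fastq", s)))
  write_fastq(data.frame(id = rr$read_id, seq = rr$rev_seq,
                         qual = rr$rev_qual),
              file.path(out, sprintf("%s_R2.fastq", s)))
}
tab <- table(sim$truth$provenance$type)
cat(sprintf("simulated %d read pairs across %d samples\n",
            nrow(sim$reads), nrow(sim$design)))
cat(sprintf("read classes: %s\n",
            paste(names(tab), tab, sep = "=", collapse = ", ")))
cat(sprintf("wrote per-sample FASTQ, reference FASTA, design and truth under %s/\n",
            out))
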