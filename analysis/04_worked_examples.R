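#!/usr/bin/env Rscript
# Step 4: worked examples computed from the bundled published trial tables
# (mean relative abundances of taxa and abundant OTUs across three diets x
# two phases): the dominant Streptococcus OTU's treatment:control fold
# ratio, and dominant-OTU shares of their family/phylum per group.

suppressPackageStartupMessages(library(ampliclean))
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

wf <- worked_fold_ratio("Ssd-00039", "PmPIII", "ConIII")
cat(sprintf("Ssd-00039 Phase III, PepM_Pro vs Control: %.3f -> %.1f-fold\n",
            wf$ratio, wf$rounded))

ws <- worked_taxon_fraction("Ssd-00039", "Streptococcaceae",
                            c("ConIII", "PmIII", "PmPIII"))
cat(sprintf("Ssd-00039 share of Streptococcaceae (Phase III): %s => range %.1f-%.1f%%\n",
            paste(sprintf("%s %.1f%%", names(ws$fractions), ws$fractions),
                  collapse = ", "), ws$min, ws$max))

wa <- worked_taxon_fraction("Ssd-00840", "Actinobacteria",
                            c("ConII", "PmII", "PmPII"))
cat(sprintf("Ssd-00840 share of Actinobacteria (Phase II): %s => range %.1f-%.1f%%\n",
            paste(sprintf("%s %.1f%%", names(wa$fractions), wa$fractions),
                  collapse = ", "), wa$min, wa$max))

write_tsv(data.frame(
  quantity = c("fold_ratio_Ssd00039_PmPIII_vs_ConIII",
               "strep_fraction_min", "strep_fraction_max",
               "actino_fraction_min", "actino_fraction_max"),
  value = c(wf$rounded, ws$min, ws$max, wa$min, wa$max)),
  file.path(out, "worked_examples.tsv"))
cat("wrote results/worked_examples.tsv\n")
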