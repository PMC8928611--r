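#!/usr/bin/env Rscript
# Step 3: community statistics on the curated OTU table - relative
# abundances, abundant-OTU selection (>= 1% in at least one group), alpha
# diversity per sample with ANOVA + Tukey across groups, Bray-Curtis PCoA,
# and the per-OTU Kruskal-Wallis / pairwise-Wilcoxon-BH testing layer with
# compact letter displays.

suppressPackageStartupMessages(library(ampliclean))

pipe_dir <- "results/pipeline"
out <- "results/stats"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
counts_df <- read.delim(file.path(pipe_dir, "otu_counts.tsv"), comment.char = "#")
design <- read.delim("results/sim/design.tsv")
counts <- as.matrix(counts_df[, -1])
rownames(counts) <- counts_df$sample_id

pct <- relative_abundance(counts)
gm <- group_means(pct, design)
abundant <- select_abundant_otus(gm)
cat(sprintf("%d of %d OTUs have a mean abundance >= 1%% in some group\n",
            length(abundant), ncol(pct)))
write_tsv(cbind(group = rownames(gm), as.data.frame(round(gm, 2))),
          file.path(out, "group_mean_abundance.tsv"),
          comment = "mean relative abundance per group, percent")

alpha <- alpha_table(counts)
write_tsv(alpha, file.path(out, "alpha_diversity.tsv"),
          comment = c("sobs/chao1(bias-corrected)/ACE(cutoff 10)/Shannon(ln)",
                      "Simpson dominance sum n(n-1)/(N(N-1)); Good's 1-n1/N"))
g <- design$group[match(alpha$sample_id, design$sample_id)]
at <- anova_tukey(alpha$shannon, g)
cat(sprintf("Shannon ANOVA across groups: F = %.2f, p = %.3f\n", at$F, at$p))

bc <- bray_curtis_matrix(pct)
write_tsv(cbind(sample_id = rownames(bc), as.data.frame(round(bc, 4))),
          file.path(out, "bray_curtis.tsv"))
pc <- pcoa_ord(bc)
coords <- as.data.frame(round(pc$coords[, 1:min(3, ncol(pc$coords)), drop = FALSE], 4))
write_tsv(cbind(sample_id = rownames(bc), coords,
                group = design$group[match(rownames(bc), design$sample_id)]),
          file.path(out, "pcoa_coordinates.tsv"))
cat(sprintf("PCoA: axes 1-2 explain %.1f%% + %.1f%% of positive inertia\n",
            100 * pc$prop_explained[1], 100 * pc$prop_explained[2]))

tf <- test_features(pct[, abundant, drop = FALSE], design)
sig <- tf$tests$feature[tf$tests$kw_p <= 0.05]
cat(sprintf("Kruskal-Wallis flags %d/%d abundant OTUs at P <= 0.05: %s\n",
            length(sig), length(abundant), paste(sig, collapse = ", ")))
letters_df <- cbind(feature = rownames(tf$letters),
                    as.data.frame(tf$letters))
tab5 <- cbind(feature = tf$tests$feature,
              as.data.frame(round(t(gm[, tf$tests$feature, drop = FALSE]), 2)),
              kw_p = signif(tf$tests$kw_p, 3))
write_tsv(tab5, file.path(out, "abundant_otu_tests.tsv"),
          comment = "mean % per group with Kruskal-Wallis p per OTU")
write_tsv(letters_df, file.path(out, "abundant_otu_letters.tsv"),
          comment = "compact letter display from pairwise Wilcoxon-BH at P<=0.05")
write_tsv(tf$pairwise, file.path(out, "pairwise_wilcoxon_bh.tsv"))
cat(sprintf("tables written under %s/\n", out))
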