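Package: ampliclean
Title: Curation and Community Analysis of 16S rRNA V1-V3 Amplicon Surveys
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a classical 16S rRNA V1-V3
    amplicon workflow for gut microbiome surveys: paired-end read merging,
    primer/length/quality screening, greedy OTU clustering at a 4 percent
    dissimilarity cutoff, de novo two-parent chimera detection, alignment
    based 5'/3' end-integrity filtering, a retention rule for one- and
    two-read OTUs, naive-Bayes bootstrap taxonomy with nearest-reference
    identity, and the downstream community statistics (alpha diversity,
    Bray-Curtis PCoA, Kruskal-Wallis and pairwise Wilcoxon tests with
    Benjamini-Hochberg correction). Includes a synthetic amplicon community
    generator with ground truth (chimeras, truncation artifacts, group by
    phase abundance effects) used to validate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
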