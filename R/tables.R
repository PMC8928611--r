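#' Bundled swine-trial mean relative-abundance tables
#'
#' Mean relative abundances (percent) of the main taxonomic groups and of
#' the most abundant OTUs from a nursery-pig feeding trial of a peptide +
#' mannose-oligosaccharide supplement, across six groups: three dietary
#' treatments (Con, Pm = peptide + MOS, PmP = peptide + MOS + protease) at
#' two feeding phases (II and III). These printed group means serve as
#' inputs to the worked examples (fold ratios and within-family OTU
#' fractions); `<0.01` entries in the source are stored as 0.005.
#'
#' @param which `"family"` (taxonomic groups) or `"otu"` (abundant OTUs
#'   with closest-taxon identity).
#' @return data.frame; abundance columns are `ConII`, `ConIII`, `PmII`,
#'   `PmIII`, `PmPII`, `PmPIII`.
#' @export
swine_trial_means <- function(which = c("family", "otu")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   sprintf("swine_trial_%s_means.tsv", which),
                   package = "ampliclean", mustWork = TRUE)
  read.delim(f, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Worked example: OTU fold ratio between groups
#'
#' Ratio of one OTU's printed mean abundance between two groups, reported
#' at one decimal (e.g. the dominant *Streptococcus alactolyticus*-like OTU
#' in Phase III, protease group over control).
#'
#' @param otu_id OTU row of the bundled table.
#' @param num_group,den_group abundance columns.
#' @return list with `ratio` (full precision) and `rounded` (1 decimal).
#' @export
worked_fold_ratio <- function(otu_id = "Ssd-00039", num_group = "PmPIII",
                              den_group = "ConIII") {
  tab <- swine_trial_means("otu")
  row <- tab[tab$otu_id == otu_id, , drop = FALSE]
  stopifnot(nrow(row) == 1)
  r <- row[[num_group]] / row[[den_group]]
  list(ratio = r, rounded = round(r, 1))
}

#' Worked example: an OTU's share of its family/phylum, per group
#'
#' For each requested group, `100 * OTU mean / taxon mean` from the bundled
#' tables: the fraction of a family's (or phylum's) reads contributed by
#' its dominant OTU. Returns the per-group fractions and their range,
#' rounded to one decimal as reported.
#'
#' @param otu_id OTU row of the bundled OTU table.
#' @param taxon row of the bundled family table.
#' @param groups abundance columns to evaluate.
#' @return list with `fractions` (named, full precision), `min`, `max`
#'   (1 decimal).
#' @export
worked_taxon_fraction <- function(otu_id, taxon, groups) {
  otu <- swine_trial_means("otu")
  fam <- swine_trial_means("family")
  orow <- otu[otu$otu_id == otu_id, , drop = FALSE]
  frow <- fam[fam$taxon == taxon, , drop = FALSE]
  stopifnot(nrow(orow) == 1, nrow(frow) == 1)
  fr <- vapply(groups, function(g) 100 * orow[[g]] / frow[[g]], numeric(1))
  list(fractions = fr, min = round(min(fr), 1), max = round(max(fr), 1))
}
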