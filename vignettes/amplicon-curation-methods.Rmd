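---
title: "Methods: 16S V1-V3 amplicon curation and community analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 16S V1-V3 amplicon curation and community analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ampliclean` re-implements, as tested and reusable code, a classical 16S
rRNA V1-V3 amplicon workflow of the kind used in livestock gut-microbiome
surveys: paired-end reads are merged into contigs, screened for intact
27F/519R primer sites, length (400-580 nt) and mean quality (Q33),
clustered into OTUs at a 4% dissimilarity cutoff, curated through three
screens (de novo chimera detection, alignment-based 5'/3' end integrity, a
strict retention rule for one- and two-read OTUs), classified with a
naive-Bayes bootstrap classifier plus nearest-reference identity, and
summarised through relative abundances, alpha diversity, Bray-Curtis PCoA
and a nonparametric testing layer. This vignette records the models,
parameter choices and their rationale, what the synthetic-data generator
does and does not emulate, and known limitations.

## Read merging

Pairs are merged over the highest-scoring ungapped overlap (score =
matches − mismatches) between the forward read and the reverse complement
of the reverse read; admissible overlaps are ≥ 10 nt with ≤ 10% mismatches,
and ties go to the longest overlap. In the overlap, agreement keeps the
higher Phred score; disagreement takes the higher-quality base with quality
`|q_f − q_r|`, and equal-quality disagreement yields `N` at quality 0. The
ungapped search is deterministic and sufficient for substitution-dominated
data; indel sequencing errors inside the overlap are not modelled (they are
rare on the simulated platform profile and merging is not the scientific
focus). The 10 nt / 10% defaults are conventional for 2×300 nt chemistry
over a 490-560 nt amplicon, where true overlaps are 40-110 nt.

## Quality screens

A contig passes when (in this order, the first failure being reported):
the forward primer matches the 5' terminus exactly under IUPAC codes, the
reverse primer's reverse complement matches the 3' terminus exactly, the
untrimmed length lies in [400, 580] nt inclusive, and the mean Phred score
is ≥ 33. "Intact" is read as zero-mismatch and end-anchored: a primer site
damaged by even one substitution fails, which is the strictest and only
deterministic reading. The length window is applied to the contig with
primers because the screening list names primers and length before any
trimming; both the window and the per-sample sufficiency threshold
(default 1000 passing contigs; samples below it are excluded) are
configurable and recorded in the run manifest. Primers are trimmed after
screening so that distances, taxonomy and identity are computed on
biological sequence only - conserved primer bases would deflate distances
at a 4% cutoff by roughly a tenth.

## Pairwise alignment and the clustering distance

Distances divide the differences of an optimal pairwise alignment -
mismatches plus internal gap *runs*, each run counting once - by the
aligned columns, with terminal gap columns excluded. Scoring is match +1,
mismatch −1, and affine gaps costing `2 + L` for a run of length L.

Two end conventions are used deliberately. The clustering distance and the
chimera projection use a *global* alignment with terminal gaps charged in
the score: with free ends, the optimal "alignment" of two dissimilar
sequences is an empty or tiny dovetail (random 460-mers share 5-8 nt exact
suffix-prefix matches), which would make unrelated sequences look nearly
identical. The reference-comparison steps (end integrity, rare-OTU
retention, nearest reference) instead use ends-local alignment in the
manner of database-search tools: the optimal-scoring segment is reported
and unaligned sequence ends surface as overhangs - the behaviour those
screens are defined against. Traceback tie-breaking is deterministic
(mismatch over gap, gap in query over gap in subject; corner-most
endpoint).

## OTU clustering

Greedy abundance-sorted centroid clustering: unique sequences (after exact
dereplication) are processed in decreasing total-count order, ties broken
lexicographically; each sequence joins the first existing OTU whose
representative is within the cutoff, else founds a new OTU. The 4% cutoff
is the default because V1-V3 is more variable than the regions for which
the conventional 3% was calibrated. The representative is the founder,
which by construction is the most abundant member.

An 8-mer prescreen skips representatives that cannot be within the cutoff:
a sequence within 4% by substitutions alone retains at least
`V − 8·floor(0.04·max(len))` of its distinct 8-mers, so candidates sharing
fewer are skipped; equal-length pairs already within the cutoff by Hamming
distance join without the dynamic program. The bound is provable for
substitution-only divergence but not for arbitrarily long internal gap runs
(one run counts as a single difference yet can destroy many 8-mers), so the
prescreen is an option (default on; the pipeline's within-cutoff pairs are
substitution-dominated) and the oracle-equivalence tests run with it both
on and off.

## Curation

Three screens run in order - chimera, end integrity, rare-OTU - and a
removed OTU is reported at the first stage that failed it; its reads are
dropped, not reassigned.

**Chimera detection** follows the abundance-skew logic of de novo
detectors. OTUs are processed in decreasing total count; candidates for a
query are the OTUs already accepted as non-chimeric with at least
`min_skew = 2` times its total count (a chimera cannot outnumber its
parents, and a chimeric sequence is not a valid parent). The query is
aligned to every candidate, differences are projected onto query
coordinates, and every ordered candidate pair (A, B) with every breakpoint
k is scored as `diffs(query[1..k] vs A) + diffs(query[(k+1)..] vs B)`. A
query is flagged iff the best two-parent model beats the best single
candidate by ≥ `min_diff_gain = 4` differences and each side has ≥
`min_votes = 2` positions supporting its assigned parent against the other.
Ties break to the smallest breakpoint, then lexicographic parent ids.

The gain rule has a known operating envelope: for a clean sequence with two
or more *divergent* candidates, the minimum over all pairs and breakpoints
almost always undercuts the best single parent by more than 4 differences,
so specificity rests entirely on the skew filter leaving clean OTUs with
fewer than two candidates. Under the exchangeable abundance model of the
simulator this holds at the study scale (48 samples: OTU totals concentrate
well within 2× of each other) and motivates both the mild default effect
sizes (see below) and caution when applying the detector to communities
with steep abundance distributions.

**End integrity**: the query is compared to its closest match of equal or
longer length in the reference database; more than five query bases left
unaligned at the 5' or 3' end (the footprint of a truncated or chimeric
junction sequence relative to a full-length homolog) discards it. Five is
kept exactly ("more than five" is strict); the check is on the query side -
a merely shorter sequence that aligns end-to-end within its match is not an
artifact.

**Rare-OTU retention**: OTUs with one or two reads are kept only with a
full-span (no unaligned query ends), ≤ 1% dissimilar best reference match;
the 1% bound is inclusive. OTUs with three or more reads bypass this check.

## Taxonomy

The classifier is the word-presence naive-Bayes scheme: for genus g and
8-mer w, `P(w|g) = (n_g(w) + P_prior(w)) / (N_g + 1)` with
`P_prior(w) = (n(w) + 0.5) / (N + 1)`. Classification bootstraps the
query's distinct word set: 100 trials each sample one eighth of the words
with replacement and pick the genus maximising the summed log
probabilities; per-rank confidence is the modal taxon's trial fraction,
made non-increasing toward the root, and the lineage is reported to the
deepest rank with confidence ≥ 0.80 (a conventional cutoff; configurable).
Set semantics make the confidence invariant under query duplication.
Species-level statements are delegated to the nearest-reference hit, with
identity defined as for the clustering distance and rounded to integer
percent for reporting.

## Community statistics

Relative abundances are row percentages; group means are arithmetic;
"abundant" features have a mean ≥ 1% in at least one group (inclusive).
Alpha diversity per sample: observed OTUs, bias-corrected Chao1
`S + n1(n1−1)/(2(n2+1))`, ACE with the rare/abundant cutoff at 10 reads,
Shannon (natural log), Simpson as the unbiased dominance form
`Σ n_i(n_i−1) / (N(N−1))` (the form whose magnitudes match fecal community
tables, and reported as dominance, not 1−D), and Good's coverage
`1 − n1/N`. No rarefaction is applied (none is part of the original
procedure); diversity indices therefore inherit depth sensitivity, which
the manifest's per-sample read counts make auditable. ACE degenerates to
the observed richness when no rare class exists and is reported missing
when its sample-coverage term is zero.

Beta diversity is Bray-Curtis `1 − 2Σmin/Σ(x+y)` with classical-scaling
PCoA (double-centred squared dissimilarities; coordinates from positive
eigenvalues; proportion explained relative to the positive spectrum; each
axis oriented so its first nonzero loading is positive). Negative
eigenvalues, expected for Bray-Curtis, are excluded from the embedding.

Hypothesis testing mirrors the original commands: `kruskal.test` across
all groups per feature, `pairwise.wilcox.test` with Benjamini-Hochberg
correction applied *within* each feature across its group pairs (the
behaviour of that command; correcting across features instead is a
documented alternative, and the calibration layer demonstrates
cross-feature BH control), and `aov` + `TukeyHSD` for alpha indices.
Significance is P ≤ 0.05 inclusive. Compact letter displays are built
greedily from the adjusted-p matrix, inserting groups by descending mean.

## The synthetic community generator

The generator stands in for the original raw sequencing data and defines
the study conditions: 3 dietary treatments × 2 phases, 8 samples per
group, 10,000 read pairs per sample, 20 reference taxa, 0.5% per-base
substitution error, 5% two-parent chimeras (breakpoint uniform in the
middle 60% of the amplicon - end-proximal chimeras are indistinguishable
from sequencing error and would make detector tests ill-posed), 3%
truncation artifacts (6-30 nt off one end), and 2% off-length amplicons
that straddle the 400-580 nt window.

References derive from one ancestral 450-520 nt core by per-taxon
substitutions at rate 0.06 plus a few short indels, giving ~11% typical
pairwise divergence - the between-genus range for V1-V3 and consistent
with the 8% minimum the OTU-recovery checks assume. Under this divergence
roughly a third of chimeras (mid-range breakpoints) are distinct enough
from both parents to found their own OTUs; the rest co-cluster with a
parent, as in real data.

Per-sample abundances are log-normal (σ = 1) around a flat expectation,
multiplied by group effect multipliers and renormalised. The default
effects are a ×2 phase-succession on one taxon and a ×2.5 single-group
treatment effect on another - deliberately mild so that study-wide totals
stay inside the 2× abundance-skew envelope the chimera detector assumes of
non-chimeric sequences; stronger (4-fold) effects are exercised where they
belong, in the count-level calibration generator and the effect-recovery
property test. The count-level generator used for FDR calibration gives
its 20 effect features a reduced (0.25×) baseline weight so that the
spiked mass stays a small fraction of the community; otherwise
compositional closure turns the "null" features into genuine
anti-correlated effects and the measured false-discovery proportion stops
being an error rate.

Quality strings decay linearly from Q38 to Q25 along each read with a
per-read offset (sd 2) and per-base jitter (sd 2); the per-read component
is what places merged-contig mean qualities on both sides of the Q33
threshold (roughly a quarter to a third of contigs pass, a deliberately
harsh but filter-exercising profile). The generator does not emulate
platform-specific error structure (homopolymer errors, quality binning),
PCR amplification bias, or taxon-specific abundance means; passing tests
therefore demonstrate the pipeline's correctness and calibration under a
controlled, exchangeable community, not performance on any particular real
instrument's error profile.

## Problem sizes used by the validation layer

The acceptance checks run the full default study design (48 samples ×
10,000 pairs) over five seeds for the recovery metrics, an error-free
single-sample-per-group run for exact OTU recovery, 10,000 null
simulations for the Kruskal-Wallis type-I rate, and 20 seeds of the
120-feature count generator for realized FDR; the oracle equivalences use
≤ 30 sequences and N ≤ 8 rank tests, where brute force is exact. The
analysis scripts under `analysis/` use a smaller demonstration cohort
(4 samples per group, 2,500 pairs) chosen to keep an interactive
walkthrough quick while exercising every stage; at that reduced scale a
few clean OTUs fall outside the chimera detector's skew envelope, which
the driver reports explicitly.

## Known limitations

- The chimera detector's specificity depends on the abundance-skew
  envelope discussed above; it is not a general-purpose replacement for
  reference-based detection on steeply skewed communities.
- Greedy first-fit clustering is order-dependent by design (deterministic,
  but a different abundance ranking can change borderline memberships);
  no multiple sequence alignment or linkage clustering is attempted.
- The end-integrity screen requires a reference of equal or longer length;
  sequences longer than every reference are discarded and logged rather
  than silently kept.
- Alpha diversity is depth-sensitive without rarefaction; between-sample
  comparisons assume comparable sequencing effort, as in the original
  procedure.
- The naive-Bayes classifier is genus-limited; species claims rest on
  nearest-reference identity only.
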