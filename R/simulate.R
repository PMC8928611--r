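#' Generate a synthetic genus-resolved reference database
#'
#' Builds `n_taxa` amplicon reference records mimicking the structure of
#' 16S rRNA V1-V3 sequences within one community: every taxon derives from
#' a shared ancestral core (star phylogeny) by per-position substitutions
#' at rate `divergence` plus a few short indels (so amplicon lengths vary
#' within the 450-520 nt target window between primer sites), and is
#' flanked by an instantiated 27F forward primer site and the reverse
#' complement of the 519R primer site. The lineage has five ranks (phylum
#' to genus; genera unique, higher ranks shared hierarchically). All
#' pairwise distances (clustering-module metric) must be at least
#' `min_pairwise_dist`; sets violating this are rejected and resampled.
#'
#' @param seed integer RNG seed; output is deterministic per seed.
#' @param n_taxa number of reference taxa (>= 2).
#' @param min_pairwise_dist minimum pairwise dissimilarity in (0, 0.5).
#' @param divergence per-taxon substitution rate from the ancestral core
#'   (0.06 gives ~11% typical pairwise dissimilarity, in the range of
#'   between-genus V1-V3 divergence).
#' @param core_len ancestral core length between the primer sites.
#' @param max_tries rejection-sampling bound.
#' @return data.frame with `ref_id`, `seq`, `phylum`, `class`, `order`,
#'   `family`, `genus`.
#' @export
generate_reference_db <- function(seed, n_taxa = 20, min_pairwise_dist = 0.08,
                                  divergence = 0.06, core_len = 485,
                                  max_tries = 20) {
  stopifnot(n_taxa >= 2, min_pairwise_dist > 0, min_pairwise_dist < 0.5)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fwd <- fwd_primer_default()
  rev3 <- revcomp(rev_primer_default())
  bases <- c("A", "C", "G", "T")
  instantiate <- function(pat) {
    ch <- strsplit(pat, "", fixed = TRUE)[[1]]
    paste(vapply(ch, function(c) {
      opts <- .iupac[[c]]
      opts[sample.int(length(opts), 1L)]
    }, character(1)), collapse = "")
  }
  for (try in seq_len(max_tries)) {
    anc <- sample(bases, core_len, replace = TRUE)
    seqs <- vapply(seq_len(n_taxa), function(i) {
      core <- anc
      nm <- which(runif(core_len) < divergence)
      if (length(nm)) {
        core[nm] <- vapply(core[nm], function(b) {
          sample(setdiff(bases, b), 1L)
        }, character(1))
      }
      for (ev in seq_len(sample(1:3, 1L))) {
        g <- sample(1:12, 1L)
        at <- sample(seq(20L, length(core) - 20L - g), 1L)
        if (runif(1) < 0.5) {
          core <- core[-seq(at, at + g - 1L)]                  # deletion
        } else {
          core <- append(core, sample(bases, g, replace = TRUE), after = at)
        }
      }
      paste0(instantiate(fwd), paste(core, collapse = ""), instantiate(rev3))
    }, character(1))
    ok <- TRUE
    for (i in seq_len(n_taxa - 1L)) {
      for (j in seq(i + 1L, n_taxa)) {
        if (pairwise_distance(seqs[i], seqs[j]) < min_pairwise_dist) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (ok) {
      i <- seq_len(n_taxa)
      return(data.frame(
        ref_id = sprintf("Ref-%03d", i), seq = seqs,
        phylum = sprintf("Phylum%02d", (i - 1L) %/% 16L + 1L),
        class = sprintf("Class%02d", (i - 1L) %/% 8L + 1L),
        order = sprintf("Order%02d", (i - 1L) %/% 4L + 1L),
        family = sprintf("Family%02d", (i - 1L) %/% 2L + 1L),
        genus = sprintf("Genus%02d", i), stringsAsFactors = FALSE))
    }
  }
  stop(sprintf("could not satisfy min_pairwise_dist=%.3f after %d attempts",
               min_pairwise_dist, max_tries))
}

#' Simulation configuration
#'
#' Defaults mirror the design of a nursery-pig feeding trial: three dietary
#' treatments (Con, PepM, PepM_Pro) crossed with two phases (PII, PIII),
#' eight samples per group, 10,000 read pairs per sample, a 0.5% per-base
#' substitution error rate, 5% two-parent chimeras, 3% truncation artifacts
#' and 2% off-length amplicons, with log-normal (sigma = 1) per-sample
#' abundance dispersion around an exchangeable (flat-expectation) taxon
#' profile. The default effect map carries a phase-succession effect (taxon
#' 1 doubled in all Phase III groups) and a treatment effect (taxon 2 up
#' 2.5x in the PepM_Pro Phase III group); these folds are deliberately
#' mild so that study-wide OTU totals stay within the 2x abundance-skew
#' envelope that de novo chimera detection assumes of non-chimeric
#' sequences.
#'
#' @param seed integer seed controlling all randomness.
#' @param n_taxa number of reference taxa used.
#' @param samples_per_group samples per (treatment, phase) group.
#' @param groups data.frame with `treatment` and `phase` columns.
#' @param reads_per_sample read pairs emitted per sample.
#' @param base_error_rate per-base substitution probability.
#' @param chimera_rate fraction of reads drawn as two-parent chimeras.
#' @param artifact_rate fraction of reads truncated by 6-30 nt at one end.
#' @param offlen_rate fraction of reads from amplicons pushed outside the
#'   400-580 nt length window (internal deletion or insertion).
#' @param lognormal_sigma log-scale abundance dispersion per sample.
#' @param effect_map named list: taxon `ref_id` -> named numeric vector of
#'   per-group multipliers (group label `treatment.phase`).
#' @param read_len sequencing read length (2 x `read_len` layout).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_taxa = 20, samples_per_group = 8,
                       groups = NULL, reads_per_sample = 10000,
                       base_error_rate = 0.005, chimera_rate = 0.05,
                       artifact_rate = 0.03, offlen_rate = 0.02,
                       lognormal_sigma = 1, effect_map = NULL,
                       read_len = 300) {
  if (is.null(groups)) {
    groups <- expand.grid(treatment = c("Con", "PepM", "PepM_Pro"),
                          phase = c("PII", "PIII"),
                          stringsAsFactors = FALSE)
  }
  glab <- paste(groups$treatment, groups$phase, sep = ".")
  if (is.null(effect_map)) {
    # Mild defaults keep every taxon's study-wide total inside the 2x
    # abundance-skew envelope the chimera detector's candidate rule
    # assumes; stronger folds are exercised explicitly in the statistical
    # calibration layer.
    phase3 <- glab[groups$phase == "PIII"]
    effect_map <- list(
      "Ref-001" = setNames(rep(2, length(phase3)), phase3),
      "Ref-002" = c(PepM_Pro.PIII = 2.5)
    )
  }
  stopifnot(n_taxa >= 2, samples_per_group >= 1,
            chimera_rate >= 0, chimera_rate <= 1,
            artifact_rate >= 0, artifact_rate <= 1,
            offlen_rate >= 0, offlen_rate <= 1,
            base_error_rate >= 0, base_error_rate <= 1,
            all(unlist(effect_map) > 0))
  structure(list(seed = seed, n_taxa = n_taxa,
                 samples_per_group = samples_per_group, groups = groups,
                 reads_per_sample = reads_per_sample,
                 base_error_rate = base_error_rate,
                 chimera_rate = chimera_rate, artifact_rate = artifact_rate,
                 offlen_rate = offlen_rate,
                 lognormal_sigma = lognormal_sigma, effect_map = effect_map,
                 read_len = read_len), class = "sim_config")
}

#' Simulate paired-end amplicon reads with ground truth
#'
#' Per sample: draws log-normal base abundances, applies the sample group's
#' effect multipliers, renormalises, then emits read pairs. Each read is a
#' regular amplicon, a two-parent chimera (breakpoint uniform in the middle
#' 60%), a 6-30 nt end-truncation artifact, or an off-length amplicon,
#' according to the configured rates. Substitution errors and a 3'-declining
#' Phred profile (38 to 25, with per-read and per-base noise) are applied to
#' both mates. Every read gets a provenance record.
#'
#' @param cfg a [sim_config()].
#' @param refs reference database from [generate_reference_db()]; effect-map
#'   keys must be a subset of `refs$ref_id`.
#' @return list with `reads` (data.frame: `sample_id`, `read_id`, `fwd_seq`,
#'   `fwd_qual`, `rev_seq`, `rev_qual`), `truth` (list: `abundance` taxa x
#'   samples matrix of true fractions, `provenance` per-read data.frame),
#'   and `design` (`sample_id`, `treatment`, `phase`, `group`).
#' @export
simulate_samples <- function(cfg, refs) {
  stopifnot(inherits(cfg, "sim_config"),
            all(names(cfg$effect_map) %in% refs$ref_id))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  n_taxa <- nrow(refs)
  glab <- paste(cfg$groups$treatment, cfg$groups$phase, sep = ".")
  design <- data.frame(
    sample_id = sprintf("S%02d", seq_len(nrow(cfg$groups) * cfg$samples_per_group)),
    treatment = rep(cfg$groups$treatment, each = cfg$samples_per_group),
    phase = rep(cfg$groups$phase, each = cfg$samples_per_group),
    group = rep(glab, each = cfg$samples_per_group),
    stringsAsFactors = FALSE)
  mult <- matrix(1, n_taxa, length(glab), dimnames = list(refs$ref_id, glab))
  for (tx in names(cfg$effect_map)) {
    em <- cfg$effect_map[[tx]]
    mult[tx, names(em)] <- em
  }
  amp <- refs$seq
  amp_len <- nchar(amp)
  abund <- matrix(0, n_taxa, nrow(design),
                  dimnames = list(refs$ref_id, design$sample_id))
  reads_list <- vector("list", nrow(design))
  prov_list <- vector("list", nrow(design))
  for (s in seq_len(nrow(design))) {
    base <- rlnorm(n_taxa, 0, cfg$lognormal_sigma) * mult[, design$group[s]]
    p <- base / sum(base)
    abund[, s] <- p
    n <- cfg$reads_per_sample
    type_draw <- runif(n)
    type <- ifelse(type_draw < cfg$chimera_rate, "chimera",
            ifelse(type_draw < cfg$chimera_rate + cfg$artifact_rate, "artifact",
            ifelse(type_draw < cfg$chimera_rate + cfg$artifact_rate +
                     cfg$offlen_rate, "offlen", "regular")))
    src <- sample.int(n_taxa, n, replace = TRUE, prob = p)
    parent_b <- rep(NA_integer_, n)
    bp_frac <- rep(NA_real_, n)
    trunc_len <- rep(NA_integer_, n)
    trunc_end <- rep(NA_character_, n)
    templates <- amp[src]
    ci <- which(type == "chimera")
    if (length(ci)) {
      pb <- vapply(src[ci], function(a) {
        repeat {
          b <- sample.int(n_taxa, 1L, prob = p)
          if (b != a) return(b)
        }
      }, integer(1))
      parent_b[ci] <- pb
      f <- runif(length(ci), 0.2, 0.8)
      bp_frac[ci] <- f
      la <- amp_len[src[ci]]
      lb <- amp_len[pb]
      ka <- round(f * la)
      kb <- round(f * lb)
      templates[ci] <- paste0(substr(amp[src[ci]], 1L, ka),
                              substr(amp[pb], kb + 1L, lb))
    }
    ai <- which(type == "artifact")
    if (length(ai)) {
      tl <- sample(6:30, length(ai), replace = TRUE)
      te <- sample(c("5p", "3p"), length(ai), replace = TRUE)
      trunc_len[ai] <- tl
      trunc_end[ai] <- te
      la <- amp_len[src[ai]]
      templates[ai] <- ifelse(te == "5p",
                              substr(amp[src[ai]], tl + 1L, la),
                              substr(amp[src[ai]], 1L, la - tl))
    }
    oi <- which(type == "offlen")
    if (length(oi)) {
      for (k in oi) {
        la <- amp_len[src[k]]
        if (runif(1) < 0.5) {   # short: internal deletion to < 400 nt
          target <- sample(360:395, 1L)
          dlen <- la - target
          at <- sample(seq(40L, la - 40L - dlen), 1L)
          templates[k] <- paste0(substr(amp[src[k]], 1L, at),
                                 substr(amp[src[k]], at + dlen + 1L, la))
        } else {                # long: internal insertion to > 580 nt
          target <- sample(583:590, 1L)
          ins <- paste(sample(c("A", "C", "G", "T"), target - la,
                              replace = TRUE), collapse = "")
          at <- sample(seq(40L, la - 40L), 1L)
          templates[k] <- paste0(substr(amp[src[k]], 1L, at), ins,
                                 substr(amp[src[k]], at + 1L, la))
        }
      }
    }
    sim <- cpp_sim_reads(templates, as.integer(cfg$read_len),
                         cfg$base_error_rate, 38, 25, 2, 2)
    rid <- sprintf("%s_r%06d", design$sample_id[s], seq_len(n))
    reads_list[[s]] <- data.frame(
      sample_id = design$sample_id[s], read_id = rid,
      fwd_seq = sim$fwd_seq, fwd_qual = sim$fwd_qual,
      rev_seq = sim$rev_seq, rev_qual = sim$rev_qual,
      stringsAsFactors = FALSE)
    prov_list[[s]] <- data.frame(
      sample_id = design$sample_id[s], read_id = rid, type = type,
      source = refs$ref_id[src],
      parent_b = ifelse(is.na(parent_b), NA_character_, refs$ref_id[parent_b]),
      breakpoint_frac = bp_frac, trunc_len = trunc_len,
      trunc_end = trunc_end, stringsAsFactors = FALSE)
  }
  list(reads = do.call(rbind, reads_list),
       truth = list(abundance = abund, provenance = do.call(rbind, prov_list)),
       design = design)
}

#' Simulate a samples x features count matrix with spiked effects
#'
#' Direct count-level generator used to calibrate the hypothesis-testing
#' layer without running the sequencing simulator: per sample, feature
#' weights are log-normal draws; `effect_features` get `fold`-times higher
#' weights in the last group; counts are multinomial at `depth` reads.
#' Effect features carry a reduced baseline weight (`effect_weight`) so the
#' spiked mass stays a small fraction of the community and compositional
#' closure does not turn the null features into real (anti-correlated)
#' effects - the calibration is meant to measure the error rate on features
#' that are genuinely null after normalisation.
#'
#' @param n_null,n_effect numbers of null and effect features.
#' @param fold effect-size multiplier.
#' @param n_per_group samples per group.
#' @param groups group labels (effect applies to the last one).
#' @param depth reads per sample.
#' @param sigma log-normal dispersion.
#' @param effect_weight baseline weight multiplier for effect features.
#' @param seed RNG seed.
#' @return list with `counts` (samples x features), `design`, and
#'   `effect_features`.
#' @export
simulate_count_matrix <- function(n_null = 100, n_effect = 20, fold = 4,
                                  n_per_group = 15, groups = c("A", "B"),
                                  depth = 20000, sigma = 0.7,
                                  effect_weight = 0.25, seed = 1) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  nf <- n_null + n_effect
  feat <- sprintf("F%03d", seq_len(nf))
  eff <- feat[seq_len(n_effect) + n_null]
  design <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_per_group * length(groups))),
    group = rep(groups, each = n_per_group), stringsAsFactors = FALSE)
  counts <- matrix(0L, nrow(design), nf,
                   dimnames = list(design$sample_id, feat))
  for (s in seq_len(nrow(design))) {
    w <- rlnorm(nf, 0, sigma)
    w[feat %in% eff] <- w[feat %in% eff] * effect_weight
    if (design$group[s] == groups[length(groups)]) {
      w[feat %in% eff] <- w[feat %in% eff] * fold
    }
    counts[s, ] <- as.integer(rmultinom(1, depth, w / sum(w)))
  }
  list(counts = counts, design = design, effect_features = eff)
}
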