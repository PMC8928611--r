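#' Relative abundance matrix (percent)
#'
#' @param m samples x features count (or abundance) matrix; row sums must be
#'   positive.
#' @return matrix of the same shape with rows summing to 100.
#' @export
relative_abundance <- function(m) {
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    stop(sprintf("zero row sum for sample '%s'",
                 rownames(m)[which(rs <= 0)[1]]))
  }
  sweep(m, 1, rs, "/") * 100
}

#' Group means of per-sample percentages
#'
#' @param pct samples x features percent matrix (rownames = sample ids).
#' @param design data.frame with `sample_id` and `group`.
#' @return groups x features matrix of arithmetic means.
#' @export
group_means <- function(pct, design) {
  g <- design$group[match(rownames(pct), design$sample_id)]
  if (anyNA(g)) stop("samples missing from design")
  groups <- unique(design$group)
  res <- vapply(groups, function(gr) {
    rows <- which(g == gr)
    if (!length(rows)) stop(sprintf("empty group '%s'", gr))
    colMeans(pct[rows, , drop = FALSE])
  }, numeric(ncol(pct)))
  out <- t(matrix(res, nrow = ncol(pct), ncol = length(groups)))
  rownames(out) <- groups
  colnames(out) <- colnames(pct)
  out
}

#' Select abundant features (>= 1% in at least one group)
#'
#' @param gm groups x features matrix of mean percentages.
#' @param cutoff inclusive percent cutoff (default 1).
#' @return character vector of selected feature names.
#' @export
select_abundant_otus <- function(gm, cutoff = 1.0) {
  colnames(gm)[apply(gm, 2, max) >= cutoff]
}

#' Alpha diversity indices for one sample
#'
#' Observed OTUs, bias-corrected Chao1, ACE (rare/abundant cutoff 10),
#' Shannon (natural log), Simpson dominance `sum n_i(n_i-1) / (N(N-1))`,
#' and Good's coverage `1 - n1/N`.
#'
#' @param counts integer vector of per-OTU read counts for one sample.
#' @return one-row data.frame: `sobs`, `chao1`, `ace`, `shannon`,
#'   `simpson`, `goods_coverage`.
#' @export
compute_alpha <- function(counts) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (N < 1) stop("sample has no reads")
  sobs <- length(counts)
  n1 <- sum(counts == 1)
  n2 <- sum(counts == 2)
  chao1 <- sobs + n1 * (n1 - 1) / (2 * (n2 + 1))
  p <- counts / N
  shannon <- -sum(p * log(p))
  simpson <- if (N > 1) sum(counts * (counts - 1)) / (N * (N - 1)) else NA_real_
  goods <- 1 - n1 / N
  rare <- counts[counts <= 10]
  s_rare <- length(rare)
  s_abund <- sobs - s_rare
  if (s_rare == 0) {
    ace <- sobs
  } else {
    n_rare <- sum(rare)
    c_ace <- 1 - n1 / n_rare
    if (c_ace == 0) {
      ace <- NA_real_
    } else {
      fi <- tabulate(rare, nbins = 10)
      gamma2 <- max(s_rare / c_ace * sum(seq_len(10) * (seq_len(10) - 1) * fi) /
                      (n_rare * (n_rare - 1)) - 1, 0)
      if (n_rare <= 1) gamma2 <- 0
      ace <- s_abund + s_rare / c_ace + n1 / c_ace * gamma2
    }
  }
  data.frame(sobs = sobs, chao1 = chao1, ace = ace, shannon = shannon,
             simpson = simpson, goods_coverage = goods)
}

#' Alpha diversity for every sample of a count matrix
#' @param m samples x OTUs count matrix.
#' @return data.frame with `sample_id` and the [compute_alpha()] columns.
#' @export
alpha_table <- function(m) {
  rows <- lapply(rownames(m), function(s) {
    cbind(sample_id = s, compute_alpha(m[s, ]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bray-Curtis dissimilarity between two vectors
#'
#' `1 - 2 * sum(min(x, y)) / sum(x + y)`.
#'
#' @param x,y non-negative abundance vectors of equal length.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both vectors are all-zero")
  1 - 2 * sum(pmin(x, y)) / tot
}

#' Bray-Curtis dissimilarity matrix
#' @param m samples x features matrix.
#' @return symmetric dissimilarity matrix.
#' @export
bray_curtis_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- bray_curtis(m[i, ], m[j, ])
    }
  }
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centres the squared dissimilarities, eigendecomposes, and returns
#' coordinates from the positive eigenvalues only, sorted descending.
#' Proportion explained is relative to the sum of positive eigenvalues.
#' Sign convention: the first nonzero loading of each axis is positive.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @return list with `coords` (samples x axes), `eigenvalues` (all, sorted
#'   descending), `prop_explained`.
#' @export
pcoa_ord <- function(d) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("dissimilarity matrix must be symmetric")
  }
  n <- nrow(d)
  cs <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  eig <- cs$eig
  tol <- max(abs(eig)) * 1e-9
  pos <- which(eig > tol)
  coords <- cs$points[, seq_along(pos), drop = FALSE]
  for (a in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, a]) > 1e-12)
    if (length(nz) && coords[nz[1], a] < 0) coords[, a] <- -coords[, a]
  }
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coords = coords, eigenvalues = sort(eig, decreasing = TRUE),
       prop_explained = eig[pos] / sum(eig[pos]))
}

#' Kruskal-Wallis rank-sum test
#'
#' Mid-ranks with tie correction, chi-square p-value with k-1 degrees of
#' freedom (wraps `stats::kruskal.test`). All-identical values give H = 0,
#' p = 1.
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 groups).
#' @return list with `H` and `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(nlevels(droplevels(groups)) >= 2, length(values) >= 2)
  if (length(unique(values)) == 1) return(list(H = 0, p = 1))
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Pairwise Wilcoxon rank-sum tests with Benjamini-Hochberg correction
#'
#' Two-sided rank-sum p per group pair (exact when group sizes permit and
#' there are no ties, else normal approximation with tie and continuity
#' correction — `stats::wilcox.test` defaults), BH-adjusted across the
#' pairs of this one feature.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return data.frame with `group1`, `group2`, `p_adj`.
#' @export
wilcoxon_pairwise_bh <- function(values, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0)) stop("empty group")
  pw <- suppressWarnings(
    pairwise.wilcox.test(values, groups, p.adjust.method = "BH"))
  m <- pw$p.value
  out <- data.frame(group1 = rownames(m)[row(m)], group2 = colnames(m)[col(m)],
                    p_adj = as.vector(m), stringsAsFactors = FALSE)
  out <- out[!is.na(out$p_adj), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Wraps `stats::aov` and `stats::TukeyHSD` (Tukey-Kramer standard errors
#' for unequal group sizes).
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return list with `F`, `p`, and `tukey` (data.frame: `comparison`,
#'   `diff`, `p_adj`).
#' @export
anova_tukey <- function(values, groups) {
  g <- as.factor(groups)
  if (isTRUE(all.equal(stats::var(values), 0)) ||
      length(unique(values)) == 1) {
    pairs <- utils::combn(levels(droplevels(g)), 2)
    return(list(F = 0, p = 1,
                tukey = data.frame(
                  comparison = paste(pairs[2, ], pairs[1, ], sep = "-"),
                  diff = 0, p_adj = 1, stringsAsFactors = FALSE)))
  }
  fit <- aov(values ~ g)
  sm <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  list(F = sm[["F value"]][1], p = sm[["Pr(>F)"]][1],
       tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE))
}

#' Fold ratio of group means for one feature
#'
#' @param gm groups x features mean matrix.
#' @param feature feature (column) name.
#' @param num_group,den_group numerator and denominator groups.
#' @return the ratio (full precision; report at one decimal).
#' @export
fold_ratio <- function(gm, feature, num_group, den_group) {
  den <- gm[den_group, feature]
  if (den == 0) stop("zero denominator mean")
  unname(gm[num_group, feature] / den)
}

#' Compact letter display from an adjusted-p matrix
#'
#' Greedy insertion by descending group mean: each group joins every letter
#' class whose members it does not differ from significantly (adjusted
#' p <= alpha), founding a new letter when none admits it. Groups sharing a
#' letter are not significantly different.
#'
#' @param pairs data.frame from [wilcoxon_pairwise_bh()] (`group1`,
#'   `group2`, `p_adj`).
#' @param means named vector of group means (defines insertion order).
#' @param alpha significance level (default 0.05, inclusive).
#' @return named character vector of letter strings per group.
#' @export
compact_letters <- function(pairs, means, alpha = 0.05) {
  groups <- names(sort(means, decreasing = TRUE))
  sig <- function(a, b) {
    hit <- pairs$p_adj[(pairs$group1 == a & pairs$group2 == b) |
                         (pairs$group1 == b & pairs$group2 == a)]
    length(hit) > 0 && !is.na(hit[1]) && hit[1] <= alpha
  }
  classes <- list()
  for (g in groups) {
    placed <- FALSE
    for (ci in seq_along(classes)) {
      if (!any(vapply(classes[[ci]], function(m) sig(g, m), logical(1)))) {
        classes[[ci]] <- c(classes[[ci]], g)
        placed <- TRUE
      }
    }
    if (!placed) classes[[length(classes) + 1L]] <- g
  }
  out <- setNames(rep("", length(means)), names(means))
  for (ci in seq_along(classes)) {
    for (g in classes[[ci]]) out[g] <- paste0(out[g], letters[ci])
  }
  out
}

#' Differential-abundance testing across groups
#'
#' For each feature: Kruskal-Wallis across all groups, pairwise Wilcoxon
#' with BH correction (within the feature), and a compact letter display at
#' `alpha`.
#'
#' @param pct samples x features percent matrix.
#' @param design data.frame with `sample_id`, `group`.
#' @param alpha significance level.
#' @return list with `tests` (per-feature `kw_p`), `pairwise` (long
#'   data.frame), `letters` (features x groups letter matrix).
#' @export
test_features <- function(pct, design, alpha = 0.05) {
  g <- design$group[match(rownames(pct), design$sample_id)]
  gm <- group_means(pct, design)
  feats <- colnames(pct)
  kw_p <- vapply(feats, function(f) kruskal_wallis(pct[, f], g)$p, numeric(1))
  pw_list <- lapply(feats, function(f) {
    cbind(feature = f, wilcoxon_pairwise_bh(pct[, f], g),
          stringsAsFactors = FALSE)
  })
  letters_m <- t(vapply(feats, function(f) {
    pw <- pw_list[[match(f, feats)]]
    compact_letters(pw, gm[, f], alpha = alpha)
  }, character(nrow(gm))))
  list(tests = data.frame(feature = feats, kw_p = kw_p, row.names = NULL,
                          stringsAsFactors = FALSE),
       pairwise = do.call(rbind, pw_list), letters = letters_m)
}
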