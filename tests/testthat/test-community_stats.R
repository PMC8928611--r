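test_that("relative abundance scales rows to percentages", {
  m <- matrix(c(2, 3, 5, 10, 0, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
  pct <- relative_abundance(m)
  expect_equal(unname(pct["s1", ]), c(20, 30, 50))
  expect_equal(unname(pct["s2", ]), c(100, 0, 0))
  expect_equal(unname(rowSums(pct)), c(100, 100), tolerance = 1e-12)
  m0 <- m; m0["s2", ] <- 0
  expect_error(relative_abundance(m0), "s2")
})

test_that("group means average per-sample percentages", {
  pct <- matrix(c(10, 20, 30, 40), 4, 1,
                dimnames = list(sprintf("s%d", 1:4), "f1"))
  design <- data.frame(sample_id = sprintf("s%d", 1:4),
                       group = c("A", "A", "B", "B"))
  gm <- group_means(pct, design)
  expect_equal(unname(gm[, "f1"]), c(15, 35))
  one <- group_means(pct[4, , drop = FALSE],
                     design[4, , drop = FALSE])
  expect_equal(unname(one[, "f1"]), 40)
  expect_error(group_means(pct, data.frame(sample_id = "s9", group = "A")),
               "missing")
})

test_that("abundant-feature selection is inclusive at 1%", {
  gm <- matrix(c(1.0, 0.2, 0.99, 0.99, 5, 0.1), 2, 3,
               dimnames = list(c("g1", "g2"), c("fa", "fb", "fc")))
  expect_equal(select_abundant_otus(gm), c("fa", "fc"))
})

test_that("alpha indices match their closed forms", {
  a <- compute_alpha(rep(25, 4))
  expect_equal(a$sobs, 4)
  expect_equal(a$shannon, log(4))
  expect_equal(a$simpson, 4 * 25 * 24 / (100 * 99))
  expect_equal(a$chao1, 4)
  expect_equal(a$goods_coverage, 1)

  b <- compute_alpha(rep(3, 5))
  expect_equal(b$chao1, 5)

  d <- compute_alpha(c(5, 2, 1, 1))
  expect_equal(d$sobs, 4)
  expect_equal(d$chao1, 4 + 2 * 1 / (2 * 2))
  expect_equal(d$goods_coverage, 1 - 2 / 9)
  expect_error(compute_alpha(integer(0)), "no reads")
})

test_that("chao1, ACE and Shannon agree with the vegan oracle", {
  skip_if_not_installed("vegan")
  set.seed(91)
  for (i in 1:10) {
    counts <- rpois(60, lambda = sample(c(2, 5, 20), 1))
    counts <- counts[counts > 0]
    if (length(counts) < 3) next
    a <- compute_alpha(counts)
    est <- vegan::estimateR(counts)
    expect_equal(a$chao1, unname(est["S.chao1"]), tolerance = 1e-8)
    expect_equal(a$ace, unname(est["S.ACE"]), tolerance = 1e-8)
    expect_equal(a$shannon, unname(vegan::diversity(counts)), tolerance = 1e-12)
  }
  expect_true(all(vapply(1:10, function(i) {
    counts <- rpois(50, 3); counts <- counts[counts > 0]
    a <- compute_alpha(counts)
    a$chao1 >= a$sobs && (a$goods_coverage == 1) == (sum(counts == 1) == 0)
  }, logical(1))))
})

test_that("Bray-Curtis follows its formula and bounds", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 5)), 1)
  expect_equal(bray_curtis(c(2, 0), c(1, 1)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  skip_if_not_installed("vegan")
  set.seed(92)
  m <- matrix(runif(40), 4, 10)
  ours <- bray_curtis_matrix(m)
  ref <- as.matrix(vegan::vegdist(m, "bray"))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
  expect_equal(ours, t(ours))
})

test_that("PCoA reproduces simple and Euclidean geometries", {
  d2 <- matrix(c(0, 2, 2, 0), 2, 2)
  p2 <- pcoa_ord(d2)
  expect_equal(sort(unname(p2$coords[, 1])), c(-1, 1))
  expect_equal(p2$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(p2$prop_explained[1], 1)

  set.seed(93)
  x <- matrix(rnorm(6 * 3), 6, 3)
  d <- as.matrix(dist(x))
  p <- pcoa_ord(d)
  expect_equal(as.matrix(dist(p$coords)), unname(d), tolerance = 1e-9,
               ignore_attr = TRUE)
  # sign convention: first nonzero loading of each axis positive
  expect_true(all(apply(p$coords, 2, function(v) v[which(abs(v) > 1e-12)[1]] > 0)))
  # identical samples land on identical coordinates
  dd <- as.matrix(dist(rbind(x[1, ], x[1, ], x[3, ])))
  pp <- pcoa_ord(dd)
  expect_equal(pp$coords[1, ], pp$coords[2, ], tolerance = 1e-9)
  expect_error(pcoa_ord(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("Kruskal-Wallis matches hand computation and the rank-formula oracle", {
  kw <- kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(kw$H, 2.4, tolerance = 1e-12)
  expect_equal(kruskal_wallis(rep(7, 6), rep(c("a", "b"), 3))$p, 1)
  set.seed(94)
  for (i in 1:10) {
    v <- sample(1:6, 8, replace = TRUE)   # ties likely
    g <- rep(c("a", "b", "c"), length.out = 8)
    if (length(unique(v)) == 1) next
    expect_equal(kruskal_wallis(v, g)$H, kw_H_oracle(v, g), tolerance = 1e-10)
  }
})

test_that("pairwise Wilcoxon p-values match exact enumeration, BH-adjusted per feature", {
  pw <- wilcoxon_pairwise_bh(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(nrow(pw), 1)
  expect_equal(pw$p_adj, 1 / 3, tolerance = 1e-12)   # single pair: adj = raw
  set.seed(95)
  for (i in 1:8) {
    x <- rnorm(4); y <- rnorm(4)
    pw <- wilcoxon_pairwise_bh(c(x, y), rep(c("a", "b"), each = 4))
    expect_equal(pw$p_adj, wilcox_exact_enum(x, y), tolerance = 1e-12)
  }
  # BH across the pairs of one feature: adjusted >= raw, monotone
  v <- c(rnorm(5), rnorm(5) + 3, rnorm(5) + 6)
  g <- rep(c("a", "b", "c"), each = 5)
  pw3 <- wilcoxon_pairwise_bh(v, g)
  raw <- suppressWarnings(
    stats::pairwise.wilcox.test(v, g, p.adjust.method = "none"))$p.value
  raw <- raw[!is.na(raw)]
  expect_true(all(pw3$p_adj >= raw - 1e-12))
})

test_that("ANOVA + Tukey HSD behave on degenerate and two-group inputs", {
  at0 <- anova_tukey(rep(5, 9), rep(c("a", "b", "c"), 3))
  expect_equal(at0$F, 0)
  expect_equal(at0$p, 1)
  set.seed(96)
  x <- rnorm(6); y <- rnorm(6) + 1
  at2 <- anova_tukey(c(x, y), rep(c("a", "b"), each = 6))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(at2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(at2$p, tt$p.value, tolerance = 1e-10)
  # Tukey adjusted p against the studentized-range closed form
  v <- c(rnorm(5), rnorm(5) + 1, rnorm(5) + 2)
  g <- rep(c("a", "b", "c"), each = 5)
  at3 <- anova_tukey(v, g)
  fit <- aov(v ~ factor(g))
  mse <- summary(fit)[[1]][["Mean Sq"]][2]
  q12 <- abs(mean(v[g == "a"]) - mean(v[g == "b"])) / sqrt(mse / 5)
  p12 <- 1 - ptukey(q12, 3, 12)
  expect_equal(at3$tukey$p_adj[at3$tukey$comparison == "b-a"], p12,
               tolerance = 1e-6)
})

test_that("fold ratios and compact letters are consistent", {
  gm <- matrix(c(17.19, 4.46, 10, 2.5), 2, 2,
               dimnames = list(c("PmPIII", "ConIII"), c("f1", "f2")))
  expect_equal(round(fold_ratio(gm, "f1", "PmPIII", "ConIII"), 1), 3.9)
  expect_equal(fold_ratio(gm, "f2", "PmPIII", "ConIII"), 4)
  expect_equal(fold_ratio(gm, "f1", "ConIII", "ConIII"), 1)
  gm0 <- gm; gm0["ConIII", "f1"] <- 0
  expect_error(fold_ratio(gm0, "f1", "PmPIII", "ConIII"), "denominator")

  pairs <- data.frame(group1 = c("A", "A", "B"), group2 = c("B", "C", "C"),
                      p_adj = c(0.01, 0.20, 0.03))
  means <- c(A = 10, B = 5, C = 8)
  lt <- compact_letters(pairs, means)
  # sharing a letter <=> not significantly different
  share <- function(a, b) {
    any(strsplit(lt[a], "")[[1]] %in% strsplit(lt[b], "")[[1]])
  }
  expect_false(share("A", "B"))
  expect_true(share("A", "C"))
  expect_false(share("B", "C"))
})
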