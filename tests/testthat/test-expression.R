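test_that("TPM normalization matches hand computations", {
  counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
  tp <- tpm(counts, c(1000, 1000))
  expect_equal(as.vector(tp$values), c(5e5, 5e5))

  counts <- matrix(c(10, 20), 2, 1, dimnames = list(c("a", "b"), "s1"))
  tp <- tpm(counts, c(1000, 1000))
  expect_equal(as.vector(tp$values), c(1e6 / 3, 2e6 / 3))

  # length normalization: same counts, gene b twice as long
  tp <- tpm(matrix(c(10, 10), 2, 1), c(1000, 2000))
  expect_equal(as.vector(tp$values), c(2e6 / 3, 1e6 / 3))
})

test_that("TPM columns always sum to one million", {
  set.seed(101)
  for (i in 1:100) {
    ng <- sample(2:40, 1); ns <- sample(1:8, 1)
    counts <- matrix(rpois(ng * ns, 50) + 1, ng, ns)
    lens <- sample(200:3000, ng)
    tp <- tpm(counts, lens)
    expect_equal(unname(colSums(tp$values)), rep(1e6, ns),
                 tolerance = 1e-6)
  }
  m <- matrix(c(1, 1, 0, 0), 2, 2, dimnames = list(NULL, c("ok", "dead")))
  expect_error(tpm(m, c(100, 100)), "dead")
})

test_that("TPM categories apply the <1 and >60 cuts", {
  counts <- matrix(c(1, 50, 2e6), 3, 1)
  tp <- tpm(counts, c(1000, 1000, 1000))
  expect_equal(as.vector(tp$category), c("null_low", "mid", "high"))
})

test_that("PCA agrees with an eigendecomposition oracle", {
  set.seed(102)
  for (i in 1:10) {
    mat <- matrix(rnorm(10 * 20), 10, 20) # genes x samples
    p <- pca_samples(mat)
    x <- scale(t(mat), center = TRUE, scale = FALSE)
    ev <- eigen(cov(x), symmetric = TRUE)
    ve <- ev$values / sum(ev$values)
    k <- length(p$variance_explained)
    expect_equal(p$variance_explained, ve[1:k], tolerance = 1e-8)
    expect_equal(sum(p$variance_explained), 1, tolerance = 1e-8)
    # scores match up to (fixed) sign
    expect_equal(abs(p$scores[, 1]), abs((x %*% ev$vectors)[, 1]),
                 ignore_attr = TRUE, tolerance = 1e-8)
  }
})

test_that("rank-1 data load entirely on PC1 and signs are fixed", {
  base <- rnorm(30)
  mat <- outer(base, seq(1, 4, length.out = 6)) # genes x samples on a line
  p <- pca_samples(mat)
  expect_equal(p$variance_explained[[1]], 1, tolerance = 1e-12)
  expect_gt(p$loadings[which.max(abs(p$loadings[, 1])), 1], 0)
  expect_warning(pca_samples(matrix(3, 4, 5)), "constant")
})

test_that("average-linkage heights match the brute-force oracle", {
  set.seed(103)
  for (i in 1:5) {
    pts <- matrix(rnorm(16), 8, 2)
    cl <- cluster_profiles(pts)
    expect_equal(cl$heights, oracle_average_linkage_heights(pts),
                 tolerance = 1e-10)
  }
  # nearest pair merges first; duplicate rows merge at height zero
  pts <- rbind(a = c(0, 0), b = c(1, 0), c = c(10, 0))
  cl <- cluster_profiles(pts)
  expect_equal(cl$tree$merge[1, ], c(-1, -2))
  pts <- rbind(c(1, 1), c(1, 1), c(5, 5))
  expect_equal(cluster_profiles(pts)$heights[[1]], 0)
  expect_error(cluster_profiles(matrix(c(1, NA, 2, 3), 2, 2)), "NA")
})

test_that("ANOVA F and p match hand sums of squares and aov", {
  at <- anova_tukey(c(1, 2, 3, 2, 3, 4, 7, 8, 9),
                    rep(c("g1", "g2", "g3"), each = 3))
  expect_equal(at$F, 31) # SSB = 62 (df 2), SSW = 6 (df 6)
  expect_equal(at$p, pf(31, 2, 6, lower.tail = FALSE))

  set.seed(104)
  for (i in 1:20) {
    g <- factor(rep(0:3, c(3, 8, 8, 7)))
    y <- rnorm(26, mean = as.integer(g) * runif(1))
    at <- anova_tukey(y, g)
    expect_equal(at$F, oracle_anova_f(split(y, g)), tolerance = 1e-10)
    fit <- stats::aov(y ~ g)
    tk <- stats::TukeyHSD(fit)$g
    expect_equal(sort(at$tukey$p_adj), sort(unname(tk[, "p adj"])),
                 tolerance = 1e-8)
  }
})

test_that("degenerate ANOVA inputs are defined", {
  at <- anova_tukey(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(at$F, 0)
  expect_equal(at$p, 1)
  expect_equal(length(unique(at$letters)), 1L)
})

test_that("compact letters are consistent with the Tukey decisions", {
  set.seed(105)
  for (i in 1:30) {
    g <- factor(rep(1:4, each = sample(3:6, 1)))
    y <- rnorm(length(g), mean = sample(0:6, 4, replace = TRUE)[g])
    at <- anova_tukey(y, g)
    for (r in seq_len(nrow(at$tukey))) {
      shared <- any(strsplit(at$letters[[at$tukey$group1[[r]]]], "")[[1]] %in%
                      strsplit(at$letters[[at$tukey$group2[[r]]]], "")[[1]])
      if (at$tukey$p_adj[[r]] < 0.05) {
        expect_false(shared)
      } else {
        expect_true(shared)
      }
    }
  }
})

test_that("profile classification follows the group definitions", {
  expect_equal(classify_profile(c(10, 8, 5, 2)), "I")
  expect_equal(classify_profile(c(2, 3, 4, 10)), "II")
  expect_equal(classify_profile(c(8, 8, 2, 8)), "III")
  expect_equal(classify_profile(c(2, 3, 10, 4)), "none") # stage-2 peak
  # invariant to uniform scaling
  expect_equal(classify_profile(c(10, 8, 5, 2) * 37), "I")
  # generator multiplier profiles recover their labels noiselessly
  e <- 2.5
  expect_equal(classify_profile(c(e, e^(2 / 3), e^(1 / 3), 1)), "I")
  expect_equal(classify_profile(c(1, 1, 1, e)), "II")
  expect_equal(classify_profile(c(e, e, 1, e)), "III")
  expect_error(classify_profile(c(1, 2, 3)), "four stages")
})

test_that("de_scan is invariant to sample permutation and alpha = 0", {
  ct <- gen_counts(n_genes = 30, n_de = 9, n_background = 100, seed = 106)
  tp <- tpm(ct$counts, ct$lengths)
  de1 <- de_scan(tp$values, ct$meta, npp_ids = ct$npp_ids)
  set.seed(1); perm <- sample(ncol(tp$values))
  de2 <- de_scan(tp$values[, perm], ct$meta[perm, ], npp_ids = ct$npp_ids)
  expect_equal(de1, de2)
  de0 <- de_scan(tp$values, ct$meta, npp_ids = ct$npp_ids, alpha = 0)
  expect_equal(sum(de0$significant), 0L)
})
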