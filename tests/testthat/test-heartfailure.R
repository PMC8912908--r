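test_that("RBP PCA is deterministic with interpretable variance", {
  set.seed(51)
  v <- matrix(rlnorm(20 * 12, log(20), 1), 20, 12,
              dimnames = list(sprintf("RBP%02d", 1:20),
                              sprintf("s%02d", 1:12)))
  v[, 12] <- v[, 11]                     # duplicated sample
  tpm <- FeatureMatrix(v, "tpm")
  pca <- jointRbpPca(tpm, rownames(v))
  expect_equal(pca$scores["s11", ], pca$scores["s12", ], tolerance = 1e-10)
  expect_true(all(diff(pca$var_explained) <= 1e-12))
  expect_lte(sum(pca$var_explained), 1 + 1e-9)
  ## rank-2 structure on the log2 scale: PC3+ variance ~ 0
  u <- rnorm(12); w <- rnorm(12)
  x <- outer(runif(20, 6, 8), rep(1, 12)) +
    outer(runif(20, 0.1, 0.3), u) + outer(runif(20, 0.1, 0.3), w)
  mix <- 2^x - 1
  dimnames(mix) <- dimnames(v)
  pca2 <- jointRbpPca(FeatureMatrix(mix, "tpm"), rownames(v))
  expect_lt(sum(pca2$var_explained[-(1:2)]), 1e-9)
  ## constant RBP dropped with warning; too few RBPs error
  v2 <- v; v2["RBP01", ] <- 7
  expect_warning(jointRbpPca(FeatureMatrix(v2, "tpm"), rownames(v2)),
                 "RBP01")
  expect_error(jointRbpPca(tpm, rownames(v)[1:5]), ">= 10")
})

hfSampleTable <- function(nGroup = 6, nPairs = 3) {
  data.frame(
    sample_id = c(sprintf("F%02d", 1:nGroup), sprintf("A%02d", 1:nGroup),
                  sprintf("pre%d", 1:nPairs), sprintf("post%d", 1:nPairs)),
    subject_id = c(sprintf("sf%02d", 1:nGroup), sprintf("sa%02d", 1:nGroup),
                   sprintf("hf%d", 1:nPairs), sprintf("hf%d", 1:nPairs)),
    tissue = rep(c("iPSC-CVPC", "adult_heart", "HF_pre", "HF_post"),
                 c(nGroup, nGroup, nPairs, nPairs)),
    sex = "F", total_reads = 1e7, pct_autosomal = 0.8, pct_mito = 0.1,
    stringsAsFactors = FALSE)
}

test_that("PC distances separate constructed pre/post geometry", {
  set.seed(52)
  samples <- hfSampleTable()
  ## fetal cluster at (0, 0), adult cluster at (10, 0); pre-LVAD samples sit
  ## on the fetal centroid, post-LVAD on the adult centroid
  pcs <- rbind(matrix(rnorm(12, 0, 0.1), 6, 2),
               cbind(rnorm(6, 10, 0.1), rnorm(6, 0, 0.1)),
               matrix(rep(c(0, 0), each = 3), 3, 2),
               matrix(rep(c(10, 0), each = 3), 3, 2))
  rownames(pcs) <- samples$sample_id
  colnames(pcs) <- c("PC1", "PC2")
  gd <- groupDistances(pcs, samples, K = 2)
  tf <- gd$paired_tests[gd$paired_tests$group == "iPSC-CVPC", ]
  ta <- gd$paired_tests[gd$paired_tests$group == "adult_heart", ]
  expect_lt(tf$p, 0.01); expect_lt(ta$p, 0.01)
  expect_lt(tf$mean_diff, 0)            # pre closer to fetal
  expect_gt(ta$mean_diff, 0)            # post closer to adult
  ## distances are invariant under rotation of the PC plane
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  gd2 <- groupDistances(pcs %*% R, samples, K = 2)
  expect_equal(gd$distances$pre, gd2$distances$pre, tolerance = 1e-10)
  ## pre == post: differences zero, p reported as 1
  pcs2 <- pcs; pcs2[13:15, ] <- pcs2[16:18, ]
  gd3 <- groupDistances(pcs2, samples, K = 2)
  expect_true(all(gd3$paired_tests$p == 1))
  ## unpaired HF samples are excluded with a warning
  s2 <- samples[-which(samples$sample_id == "post3"), ]
  expect_warning(groupDistances(pcs[s2$sample_id, ], s2, K = 2), "hf3")
})

test_that("paired t on distances reproduces the closed form", {
  samples <- hfSampleTable(nGroup = 1, nPairs = 3)
  ## one fetal reference sample at the origin; pre/post at chosen offsets so
  ## the paired differences are (3, 4, 8)
  pcs <- matrix(0, 8, 2,
                dimnames = list(samples$sample_id, c("PC1", "PC2")))
  pcs["A01", ] <- c(100, 0)
  pcs[c("pre1", "pre2", "pre3"), 1] <- c(4, 6, 10)
  pcs[c("post1", "post2", "post3"), 1] <- c(1, 2, 2)
  gd <- groupDistances(pcs, samples, groups = "iPSC-CVPC", K = 2)
  d <- c(3, 4, 8)
  tExp <- mean(d) / (sd(d) / sqrt(3))
  pExp <- 2 * pt(-abs(tExp), df = 2)
  expect_equal(gd$paired_tests$t, tExp, tolerance = 1e-10)
  expect_equal(gd$paired_tests$p, pExp, tolerance = 1e-10)
})

test_that("RBP location test handles symmetric, degenerate and small input", {
  x <- c(-2, -1, -0.5, 0.5, 1, 2)
  res <- rbpEffectSizeLocationTest(x)
  expect_equal(res$mean, 0)
  expect_equal(res$p, 1)
  res2 <- rbpEffectSizeLocationTest(rep(0.5, 10))
  expect_true(res2$degenerate)
  expect_equal(res2$p, 0)
  expect_error(rbpEffectSizeLocationTest(c(1, 2)), ">= 3")
  ## power: a modest shift is detected at n = 122
  set.seed(53)
  hits <- sum(replicate(50, rbpEffectSizeLocationTest(
    rnorm(122, 0.3, 0.5))$p < 0.05))
  expect_gte(hits, 48)
})

test_that("reversion statistic counts same-trend isoforms", {
  de <- data.frame(feature_id = sprintf("i%03d", 1:100),
                   effect = c(rnorm(50, 2), rnorm(50, 0, 0.1)),
                   p_adj = rep(c(0.001, 0.8), each = 50),
                   stringsAsFactors = FALSE)
  ## identical runs: A = all DE isoforms, r = 1
  res <- reversionStatistic(de, de)
  expect_equal(unname(res$counts["A"]), 50)
  expect_equal(unname(res$counts["C"]), 0)
  expect_equal(res$r, 1)
  expect_gt(res$odds_ratio, 1)
  ## opposite signs never count as same trend
  flip <- de; flip$effect <- -flip$effect
  res2 <- reversionStatistic(de, flip)
  expect_equal(unname(res2$counts["A"]), 0)
  disjoint <- de; disjoint$feature_id <- sprintf("z%03d", 1:100)
  expect_error(reversionStatistic(de, disjoint), "empty")
})
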