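test_that("linear DE equals the normal-equations oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n1 <- 12; n2 <- 14; n <- n1 + n2
    samples <- twoTissueSamples(n1, n2, seed = seed)
    Y <- matrix(rnorm(8 * n), 8, n,
                dimnames = list(sprintf("f%d", 1:8), samples$sample_id))
    norm <- FeatureMatrix(Y, "normalized")
    de <- fitLinearDE(norm, samples, "iPSC-CVPC", "adult_heart")
    X <- cbind(1, as.numeric(samples$tissue == "iPSC-CVPC"),
               covariateMatrix(samples))
    for (f in c("f1", "f5")) {
      o <- olsOracle(Y[f, ], X, 2)
      row <- de[de$feature_id == f, ]
      expect_equal(row$effect, unname(o["beta"]), tolerance = 1e-8)
      expect_equal(row$se, unname(o["se"]), tolerance = 1e-8)
      expect_equal(row$p, unname(o["p"]), tolerance = 1e-8)
    }
  }
})

test_that("noise-free group effect is recovered exactly", {
  samples <- twoTissueSamples(10, 10, seed = 2)
  tvec <- as.numeric(samples$tissue == "iPSC-CVPC")
  Y <- matrix(2 * tvec, 1, 20, dimnames = list("f1", samples$sample_id))
  ## covariate orthogonal to the tissue indicator, response noise-free
  C <- cbind(z1 = residuals(lm(rnorm(20) ~ tvec)))
  de <- fitLinearDE(FeatureMatrix(Y, "normalized"), samples, "iPSC-CVPC",
                    "adult_heart", covariates = C)
  expect_equal(de$effect, 2, tolerance = 1e-12)
})

test_that("rank-deficient designs are rejected with the offending column", {
  samples <- twoTissueSamples(8, 8, seed = 3)
  samples$pct_autosomal <- 0.8          # constant -> collinear w/ intercept
  Y <- matrix(rnorm(16), 1, 16, dimnames = list("f", samples$sample_id))
  expect_error(fitLinearDE(FeatureMatrix(Y, "normalized"), samples,
                           "iPSC-CVPC", "adult_heart"), "pct_autosomal")
})

test_that("specificity classification applies strict ratio and p thresholds", {
  samples <- twoTissueSamples(4, 4, seed = 1)
  mk <- function(m1, m2) {
    v <- matrix(rep(c(m1, m2), c(4, 4)), 1, 8,
                dimnames = list("f1", samples$sample_id))
    FeatureMatrix(v, "tpm")
  }
  de <- data.frame(feature_id = "f1", effect = 1, se = 0.1, t = 10,
                   p = 1e-12, p_adj = 1e-10, stringsAsFactors = FALSE)
  ## log2((15+1)/(3+1)) = 2 exactly: NOT specific (strict >)
  out <- classifySpecific(de, mk(15, 3), samples, "iPSC-CVPC", "adult_heart")
  expect_equal(out$log2_ratio, 2)
  expect_equal(out$class, "DE_only")
  ## log2(64/4) = 4: tissue1-specific
  out2 <- classifySpecific(de, mk(63, 3), samples, "iPSC-CVPC", "adult_heart")
  expect_equal(out2$class, "tissue1_specific")
  ## non-significant stays not_DE regardless of ratio
  de$p_adj <- 0.2
  out3 <- classifySpecific(de, mk(63, 3), samples, "iPSC-CVPC", "adult_heart")
  expect_equal(out3$class, "not_DE")
  ## usage kind switches the pseudocount to 0.01
  u <- matrix(rep(c(0.63, 0.03), c(4, 4)), 1, 8,
              dimnames = list("f1", samples$sample_id))
  de$p_adj <- 1e-10
  out4 <- classifySpecific(de, FeatureMatrix(u, "usage"), samples,
                           "iPSC-CVPC", "adult_heart")
  expect_equal(out4$log2_ratio, log2(0.64 / 0.04))
})

test_that("ridge at lambda = 0 reproduces OLS on a full-rank design", {
  set.seed(8)
  samples <- twoTissueSamples(20, 20, seed = 8)
  P <- matrix(runif(40 * 3, 0.1, 0.5), 40, 3,
              dimnames = list(samples$sample_id, c("ctA", "ctB", "ctC")))
  Y <- matrix(rnorm(5 * 40), 5, 40,
              dimnames = list(sprintf("f%d", 1:5), samples$sample_id))
  norm <- FeatureMatrix(Y, "normalized")
  rr <- fitRidgeDE(norm, samples, "iPSC-CVPC", "adult_heart", P, lambda = 0)
  X0 <- cbind(tissue = as.numeric(samples$tissue == "iPSC-CVPC"),
              covariateMatrix(samples), P)
  Xs <- scale(X0)
  for (f in c("f1", "f4")) {
    fit <- lm(Y[f, ] ~ Xs)
    co <- summary(fit)$coefficients
    row <- rr[rr$feature_id == f & rr$coefficient == "tissue", ]
    expect_equal(row$effect, unname(co["Xstissue", 1]), tolerance = 1e-8)
    expect_equal(row$se, unname(co["Xstissue", 2]), tolerance = 1e-8)
    rowC <- rr[rr$feature_id == f & rr$coefficient == "ctB", ]
    expect_equal(rowC$effect, unname(co["XsctB", 1]), tolerance = 1e-8)
  }
})

test_that("ridge handles simplex-collinear proportions and shrinks with lambda", {
  set.seed(9)
  samples <- twoTissueSamples(15, 15, seed = 9)
  P <- t(apply(matrix(rgamma(30 * 6, 2), 30), 1, function(x) x / sum(x)))
  dimnames(P) <- list(samples$sample_id, paste0("ct", 1:6))
  Y <- matrix(rnorm(4 * 30), 4, 30,
              dimnames = list(sprintf("f%d", 1:4), samples$sample_id))
  norm <- FeatureMatrix(Y, "normalized")
  rr <- suppressWarnings(          # boundary lambda on pure-noise features
    fitRidgeDE(norm, samples, "iPSC-CVPC", "adult_heart", P))
  expect_true(all(is.finite(rr$effect)))
  expect_true(all(is.finite(rr$se)))
  ## coefficient norm is monotone non-increasing in lambda
  norms <- sapply(c(0.01, 1, 100, 1e4), function(l) {
    r <- fitRidgeDE(norm, samples, "iPSC-CVPC", "adult_heart", P, lambda = l)
    sqrt(sum(r$effect[r$feature_id == "f1"]^2))
  })
  expect_true(all(diff(norms) <= 1e-10))
  expect_lt(norms[4], 0.01 * norms[1] + 1e-6)
  expect_error(fitRidgeDE(norm, samples[1:8, ], "iPSC-CVPC", "adult_heart",
                          P), "at least 10")
})

test_that("effect-size GSEA detects shifted sets and skips degenerate ones", {
  set.seed(10)
  eff <- rnorm(500)
  names(eff) <- sprintf("g%03d", 1:500)
  sets <- list(SHIFTED = names(eff)[1:50], NULLSET = names(eff)[51:100])
  eff[sets$SHIFTED] <- eff[sets$SHIFTED] + 1.5
  res <- gseaEffectSizeTTest(eff, sets)
  expect_lt(res$p[res$set == "SHIFTED"], 1e-6)
  expect_gt(res$p[res$set == "NULLSET"], 1e-4)
  expect_warning(
    res2 <- gseaEffectSizeTTest(eff, list(ALL = names(eff))), "skipped")
  expect_null(res2)
})

test_that("isoform-DE gene-set Fisher matches the enumeration oracle", {
  sets <- list(S = sprintf("g%02d", 1:20))
  ## table (10,10 / 10,10): OR 1, p 1
  g1 <- sprintf("g%02d", 1:20)          # 10 in S, 10 out
  res <- fisherIsoformGeneSet(c(sprintf("g%02d", 1:10),
                                sprintf("x%02d", 1:10)),
                              c(sprintf("g%02d", 11:20),
                                sprintf("x%02d", 11:20)), sets)
  expect_equal(res$odds_ratio, 1, tolerance = 1e-9)
  expect_equal(res$p, 1)
  ## table (9,1 / 1,9): conditional MLE equals the enumeration oracle
  spec <- c(sprintf("g%02d", 1:9), "x01")
  node <- c("g10", sprintf("x%02d", 2:10))
  res2 <- fisherIsoformGeneSet(spec, node, sets)
  o <- fisherOracle(9, 1, 1, 9)
  ## both estimates are numeric optimizations of the same likelihood
  expect_equal(res2$odds_ratio, o$or, tolerance = 2e-3)
  expect_equal(res2$p, o$p, tolerance = 1e-10)
  ## disjoint set skipped; empty group errors
  expect_null(fisherIsoformGeneSet(c("a"), c("b"), list(Z = "zz")))
  expect_error(fisherIsoformGeneSet(character(0), c("b"), sets), "nonempty")
})
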