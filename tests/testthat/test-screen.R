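makeToyMatrix <- function() {
  # 3 features x 5 samples with hand-set values
  v <- rbind(f1 = c(1, 2, 3, 5, 6),
             f2 = c(4, 4, 4, 4, 4),
             f3 = c(10, 9, 8, 2, 1))
  colnames(v) <- paste0("s", 1:5)
  ExpressionMatrix(v, setNames(c("A", "A", "A", "B", "B"), colnames(v)))
}

test_that("screen statistics match direct formula evaluation", {
  res <- differentialScreen(makeToyMatrix(), "A", "B", fcMin = 2)
  # hand computation, feature f1: means 2 and 5.5, pooled var
  d <- 5.5 - 2
  sp2 <- ((3 - 1) * var(c(1, 2, 3)) + (2 - 1) * var(c(5, 6))) / 3
  tstat <- d / sqrt(sp2 * (1 / 3 + 1 / 2))
  expect_equal(res$log2fc[1], d)
  expect_equal(res$t[1], tstat, tolerance = 1e-12)
  expect_equal(res$p_value[1], 2 * pt(-abs(tstat), 3), tolerance = 1e-12)
  expect_equal(res$fold_change, 2^abs(res$log2fc))
  # cross-check against stats::t.test per feature
  tt <- t.test(c(5, 6), c(1, 2, 3), var.equal = TRUE)
  expect_equal(res$p_value[1], tt$p.value, tolerance = 1e-12)
  # constant feature: p = 1, never passes
  expect_equal(res$p_value[2], 1)
  expect_false(res$passes[2])
  # down-regulated feature passes the symmetric filter
  expect_identical(res$direction[3], "down")
  expect_true(res$passes[3])
})

test_that("swapping groups negates log2fc and preserves p, fdr, passes", {
  sim <- simulateExpression(100, 10, seed = 21)
  a <- differentialScreen(sim$mirna, "RDEB-KC", "RDEB-cSCC")
  b <- differentialScreen(sim$mirna, "RDEB-cSCC", "RDEB-KC")
  expect_equal(b$log2fc, -a$log2fc, tolerance = 1e-12)
  expect_equal(b$p_value, a$p_value, tolerance = 1e-12)
  expect_equal(b$fdr, a$fdr, tolerance = 1e-12)
  expect_identical(b$passes, a$passes)
})

test_that("screen rejects invalid group specifications", {
  sim <- simulateExpression(10, 10, groupSizes = c(A = 1, B = 5), seed = 1)
  expect_error(differentialScreen(sim$mirna, "A", "B"), "fewer than 2")
  expect_error(differentialScreen(sim$mirna, "B", "C"), "unknown group")
  expect_error(differentialScreen(sim$mirna, "B", "B"), "disjoint")
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhFdr(0.5), 0.5)
  expect_error(bhFdr(c(0.1, 1.2)), "\\[0, 1\\]")
  # property: matches the brute-force step-up on random inputs
  set.seed(42)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bhFdr(p), bruteBH(p), tolerance = 1e-12)
  }
  # sorted input gives nondecreasing output
  p <- sort(runif(20))
  expect_true(!is.unsorted(bhFdr(p)))
})

test_that("null screen has calibrated p-values", {
  set.seed(7)
  frac <- replicate(25, {
    sim <- simulateExpression(2000, 5, noiseSd = 0.3,
                              seed = sample.int(1e6, 1))
    res <- differentialScreen(sim$mirna, "RDEB-KC", "RDEB-cSCC")
    mean(res$p_value <= 0.05)
  })
  n <- 25 * 2000
  ci <- 0.05 + c(-1, 1) * qnorm(0.995) * sqrt(0.05 * 0.95 / n)
  expect_gt(mean(frac), ci[1])
  expect_lt(mean(frac), ci[2])
})

test_that("planted 2.2-fold features are recovered at the oracle rate", {
  # binding constraint is the estimated-fold gate:
  # log2fc_hat ~ N(1.1375, 0.3 * sqrt(1/4 + 1/6)), so
  # P(pass) ~= 0.72 (computed by direct formula simulation)
  set.seed(13)
  rec <- replicate(60, {
    sim <- simulateExpression(500, 5,
                              plantedFC = setNames(rep(log2(2.2), 20),
                                                   paste0("hsa-miR-", 1:20)),
                              noiseSd = 0.3, seed = sample.int(1e6, 1))
    res <- differentialScreen(sim$mirna, "RDEB-KC", "RDEB-cSCC")
    sel <- selectSignificant(res)
    mean(paste0("hsa-miR-", 1:20) %in% sel)
  })
  se <- sd(rec) / sqrt(length(rec))
  expect_lt(abs(mean(rec) - 0.72), 4 * se + 0.02)
})

test_that("selectSignificant equals brute-force re-evaluation of the filter", {
  sim <- simulateExpression(100, 5,
                            plantedFC = setNames(rep(1.5, 10),
                                                 paste0("hsa-miR-", 1:10)),
                            seed = 3)
  res <- differentialScreen(sim$mirna, "RDEB-KC", "RDEB-cSCC")
  manual <- res$feature_id[res$fold_change >= 2 & res$p_value <= 0.05 &
                             res$fdr <= 0.2]
  expect_identical(selectSignificant(res), manual)
  allNull <- res
  allNull$passes <- rep(FALSE, nrow(res))
  expect_identical(selectSignificant(allNull), character(0))
})

test_that("PCA satisfies reconstruction and orthonormality invariants", {
  sim <- simulateExpression(30, 5, groupSizes = c(A = 4, B = 4), seed = 5)
  pc <- pcaScreen(sim$mirna)
  L <- pc$loadings
  expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pc$explainedVariance) <= 1e-10))
  v <- exprValues(sim$mirna)
  totalVar <- sum(apply(v, 1, var))
  expect_equal(sum(pc$explainedVariance), totalVar, tolerance = 1e-6)
  # reconstruction: scores %*% t(loadings) + center = original
  rec <- pc$scores %*% t(L) + matrix(pc$center, ncol(v), nrow(v),
                                     byrow = TRUE)
  expect_equal(rec, t(v), tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pcaScreen(sim$mirna, nComponents = 10), "nComponents")
})

test_that("group separation is high for distant clusters, errors degenerate", {
  sim <- simulateExpression(50, 5, groupSizes = c(KC = 5, cSCC = 5),
                            plantedFC = setNames(rep(5, 25),
                                                 paste0("hsa-miR-", 1:25)),
                            noiseSd = 0.3, seed = 6)
  pc <- pcaScreen(sim$mirna, nComponents = 2)
  sep <- groupSeparation(pc$scores, sampleGroups(sim$mirna))
  expect_gt(sep, 0.9)
  same <- matrix(1, 4, 2, dimnames = list(paste0("s", 1:4), NULL))
  expect_error(groupSeparation(same, c("A", "A", "B", "B")), "identical")
})
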