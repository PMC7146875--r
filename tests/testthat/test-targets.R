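test_that("repository merge resolves evidence and deduplicates", {
  v <- data.frame(mirna_id = "m1", gene_id = c("A", "B", "C"))
  p <- data.frame(mirna_id = "m1", gene_id = c("C", "D", "E"))
  repo <- mergeRepositories(list(val = v, pred = p),
                            evidence = c("validated", "predicted"))
  r <- repositoryRecords(repo)
  expect_identical(length(repo), 5L)
  expect_identical(r$evidence[r$gene_id == "C"], "both")
  expect_setequal(r$evidence[r$gene_id %in% c("A", "B")], "validated")

  # idempotence: merging a table with itself changes nothing
  r2 <- repositoryRecords(mergeRepositories(list(a = v, a2 = v)))
  expect_identical(r2[, c("mirna_id", "gene_id", "evidence")],
                   repositoryRecords(mergeRepositories(list(a = v)))[,
                     c("mirna_id", "gene_id", "evidence")])

  expect_identical(length(mergeRepositories(list())), 0L)
  expect_error(mergeRepositories(list(bad = data.frame(x = 1))),
               "mirna_id/gene_id")
})

test_that("DE-repository intersection equals brute-force double loop", {
  repo <- mergeRepositories(list(v = data.frame(
    mirna_id = "m1", gene_id = c("B", "C", "D"))))
  expect_identical(intersectDeTargets(c("A", "B", "C"), repo, "m1"),
                   c("B", "C"))
  expect_identical(intersectDeTargets(c("X", "Y"), repo, "m1"),
                   character(0))
  expect_error(intersectDeTargets("A", repo, character(0)), "nonempty")

  # 500-gene random instance vs literal double loop
  set.seed(31)
  genes <- paste0("G", 1:500)
  de <- sample(genes, 200)
  tab <- data.frame(mirna_id = sample(c("m1", "m2", "m3"), 400,
                                      replace = TRUE),
                    gene_id = sample(genes, 400, replace = TRUE))
  repo <- mergeRepositories(list(t = tab))
  fam <- c("m1", "m2")
  got <- intersectDeTargets(de, repo, fam)
  brute <- de[vapply(de, function(g)
    any(tab$gene_id == g & tab$mirna_id %in% fam), logical(1))]
  expect_identical(got, brute)
})

test_that("family signal is the per-sample mean of member rows", {
  v <- rbind(`hsa-miR-10a` = c(2, 4), `hsa-miR-10b` = c(4, 6))
  colnames(v) <- c("s1", "s2")
  em <- ExpressionMatrix(v, setNames(c("A", "A"), colnames(v)))
  expect_equal(mirFamilySignal(em, rownames(v)), c(s1 = 3, s2 = 5))
  expect_equal(mirFamilySignal(em, "hsa-miR-10a"), c(s1 = 2, s2 = 4))
  expect_error(mirFamilySignal(em, "hsa-miR-10c"), "missing")
})

test_that("inverse-correlation ranking orders by ascending r with ties", {
  sim <- simulateExpression(5, 50, groupSizes = c(A = 5, B = 5),
                            plantedTargets = data.frame(
                              mir = "hsa-miR-1", gene = "GENE1",
                              slope = -1, residual_sd = 0),
                            seed = 41)
  sig <- mirFamilySignal(sim$mirna, "hsa-miR-1")
  rk <- inverseCorrelationRank(sig, sim$mrna, paste0("GENE", 1:50), k = 20)
  expect_identical(rk$gene_id[1], "GENE1")
  expect_equal(rk$correlation_r[1], -1, tolerance = 1e-9)
  expect_identical(rk$rank, 1:20)
  expect_equal(nrow(rk), 20L)
  expect_true(!is.unsorted(rk$correlation_r))

  # fewer candidates than k: all returned
  expect_equal(nrow(inverseCorrelationRank(sig, sim$mrna,
                                           paste0("GENE", 1:5))), 5L)
  expect_error(inverseCorrelationRank(sig[1:2], sim$mrna, "GENE1"),
               "3 matched")
})

test_that("ranking is invariant to positive affine transforms of a candidate", {
  set.seed(43)
  for (i in 1:20) {
    sim <- simulateExpression(3, 30, groupSizes = c(A = 4, B = 4),
                              seed = sample.int(1e6, 1))
    sig <- mirFamilySignal(sim$mirna, "hsa-miR-1")
    cand <- paste0("GENE", 1:30)
    base <- inverseCorrelationRank(sig, sim$mrna, cand, k = 30)
    pick <- sample(cand, 1)
    v <- exprValues(sim$mrna)
    v[pick, ] <- 2.5 * v[pick, ] + 7
    em2 <- ExpressionMatrix(v, sampleGroups(sim$mrna))
    tr <- inverseCorrelationRank(sig, em2, cand, k = 30)
    expect_identical(tr$gene_id, base$gene_id)
  }
})

test_that("planted inverse targets are recovered in the top-20", {
  set.seed(47)
  hits <- replicate(30, {
    planted <- data.frame(mir = "hsa-miR-10b-5p",
                          gene = paste0("TGT", 1:15),
                          slope = -1, residual_sd = 0.2)
    sim <- simulateExpression(5, 114, groupSizes = c(KC = 5, SCC = 5),
                              plantedFC = c(`hsa-miR-10b-5p` = 1.14),
                              plantedTargets = planted,
                              seed = sample.int(1e6, 1))
    sig <- mirFamilySignal(sim$mirna, "hsa-miR-10b-5p")
    rk <- inverseCorrelationRank(sig, sim$mrna, rownames(sim$mrna), k = 20)
    sum(paste0("TGT", 1:15) %in% rk$gene_id)
  })
  expect_gte(median(hits), 13)
})

test_that("positive-slope decoys never enter the top-k", {
  set.seed(53)
  for (i in 1:25) {
    sim <- simulateExpression(5, 40, groupSizes = c(A = 5, B = 5),
                              plantedTargets = data.frame(
                                mir = "hsa-miR-1",
                                gene = c("NEG1", "POS1"),
                                slope = c(-1, 1), residual_sd = 0.2),
                              seed = sample.int(1e6, 1))
    sig <- mirFamilySignal(sim$mirna, "hsa-miR-1")
    rk <- inverseCorrelationRank(sig, sim$mrna, rownames(sim$mrna), k = 5)
    expect_false("POS1" %in% rk$gene_id)
  }
})

test_that("over-representation p equals the exact hypergeometric sum", {
  universe <- paste0("G", 1:20)
  sets <- list(S = paste0("G", 1:5))
  hits <- paste0("G", c(1, 2, 6, 7))
  res <- overrepresentation(hits, sets, universe)
  # P(X >= 2), X ~ Hypergeom(N = 20, m = 5, k = 4), by enumeration
  pExact <- sum(choose(5, 2:4) * choose(15, 4 - 2:4)) / choose(20, 4)
  expect_equal(res$p_value, pExact, tolerance = 1e-12)
  expect_equal(res$overlap, 2L, ignore_attr = TRUE)
  expect_equal(res$expected, 4 * 5 / 20)

  # extreme case: hits identical to a set in a large universe
  big <- paste0("G", 1:2000)
  r2 <- overrepresentation(paste0("G", 1:50), list(S = paste0("G", 1:50)),
                           big)
  expect_lt(r2$p_value, 1e-20)
  expect_equal(r2$overlap, 50L, ignore_attr = TRUE)

  expect_error(overrepresentation(c("G1", "ZZ"), sets, universe),
               "outside the universe")
})

test_that("over-representation is calibrated under the null", {
  N <- 2000; mSet <- 100; kHit <- 100
  universe <- paste0("G", seq_len(N))
  sets <- list(S = paste0("G", seq_len(mSet)))
  exact <- exactOraRejectionRate(N, mSet, kHit, 0.05)
  set.seed(59)
  rej <- mean(replicate(400, {
    overrepresentation(sample(universe, kHit), sets, universe)$p_value <=
      0.05
  }))
  ci <- qnorm(0.995) * sqrt(exact * (1 - exact) / 400)
  expect_lt(abs(rej - exact), ci + 1e-9)
})
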