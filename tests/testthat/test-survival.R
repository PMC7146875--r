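test_that("quantile stratification matches hand-computed cuts", {
  # Q_0.75 of 1..8 = 6.25 by linear interpolation; high = {7, 8}
  lab <- stratifyByQuantile(1:8, 0.75)
  expect_identical(which(lab == "high"), c(7L, 8L))
  # Q_0.5 of {1,2,3,4} = 2.5; high = {3, 4}
  expect_identical(which(stratifyByQuantile(c(1, 2, 3, 4), 0.5) == "high"),
                   c(3L, 4L))
  # strictly increasing transform leaves labels unchanged
  x <- rnorm(20)
  expect_identical(stratifyByQuantile(x), stratifyByQuantile(exp(x)))
  expect_error(stratifyByQuantile(rep(2, 10)), "all expression values")
  expect_error(stratifyByQuantile(c(1, 2, 3)), "at least 4")
})

test_that("KM estimate matches hand product-limit computations", {
  # no censoring: S = 1 - ECDF
  km <- kmEstimate(c(2, 4), c(TRUE, TRUE))
  expect_equal(km@surv, c(0.5, 0))
  # censored at 1, event at 2: risk set of 1 at t = 2, S(2) = 0
  km2 <- kmEstimate(c(1, 2), c(FALSE, TRUE))
  expect_equal(km2@time, 2)
  expect_equal(km2@nRisk, 1)
  expect_equal(km2@surv, 0)
  expect_error(kmEstimate(c(1, 2), c(FALSE, FALSE)), "at least one event")
  expect_error(kmEstimate(c(0, 1), c(TRUE, TRUE)), "positive")
})

test_that("KM equals brute-force risk-set recomputation and survfit", {
  skip_if_not_installed("survival")
  set.seed(61)
  for (i in 1:20) {
    inst <- randomSurvivalInstance(10)
    if (!any(inst$event)) next
    km <- kmEstimate(inst$time, inst$event)
    ref <- bruteKM(inst$time, inst$event)
    expect_equal(km@time, ref$time)
    expect_equal(km@surv, ref$surv, tolerance = 1e-12)
    sf <- survival::survfit(survival::Surv(inst$time, inst$event) ~ 1)
    expect_equal(km@surv, summary(sf, times = km@time)$surv,
                 tolerance = 1e-10)
  }
})

test_that("KM with zero censoring equals 1 - ECDF at every time", {
  set.seed(62)
  t <- sample(1:50, 30, replace = TRUE)
  km <- kmEstimate(t, rep(TRUE, 30))
  ec <- ecdf(t)
  expect_equal(km@surv, 1 - ec(km@time), tolerance = 1e-12)
})

test_that("log-rank matches brute force and survdiff; label-symmetric", {
  skip_if_not_installed("survival")
  set.seed(63)
  for (i in 1:50) {
    inst <- randomSurvivalInstance(12)
    if (!any(inst$event) || length(unique(inst$group)) < 2) next
    lr <- logrankTest(inst$time, inst$event, inst$group)
    expect_equal(lr@chisq, bruteLogrank(inst$time, inst$event, inst$group),
                 tolerance = 1e-10)
    sd <- survival::survdiff(survival::Surv(inst$time, inst$event) ~
                               inst$group)
    expect_equal(lr@chisq, sd$chisq, tolerance = 1e-8)
    # expected deaths sum to observed deaths
    expect_equal(sum(lr@expected), sum(lr@observed), tolerance = 1e-10)
    # swapping labels leaves chi-square unchanged
    swapped <- ifelse(inst$group == "a", "b", "a")
    expect_equal(logrankTest(inst$time, inst$event, swapped)@chisq,
                 lr@chisq, tolerance = 1e-10)
  }
})

test_that("log-rank is exactly null on duplicated groups and errors on one", {
  t <- c(1, 3, 5, 7); e <- c(TRUE, TRUE, FALSE, TRUE)
  lr <- logrankTest(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(lr@chisq, 0, tolerance = 1e-12)
  expect_equal(lr@p, 1)
  expect_error(logrankTest(t, e, rep("a", 4)), "two groups")
})

test_that("A-vs-B separated events match enumerated risk sets", {
  lr <- logrankTest(1:6, rep(TRUE, 6), rep(c("A", "B"), each = 3))
  expect_equal(lr@chisq, bruteLogrank(1:6, rep(TRUE, 6),
                                      rep(c("A", "B"), each = 3)),
               tolerance = 1e-12)
  expect_gt(lr@chisq, 0)
})

test_that("restricted mean survival reduces to known areas", {
  # no censoring, tau = max time: arithmetic mean of times
  km <- kmEstimate(c(1, 3, 5), rep(TRUE, 3))
  expect_equal(meanSurvival(km), 3, tolerance = 1e-12)
  # step curve 1 on [0,2), 0.5 on [2,4), 0 after; area to tau = 4 is 3
  km2 <- kmEstimate(c(2, 4), c(TRUE, TRUE))
  expect_equal(meanSurvival(km2, tau = 4), 3, tolerance = 1e-12)
  # S = 1 up to tau before the first event: area = tau
  km3 <- kmEstimate(c(10, 12), c(TRUE, TRUE))
  expect_equal(meanSurvival(km3, tau = 5), 5, tolerance = 1e-12)
  expect_error(meanSurvival(km3, tau = -1), "tau")
  # general random instance equals trapezoid-free rectangle sum by hand
  set.seed(64)
  t <- rexp(20, 0.1); e <- runif(20) < 0.7
  if (any(e)) {
    km4 <- kmEstimate(t, e)
    tau <- max(t)
    grid <- sort(unique(c(0, km4@time, tau)))
    sfun <- stepfun(km4@time, c(1, km4@surv), right = FALSE)
    area <- sum(diff(grid) * sfun(head(grid, -1)))
    expect_equal(meanSurvival(km4, tau), area, tolerance = 1e-10)
  }
})

test_that("log-rank type-I error is calibrated under the null", {
  set.seed(65)
  rej <- mean(replicate(300, {
    s <- simulateSurvival(200, hazardRatio = 1, seed = sample.int(1e6, 1))
    lab <- stratifyByQuantile(s$expr, 0.75)
    logrankTest(s$time_days, s$event, lab)@p < 0.05
  }))
  ci <- qnorm(0.995) * sqrt(0.05 * 0.95 / 300)
  expect_lt(abs(rej - 0.05), ci)
})

test_that("survival screen ranks a planted protective gene first", {
  set.seed(66)
  firsts <- replicate(25, {
    s <- simulateSurvival(200, hazardRatio = 3, seed = sample.int(1e6, 1))
    genes <- c("PLANTED", paste0("NULL", 1:19))
    m <- matrix(rnorm(20 * 200, 8, 1), 20, 200,
                dimnames = list(genes, s$subject_id))
    m["PLANTED", ] <- s$expr
    res <- survivalScreen(m, s)
    res$gene[1] == "PLANTED"
  })
  expect_gte(mean(firsts), 0.9)
})

test_that("single-candidate screen equals running the operations directly", {
  s <- simulateSurvival(100, seed = 67)
  m <- matrix(s$expr, 1, 100, dimnames = list("G1", s$subject_id))
  res <- survivalScreen(m, s)
  lab <- stratifyByQuantile(s$expr)
  lr <- logrankTest(s$time_days, s$event, lab)
  expect_equal(res$chi_square, lr@chisq)
  expect_equal(res$p_value, lr@p)
  tau <- max(s$time_days)
  expect_equal(res$mst_high,
               meanSurvival(kmEstimate(s$time_days[lab == "high"],
                                       s$event[lab == "high"]), tau))
})

test_that("survival screen marks failing genes NA instead of aborting", {
  s <- simulateSurvival(50, seed = 68)
  m <- rbind(G1 = s$expr, CONST = rep(1, 50))
  colnames(m) <- s$subject_id
  expect_warning(res <- survivalScreen(m, s), "CONST")
  expect_true(is.na(res$p_value[res$gene == "CONST"]))
  expect_false(is.na(res$p_value[res$gene == "G1"]))
})
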