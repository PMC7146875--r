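# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use the most literal definition of
# each quantity and share no code with the package internals.

# BH step-up by definition: adj_i = min_{j : p_(j) >= p_(i)} p_(j) * m / j,
# clipped at 1, in input order.
bruteBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- ranked * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# log-rank chi-square by literal risk-set enumeration at every event time
bruteLogrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  oe <- 0; v <- 0
  for (t in sort(unique(time[event]))) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g == 1L)
    d <- sum(time == t & event); d1 <- sum(time == t & event & g == 1L)
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * ((n - n1) / n) * (n - d) / (n - 1)
  }
  if (v == 0) 0 else oe^2 / v
}

# KS D by evaluating both ECDFs at every pooled point
bruteKS <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(x) abs(mean(a <= x) - mean(b <= x)), numeric(1)))
}

# KM survival by literal risk-set recomputation at each distinct event time
bruteKM <- function(time, event) {
  et <- sort(unique(time[event]))
  s <- 1
  out <- numeric(length(et))
  for (i in seq_along(et)) {
    n <- sum(time >= et[i])
    d <- sum(time == et[i] & event)
    s <- s * (1 - d / n)
    out[i] <- s
  }
  list(time = et, surv = out)
}

# a small two-group survival instance with ties across event/censor times
randomSurvivalInstance <- function(n) {
  list(time = sample(1:6, n, replace = TRUE),
       event = runif(n) < 0.7,
       group = c("a", "b")[1 + (runif(n) < 0.5)])
}

# exact rejection rate of the one-sided hypergeometric ORA test under the
# null, for given universe/set/hit sizes and level alpha
exactOraRejectionRate <- function(N, mSet, kHit, alpha) {
  ks <- 0:min(mSet, kHit)
  pv <- phyper(ks - 1, mSet, N - mSet, kHit, lower.tail = FALSE)
  sum(dhyper(ks, mSet, N - mSet, kHit)[pv <= alpha])
}

# match measured cells to generator truth rows by centroid proximity
matchCellsToTruth <- function(measured, truth) {
  vapply(seq_len(nrow(measured)), function(i)
    which.min((truth$row - measured$centroid_row[i])^2 +
              (truth$col - measured$centroid_col[i])^2), integer(1))
}
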