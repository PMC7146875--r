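#' Normalize a gap-closure series to its initial gap area
#'
#' @param series data.frame with strictly increasing `time_h` and
#'   nonnegative `gap_area` columns (see [simulateGapSeries()]).
#' @return the series with an added `gap_fraction` column
#'   (`gap_area / gap_area[1]`, so 1 at the first timepoint).
#' @export
gapFractionSeries <- function(series) {
  stopifnot(all(c("time_h", "gap_area") %in% colnames(series)))
  if (is.unsorted(series$time_h, strictly = TRUE))
    stop("timepoints must be strictly increasing")
  if (series$gap_area[1] <= 0) stop("initial gap area must be positive")
  series$gap_fraction <- series$gap_area / series$gap_area[1]
  series
}

#' Time to gap closure
#'
#' First time at which the remaining gap fraction reaches `closedFrac`,
#' linearly interpolated between the bracketing timepoints; `NA` when the
#' threshold is never reached ("not closed").
#'
#' @param series as in [gapFractionSeries()].
#' @param closedFrac gap fraction counted as closed (default 0.01).
#' @return closure time in hours, or `NA_real_` if the gap never closes.
#' @examples
#' s <- data.frame(time_h = c(0, 10), gap_area = c(100, 0))
#' timeToClosure(s)   # 9.9 h
#' @export
timeToClosure <- function(series, closedFrac = 0.01) {
  series <- gapFractionSeries(series)
  f <- series$gap_fraction
  t <- series$time_h
  hit <- which(f <= closedFrac)
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  if (i == 1) return(t[1])
  # linear interpolation on the bracketing segment
  t[i - 1] + (f[i - 1] - closedFrac) / (f[i - 1] - f[i]) * (t[i] - t[i - 1])
}

#' Gap readout at a fixed timepoint
#'
#' Linearly interpolated gap area, gap fraction and percent closure at a
#' given time — the 6-hour comparison point of the migration assays.
#'
#' @param series as in [gapFractionSeries()].
#' @param at readout time in hours (default 6).
#' @return one-row data.frame `time_h`, `gap_area`, `gap_fraction`,
#'   `percent_closure`.
#' @export
gapReadout <- function(series, at = 6) {
  series <- gapFractionSeries(series)
  if (at < min(series$time_h) || at > max(series$time_h))
    stop("readout time outside the measured range")
  area <- stats::approx(series$time_h, series$gap_area, xout = at)$y
  frac <- area / series$gap_area[1]
  data.frame(time_h = at, gap_area = area, gap_fraction = frac,
             percent_closure = 100 * (1 - frac))
}

#' Compare gap closure between conditions at a fixed timepoint
#'
#' Unpaired two-sided t-test on the per-replicate gap fractions of two
#' conditions at the readout time.
#'
#' @param seriesA,seriesB lists of replicate series (each as in
#'   [gapFractionSeries()]), one list per condition.
#' @param at readout time in hours (default 6).
#' @param varEqual pooled-variance Student's t (default TRUE).
#' @return list with `fractions_a`, `fractions_b`, `estimate` (difference of
#'   mean fractions, B - A), `p_value`.
#' @export
compareGapClosure <- function(seriesA, seriesB, at = 6, varEqual = TRUE) {
  fa <- vapply(seriesA, function(s) gapReadout(s, at)$gap_fraction,
               numeric(1))
  fb <- vapply(seriesB, function(s) gapReadout(s, at)$gap_fraction,
               numeric(1))
  if (length(fa) < 2 || length(fb) < 2)
    stop("at least 2 replicate series per condition")
  tt <- stats::t.test(fb, fa, var.equal = varEqual)
  list(fractions_a = fa, fractions_b = fb,
       estimate = mean(fb) - mean(fa), p_value = tt$p.value)
}

#' Delta-delta-Cq relative quantification
#'
#' Per sample, `dCq = mean Cq(target) - mean per-reference dCq` over
#' technical replicates (with several reference genes the per-reference
#' delta-Cqs are averaged, equivalent to normalizing against their geometric
#' mean expression); `ddCq = dCq - mean dCq(control group)`; relative
#' quantity `RQ = 2^-ddCq`. Group comparison is an unpaired two-sided t-test
#' on the per-sample dCq values (log2 scale).
#'
#' @param table Cq data.frame with columns `sample_id`, `group`, `gene`,
#'   `role` (`"target"`/`"reference"`), `cq` (see [simulateCq()]).
#' @param controlGroup label of the calibrator group (default `"control"`).
#' @param varEqual pooled-variance Student's t (default TRUE).
#' @return list with `samples` (data.frame `sample_id`, `group`, `dcq`,
#'   `ddcq`, `rq`), `groupMeans` (mean RQ per group), `p_value`, and
#'   `log2fc` (difference of group mean dCq, test minus control, negated so
#'   positive = up in test).
#' @examples
#' cq <- simulateCq(plantedFold = 4, cqSd = 0, seed = 1)
#' ddcq(cq)$groupMeans
#' @export
ddcq <- function(table, controlGroup = "control", varEqual = TRUE) {
  need <- c("sample_id", "group", "gene", "role", "cq")
  if (!all(need %in% colnames(table)))
    stop("Cq table needs columns: ", paste(need, collapse = ", "))
  if (!controlGroup %in% table$group)
    stop("control group '", controlGroup, "' not present")
  if (any(table$cq <= 0)) stop("Cq values must be positive")
  samples <- unique(table[, c("sample_id", "group")])
  dcq <- vapply(seq_len(nrow(samples)), function(i) {
    d <- table[table$sample_id == samples$sample_id[i], ]
    tgt <- d$cq[d$role == "target"]
    if (!length(tgt))
      stop("sample '", samples$sample_id[i], "' has no target Cq")
    refs <- d[d$role == "reference", ]
    if (!nrow(refs))
      stop("sample '", samples$sample_id[i], "' has no reference Cq")
    refMeans <- tapply(refs$cq, refs$gene, mean)
    mean(mean(tgt) - refMeans)   # mean of per-reference delta-Cq
  }, numeric(1))
  grp <- samples$group
  if (any(table(grp) < 2)) stop("at least 2 samples per group are required")
  ddcqv <- dcq - mean(dcq[grp == controlGroup])
  rq <- 2^(-ddcqv)
  out <- data.frame(sample_id = samples$sample_id, group = grp,
                    dcq = dcq, ddcq = ddcqv, rq = rq,
                    stringsAsFactors = FALSE)
  other <- setdiff(unique(grp), controlGroup)
  p <- if (length(other) == 1) {
    x <- dcq[grp == other[1]]; y <- dcq[grp == controlGroup]
    if (sd(x) == 0 && sd(y) == 0) {
      # noiseless limit: no within-group variability
      if (mean(x) == mean(y)) 1 else 0
    } else stats::t.test(x, y, var.equal = varEqual)$p.value
  } else NA_real_
  log2fc <- if (length(other) == 1)
    -(mean(dcq[grp == other[1]]) - mean(dcq[grp == controlGroup])) else
      NA_real_
  list(samples = out,
       groupMeans = tapply(rq, grp, mean),
       p_value = p, log2fc = log2fc)
}

#' Proliferation-rate confounder check
#'
#' Fits a log-linear growth rate per condition and replicate
#' (`lm(log(count) ~ day)`) and compares the fitted rates between two
#' conditions with an unpaired two-sided t-test. The verdict is
#' `"confounded"` iff the rates differ at `alpha` — used to exclude
#' differential proliferation as a confounder of migration readouts.
#'
#' @param counts data.frame with columns `condition`, `replicate`, `day`,
#'   `count` (positive; see [simulateProliferation()]); exactly two
#'   conditions, >= 3 timepoints and >= 2 replicates each.
#' @param alpha significance level (default 0.05).
#' @param varEqual pooled-variance Student's t (default TRUE).
#' @return list with `rates` (data.frame `condition`, `replicate`,
#'   `rate_per_day`), `rate_difference`, `p_value`, `verdict`
#'   (`"confounded"` / `"not confounded"`).
#' @export
proliferationCheck <- function(counts, alpha = 0.05, varEqual = TRUE) {
  need <- c("condition", "replicate", "day", "count")
  if (!all(need %in% colnames(counts)))
    stop("'counts' needs columns: ", paste(need, collapse = ", "))
  if (any(counts$count <= 0)) stop("counts must be positive")
  conds <- unique(counts$condition)
  if (length(conds) != 2) stop("exactly two conditions are required")
  fits <- do.call(rbind, lapply(split(counts,
                                      counts[, c("condition", "replicate")],
                                      drop = TRUE), function(d) {
    if (length(unique(d$day)) < 3)
      stop("at least 3 timepoints per curve are required")
    data.frame(condition = d$condition[1], replicate = d$replicate[1],
               rate_per_day = unname(coef(lm(log(d$count) ~ d$day))[2]),
               stringsAsFactors = FALSE)
  }))
  rownames(fits) <- NULL
  if (any(table(fits$condition) < 2))
    stop("at least 2 replicates per condition are required")
  r1 <- fits$rate_per_day[fits$condition == conds[1]]
  r2 <- fits$rate_per_day[fits$condition == conds[2]]
  if (sd(c(r1, r2)) == 0) {
    p <- 1
  } else {
    p <- stats::t.test(r1, r2, var.equal = varEqual)$p.value
  }
  list(rates = fits,
       rate_difference = mean(r2) - mean(r1),
       p_value = p,
       verdict = if (p < alpha) "confounded" else "not confounded")
}
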