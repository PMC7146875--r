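#' Stratify subjects by an expression quantile
#'
#' Labels each subject `"high"` if its expression strictly exceeds the
#' linear-interpolation sample quantile `Q_q` (R type-7 quantile), otherwise
#' `"mid_low"` — the 75%-quantile split used to stratify cohorts into high
#' versus mid/low expressors.
#'
#' @param expr numeric expression values, one per subject.
#' @param q quantile in (0, 1), default 0.75.
#' @return character vector of labels `"high"` / `"mid_low"`.
#' @examples
#' stratifyByQuantile(1:8)          # Q = 6.25; subjects 7, 8 are "high"
#' @export
stratifyByQuantile <- function(expr, q = 0.75) {
  assertScalarNumber(q, "q", 0, 1, strict = TRUE)
  if (length(expr) < 4) stop("at least 4 subjects are required")
  if (diff(range(expr)) == 0)
    stop("all expression values are equal; stratification is undefined")
  cut <- quantile(expr, q, type = 7, names = FALSE)
  labels <- ifelse(expr > cut, "high", "mid_low")
  if (length(unique(labels)) < 2)
    stop("stratum empty at q = ", q, "; try a different quantile")
  labels
}

#' Kaplan-Meier product-limit estimate
#'
#' Survival function estimate under right censoring: at each distinct event
#' time, `S` is multiplied by `1 - d / n_at_risk`. Ties between deaths and
#' censorings at the same time are resolved by processing deaths first
#' (censored subjects at time t are still at risk at t).
#'
#' @param time positive observation times (days).
#' @param event logical, TRUE = death observed, FALSE = right-censored.
#' @return a [KMCurve-class].
#' @examples
#' kmEstimate(c(2, 4), c(TRUE, TRUE))   # S: 1 -> 0.5 -> 0
#' @export
kmEstimate <- function(time, event) {
  if (length(time) != length(event)) stop("time/event length mismatch")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be positive and finite")
  event <- as.logical(event)
  if (!any(event)) stop("at least one event is required")
  et <- sort(unique(time[event]))
  nRisk <- vapply(et, function(t) sum(time >= t), numeric(1))
  nEvent <- vapply(et, function(t) sum(time == t & event), numeric(1))
  surv <- cumprod(1 - nEvent / nRisk)
  new("KMCurve", time = et, surv = surv, nRisk = nRisk, nEvent = nEvent,
      maxTime = max(time))
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank chi-square with hypergeometric variance at
#' each distinct event time, 1 degree of freedom, no continuity correction.
#'
#' @param time,event as in [kmEstimate()].
#' @param group two-level group label per subject.
#' @return a [LogRankResult-class].
#' @export
logrankTest <- function(time, event, group) {
  if (length(unique(group)) != 2)
    stop("exactly two groups are required (got ",
         length(unique(group)), ")")
  event <- as.logical(event)
  if (!any(event)) stop("at least one event is required")
  g <- factor(group)
  lv <- levels(g)
  et <- sort(unique(time[event]))
  oe <- 0; vv <- 0
  obs <- setNames(c(0, 0), lv); expd <- setNames(c(0, 0), lv)
  for (t in et) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & g == lv[1])
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & g == lv[1])
    e1 <- d * n1 / n
    oe <- oe + (d1 - e1)
    if (n > 1) vv <- vv + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    obs[1] <- obs[1] + d1; obs[2] <- obs[2] + (d - d1)
    expd[1] <- expd[1] + e1; expd[2] <- expd[2] + (d - e1)
  }
  chisq <- if (vv > 0) oe^2 / vv else 0
  new("LogRankResult", chisq = chisq,
      p = pchisq(chisq, df = 1, lower.tail = FALSE),
      observed = obs, expected = expd)
}

#' Restricted mean survival time
#'
#' Area under the Kaplan-Meier step function on `[0, tau]` — the only "mean
#' survival time" well-defined under right censoring. With no censoring and
#' `tau` equal to the largest time this reduces to the arithmetic mean of the
#' event times.
#'
#' @param curve a [KMCurve-class].
#' @param tau truncation time in days (default: largest observed time).
#' @return restricted mean survival time in days.
#' @export
meanSurvival <- function(curve, tau = NULL) {
  stopifnot(is(curve, "KMCurve"))
  if (is.null(tau)) tau <- curve@maxTime
  assertScalarNumber(tau, "tau", lower = 0, strict = TRUE)
  # step function: S = 1 on [0, t1), surv[i] on [t_i, t_{i+1})
  times <- c(0, curve@time[curve@time <= tau], tau)
  s <- c(1, curve@surv[curve@time <= tau])
  sum(diff(times) * s)
}

#' Survival screen over candidate genes
#'
#' For each candidate gene: stratify subjects by expression quantile, fit
#' Kaplan-Meier curves per stratum, run the log-rank test, and compute
#' restricted mean survival time per stratum (truncated at the largest
#' observed time across both strata). Genes whose stratification or testing
#' fails (e.g. constant expression) get an NA row with a warning rather than
#' aborting the screen.
#'
#' @param exprByGene genes x subjects numeric matrix of log2 expression
#'   (rownames = gene ids, colnames = subject ids).
#' @param clinical data.frame with columns `subject_id`, `time_days`,
#'   `event` (coercible to logical), as produced by [simulateSurvival()].
#' @param genes candidate gene ids (default: all rows of `exprByGene`).
#' @param q stratification quantile, default 0.75.
#' @return data.frame `gene`, `chi_square`, `p_value`, `mst_high`,
#'   `mst_low`, `n_high`, `n_low`, sorted by ascending p.
#' @export
survivalScreen <- function(exprByGene, clinical, genes = rownames(exprByGene),
                           q = 0.75) {
  need <- c("subject_id", "time_days", "event")
  if (!all(need %in% colnames(clinical)))
    stop("'clinical' needs columns: ", paste(need, collapse = ", "))
  missing <- setdiff(clinical$subject_id, colnames(exprByGene))
  if (length(missing))
    stop("no expression for subject(s): ", paste(missing, collapse = ", "))
  rows <- lapply(genes, function(gene) {
    out <- data.frame(gene = gene, chi_square = NA_real_,
                      p_value = NA_real_, mst_high = NA_real_,
                      mst_low = NA_real_, n_high = NA_integer_,
                      n_low = NA_integer_, stringsAsFactors = FALSE)
    tryCatch({
      expr <- exprByGene[gene, clinical$subject_id]
      lab <- stratifyByQuantile(expr, q)
      lr <- logrankTest(clinical$time_days, clinical$event, lab)
      tau <- max(clinical$time_days)
      hi <- lab == "high"
      out$chi_square <- lr@chisq
      out$p_value <- lr@p
      out$mst_high <- meanSurvival(
        kmEstimate(clinical$time_days[hi], clinical$event[hi]), tau)
      out$mst_low <- meanSurvival(
        kmEstimate(clinical$time_days[!hi], clinical$event[!hi]), tau)
      out$n_high <- sum(hi); out$n_low <- sum(!hi)
      out
    }, error = function(e) {
      warning("gene '", gene, "' skipped: ", conditionMessage(e),
              call. = FALSE)
      out
    })
  })
  res <- do.call(rbind, rows)
  res[order(res$p_value), , drop = FALSE]
}
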