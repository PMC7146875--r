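#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment of a p-value vector, with input validation. Output
#' order matches input order.
#'
#' @param p numeric vector of p-values, all in \[0, 1\].
#' @return adjusted values in \[0, 1\], same length and order as `p`.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03))
#' @export
bhFdr <- function(p) {
  if (!is.numeric(p)) stop("'p' must be numeric")
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("all p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# vectorized per-row two-sample t-test on a features x samples matrix
rowTTest <- function(values, idxA, idxB, varEqual = TRUE) {
  n1 <- length(idxA); n2 <- length(idxB)
  m1 <- rowMeans(values[, idxA, drop = FALSE])
  m2 <- rowMeans(values[, idxB, drop = FALSE])
  v1 <- apply(values[, idxA, drop = FALSE], 1L, var)
  v2 <- apply(values[, idxB, drop = FALSE], 1L, var)
  d <- m2 - m1
  if (varEqual) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(d))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  }
  t <- d / se
  p <- 2 * pt(-abs(t), df)
  # degenerate features: zero variance in both groups
  degen <- se == 0
  if (any(degen)) {
    p[degen & d == 0] <- 1       # constant feature: no evidence, p := 1
    t[degen & d == 0] <- 0
    p[degen & d != 0] <- 0       # perfect separation, zero within-group var
    t[degen & d != 0] <- sign(d[degen & d != 0]) * Inf
  }
  list(log2fc = d, t = t, p = p, df = df)
}

#' Differential expression screen with fold-change / p / FDR filter
#'
#' Per-feature unpaired two-sided t-test (Student's pooled-variance by
#' default, Welch behind `varEqual = FALSE`) comparing `groupB` against
#' `groupA` on log2 values, BH-adjusted across features, with the composite
#' pass rule used for miRNome/transcriptome screening: a feature passes iff
#' its estimated fold change `2^|log2fc|` is at least `fcMin` (up- or
#' down-regulation treated symmetrically), `p <= pMax` and `fdr <= fdrMax`.
#' Features that are constant across all samples get `p = 1` and never pass.
#'
#' @param mat an [ExpressionMatrix-class].
#' @param groupA,groupB group labels; `log2fc = mean(groupB) - mean(groupA)`.
#' @param fcMin minimum fold change (linear scale, default 2).
#' @param pMax maximum t-test p-value (default 0.05).
#' @param fdrMax maximum BH FDR (default 0.2).
#' @param varEqual pooled-variance Student's t (TRUE, default) or Welch.
#' @return data.frame with one row per feature, in matrix feature order:
#'   `feature_id`, `log2fc`, `fold_change` (= `2^|log2fc|`), `direction`
#'   (up/down/none), `t`, `p_value`, `fdr`, `passes`. Screen parameters are
#'   attached as attribute `params`.
#' @examples
#' sim <- simulateExpression(20, 20, plantedFC = c(`hsa-miR-10b-5p` = 1.14),
#'                           seed = 1)
#' res <- differentialScreen(sim$mirna, "RDEB-KC", "RDEB-cSCC")
#' head(res)
#' @export
differentialScreen <- function(mat, groupA, groupB, fcMin = 2, pMax = 0.05,
                               fdrMax = 0.2, varEqual = TRUE) {
  stopifnot(is(mat, "ExpressionMatrix"))
  g <- sampleGroups(mat)
  for (lab in c(groupA, groupB)) {
    if (!lab %in% g) stop("unknown group label: ", lab)
    if (sum(g == lab) < 2)
      stop("group '", lab, "' has fewer than 2 samples")
  }
  if (identical(groupA, groupB)) stop("groups must be disjoint")
  v <- exprValues(mat)
  tt <- rowTTest(v, which(g == groupA), which(g == groupB), varEqual)
  fdr <- bhFdr(tt$p)
  fc <- 2^abs(tt$log2fc)
  passes <- fc >= fcMin & tt$p <= pMax & fdr <= fdrMax
  out <- data.frame(feature_id = rownames(v),
                    log2fc = tt$log2fc,
                    fold_change = fc,
                    direction = ifelse(tt$log2fc > 0, "up",
                                       ifelse(tt$log2fc < 0, "down", "none")),
                    t = tt$t, p_value = tt$p, fdr = fdr, passes = passes,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "params") <- list(group_a = groupA, group_b = groupB,
                              fc_min = fcMin, p_max = pMax,
                              fdr_max = fdrMax, var_equal = varEqual)
  out
}

#' Features passing the differential screen
#'
#' @param result data.frame from [differentialScreen()].
#' @return character vector of feature ids with `passes = TRUE`, in the
#'   stable feature order of the input.
#' @export
selectSignificant <- function(result) {
  stopifnot(is.data.frame(result), "passes" %in% colnames(result))
  result$feature_id[result$passes]
}

#' Principal component analysis of an expression matrix
#'
#' PCA over samples on centered (optionally unit-scaled) log2 values, via
#' [stats::prcomp]. Loadings columns are orthonormal; explained variances are
#' the score variances and sum to the total variance of the centered data
#' when all components are kept.
#'
#' @param mat an [ExpressionMatrix-class].
#' @param nComponents number of components (default
#'   `min(samples - 1, features)`).
#' @param scale unit-scale features before PCA (default FALSE; array data
#'   are already on a comparable log2 scale).
#' @return list with `scores` (samples x components), `loadings`
#'   (features x components), `explainedVariance`, `center` (feature means).
#' @export
pcaScreen <- function(mat, nComponents = NULL, scale = FALSE) {
  stopifnot(is(mat, "ExpressionMatrix"))
  v <- exprValues(mat)
  if (ncol(v) < 2) stop("PCA requires at least 2 samples")
  kmax <- min(ncol(v) - 1L, nrow(v))
  if (is.null(nComponents)) nComponents <- kmax
  if (nComponents > kmax)
    stop("nComponents must be <= min(samples - 1, features)")
  pr <- prcomp(t(v), center = TRUE, scale. = scale)
  k <- seq_len(nComponents)
  list(scores = pr$x[, k, drop = FALSE],
       loadings = pr$rotation[, k, drop = FALSE],
       explainedVariance = pr$sdev[k]^2,
       center = pr$center)
}

#' Silhouette-based group-separation score in PCA space
#'
#' Mean silhouette width of the samples over their group labels, using
#' Euclidean distance in score space; 1 means perfectly separated clusters,
#' values near 0 or below mean overlapping groups.
#'
#' @param scores samples x components score matrix (rownames = sample ids).
#' @param groups group label per sample (named vector or in score row order).
#' @return mean silhouette width in \[-1, 1\].
#' @export
groupSeparation <- function(scores, groups) {
  if (!is.null(names(groups)) && !is.null(rownames(scores)))
    groups <- groups[rownames(scores)]
  if (length(unique(groups)) < 2)
    stop("at least two groups are required")
  d <- dist(scores)
  if (all(d == 0))
    stop("all samples are identical; separation is undefined")
  sil <- cluster::silhouette(as.integer(factor(groups)), d)
  mean(sil[, "sil_width"])
}
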