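# Otsu threshold on an arbitrary-range raster (EBImage::otsu expects [0,1])
otsuThreshold <- function(im) {
  rng <- range(im)
  if (diff(rng) == 0) return(rng[1])
  scaled <- (im - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  rng[1] + thr * diff(rng)
}

# connected-component labeling with 8-connectivity: EBImage::bwlabel is
# 4-connective, so labels touching only diagonally are merged afterwards
# with a union-find pass over diagonal adjacencies.
labelComponents <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab < 2) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  for (shift in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1L), if (shift[2] == 1L) seq_len(nc - 1L)
             else 2L:nc]
    b <- lab[2L:nr, if (shift[2] == 1L) 2L:nc else seq_len(nc - 1L)]
    touch <- which(a > 0L & b > 0L & a != b)
    for (i in touch) {
      ra <- find(a[i]); rb <- find(b[i])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

#' Segment aggregates from a well image and extract cross-section sizes
#'
#' Global Otsu threshold, 8-connective connected components, and a minimum
#' object-size filter; object areas are pixel counts, converted to physical
#' units when a pixel size is given. A blank image (no foreground) yields an
#' empty sample with a warning.
#'
#' @param image single-channel 2D numeric matrix.
#' @param minAreaPx discard objects smaller than this many pixels
#'   (default 4).
#' @param pixelSize micrometer per pixel; when given, areas are in um^2.
#' @param condition condition label attached to the result.
#' @return list with `sizes` (numeric areas, attributes `unit` and
#'   `condition`), `labels` (label matrix) and `n` (object count).
#' @export
segmentObjects <- function(image, minAreaPx = 4, pixelSize = NULL,
                           condition = "sample") {
  stopifnot(is.matrix(image))
  if (diff(range(image)) == 0) {
    warning("blank image: no foreground objects found")
    sizes <- numeric(0)
    attr(sizes, "unit") <- if (is.null(pixelSize)) "px^2" else "um^2"
    attr(sizes, "condition") <- condition
    return(list(sizes = sizes, labels = matrix(0L, nrow(image), ncol(image)),
                n = 0L))
  }
  mask <- image > otsuThreshold(image)
  lab <- labelComponents(mask)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= minAreaPx)
  relab <- integer(max(lab, 1L))
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  sizes <- as.numeric(areas[keep])
  unit <- "px^2"
  if (!is.null(pixelSize)) { sizes <- sizes * pixelSize^2; unit <- "um^2" }
  attr(sizes, "unit") <- unit
  attr(sizes, "condition") <- condition
  list(sizes = sizes, labels = lab, n = length(keep))
}

# D evaluated on pre-sorted pooled values via cumulative label counts;
# `tieEnds` marks the last index of each tie group (sup over distinct points)
ksDFromLabels <- function(labSorted, nA, nB, tieEnds) {
  cumA <- cumsum(labSorted) / nA
  cumB <- cumsum(!labSorted) / nB
  max(abs(cumA[tieEnds] - cumB[tieEnds]))
}

#' Exact two-sample Kolmogorov-Smirnov statistic
#'
#' Supremum absolute difference of the two empirical CDFs, evaluated at all
#' pooled data points (ties handled exactly).
#'
#' @param a,b nonempty numeric samples.
#' @return D in \[0, 1\].
#' @examples
#' ksStatistic(c(1, 3), c(2, 4))   # 0.5
#' @export
ksStatistic <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  pooled <- c(a, b)
  ord <- order(pooled)
  sorted <- pooled[ord]
  lab <- c(rep(TRUE, length(a)), rep(FALSE, length(b)))[ord]
  tieEnds <- c(which(diff(sorted) > 0), length(sorted))
  ksDFromLabels(lab, length(a), length(b), tieEnds)
}

#' Two-sample KS test with a Monte-Carlo resampling null
#'
#' The null distribution of D is built by repeatedly re-partitioning the
#' pooled sample into groups of the original sizes — by permutation without
#' replacement (default; an exact conditional null) or by bootstrap with
#' replacement — and the p-value uses the add-one formula
#' `(1 + #(D* >= D_obs)) / (B + 1)`, which can never be zero.
#'
#' @param a,b nonempty numeric samples.
#' @param nResamples number of Monte-Carlo resamples B (>= 99).
#' @param seed integer RNG seed; fixed seed gives a bit-reproducible result.
#' @param method `"permutation"` (default) or `"bootstrap"`.
#' @return a [KSResult-class].
#' @examples
#' r <- mcKsTest(rnorm(50), rnorm(50, 2), nResamples = 999, seed = 1)
#' @export
mcKsTest <- function(a, b, nResamples = 10000, seed = NULL,
                     method = c("permutation", "bootstrap")) {
  method <- match.arg(method)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  if (nResamples < 99) stop("nResamples must be >= 99")
  nA <- length(a); nB <- length(b); n <- nA + nB
  pooled <- c(a, b)
  ord <- order(pooled)
  sorted <- pooled[ord]
  tieEnds <- c(which(diff(sorted) > 0), n)
  labObs <- c(rep(TRUE, nA), rep(FALSE, nB))[ord]
  dObs <- ksDFromLabels(labObs, nA, nB, tieEnds)
  nGe <- withSeed(seed, {
    count <- 0L
    for (i in seq_len(nResamples)) {
      if (method == "permutation") {
        lab <- logical(n)
        lab[sample.int(n, nA)] <- TRUE
        d <- ksDFromLabels(lab, nA, nB, tieEnds)
      } else {
        idxA <- sample.int(n, nA, replace = TRUE)
        idxB <- sample.int(n, nB, replace = TRUE)
        d <- ksStatistic(pooled[idxA], pooled[idxB])
      }
      if (d >= dObs - 1e-12) count <- count + 1L
    }
    count
  })
  new("KSResult", statistic = dObs,
      pMC = (1 + nGe) / (nResamples + 1),
      nResamples = as.integer(nResamples),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      nA = as.integer(nA), nB = as.integer(nB), method = method)
}

#' Fraction of small objects in a size sample
#'
#' Fraction of objects with cross-section area strictly below the cutoff —
#' the readout for fragmentation into single cells and aggregate fragments.
#'
#' @param sizes nonempty numeric vector of object areas.
#' @param cutoffArea area cutoff (same unit as `sizes`).
#' @return fraction in \[0, 1\].
#' @export
smallObjectFraction <- function(sizes, cutoffArea) {
  if (!length(sizes)) stop("size sample must be nonempty")
  mean(sizes < cutoffArea)
}

#' All pairwise MC-KS comparisons between conditions
#'
#' Runs [mcKsTest()] for every pair of conditions (e.g. parental, knock-out,
#' mixed) and adjusts the Monte-Carlo p-values across pairs with BH.
#'
#' @param samples named list of numeric size (or intensity) samples.
#' @param nResamples,seed,method passed to [mcKsTest()]; each pair uses an
#'   offset of `seed` so pairs are independent but reproducible.
#' @return data.frame `condition_a`, `condition_b`, `d_statistic`, `p_mc`,
#'   `fdr`.
#' @export
pairwiseKsTests <- function(samples, nResamples = 10000, seed = NULL,
                            method = "permutation") {
  if (length(samples) < 2) stop("at least two conditions are required")
  nm <- names(samples)
  pairs <- utils::combn(length(samples), 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    ks <- mcKsTest(samples[[i1]], samples[[i2]], nResamples,
                   seed = if (is.null(seed)) NULL else seed + j,
                   method = method)
    data.frame(condition_a = nm[i1], condition_b = nm[i2],
               d_statistic = ks@statistic, p_mc = ks@pMC,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$fdr <- bhFdr(res$p_mc)
  res
}
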