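#' Segment nuclei from the nuclear (DAPI) channel
#'
#' Otsu threshold, hole filling, 8-connective connected components and a
#' minimum-area filter. A blank channel yields an empty mask with a warning.
#'
#' @param nuclearChannel 2D nonnegative numeric matrix.
#' @param minAreaPx discard nuclei smaller than this (default 9 px).
#' @return integer label matrix (0 = background, 1..n = nuclei).
#' @export
segmentNuclei <- function(nuclearChannel, minAreaPx = 9) {
  stopifnot(is.matrix(nuclearChannel))
  if (diff(range(nuclearChannel)) == 0) {
    warning("blank nuclear channel: no nuclei found")
    return(matrix(0L, nrow(nuclearChannel), ncol(nuclearChannel)))
  }
  mask <- nuclearChannel > otsuThreshold(nuclearChannel)
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  lab <- labelComponents(matrix(as.numeric(filled) > 0,
                                nrow(mask), ncol(mask)))
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= minAreaPx)
  relab <- integer(max(lab, 1L))
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

# centroids of a label matrix: one (row, col) per label 1..n
maskCentroids <- function(lab) {
  n <- max(lab)
  idx <- which(lab > 0L)
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  l <- lab[idx]
  cbind(row = tapply(rows, l, mean), col = tapply(cols, l, mean))[seq_len(n), ,
                                                                  drop = FALSE]
}

#' Segment cells from the marker channel using nuclear seeds
#'
#' Foreground by Otsu on the marker channel; 8-connective foreground
#' components that contain no nucleus are discarded; remaining foreground
#' pixels are partitioned into cells by assignment to the nearest nucleus
#' centroid (Euclidean distance), so each cell carries its seed nucleus'
#' label.
#'
#' @param markerChannel 2D numeric matrix (cell-marker fluorescence).
#' @param nuclearMask label matrix from [segmentNuclei()]; must contain at
#'   least one nucleus.
#' @return integer cell label matrix aligned with the nuclear labels.
#' @export
segmentCells <- function(markerChannel, nuclearMask) {
  stopifnot(is.matrix(markerChannel),
            identical(dim(markerChannel), dim(nuclearMask)))
  nNuc <- max(nuclearMask)
  if (nNuc == 0) stop("no nuclei in mask; cannot seed cell segmentation")
  fg <- markerChannel > otsuThreshold(markerChannel)
  comp <- labelComponents(fg)
  # keep only components that contain at least one nucleus pixel
  withNuc <- unique(comp[comp > 0L & nuclearMask > 0L])
  keep <- comp > 0L & comp %in% withNuc
  cent <- maskCentroids(nuclearMask)
  idx <- which(keep)
  rows <- (idx - 1L) %% nrow(comp) + 1L
  cols <- (idx - 1L) %/% nrow(comp) + 1L
  d2 <- outer(rows, cent[, "row"], "-")^2 + outer(cols, cent[, "col"], "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  out <- matrix(0L, nrow(comp), ncol(comp))
  out[idx] <- nearest
  out
}

#' Per-cell probe intensity quantification with nuclear subtraction
#'
#' Background-corrects the probe channel (per-pixel subtraction of the
#' background estimate, clipped at 0) and integrates it per cell: `total`
#' over all cell pixels, `nuclear` over cell-and-nucleus pixels, and
#' `cytoplasmic = total - nuclear` — the cytoplasm-confined signal used to
#' quantify mature miRNA abundance per cell.
#'
#' @param probeChannel 2D numeric matrix.
#' @param cellMask cell label matrix from [segmentCells()].
#' @param nuclearMask nuclear label matrix from [segmentNuclei()].
#' @param background background level; default is the median probe intensity
#'   outside all cell labels.
#' @return data.frame `cell_id`, `area_px`, `total`, `nuclear`,
#'   `cytoplasmic`, `centroid_row`, `centroid_col`.
#' @export
quantifyCells <- function(probeChannel, cellMask, nuclearMask,
                          background = NULL) {
  stopifnot(is.matrix(probeChannel),
            identical(dim(probeChannel), dim(cellMask)),
            identical(dim(probeChannel), dim(nuclearMask)))
  if (is.null(background))
    background <- if (any(cellMask == 0L))
      median(probeChannel[cellMask == 0L]) else 0
  corr <- pmax(probeChannel - background, 0)
  n <- max(cellMask)
  if (n == 0)
    return(data.frame(cell_id = integer(), area_px = integer(),
                      total = numeric(), nuclear = numeric(),
                      cytoplasmic = numeric(), centroid_row = numeric(),
                      centroid_col = numeric()))
  cent <- maskCentroids(cellMask)
  rows <- lapply(seq_len(n), function(i) {
    inCell <- cellMask == i
    total <- sum(corr[inCell])
    nuclear <- sum(corr[inCell & nuclearMask > 0L])
    data.frame(cell_id = i, area_px = sum(inCell), total = total,
               nuclear = nuclear, cytoplasmic = total - nuclear,
               centroid_row = cent[i, "row"], centroid_col = cent[i, "col"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full single-field quantification
#'
#' Convenience wrapper chaining [segmentNuclei()], [segmentCells()] and
#' [quantifyCells()] on a [FieldImage-class].
#'
#' @param field a [FieldImage-class].
#' @param minNucleusAreaPx passed to [segmentNuclei()].
#' @param background passed to [quantifyCells()].
#' @return as [quantifyCells()].
#' @export
quantifyField <- function(field, minNucleusAreaPx = 9, background = NULL) {
  stopifnot(is(field, "FieldImage"))
  nuc <- segmentNuclei(field@nuclear, minNucleusAreaPx)
  cells <- segmentCells(field@marker, nuc)
  quantifyCells(field@probe, cells, nuc, background)
}

#' Per-sample intensity density curve
#'
#' Gaussian kernel density with Silverman's rule-of-thumb bandwidth
#' (`bw.nrd0`) on a 512-point grid spanning the data range (extended by four
#' bandwidths so the curve integrates to 1) — the "distribution density
#' function of intensity per single cell" display.
#'
#' @param values per-cell intensities (>= 5 cells).
#' @param n grid size (default 512).
#' @return data.frame `grid`, `density`, with attributes `bandwidth` and
#'   `n_cells`.
#' @export
intensityDensity <- function(values, n = 512) {
  if (length(values) < 5) stop("at least 5 cells are required")
  d <- density(values, bw = "nrd0", n = n, cut = 4)
  out <- data.frame(grid = d$x, density = d$y)
  attr(out, "bandwidth") <- d$bw
  attr(out, "n_cells") <- length(values)
  out
}

#' Compare per-cell intensity distributions between samples
#'
#' All pairwise Monte-Carlo KS tests on the raw per-cell values (not the
#' smoothed curves), BH-adjusted across pairs; delegates to
#' [pairwiseKsTests()].
#'
#' @param samples named list of per-cell intensity vectors (>= 5 cells each).
#' @param nResamples,seed passed on to [mcKsTest()].
#' @return data.frame as [pairwiseKsTests()].
#' @export
compareIntensity <- function(samples, nResamples = 10000, seed = NULL) {
  if (any(lengths(samples) < 5)) stop("at least 5 cells per sample")
  pairwiseKsTests(samples, nResamples = nResamples, seed = seed)
}
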