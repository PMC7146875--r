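#' Simulate matched miRNA and mRNA log2 expression matrices
#'
#' Generates two-group (or multi-group) log2 expression matrices with planted
#' fold changes and planted miRNA-to-gene inverse-correlation relationships,
#' emulating post-normalization microarray data from keratinocyte (KC) versus
#' cutaneous squamous-cell-carcinoma (cSCC) cultures. Expression is drawn
#' directly on the log2 scale: feature baselines from
#' `Normal(baselineMean, baselineSd)`, per-sample noise
#' `Normal(0, noiseSd)`, and for features listed in `plantedFC` the stated
#' log2 fold change is added to every sample of `caseGroup`. For each row of
#' `plantedTargets` the gene's values are rewritten as
#' `baseline + slope * (miR value - mean miR value) + Normal(0, residualSd)`,
#' planting an inverse (negative-slope) correlation across matched samples.
#'
#' @param nMirna,nGenes number of miRNA and mRNA features.
#' @param groupSizes named integer vector, group label -> number of samples,
#'   e.g. `c("RDEB-KC" = 6, "RDEB-cSCC" = 4)`.
#' @param caseGroup group receiving the planted fold changes (default: last
#'   label of `groupSizes`).
#' @param plantedFC named numeric vector of planted log2 fold changes
#'   (case vs the other groups); names must be feature ids of either matrix.
#' @param plantedTargets data.frame with columns `mir`, `gene`, `slope`
#'   (log2-per-log2, negative for genuine targets) and `residual_sd`.
#' @param noiseSd per-sample log2 noise standard deviation (> 0).
#' @param baselineMean,baselineSd distribution of per-feature baselines.
#' @param mirPrefix,genePrefix feature id prefixes for autogenerated ids.
#' @param seed integer RNG seed; all randomness flows from it.
#' @return list with elements `mirna` and `mrna` ([ExpressionMatrix-class])
#'   and `truth`, a data.frame of planted effects (one row per planted fold
#'   change and per planted target pair).
#' @examples
#' sim <- simulateExpression(nMirna = 50, nGenes = 100,
#'   groupSizes = c("RDEB-KC" = 6, "RDEB-cSCC" = 4),
#'   plantedFC = c(`hsa-miR-10b-5p` = log2(2.2)), seed = 1)
#' @export
simulateExpression <- function(nMirna, nGenes,
                               groupSizes = c("RDEB-KC" = 6, "RDEB-cSCC" = 4),
                               caseGroup = NULL,
                               plantedFC = numeric(),
                               plantedTargets = NULL,
                               noiseSd = 0.3,
                               baselineMean = 8, baselineSd = 1.5,
                               mirPrefix = "hsa-miR-", genePrefix = "GENE",
                               seed = NULL) {
  assertScalarNumber(noiseSd, "noiseSd", lower = 0, strict = TRUE)
  if (is.null(names(groupSizes)) || any(groupSizes < 1))
    stop("'groupSizes' must be a named vector of positive counts")
  if (is.null(caseGroup)) caseGroup <- names(groupSizes)[length(groupSizes)]
  if (!caseGroup %in% names(groupSizes)) stop("unknown caseGroup")
  if (length(plantedFC) && anyDuplicated(names(plantedFC)))
    stop("duplicate feature ids in 'plantedFC'")

  if (!is.null(plantedTargets)) {
    need <- c("mir", "gene", "slope", "residual_sd")
    if (!all(need %in% colnames(plantedTargets)))
      stop("'plantedTargets' needs columns: ", paste(need, collapse = ", "))
    if (any(plantedTargets$residual_sd < 0)) stop("residual_sd must be >= 0")
  }
  # planted ids looking like miRNAs go to the miRNA matrix, others to mRNA;
  # they replace the first autogenerated ids of the respective matrix
  planted <- unique(c(names(plantedFC),
                      plantedTargets$mir, plantedTargets$gene))
  isMir <- grepl("mir", planted, ignore.case = TRUE) &
    !planted %in% plantedTargets$gene
  inject <- function(auto, ids, n, what) {
    if (length(ids) > n)
      stop("more planted ", what, " feature ids than features")
    auto[seq_along(ids)] <- ids
    if (anyDuplicated(auto)) stop("duplicate feature ids")
    auto
  }
  mirIds <- inject(paste0(mirPrefix, seq_len(nMirna)), planted[isMir],
                   nMirna, "miRNA")
  geneIds <- inject(paste0(genePrefix, seq_len(nGenes)), planted[!isMir],
                    nGenes, "gene")
  if (!is.null(plantedTargets) &&
      !all(plantedTargets$mir %in% mirIds & plantedTargets$gene %in% geneIds))
    stop("planted target feature id(s) could not be assigned to a matrix")

  nS <- sum(groupSizes)
  sampleIds <- paste0("S", seq_len(nS))
  groups <- setNames(rep(names(groupSizes), groupSizes), sampleIds)
  isCase <- groups == caseGroup

  withSeed(seed, {
    gen <- function(ids) {
      base <- rnorm(length(ids), baselineMean, baselineSd)
      m <- base + matrix(rnorm(length(ids) * nS, 0, noiseSd),
                         length(ids), nS)
      dimnames(m) <- list(ids, sampleIds)
      fc <- plantedFC[names(plantedFC) %in% ids]
      if (length(fc)) m[names(fc), isCase] <- m[names(fc), isCase] + fc
      list(values = m, base = setNames(base, ids))
    }
    mir <- gen(mirIds)
    mrna <- gen(geneIds)
    truth <- data.frame(feature = names(plantedFC),
                        kind = rep("fold_change", length(plantedFC)),
                        value = unname(plantedFC),
                        partner = rep(NA_character_, length(plantedFC)),
                        stringsAsFactors = FALSE)
    if (!is.null(plantedTargets) && nrow(plantedTargets)) {
      for (i in seq_len(nrow(plantedTargets))) {
        g <- plantedTargets$gene[i]; mi <- plantedTargets$mir[i]
        mv <- mir$values[mi, ]
        mrna$values[g, ] <- mrna$base[g] +
          plantedTargets$slope[i] * (mv - mean(mv)) +
          rnorm(nS, 0, plantedTargets$residual_sd[i])
      }
      truth <- rbind(truth,
                     data.frame(feature = plantedTargets$gene,
                                kind = "target_slope",
                                value = plantedTargets$slope,
                                partner = plantedTargets$mir,
                                stringsAsFactors = FALSE))
    }
    list(mirna = ExpressionMatrix(mir$values, groups),
         mrna = ExpressionMatrix(mrna$values, groups),
         truth = truth)
  })
}

#' Simulate a right-censored survival cohort with expression-dependent hazard
#'
#' Emulates a clinical cohort (e.g. metastatic stage-IV HNSCC) in which high
#' expression of a protective gene lowers the event hazard. Each subject
#' receives a log2 expression value from `Normal(exprMean, exprSd)`; subjects
#' above the `quantileCut` sample quantile ("high" expressors) have
#' exponential event times at rate `baselineHazard / hazardRatio`, the rest
#' at `baselineHazard`. Censoring is independent exponential at `censorRate`
#' (0 means no censoring); the observed time is the minimum of event and
#' censoring time, with an event flag.
#'
#' @param nSubjects cohort size.
#' @param exprMean,exprSd distribution of the stratifying gene's log2
#'   expression.
#' @param hazardRatio hazard ratio low-vs-high (> 0); values > 1 make high
#'   expression protective, 1 is the null.
#' @param baselineHazard per-day event rate of the low/mid stratum.
#' @param censorRate per-day censoring rate (>= 0).
#' @param quantileCut quantile in (0, 1) defining "high" expression.
#' @param seed integer RNG seed.
#' @return data.frame with columns `subject_id`, `time_days`, `event`
#'   (logical), `expr`.
#' @export
simulateSurvival <- function(nSubjects, exprMean = 8, exprSd = 1,
                             hazardRatio = 3, baselineHazard = 1 / 1000,
                             censorRate = 1 / 4000, quantileCut = 0.75,
                             seed = NULL) {
  assertScalarNumber(hazardRatio, "hazardRatio", lower = 0, strict = TRUE)
  assertScalarNumber(quantileCut, "quantileCut", 0, 1, strict = TRUE)
  assertScalarNumber(censorRate, "censorRate", lower = 0)
  assertScalarNumber(baselineHazard, "baselineHazard", lower = 0,
                     strict = TRUE)
  withSeed(seed, {
    expr <- rnorm(nSubjects, exprMean, exprSd)
    high <- expr > quantile(expr, quantileCut, type = 7)
    rate <- ifelse(high, baselineHazard / hazardRatio, baselineHazard)
    tEvent <- rexp(nSubjects, rate)
    tCens <- if (censorRate > 0) rexp(nSubjects, censorRate) else
      rep(Inf, nSubjects)
    data.frame(subject_id = paste0("P", seq_len(nSubjects)),
               time_days = pmin(tEvent, tCens),
               event = tEvent <= tCens,
               expr = expr,
               stringsAsFactors = FALSE)
  })
}

# disk pixel mask helper: TRUE where (r - r0)^2 + (c - c0)^2 <= radius^2
diskMask <- function(shape, center, radius) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

#' Simulate a multichannel fluorescence field with known per-cell signal
#'
#' Renders non-overlapping disk-shaped cells, each with a concentric nuclear
#' disk, into a three-channel field (nuclear / marker / probe). The probe
#' channel of each cell integrates (before noise) to the cell's
#' `probe_total`, with `nuclear_fraction` of it spread uniformly over the
#' nucleus disk and the remainder uniformly over the cytoplasmic annulus.
#' Gaussian read noise and a constant background can be added. The returned
#' truth table records the exact rendered (noiseless, background-free)
#' per-cell total, nuclear and cytoplasmic integrated intensities.
#'
#' @param shape `c(rows, cols)` in pixels.
#' @param cells data.frame with columns `row`, `col`, `cell_radius`,
#'   `nucleus_radius`, `probe_total`, `nuclear_fraction`. May have 0 rows.
#' @param background constant background intensity added to all channels.
#' @param noiseSd Gaussian noise sd (a.u.); 0 for noiseless fields.
#' @param nuclearLevel,markerLevel rendered intensity of the nucleus disk in
#'   the nuclear channel and of the cell disk in the marker channel.
#' @param seed integer RNG seed.
#' @return list with `image` ([FieldImage-class]) and `truth` (data.frame:
#'   `cell_id`, `row`, `col`, `total`, `nuclear`, `cytoplasmic`, `area_px`).
#' @export
simulateFieldImage <- function(shape = c(256, 256), cells,
                               background = 0, noiseSd = 0,
                               nuclearLevel = 1000, markerLevel = 500,
                               seed = NULL) {
  need <- c("row", "col", "cell_radius", "nucleus_radius", "probe_total",
            "nuclear_fraction")
  if (!all(need %in% colnames(cells)))
    stop("'cells' needs columns: ", paste(need, collapse = ", "))
  n <- nrow(cells)
  if (n) {
    if (any(cells$nucleus_radius >= cells$cell_radius))
      stop("nucleus_radius must be smaller than cell_radius")
    if (any(cells$nuclear_fraction < 0 | cells$nuclear_fraction > 1))
      stop("nuclear_fraction must be in [0, 1]")
    if (any(cells$row - cells$cell_radius < 1 |
            cells$row + cells$cell_radius > shape[1] |
            cells$col - cells$cell_radius < 1 |
            cells$col + cells$cell_radius > shape[2]))
      stop("cells must fit inside image bounds")
    if (n > 1) {
      d <- as.matrix(dist(cells[, c("row", "col")]))
      lim <- outer(cells$cell_radius, cells$cell_radius, "+")
      diag(d) <- Inf
      if (any(d <= lim)) stop("cells overlap; generator requires ",
                              "pairwise non-overlapping cells")
    }
  }
  nuc <- mark <- probe <- matrix(0, shape[1], shape[2])
  truth <- data.frame(cell_id = integer(), row = numeric(), col = numeric(),
                      total = numeric(), nuclear = numeric(),
                      cytoplasmic = numeric(), area_px = integer())
  for (i in seq_len(n)) {
    cm <- diskMask(shape, c(cells$row[i], cells$col[i]), cells$cell_radius[i])
    nm <- diskMask(shape, c(cells$row[i], cells$col[i]),
                   cells$nucleus_radius[i])
    cyto <- cm & !nm
    nuc[nm] <- nuclearLevel
    mark[cm] <- markerLevel
    nucSignal <- cells$probe_total[i] * cells$nuclear_fraction[i]
    cytSignal <- cells$probe_total[i] - nucSignal
    if (sum(nm)) probe[nm] <- probe[nm] + nucSignal / sum(nm)
    if (sum(cyto)) probe[cyto] <- probe[cyto] + cytSignal / sum(cyto)
    # rendered truth: integrals of the noiseless probe raster over the masks
    truth <- rbind(truth, data.frame(
      cell_id = i, row = cells$row[i], col = cells$col[i],
      total = sum(probe[cm]), nuclear = sum(probe[nm]),
      cytoplasmic = sum(probe[cyto]), area_px = sum(cm)))
  }
  withSeed(seed, {
    addNoise <- function(m) {
      m <- m + background
      if (noiseSd > 0) m <- m + matrix(rnorm(length(m), 0, noiseSd),
                                       nrow(m), ncol(m))
      pmax(m, 0)
    }
    img <- FieldImage(addNoise(nuc), addNoise(mark), addNoise(probe))
    list(image = img, truth = truth)
  })
}

#' Sample non-overlapping cell layouts for field simulation
#'
#' Convenience layout generator for [simulateFieldImage()]: draws cell
#' centers by rejection sampling so that disks never overlap, with lognormal
#' per-cell probe totals.
#'
#' @param n number of cells.
#' @param shape image shape `c(rows, cols)`.
#' @param cellRadius,nucleusRadius disk radii in pixels.
#' @param probeMeanlog,probeSdlog lognormal parameters of per-cell probe
#'   totals.
#' @param nuclearFraction fraction of a cell's probe signal inside the
#'   nucleus.
#' @param maxTries rejection-sampling retry bound.
#' @param seed integer RNG seed.
#' @return data.frame suitable as the `cells` argument of
#'   [simulateFieldImage()].
#' @export
sampleCellLayout <- function(n, shape = c(256, 256), cellRadius = 9,
                             nucleusRadius = 4, probeMeanlog = log(5000),
                             probeSdlog = 0.5, nuclearFraction = 0.3,
                             maxTries = 2000L, seed = NULL) {
  withSeed(seed, {
    rows <- cols <- numeric(0)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (t in seq_len(maxTries)) {
        r <- runif(1, cellRadius + 1, shape[1] - cellRadius - 1)
        c <- runif(1, cellRadius + 1, shape[2] - cellRadius - 1)
        if (!length(rows) ||
            all((rows - r)^2 + (cols - c)^2 > (2 * cellRadius + 2)^2)) {
          rows <- c(rows, r); cols <- c(cols, c); placed <- TRUE; break
        }
      }
      if (!placed) stop("could not place ", n, " non-overlapping cells in ",
                        maxTries, " tries; reduce n or enlarge the field")
    }
    data.frame(row = round(rows), col = round(cols),
               cell_radius = cellRadius, nucleus_radius = nucleusRadius,
               probe_total = rlnorm(n, probeMeanlog, probeSdlog),
               nuclear_fraction = nuclearFraction)
  })
}

#' Simulate spheroid cross-section sizes, optionally rendered into an image
#'
#' Draws object cross-section areas i.i.d. from a lognormal mixture,
#' emulating whole-well images of cell aggregates where stable spheroid
#' formers produce large objects and fragmenting cultures shift mass toward
#' small single-cell objects. With `render = TRUE` the sizes are additionally
#' rendered as non-overlapping bright disks (radius `sqrt(area / pi)`) on a
#' dark background so that segmentation ground truth is exact up to
#' pixelation.
#'
#' @param mixture data.frame with columns `weight`, `meanlog`, `sdlog`
#'   describing the lognormal mixture over areas (weights must sum to 1).
#' @param nObjects number of objects (>= 1).
#' @param render render a well image of the drawn sizes.
#' @param shape image shape when rendering.
#' @param foreground,background rendered intensities.
#' @param maxTries per-object placement retry bound when rendering.
#' @param seed integer RNG seed.
#' @return list with `sizes` (numeric areas, attribute `unit = "px^2"`) and,
#'   when rendering, `image` (numeric matrix) and `truth` (data.frame of
#'   placed disks: `row`, `col`, `radius_px`, `area`).
#' @export
simulateSpheroids <- function(mixture = data.frame(weight = 1,
                                                   meanlog = log(500),
                                                   sdlog = 0.4),
                              nObjects = 100, render = FALSE,
                              shape = c(512, 512), foreground = 1,
                              background = 0, maxTries = 500L, seed = NULL) {
  if (nObjects < 1) stop("nObjects must be >= 1")
  if (abs(sum(mixture$weight) - 1) > 1e-8)
    stop("mixture weights must sum to 1")
  withSeed(seed, {
    comp <- sample.int(nrow(mixture), nObjects, replace = TRUE,
                       prob = mixture$weight)
    sizes <- rlnorm(nObjects, mixture$meanlog[comp], mixture$sdlog[comp])
    attr(sizes, "unit") <- "px^2"
    if (!render) return(list(sizes = sizes))
    radii <- sqrt(sizes / pi)
    if (any(2 * radii + 2 > min(shape)))
      stop("an object is too large for the image shape")
    img <- matrix(background, shape[1], shape[2])
    rows <- cols <- placedR <- numeric(0)
    for (i in order(radii, decreasing = TRUE)) {
      placed <- FALSE
      for (t in seq_len(maxTries)) {
        r <- runif(1, radii[i] + 1, shape[1] - radii[i] - 1)
        c <- runif(1, radii[i] + 1, shape[2] - radii[i] - 1)
        if (!length(rows) ||
            all(sqrt((rows - r)^2 + (cols - c)^2) >
                radii[i] + placedR + 2)) {
          rows <- c(rows, r); cols <- c(cols, c)
          placedR <- c(placedR, radii[i]); placed <- TRUE
          img[diskMask(shape, c(r, c), radii[i])] <- foreground
          break
        }
      }
      if (!placed)
        stop("could not place all objects without overlap after ", maxTries,
             " tries per object; reduce nObjects or object sizes")
    }
    ord <- order(radii, decreasing = TRUE)
    list(sizes = sizes,
         image = img,
         truth = data.frame(row = rows, col = cols,
                            radius_px = radii[ord], area = sizes[ord]))
  })
}

#' Simulate a qPCR Cq table with a planted expression fold change
#'
#' Produces Cq values for a target gene and reference genes (GAPDH, TUBA1) in
#' a control and a test group, such that delta-delta-Cq analysis recovers
#' `plantedFold` in expectation: the test group's target Cq is lowered by
#' `log2(plantedFold)` cycles.
#'
#' @param plantedFold planted relative expression of the test group (> 0).
#' @param nPerGroup biological samples per group (>= 2).
#' @param cqSd per-reaction Cq noise sd (cycles).
#' @param nReplicates technical replicates per reaction.
#' @param referenceGenes reference gene names.
#' @param targetCq,referenceCq mean Cq of target / reference reactions in the
#'   control condition.
#' @param seed integer RNG seed.
#' @return data.frame with columns `sample_id`, `group`, `gene`, `role`
#'   (target/reference), `replicate`, `cq`.
#' @export
simulateCq <- function(plantedFold, nPerGroup = 3, cqSd = 0.2,
                       nReplicates = 2,
                       referenceGenes = c("GAPDH", "TUBA1"),
                       targetCq = 25, referenceCq = 20, seed = NULL) {
  assertScalarNumber(plantedFold, "plantedFold", lower = 0, strict = TRUE)
  if (nPerGroup < 2) stop("nPerGroup must be >= 2 (t-test undefined)")
  withSeed(seed, {
    rows <- list()
    for (grp in c("control", "test")) {
      shift <- if (grp == "test") -log2(plantedFold) else 0
      for (s in seq_len(nPerGroup)) {
        sid <- paste0(grp, "_", s)
        for (rep in seq_len(nReplicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, group = grp, gene = "target", role = "target",
            replicate = rep, cq = targetCq + shift + rnorm(1, 0, cqSd))
          for (rg in referenceGenes)
            rows[[length(rows) + 1L]] <- data.frame(
              sample_id = sid, group = grp, gene = rg, role = "reference",
              replicate = rep, cq = referenceCq + rnorm(1, 0, cqSd))
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a gap-closure (migration assay) time series
#'
#' Gap area declines linearly at `closureRate` (fraction of the initial gap
#' per hour) until closed, with optional Gaussian measurement noise,
#' emulating plate-reader confluence measurements of a wound-healing insert
#' assay.
#'
#' @param closureRate fraction of the initial gap closed per hour (>= 0).
#' @param nTimepoints number of measurements.
#' @param dtHours spacing between measurements in hours.
#' @param initialArea gap area at time 0 (area units).
#' @param roiArea constant measurement region area (>= initialArea).
#' @param noiseSd measurement noise sd (area units).
#' @param seed integer RNG seed.
#' @return data.frame with columns `time_h`, `gap_area`, attribute
#'   `roi_area`.
#' @export
simulateGapSeries <- function(closureRate, nTimepoints = 13, dtHours = 1,
                              initialArea = 100, roiArea = 400,
                              noiseSd = 0, seed = NULL) {
  assertScalarNumber(closureRate, "closureRate", lower = 0)
  withSeed(seed, {
    t <- (seq_len(nTimepoints) - 1) * dtHours
    area <- pmax(initialArea * (1 - closureRate * t), 0)
    if (noiseSd > 0) area <- pmin(pmax(area + rnorm(length(t), 0, noiseSd),
                                       0), roiArea)
    out <- data.frame(time_h = t, gap_area = area)
    attr(out, "roi_area") <- roiArea
    out
  })
}

#' Simulate cell-count proliferation curves
#'
#' Exponential growth with multiplicative lognormal noise, one curve per
#' replicate and condition; used to test the proliferation-confounder check
#' that accompanies migration assays.
#'
#' @param doublingHours named vector, condition -> doubling time in hours.
#' @param nReplicates replicates per condition.
#' @param days measurement days.
#' @param n0 seeded cell count.
#' @param noiseCv multiplicative coefficient of variation of counts.
#' @param seed integer RNG seed.
#' @return data.frame with columns `condition`, `replicate`, `day`, `count`.
#' @export
simulateProliferation <- function(doublingHours, nReplicates = 4,
                                  days = 0:7, n0 = 1e4, noiseCv = 0.05,
                                  seed = NULL) {
  withSeed(seed, {
    out <- expand.grid(condition = names(doublingHours),
                       replicate = seq_len(nReplicates), day = days,
                       stringsAsFactors = FALSE)
    rate <- log(2) / (doublingHours[out$condition] / 24)  # per day
    mu <- n0 * exp(rate * out$day)
    out$count <- if (noiseCv > 0)
      mu * rlnorm(nrow(out), -noiseCv^2 / 2, noiseCv) else mu
    out[order(out$condition, out$replicate, out$day), ]
  })
}
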