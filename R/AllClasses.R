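#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Log2 expression matrix with sample group annotations
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding a
#' single `"log2"` assay (features in rows, samples in columns) and a `group`
#' column in `colData`. This is the substrate of the differential screen and
#' of the inverse-correlation target ranking; values are assumed to be
#' post-normalization log2 intensities.
#'
#' @slot .Data see `SummarizedExperiment`.
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (!"log2" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log2' is required")
  else {
    v <- SummarizedExperiment::assay(object, "log2")
    if (anyNA(v)) msg <- c(msg, "log2 values must not contain NA")
  }
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  else if (anyNA(SummarizedExperiment::colData(object)$group))
    msg <- c(msg, "every sample must have a group label")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "feature ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix of log2 intensities, features x samples, with
#'   unique `rownames` (feature ids) and `colnames` (sample ids).
#' @param groups named character vector mapping sample id to group label
#'   (e.g. `"RDEB-KC"`, `"RDEB-cSCC"`); names must cover all samples.
#' @return an [ExpressionMatrix-class] object.
#' @examples
#' v <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
#' em <- ExpressionMatrix(v, setNames(rep(c("KC", "cSCC"), each = 2),
#'                                    colnames(v)))
#' @export
ExpressionMatrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (is.null(names(groups)))
    stop("'groups' must be named by sample id")
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop("no group label for sample(s): ", paste(missing, collapse = ", "))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = values),
    colData = S4Vectors::DataFrame(group = as.character(groups[colnames(values)]),
                                   row.names = colnames(values)))
  new("ExpressionMatrix", se)
}

#' @describeIn ExpressionMatrix log2 intensity matrix.
#' @param object,x an `ExpressionMatrix`.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "log2")

#' @describeIn ExpressionMatrix named vector of sample group labels.
#' @export
sampleGroups <- function(x)
  setNames(SummarizedExperiment::colData(x)$group, colnames(x))

setMethod("show", "ExpressionMatrix", function(object) {
  cat("ExpressionMatrix:", nrow(object), "features x", ncol(object),
      "samples\n")
  cat("groups:", paste(sprintf("%s (n=%d)",
                               names(table(sampleGroups(object))),
                               table(sampleGroups(object))), collapse = ", "),
      "\n")
})

#' Merged miRNA-gene interaction repository
#'
#' Deduplicated union of validated and predicted miRNA-target interaction
#' records (miRTarbase/TargetScan-like). A pair carries evidence `"both"` iff
#' it appeared in at least one validated and one predicted source.
#'
#' @slot records data.frame with columns `mirna_id`, `gene_id`,
#'   `evidence` (validated/predicted/both) and `source`.
#' @export
setClass("TargetRepository", representation(records = "data.frame"))

setValidity("TargetRepository", function(object) {
  r <- object@records
  need <- c("mirna_id", "gene_id", "evidence", "source")
  if (!all(need %in% colnames(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(r[, c("mirna_id", "gene_id")]))
    return("(mirna_id, gene_id) pairs must be unique")
  if (!all(r$evidence %in% c("validated", "predicted", "both")))
    return("evidence must be validated, predicted or both")
  TRUE
})

#' @describeIn TargetRepository interaction records as a data.frame.
#' @param x a `TargetRepository`.
#' @export
repositoryRecords <- function(x) x@records

setMethod("length", "TargetRepository", function(x) nrow(x@records))

setMethod("show", "TargetRepository", function(object) {
  cat("TargetRepository:", nrow(object@records), "interactions,",
      length(unique(object@records$mirna_id)), "miRNAs,",
      length(unique(object@records$gene_id)), "genes\n")
  print(table(object@records$evidence))
})

#' Kaplan-Meier product-limit curve
#'
#' @slot time ascending distinct event times.
#' @slot surv product-limit survival estimate just after each event time.
#' @slot nRisk number at risk at each event time.
#' @slot nEvent deaths at each event time.
#' @slot maxTime largest observed time (event or censoring).
#' @export
setClass("KMCurve", representation(time = "numeric", surv = "numeric",
                                   nRisk = "numeric", nEvent = "numeric",
                                   maxTime = "numeric"))

setValidity("KMCurve", function(object) {
  if (length(object@time) < 1L) return("at least one event time required")
  if (is.unsorted(object@time, strictly = TRUE))
    return("event times must be strictly ascending")
  if (any(diff(c(1, object@surv)) > 1e-12))
    return("survival must start <= 1 and be nonincreasing")
  if (length(object@surv) != length(object@time) ||
      length(object@nRisk) != length(object@time) ||
      length(object@nEvent) != length(object@time))
    return("slot lengths must agree")
  TRUE
})

setMethod("show", "KMCurve", function(object) {
  cat("KMCurve:", length(object@time), "event times, S(last) =",
      signif(object@surv[length(object@surv)], 4), "\n")
})

#' Two-group log-rank test result
#'
#' @slot chisq log-rank chi-square statistic (1 df).
#' @slot p upper-tail chi-square p-value.
#' @slot observed observed deaths per group.
#' @slot expected expected deaths per group under the null.
#' @export
setClass("LogRankResult", representation(chisq = "numeric", p = "numeric",
                                         observed = "numeric",
                                         expected = "numeric"))

setMethod("show", "LogRankResult", function(object) {
  cat(sprintf("Log-rank test: chi-square = %.4g (1 df), p = %.4g\n",
              object@chisq, object@p))
  print(data.frame(group = names(object@observed),
                   observed = object@observed, expected = object@expected,
                   row.names = NULL))
})

#' Two-sample KS test with Monte-Carlo permutation null
#'
#' @slot statistic exact two-sample KS statistic D (sup ECDF difference).
#' @slot pMC add-one Monte-Carlo p-value, `(1 + #(D* >= D)) / (B + 1)`.
#' @slot nResamples number of Monte-Carlo resamples B.
#' @slot seed RNG seed used (NA if none supplied).
#' @slot nA,nB observed sample sizes.
#' @slot method resampling scheme: `"permutation"` or `"bootstrap"`.
#' @export
setClass("KSResult", representation(statistic = "numeric", pMC = "numeric",
                                    nResamples = "integer", seed = "integer",
                                    nA = "integer", nB = "integer",
                                    method = "character"))

setValidity("KSResult", function(object) {
  if (object@statistic < 0 || object@statistic > 1)
    return("D must be in [0, 1]")
  if (object@pMC <= 0 || object@pMC > 1) return("p must be in (0, 1]")
  TRUE
})

setMethod("show", "KSResult", function(object) {
  cat(sprintf("MC-KS test (%s null): D = %.4g, p = %.4g (B = %d, n = %d vs %d)\n",
              object@method, object@statistic, object@pMC,
              object@nResamples, object@nA, object@nB))
})

#' Multichannel fluorescence field image
#'
#' Row-major rasters (origin top-left) for the nuclear (DAPI), cell-marker
#' (pan-keratin) and probe (anti-DIG FITC) channels of one imaged field.
#'
#' @slot nuclear,marker,probe numeric matrices of identical shape,
#'   nonnegative intensities in arbitrary units.
#' @slot pixelSize micrometer per pixel (NA if uncalibrated).
#' @slot sample sample label.
#' @export
setClass("FieldImage", representation(nuclear = "matrix", marker = "matrix",
                                      probe = "matrix", pixelSize = "numeric",
                                      sample = "character"))

setValidity("FieldImage", function(object) {
  d <- dim(object@nuclear)
  if (!identical(d, dim(object@marker)) || !identical(d, dim(object@probe)))
    return("all channels must have identical shape")
  if (min(object@nuclear, object@marker, object@probe) < 0)
    return("intensities must be nonnegative")
  TRUE
})

#' @describeIn FieldImage construct a field image from three channel rasters.
#' @param nuclear,marker,probe numeric matrices (same shape).
#' @param pixelSize micrometer per pixel, or NA.
#' @param sample sample label.
#' @export
FieldImage <- function(nuclear, marker, probe, pixelSize = NA_real_,
                       sample = "field") {
  new("FieldImage", nuclear = nuclear, marker = marker, probe = probe,
      pixelSize = as.numeric(pixelSize), sample = sample)
}

setMethod("show", "FieldImage", function(object) {
  cat("FieldImage '", object@sample, "': ", nrow(object@nuclear), " x ",
      ncol(object@nuclear), " px, 3 channels (nuclear/marker/probe)\n",
      sep = "")
})
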