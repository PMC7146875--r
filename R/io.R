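#' Write / read an expression matrix as TSV with a group sidecar
#'
#' The matrix file has feature rows, a header row of sample ids and a
#' leading `feature_id` column; the sidecar maps `sample_id` to `group`.
#'
#' @param mat an [ExpressionMatrix-class].
#' @param file,groupsFile paths of the matrix TSV and the group sidecar TSV.
#' @return `writeExpressionMatrix` returns the paths invisibly;
#'   `readExpressionMatrix` returns an [ExpressionMatrix-class].
#' @export
writeExpressionMatrix <- function(mat, file, groupsFile) {
  stopifnot(is(mat, "ExpressionMatrix"))
  v <- exprValues(mat)
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- sampleGroups(mat)
  utils::write.table(data.frame(sample_id = names(g), group = unname(g)),
                     groupsFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(file, groupsFile))
}

#' @rdname writeExpressionMatrix
#' @export
readExpressionMatrix <- function(file, groupsFile) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  g <- read.delim(groupsFile, stringsAsFactors = FALSE)
  ExpressionMatrix(v, setNames(g$group, g$sample_id))
}

#' Read a miRNA-target interaction TSV
#'
#' Expects a header with at least `mirna_id` and `gene_id`; optional
#' `evidence` and `source` columns are honored.
#'
#' @param file path to the TSV.
#' @param evidence default evidence label when the file has none.
#' @param source source tag (default: file name).
#' @return data.frame suitable for [mergeRepositories()].
#' @export
readInteractionTable <- function(file, evidence = "validated",
                                 source = basename(file)) {
  d <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "gene_id") %in% colnames(d)))
    stop("file '", file, "' lacks mirna_id/gene_id columns")
  if (!"evidence" %in% colnames(d)) d$evidence <- evidence
  if (!"source" %in% colnames(d)) d$source <- source
  d
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member...`.
#'
#' @param file path to the GMT file.
#' @return named list of gene-id character vectors.
#' @export
readGMT <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(bad, collapse = ", "))
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[[`, character(1), 1))
}

#' Read / write a clinical survival table
#'
#' TSV columns: `subject_id`, `time_days`, `event` (0/1 or logical) and,
#' optionally, `expr`.
#'
#' @param file path.
#' @param table data.frame as returned by [simulateSurvival()].
#' @return `readSurvivalTable` returns a data.frame with logical `event`.
#' @export
readSurvivalTable <- function(file) {
  d <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("subject_id", "time_days", "event")
  if (!all(need %in% colnames(d)))
    stop("survival table needs columns: ", paste(need, collapse = ", "))
  d$event <- as.logical(d$event)
  d
}

#' @rdname readSurvivalTable
#' @export
writeSurvivalTable <- function(table, file) {
  out <- table
  out$event <- as.integer(out$event)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write / read a multichannel field image as multi-page TIFF
#'
#' One 32-bit float page per channel in the order nuclear / marker / probe;
#' a JSON sidecar records channel names, the intensity scale factor used to
#' fit the TIFF's \[0, 1\] range, and the pixel size.
#'
#' @param field a [FieldImage-class].
#' @param file TIFF path; the sidecar is written next to it as
#'   `<file>.json`.
#' @return `readFieldImage` returns a [FieldImage-class].
#' @export
writeFieldImage <- function(field, file) {
  stopifnot(is(field, "FieldImage"))
  chans <- list(nuclear = field@nuclear, marker = field@marker,
                probe = field@probe)
  scale <- max(1, vapply(chans, max, numeric(1)))
  jsonlite::write_json(list(channels = names(chans), scale = scale,
                            pixel_size = field@pixelSize,
                            sample = field@sample),
                       paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  tiff::writeTIFF(lapply(chans, function(m) m / scale), file,
                  bits.per.sample = 32L)
  invisible(file)
}

#' @rdname writeFieldImage
#' @export
readFieldImage <- function(file) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(file, all = TRUE)
  chans <- lapply(pages, function(p) p * meta$scale)
  names(chans) <- meta$channels
  FieldImage(chans$nuclear, chans$marker, chans$probe,
             pixelSize = if (is.null(meta$pixel_size)) NA_real_ else
               meta$pixel_size,
             sample = if (is.null(meta$sample)) "field" else meta$sample)
}

#' Write / read an object-size sample as single-column CSV
#'
#' The header names the unit (`area_px2` or `area_um2`).
#'
#' @param sizes numeric areas with a `unit` attribute.
#' @param file CSV path.
#' @return `readSizesCSV` returns the numeric vector with its `unit`
#'   attribute restored.
#' @export
writeSizesCSV <- function(sizes, file) {
  unit <- attr(sizes, "unit")
  header <- if (identical(unit, "um^2")) "area_um2" else "area_px2"
  writeLines(c(header, format(as.numeric(sizes), digits = 15,
                              scientific = FALSE, trim = TRUE)), file)
  invisible(file)
}

#' @rdname writeSizesCSV
#' @export
readSizesCSV <- function(file) {
  d <- read.csv(file)
  sizes <- as.numeric(d[[1]])
  attr(sizes, "unit") <- if (identical(colnames(d)[1], "area_um2"))
    "um^2" else "px^2"
  sizes
}
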