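#' Merge miRNA-target interaction tables into one repository
#'
#' Deduplicated union of validated (miRTarbase-like) and predicted
#' (TargetScan-like) interaction tables. A (miRNA, gene) pair that appears in
#' at least one validated and at least one predicted source is labelled
#' `"both"`; sources contributing a pair are concatenated.
#'
#' @param sources list of data.frames, each with columns `mirna_id` and
#'   `gene_id`; an `evidence` column (values `"validated"`/`"predicted"`) and
#'   a `source` column are used when present, otherwise taken from the
#'   `evidence` argument and the list element name.
#' @param evidence default evidence label per source table (recycled).
#' @return a [TargetRepository-class].
#' @examples
#' v <- data.frame(mirna_id = "hsa-miR-10b-5p",
#'                 gene_id = c("HOXD10", "DIAPH2", "KLF4"))
#' p <- data.frame(mirna_id = "hsa-miR-10b-5p",
#'                 gene_id = c("DIAPH2", "BDNF", "NR4A3"))
#' mergeRepositories(list(mirtarbase = v, targetscan = p),
#'                   evidence = c("validated", "predicted"))
#' @export
mergeRepositories <- function(sources, evidence = "validated") {
  if (!length(sources))
    return(new("TargetRepository",
               records = data.frame(mirna_id = character(),
                                    gene_id = character(),
                                    evidence = character(),
                                    source = character())))
  evidence <- rep_len(evidence, length(sources))
  nm <- names(sources)
  if (is.null(nm)) nm <- paste0("source", seq_along(sources))
  all <- lapply(seq_along(sources), function(i) {
    s <- sources[[i]]
    if (!all(c("mirna_id", "gene_id") %in% colnames(s)))
      stop("source '", nm[i], "' lacks mirna_id/gene_id columns")
    data.frame(mirna_id = as.character(s$mirna_id),
               gene_id = as.character(s$gene_id),
               evidence = if ("evidence" %in% colnames(s))
                 as.character(s$evidence) else evidence[i],
               source = if ("source" %in% colnames(s))
                 as.character(s$source) else nm[i],
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, all)
  if (!all(all$evidence %in% c("validated", "predicted")))
    stop("evidence labels must be 'validated' or 'predicted'")
  key <- paste(all$mirna_id, all$gene_id, sep = "\r")
  recs <- do.call(rbind, lapply(split(all, factor(key, unique(key))),
                                function(d) {
    ev <- unique(d$evidence)
    data.frame(mirna_id = d$mirna_id[1], gene_id = d$gene_id[1],
               evidence = if (length(ev) > 1) "both" else ev,
               source = paste(unique(d$source), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(recs) <- NULL
  new("TargetRepository", records = recs)
}

#' Intersect differentially expressed genes with repository targets
#'
#' Genes that are differentially expressed *and* reported as a target of at
#' least one member of the given miRNA family, in the stable order of
#' `deGenes`.
#'
#' @param deGenes character vector of DE gene ids.
#' @param repo a [TargetRepository-class].
#' @param mirFamily nonempty character vector of miRNA ids (e.g. the miR-10
#'   family members).
#' @return character vector of candidate gene ids.
#' @export
intersectDeTargets <- function(deGenes, repo, mirFamily) {
  stopifnot(is(repo, "TargetRepository"))
  if (!length(mirFamily)) stop("'mirFamily' must be nonempty")
  r <- repositoryRecords(repo)
  targeted <- unique(r$gene_id[r$mirna_id %in% mirFamily])
  deGenes[deGenes %in% targeted]
}

#' Family-level miRNA signal
#'
#' Per-sample arithmetic mean of the log2 values of the given family members
#' (a single member returns its row unchanged), used as the miR-10 signal for
#' inverse-correlation ranking.
#'
#' @param mat an [ExpressionMatrix-class].
#' @param members feature ids of the family members; all must be present.
#' @return named numeric vector, one value per sample.
#' @export
mirFamilySignal <- function(mat, members) {
  stopifnot(is(mat, "ExpressionMatrix"))
  missing <- setdiff(members, rownames(mat))
  if (length(missing))
    stop("family member(s) missing from matrix: ",
         paste(missing, collapse = ", "))
  v <- exprValues(mat)[members, , drop = FALSE]
  colMeans(v)
}

#' Rank candidate targets by inverse correlation with the miRNA signal
#'
#' Pearson (or Spearman) correlation of each candidate gene's log2 values
#' with the per-sample miRNA signal across matched samples, sorted ascending
#' (most negative first, ties broken lexicographically by gene id); the top
#' `k` are returned with ranks. Candidates whose values are constant (or if
#' the miRNA signal is constant) have undefined correlation and are dropped
#' with a warning.
#'
#' @param mirSignal named per-sample values (e.g. [mirFamilySignal()]).
#' @param mrna an [ExpressionMatrix-class] of gene expression.
#' @param candidates gene ids to rank (must be rows of `mrna`).
#' @param k number of top candidates to return (default 20); all are
#'   returned when fewer candidates are available.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame `gene_id`, `correlation_r`, `rank`.
#' @export
inverseCorrelationRank <- function(mirSignal, mrna, candidates, k = 20,
                                   method = c("pearson", "spearman")) {
  stopifnot(is(mrna, "ExpressionMatrix"))
  method <- match.arg(method)
  if (is.null(names(mirSignal))) stop("'mirSignal' must be named by sample")
  shared <- intersect(names(mirSignal), colnames(mrna))
  if (length(shared) < 3)
    stop("at least 3 matched samples are required (have ", length(shared),
         ")")
  missing <- setdiff(candidates, rownames(mrna))
  if (length(missing))
    stop("candidate(s) missing from matrix: ",
         paste(missing, collapse = ", "))
  sig <- mirSignal[shared]
  v <- exprValues(mrna)[candidates, shared, drop = FALSE]
  if (sd(sig) == 0) {
    warning("miRNA signal is constant; no correlations defined")
    return(data.frame(gene_id = character(), correlation_r = numeric(),
                      rank = integer()))
  }
  r <- apply(v, 1L, function(x)
    if (sd(x) == 0) NA_real_ else cor(x, sig, method = method))
  if (anyNA(r)) {
    warning("dropping candidate(s) with constant expression: ",
            paste(candidates[is.na(r)], collapse = ", "))
    r <- r[!is.na(r)]
  }
  ord <- order(r, names(r))
  r <- r[ord]
  top <- utils::head(seq_along(r), k)
  data.frame(gene_id = names(r)[top], correlation_r = unname(r[top]),
             rank = seq_along(top), stringsAsFactors = FALSE)
}

#' Gene-set over-representation test
#'
#' One-sided hypergeometric tail test of each gene set against the hit list
#' within the given universe, with BH adjustment across sets; the standard
#' enrichment screen for nominated targets against KEGG/MSigDB-style
#' collections supplied as GMT files.
#'
#' @param hits character vector of hit gene ids (must be within `universe`).
#' @param sets named list of gene-id vectors (e.g. from [readGMT()]); set
#'   members outside the universe are ignored, sets empty after restriction
#'   are dropped.
#' @param universe character vector of all assayed gene ids.
#' @return data.frame `set_name`, `set_size`, `overlap`, `expected`,
#'   `p_value`, `fdr`, sorted by input set order.
#' @export
overrepresentation <- function(hits, sets, universe) {
  hits <- unique(hits)
  universe <- unique(universe)
  bad <- setdiff(hits, universe)
  if (length(bad))
    stop("hit(s) outside the universe: ", paste(bad, collapse = ", "))
  sets <- lapply(sets, function(s) unique(intersect(s, universe)))
  sets <- sets[lengths(sets) > 0]
  if (!length(sets))
    return(data.frame(set_name = character(), set_size = integer(),
                      overlap = integer(), expected = numeric(),
                      p_value = numeric(), fdr = numeric()))
  N <- length(universe); kHit <- length(hits)
  res <- data.frame(
    set_name = names(sets),
    set_size = lengths(sets),
    overlap = vapply(sets, function(s) length(intersect(s, hits)),
                     integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  res$expected <- kHit * res$set_size / N
  res$p_value <- phyper(res$overlap - 1, res$set_size, N - res$set_size,
                        kHit, lower.tail = FALSE)
  res$fdr <- bhFdr(res$p_value)
  res
}
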