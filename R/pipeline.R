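#' Default all-synthetic demo pipeline configuration
#'
#' Parameter block for [runPipeline()] that exercises every stage on
#' generated data with planted ground truth: a two-group miRNome/
#' transcriptome with a planted miR-10b-like 2.2-fold up-regulation and
#' inverse-correlated targets, a synthetic interaction repository covering
#' the planted pairs plus decoys, a protective-gene survival cohort, spheroid
#' size mixtures for three conditions, one fluorescence field, a planted
#' 4-fold qPCR table and two gap-closure conditions.
#'
#' @param seed global integer seed; stage seeds are derived as fixed offsets.
#' @return nested list understood by [runPipeline()].
#' @export
demoRunConfig <- function(seed = 1) {
  list(
    seed = seed,
    expression = list(
      n_mirna = 200, n_genes = 400,
      group_sizes = c("RDEB-KC" = 6, "RDEB-cSCC" = 4),
      mir_id = "hsa-miR-10b-5p", planted_fc = log2(2.2),
      noise_sd = 0.3,
      n_targets = 10, target_slope = -1, target_residual_sd = 0.2),
    screen = list(fc_min = 2, p_max = 0.05, fdr_max = 0.2),
    nominate = list(k = 20, n_decoy_interactions = 300),
    survival = list(n_subjects = 200, hazard_ratio = 3,
                    baseline_hazard = 1 / 1000, censor_rate = 1 / 4000,
                    q = 0.75, n_null_genes = 9),
    spheroids = list(
      n_objects = 400, resamples = 2000,
      conditions = list(
        parental = data.frame(weight = c(0.1, 0.9),
                              meanlog = log(c(40, 900)),
                              sdlog = c(0.4, 0.35)),
        knockout = data.frame(weight = c(0.6, 0.4),
                              meanlog = log(c(40, 400)),
                              sdlog = c(0.4, 0.35)),
        mixed = data.frame(weight = c(0.15, 0.85),
                           meanlog = log(c(40, 850)),
                           sdlog = c(0.4, 0.35)))),
    field = list(n_cells = 30, shape = c(256, 256), noise_sd = 1,
                 background = 10),
    cq = list(planted_fold = 4, n_per_group = 3, cq_sd = 0.2),
    gap = list(rates = c(parental = 0.12, mir10b = 0.05),
               n_replicates = 4, noise_sd = 2))
}

pipelineStage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline on a configuration
#'
#' Executes simulate -> screen -> nominate -> survive -> spheroids ->
#' ishquant -> assays on an all-synthetic configuration (see
#' [demoRunConfig()]), writing one CSV per stage plus a JSON reproducibility
#' manifest (`manifest.json`) recording the package version, seed, stage
#' parameters and MD5 checksums of every output. Reruns with the same
#' configuration and seed produce byte-identical outputs. A YAML file path
#' may be given instead of a list; any stage failure aborts with the stage
#' name while earlier outputs are preserved.
#'
#' @param config nested parameter list, or path to a YAML file holding one.
#' @param outDir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = demoRunConfig(), outDir = "stemir_run") {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    config$expression$group_sizes <- unlist(config$expression$group_sizes)
    config$gap$rates <- unlist(config$gap$rates)
    for (i in seq_along(config$spheroids$conditions))
      config$spheroids$conditions[[i]] <-
        as.data.frame(config$spheroids$conditions[[i]])
  }
  if (is.null(config$seed)) stop("config must carry a global 'seed'")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(outDir, name)
    write.csv(df, path, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  # --- expression + screen -------------------------------------------------
  cfgE <- config$expression
  sim <- pipelineStage("simulate_expression", {
    targets <- if (cfgE$n_targets > 0)
      data.frame(mir = cfgE$mir_id,
                 gene = paste0("TGT", seq_len(cfgE$n_targets)),
                 slope = cfgE$target_slope,
                 residual_sd = cfgE$target_residual_sd) else NULL
    simulateExpression(cfgE$n_mirna, cfgE$n_genes,
                       groupSizes = cfgE$group_sizes,
                       plantedFC = setNames(cfgE$planted_fc, cfgE$mir_id),
                       plantedTargets = targets,
                       noiseSd = cfgE$noise_sd, seed = seed + 11)
  })
  labs <- names(cfgE$group_sizes)
  cfgS <- config$screen
  mirDE <- pipelineStage("screen_mirna", differentialScreen(
    sim$mirna, labs[1], labs[2], cfgS$fc_min, cfgS$p_max, cfgS$fdr_max))
  geneDE <- pipelineStage("screen_mrna", differentialScreen(
    sim$mrna, labs[1], labs[2], cfgS$fc_min, cfgS$p_max, cfgS$fdr_max))
  emit(mirDE, "screen_mirna.csv")
  emit(geneDE, "screen_mrna.csv")

  # --- nomination ----------------------------------------------------------
  cfgN <- config$nominate
  nom <- pipelineStage("nominate", {
    planted <- sim$truth[sim$truth$kind == "target_slope", ]
    decoys <- withSeed(seed + 23, data.frame(
      mirna_id = cfgE$mir_id,
      gene_id = sample(rownames(sim$mrna),
                       min(cfgN$n_decoy_interactions, nrow(sim$mrna)))))
    repo <- mergeRepositories(list(
      validated = data.frame(mirna_id = planted$partner,
                             gene_id = planted$feature),
      predicted = decoys), evidence = c("validated", "predicted"))
    deGenes <- selectSignificant(geneDE)
    candidates <- intersectDeTargets(deGenes, repo, cfgE$mir_id)
    # fall back to all repository targets if the DE gate leaves < k genes
    if (length(candidates) < cfgN$k)
      candidates <- intersectDeTargets(rownames(sim$mrna), repo, cfgE$mir_id)
    sig <- mirFamilySignal(sim$mirna, cfgE$mir_id)
    inverseCorrelationRank(sig, sim$mrna, candidates, k = cfgN$k)
  })
  emit(nom, "nominated_targets.csv")

  # --- survival screen -----------------------------------------------------
  cfgV <- config$survival
  surv <- pipelineStage("survive", {
    clinical <- simulateSurvival(cfgV$n_subjects,
                                 hazardRatio = cfgV$hazard_ratio,
                                 baselineHazard = cfgV$baseline_hazard,
                                 censorRate = cfgV$censor_rate,
                                 quantileCut = cfgV$q, seed = seed + 31)
    genes <- c("PLANTED", paste0("NULL", seq_len(cfgV$n_null_genes)))
    exprM <- withSeed(seed + 32, {
      m <- matrix(rnorm(length(genes) * cfgV$n_subjects, 8, 1),
                  length(genes), cfgV$n_subjects,
                  dimnames = list(genes, clinical$subject_id))
      m["PLANTED", ] <- clinical$expr
      m
    })
    survivalScreen(exprM, clinical, q = cfgV$q)
  })
  emit(surv, "survival_screen.csv")

  # --- spheroids -----------------------------------------------------------
  cfgP <- config$spheroids
  sph <- pipelineStage("spheroids", {
    sizes <- lapply(seq_along(cfgP$conditions), function(i)
      simulateSpheroids(cfgP$conditions[[i]], cfgP$n_objects,
                        seed = seed + 40 + i)$sizes)
    names(sizes) <- names(cfgP$conditions)
    pairwiseKsTests(sizes, nResamples = cfgP$resamples, seed = seed + 50)
  })
  emit(sph, "spheroid_ks.csv")

  # --- in-situ quantification ---------------------------------------------
  cfgF <- config$field
  cells <- pipelineStage("ishquant", {
    layout <- sampleCellLayout(cfgF$n_cells, shape = cfgF$shape,
                               seed = seed + 61)
    fld <- simulateFieldImage(cfgF$shape, layout,
                              background = cfgF$background,
                              noiseSd = cfgF$noise_sd, seed = seed + 62)
    quantifyField(fld$image)
  })
  emit(cells, "cell_intensities.csv")

  # --- assays --------------------------------------------------------------
  cfgQ <- config$cq
  dd <- pipelineStage("ddcq", ddcq(simulateCq(
    cfgQ$planted_fold, cfgQ$n_per_group, cfgQ$cq_sd, seed = seed + 71)))
  emit(dd$samples, "ddcq_samples.csv")
  cfgG <- config$gap
  gap <- pipelineStage("gap", {
    mk <- function(rate, s) lapply(seq_len(cfgG$n_replicates), function(r)
      simulateGapSeries(rate, noiseSd = cfgG$noise_sd, seed = s + r))
    cmp <- compareGapClosure(mk(cfgG$rates[1], seed + 80),
                             mk(cfgG$rates[2], seed + 90))
    data.frame(condition = names(cfgG$rates),
               mean_gap_fraction_6h = c(mean(cmp$fractions_a),
                                        mean(cmp$fractions_b)),
               p_value = cmp$p_value)
  })
  emit(gap, "gap_closure.csv")

  manifest <- list(
    package = "stemir",
    version = as.character(packageVersion("stemir")),
    seed = seed,
    parameters = config,
    outputs = setNames(as.list(unname(tools::md5sum(outputs))),
                       basename(outputs)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
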