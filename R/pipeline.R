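# End-to-end orchestration of the synthetic study:
# simulate -> normalize -> model -> diagnose -> call -> validate, with a
# manifest of seeds, digests and stage outputs.

#' Assemble a run configuration
#'
#' Collects every analysis threshold and simulation parameter in one
#' validated list. Defaults are the printed analysis rules: responsive-gene
#' fold-change cutoff 0.585 with raw p <= 0.05 (criterion 1) and >= 0.5
#' (criterion 2), dampening threshold -0.5, DEG FDR 0.05, qPCR Ct gate 30,
#' cell QC at 1000 genes and 25% mitochondrial content.
#'
#' @param outDir output directory.
#' @param seed master seed; stage seeds are derived from it.
#' @param nGenes,nDonorsPerGroup,libSize simulation size parameters.
#' @param nResponsive,responsiveLfc planted responsive genes and their
#'   absolute log2FC.
#' @param dampenFrac,dampenLfc,dampenGroups dampening scenario parameters.
#' @param fcThreshold,p1,p2 responsive-caller thresholds.
#' @param deltaThreshold dampening cutoff.
#' @param degFdr adjusted-p cutoff for DEG counting.
#' @param ctGate qPCR Ct exclusion gate.
#' @param qcMinGenes,qcMaxMito single-cell QC thresholds.
#' @param bootstrapReplicates bootstrap replicates (0 disables the stage).
#' @param qpcrTargets number of responsive genes carried into the simulated
#'   qPCR validation.
#' @param qpcrNoiseSd Ct measurement noise.
#' @param groups disease groups analysed (separately).
#' @return named list (class "pdlsigConfig").
#' @export
runConfig <- function(outDir = tempfile("pdlsig_run_"), seed = 1L,
                      nGenes = 2000, nDonorsPerGroup = 3, libSize = 2e6,
                      nResponsive = 100, responsiveLfc = 1.5,
                      dampenFrac = 0, dampenLfc = -1, dampenGroups = "NI",
                      fcThreshold = 0.585, p1 = 0.05, p2 = 0.5,
                      deltaThreshold = -0.5, degFdr = 0.05, ctGate = 30,
                      qcMinGenes = 1000, qcMaxMito = 0.25,
                      bootstrapReplicates = 0, qpcrTargets = 5,
                      qpcrNoiseSd = 0.2, groups = c("NI", "RA")) {
  cfg <- as.list(environment())
  stopifnot(cfg$fcThreshold > 0, cfg$p1 >= 0, cfg$p1 <= 1,
            cfg$p2 >= 0, cfg$p2 <= 1, cfg$deltaThreshold < 0,
            cfg$degFdr >= 0, cfg$degFdr <= 1, cfg$ctGate > 0,
            cfg$qcMinGenes >= 1, cfg$qcMaxMito >= 0, cfg$qcMaxMito <= 1,
            cfg$nGenes >= 10, cfg$nDonorsPerGroup >= 2)
  class(cfg) <- "pdlsigConfig"
  cfg
}

stageFile <- function(dir, ...) file.path(dir, paste0(...))

#' Run the full synthetic analysis pipeline
#'
#' Simulates a study under the configuration's truth, then per disease
#' group runs filtering, TMM normalization, precision weighting, the
#' donor-blocked moderated-t contrasts, the dampening summary, the
#' responsive-gene caller with truth recovery, optional bootstrap
#' stability, and the qPCR validation arm. Every artifact is written under
#' `config$outDir` and listed in the returned manifest; rerunning the same
#' configuration reproduces identical outputs.
#'
#' @param config list from [runConfig()].
#' @return the manifest (invisibly written to manifest.json): stage
#'   outputs, seeds, file digests, timings, and headline numbers (DEG
#'   counts, dampened fractions, responsive-gene counts, recovery).
#' @export
runPipeline <- function(config = runConfig()) {
  stopifnot(inherits(config, "pdlsigConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(
    utils::packageVersion("pdlsig")), seed = config$seed, stages = list())
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    ts <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(elapsed = round(
      proc.time()[["elapsed"]] - ts, 3))
    val
  }

  design <- fiveConditionDesign(config$nDonorsPerGroup,
                                groups = config$groups)
  truth <- stage("simulate_truth", simulateTruth(
    design, nGenes = config$nGenes, nResponsive = config$nResponsive,
    responsiveLfc = config$responsiveLfc, dampenFrac = config$dampenFrac,
    dampenLfc = config$dampenLfc, dampenGroups = config$dampenGroups,
    libSize = config$libSize, seed = config$seed))
  se <- stage("simulate_counts", simulateBulkCounts(truth, design))
  writeCounts(se, stageFile(config$outDir, "counts.tsv"))
  writeDesignTable(design, stageFile(config$outDir, "design.tsv"))
  writeTruth(truth, stageFile(config$outDir, "truth.json"))

  results <- list()
  for (g in config$groups) {
    res <- stage(paste0("contrasts_", g), fitContrasts(se, group = g))
    for (cn in names(res$tables))
      writeContrastTable(res$tables[[cn]],
                         stageFile(config$outDir, g, "_", cn, ".tsv"))
    degs <- vapply(res$tables, function(tb)
      sum(resultTable(tb)$p_adj <= config$degFdr), numeric(1))
    damp <- stage(paste0("dampening_", g), deltaLog2Fc(
      res$tables$TNFsPD1_vs_control, res$tables$TNF_vs_control,
      threshold = config$deltaThreshold, group = g))
    writeDampening(damp, stageFile(config$outDir, g, "_dampening.json"),
                   stageFile(config$outDir, g, "_dampening.tsv"))
    calls <- stage(paste0("responsive_", g), callResponsive(
      res$tables$TNFsPD1_vs_TNF, res$tables$KO_PDL1_vs_TNF,
      res$tables$KO_PDL2_vs_TNF, fcThreshold = config$fcThreshold,
      p1 = config$p1, p2 = config$p2))
    writeResponsiveCalls(calls,
                         stageFile(config$outDir, g, "_responsive.tsv"))
    recov <- recoverTruth(calls, truth)
    boot <- NULL
    if (config$bootstrapReplicates >= 50) {
      boot <- stage(paste0("bootstrap_", g), bootstrapStability(
        se, group = g, contrast = "TNFsPD1_vs_TNF",
        nReplicates = config$bootstrapReplicates,
        seed = config$seed + 100L))
      writeStability(boot, stageFile(config$outDir, g, "_bootstrap.tsv"),
                     stageFile(config$outDir, g, "_bootstrap.json"))
    }
    results[[g]] <- list(
      deg_counts = as.list(degs),
      dampened_fraction = damp@dampenedFraction,
      amplified_fraction = damp@amplifiedFraction,
      n_responsive = sum(resultTable(calls)$responsive),
      recovery = recov,
      bootstrap_median_rho = if (!is.null(boot)) medianRho(boot) else NULL,
      consensus_rho = consensusRho(res$ebayes))
  }

  # qPCR validation arm on a few planted responsive genes plus a null
  # reference gene
  nullGenes <- geneIds(truth)[truth@ligandDependency == "none" &
                                rowSums(abs(truth@tnfEffect)) == 0 &
                                rowSums(abs(truth@spd1Effect)) == 0]
  targets <- utils::head(responsiveGenes(truth), config$qpcrTargets)
  qpcrSummary <- NULL
  if (length(targets) && length(nullGenes)) {
    refGene <- nullGenes[1L]
    ct <- stage("simulate_qpcr", simulateQpcr(
      truth, design, targets = targets, referenceGene = refGene,
      noiseSd = config$qpcrNoiseSd))
    writeCtTable(ct, stageFile(config$outDir, "qpcr_ct.csv"))
    keptTargets <- ctExclusion(ct, threshold = config$ctGate)$retained
    if (length(keptTargets)) {
      dd <- stage("ddct", ddct(
        ct[ct$target %in% c(keptTargets, refGene), ],
        referenceGene = refGene, baselineCondition = "TNF"))
      utils::write.table(dd$records,
                         stageFile(config$outDir, "qpcr_ddct.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      qpcrSummary <- list(n_targets = length(targets),
                          n_retained = length(keptTargets))
    }
  }
  manifest$results <- results
  manifest$qpcr <- qpcrSummary
  manifest$inputs <- as.list(tools::md5sum(c(
    counts = stageFile(config$outDir, "counts.tsv"),
    design = stageFile(config$outDir, "design.tsv"))))
  manifest$elapsed <- round(proc.time()[["elapsed"]] - t0, 3)
  jsonlite::write_json(manifest,
                       stageFile(config$outDir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(manifest)
}

#' Validate count and design files
#'
#' Checks the on-disk inputs against the type invariants (non-negative
#' integer counts, unique identifiers, known condition vocabulary, donor
#' consistency) without mutating them.
#'
#' @param countsPath counts TSV or MTX path.
#' @param designPath design TSV path.
#' @return character vector of violations (empty when clean).
#' @export
validateInputs <- function(countsPath, designPath) {
  violations <- character()
  x <- readCounts(countsPath)
  if (anyDuplicated(rownames(x)))
    violations <- c(violations, "duplicate gene identifiers")
  if (anyDuplicated(colnames(x)))
    violations <- c(violations, "duplicate sample identifiers")
  neg <- which(x < 0, arr.ind = TRUE)
  if (nrow(neg))
    violations <- c(violations, paste0(
      "negative count for gene ", rownames(x)[neg[, 1L]],
      ", sample ", colnames(x)[neg[, 2L]]))
  if (any(x != floor(x)))
    violations <- c(violations, "non-integer counts")
  design <- readDesignTable(designPath)
  chk <- tryCatch({ checkDesignTable(design); NULL },
                  error = function(e) conditionMessage(e))
  if (!is.null(chk)) violations <- c(violations, chk)
  if (!is.null(colnames(x)) && "sample_id" %in% names(design)) {
    missing <- setdiff(colnames(x), design$sample_id)
    if (length(missing))
      violations <- c(violations, paste0(
        "sample missing from design: ", missing))
  }
  violations
}
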