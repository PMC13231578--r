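# Synthetic-data generators: bulk NB counts with donor random effects,
# comparative-Ct qPCR tables, and structured single-cell matrices, each with
# a recorded ground truth for recovery testing.

#' Build the five-condition stimulation design
#'
#' Constructs the sample sheet of the sPD1 stimulation experiment: each donor
#' (primary FLS cell line) contributes one sample per condition (unstimulated
#' control, TNF, TNF+sPD1, and TNF+sPD1 on PD-L1 or PD-L2 knockout cells),
#' within either the non-inflammatory (NI) or rheumatoid arthritis (RA)
#' disease group.
#'
#' @param nDonorsPerGroup donors (cell lines) per disease group; the study
#'   design uses 3.
#' @param groups disease groups to include.
#' @param conditions conditions to include (subset of the five-arm design).
#' @return data.frame with columns sample_id, donor_id, disease_group,
#'   condition.
#' @export
fiveConditionDesign <- function(nDonorsPerGroup = 3, groups = c("NI", "RA"),
                                conditions = conditionLevels()) {
  bad <- setdiff(conditions, conditionLevels())
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  rows <- do.call(rbind, lapply(groups, function(g) {
    donors <- sprintf("%s_d%d", g, seq_len(nDonorsPerGroup))
    expand.grid(donor_id = donors, condition = conditions,
                stringsAsFactors = FALSE)[, c("donor_id", "condition")] |>
      transform(disease_group = g)
  }))
  rows$sample_id <- paste(rows$donor_id, rows$condition, sep = ".")
  rows <- rows[, c("sample_id", "donor_id", "disease_group", "condition")]
  rownames(rows) <- NULL
  checkDesignTable(rows)
}

#' Draw a synthetic ground truth for the bulk experiment
#'
#' Samples every generative parameter of the negative-binomial bulk model:
#' per-gene baselines and dispersions, donor random effects, TNF response
#' effects, planted ligand-dependent sPD1 effects, an optional dampening
#' scenario in which sPD1 attenuates a fraction of the TNF-induced genes in
#' selected groups, and per-sample intended sequencing depths.
#'
#' @param design sample sheet from [fiveConditionDesign()].
#' @param nGenes number of genes (study scale ~20000; tests use far fewer).
#' @param baselineMean,baselineSd normal parameters of the per-gene baseline
#'   log2 abundance.
#' @param dispersionMeanLog,dispersionSdLog lognormal parameters of the NB
#'   dispersion (default centred on 0.05, a typical bulk RNA-seq scale).
#' @param donorSd SD of the per-donor, per-gene additive log2 shift
#'   (default 0.3; donor variability dominates treatment effects, as in the
#'   underlying experiment).
#' @param fracTnf fraction of genes responding to TNF.
#' @param tnfLfcSd SD of TNF-responder log2 fold-changes.
#' @param nResponsive number of planted sPD1-responsive (ligand-dependent)
#'   genes.
#' @param responsiveLfc absolute log2FC of the planted sPD1 effect (sign
#'   drawn at random per gene).
#' @param ligandProbs named probabilities over PD-L1 / PD-L2 / both for the
#'   ligand dependency of responsive genes.
#' @param responsiveGroups groups in which the responsive effect is active
#'   (default: all groups in the design).
#' @param dampenFrac fraction of TNF-induced genes receiving an additional
#'   sPD1 attenuation (`dampenLfc`) in `dampenGroups`; these genes stay
#'   ligand-unattributed.
#' @param dampenLfc log2 attenuation applied to dampened genes (negative).
#' @param dampenGroups groups receiving the dampening scenario.
#' @param libSize,libSizeSdLog lognormal parameters of the intended
#'   per-sample depth (default centred on 30 million reads).
#' @param seed integer RNG seed; the truth is a pure function of it.
#' @return a [SyntheticTruth-class] object.
#' @export
simulateTruth <- function(design, nGenes = 20000,
                          baselineMean = 5, baselineSd = 2,
                          dispersionMeanLog = log(0.05),
                          dispersionSdLog = 0.4,
                          donorSd = 0.3,
                          fracTnf = 0.2, tnfLfcSd = 2,
                          nResponsive = 0, responsiveLfc = 1.5,
                          ligandProbs = c("PD-L1" = 0.4, "PD-L2" = 0.4,
                                          "both" = 0.2),
                          responsiveGroups = NULL,
                          dampenFrac = 0, dampenLfc = -1,
                          dampenGroups = "NI",
                          libSize = 3e7, libSizeSdLog = 0.15,
                          seed = 1L) {
  checkDesignTable(design)
  if (nResponsive > 0 && responsiveLfc == 0)
    stop("planted responsive genes require a nonzero sPD1 effect")
  groups <- unique(as.character(design$disease_group))
  if (is.null(responsiveGroups)) responsiveGroups <- groups
  donors <- unique(as.character(design$donor_id))
  withSeed(seed, {
    geneIds <- sprintf("g%05d", seq_len(nGenes))
    baseline <- stats::rnorm(nGenes, baselineMean, baselineSd)
    phi <- stats::rlnorm(nGenes, dispersionMeanLog, dispersionSdLog)
    donorEff <- matrix(stats::rnorm(nGenes * length(donors), 0, donorSd),
                       nGenes, length(donors),
                       dimnames = list(geneIds, donors))
    tnf <- matrix(0, nGenes, length(groups),
                  dimnames = list(geneIds, groups))
    nTnf <- round(fracTnf * nGenes)
    tnfIdx <- sample.int(nGenes, nTnf)
    tnf[tnfIdx, ] <- stats::rnorm(nTnf, 0, tnfLfcSd)

    spd1 <- matrix(0, nGenes, length(groups),
                   dimnames = list(geneIds, groups))
    ligand <- rep("none", nGenes)
    if (nResponsive > 0) {
      respIdx <- sample.int(nGenes, nResponsive)
      sgn <- sample(c(-1, 1), nResponsive, replace = TRUE)
      spd1[respIdx, responsiveGroups] <- sgn * responsiveLfc
      ligand[respIdx] <- sample(names(ligandProbs), nResponsive,
                                replace = TRUE, prob = ligandProbs)
    } else {
      respIdx <- integer()
    }
    if (dampenFrac > 0) {
      induced <- setdiff(which(tnf[, 1L] > 0), respIdx)
      nDamp <- round(dampenFrac * length(induced))
      dampIdx <- sample(induced, nDamp)
      spd1[dampIdx, intersect(dampenGroups, groups)] <-
        spd1[dampIdx, intersect(dampenGroups, groups)] + dampenLfc
    }
    libs <- stats::rlnorm(nrow(design), log(libSize), libSizeSdLog)
    names(libs) <- design$sample_id
    methods::new("SyntheticTruth",
                 geneIds = geneIds, baselineLog2Mean = baseline,
                 dispersion = phi, donorEffects = donorEff,
                 tnfEffect = tnf, spd1Effect = spd1,
                 ligandDependency = ligand, librarySizes = libs,
                 seed = as.integer(seed))
  })
}

# Share of the sPD1 effect retained in a knockout arm, per dependency label:
# the matched ligand loses its share (all of it for a single-ligand gene,
# half for a "both" gene, nothing for unattributed or other-ligand genes).
koRetainedShare <- function(dependency, knockedOut) {
  ifelse(dependency == knockedOut, 0,
         ifelse(dependency == "both", 0.5, 1))
}

# log2-scale condition effect active for each (gene, sample) pair.
conditionEffectMatrix <- function(truth, design) {
  g <- length(truth@geneIds)
  eff <- matrix(0, g, nrow(design),
                dimnames = list(truth@geneIds, design$sample_id))
  grp <- as.character(design$disease_group)
  cond <- as.character(design$condition)
  for (j in seq_len(nrow(design))) {
    if (cond[j] == "control") next
    e <- truth@tnfEffect[, grp[j]]
    if (cond[j] == "TNF_sPD1")
      e <- e + truth@spd1Effect[, grp[j]]
    else if (cond[j] == "KO_PDL1_TNF_sPD1")
      e <- e + truth@spd1Effect[, grp[j]] *
        koRetainedShare(truth@ligandDependency, "PD-L1")
    else if (cond[j] == "KO_PDL2_TNF_sPD1")
      e <- e + truth@spd1Effect[, grp[j]] *
        koRetainedShare(truth@ligandDependency, "PD-L2")
    eff[, j] <- e
  }
  eff
}

#' Expected counts under a synthetic truth
#'
#' The NB mean surface: library-size-scaled relative abundances
#' 2^(baseline + donor effect + active condition effects), normalized by the
#' total baseline abundance so that expected totals track the intended
#' depths.
#'
#' @param truth a [SyntheticTruth-class].
#' @param design sample sheet covering donors recorded in `truth`.
#' @return matrix of expected counts, genes x samples.
#' @export
expectedCounts <- function(truth, design) {
  checkDesignTable(design)
  missing <- setdiff(unique(design$donor_id), colnames(truth@donorEffects))
  if (length(missing))
    stop("donor(s) missing from truth: ", paste(missing, collapse = ", "))
  badGrp <- setdiff(unique(as.character(design$disease_group)),
                    colnames(truth@tnfEffect))
  if (length(badGrp))
    stop("disease group(s) missing from truth: ",
         paste(badGrp, collapse = ", "))
  libs <- truth@librarySizes[design$sample_id]
  if (anyNA(libs))
    stop("truth records no library size for some design samples")
  rel <- truth@baselineLog2Mean +
    truth@donorEffects[, as.character(design$donor_id), drop = FALSE] +
    conditionEffectMatrix(truth, design)
  norm <- sum(2^truth@baselineLog2Mean)
  mu <- sweep(2^rel, 2L, libs / norm, `*`)
  dimnames(mu) <- list(truth@geneIds, design$sample_id)
  mu
}

#' Simulate bulk NB counts for a design
#'
#' Draws gene x sample counts NB(mu, phi) with variance mu + phi * mu^2,
#' where mu comes from [expectedCounts()]. Knockout conditions suppress the
#' planted sPD1 effect for genes whose ligand dependency matches the knocked
#' out ligand ("both" genes lose half per knockout). Bit-identical for a
#' fixed seed.
#'
#' @param truth a [SyntheticTruth-class].
#' @param design sample sheet.
#' @param seed RNG seed; defaults to the truth's seed + 1.
#' @return a [SummarizedExperiment::SummarizedExperiment] with a `counts`
#'   assay and donor/group/condition column data.
#' @export
simulateBulkCounts <- function(truth, design, seed = NULL) {
  mu <- expectedCounts(truth, design)
  if (is.null(seed)) seed <- truth@seed + 1L
  size <- 1 / truth@dispersion
  counts <- withSeed(seed, {
    matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                          size = rep(size, times = ncol(mu))),
           nrow(mu), ncol(mu), dimnames = dimnames(mu))
  })
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(
      donor_id = design$donor_id,
      disease_group = design$disease_group,
      condition = design$condition,
      row.names = design$sample_id
    )
  )
}

#' Simulate a comparative-Ct qPCR table
#'
#' Generates technical-duplicate Ct values per sample and target gene, with
#' Ct decreasing one unit per doubling of expression (perfect amplification
#' efficiency) and Gaussian measurement noise. At zero noise the -ddCt of any
#' condition versus its within-donor baseline equals the planted log2FC
#' exactly.
#'
#' @param truth a [SyntheticTruth-class].
#' @param design sample sheet.
#' @param targets target gene identifiers (must exist in `truth`).
#' @param referenceGene housekeeping gene used for normalization; it must
#'   carry no planted condition effect.
#' @param noiseSd Gaussian noise SD in Ct units.
#' @param ct0 Ct of a gene at baseline log2 expression 0 (instrument anchor).
#' @param seed RNG seed; defaults to the truth's seed + 2.
#' @return data.frame with columns sample_id, donor_id, disease_group,
#'   condition, target, replicate, ct.
#' @export
simulateQpcr <- function(truth, design, targets, referenceGene,
                         noiseSd = 0.2, ct0 = 38, seed = NULL) {
  checkDesignTable(design)
  genes <- unique(c(targets, referenceGene))
  missing <- setdiff(genes, truth@geneIds)
  if (length(missing))
    stop("gene(s) absent from truth: ", paste(missing, collapse = ", "))
  ri <- match(referenceGene, truth@geneIds)
  if (any(truth@tnfEffect[ri, ] != 0) || any(truth@spd1Effect[ri, ] != 0))
    stop("reference gene '", referenceGene,
         "' carries a planted condition effect; ddCt normalization assumes ",
         "an unaffected reference")
  if (is.null(seed)) seed <- truth@seed + 2L
  gi <- match(genes, truth@geneIds)
  level <- truth@baselineLog2Mean[gi] +
    truth@donorEffects[gi, as.character(design$donor_id), drop = FALSE] +
    conditionEffectMatrix(truth, design)[gi, , drop = FALSE]
  ctMean <- ct0 - level  # genes x samples
  withSeed(seed, {
    long <- expand.grid(replicate = 1:2, target = genes,
                        sample_id = design$sample_id,
                        stringsAsFactors = FALSE)
    idx <- cbind(match(long$target, genes),
                 match(long$sample_id, design$sample_id))
    long$ct <- ctMean[idx] + stats::rnorm(nrow(long), 0, noiseSd)
    m <- match(long$sample_id, design$sample_id)
    data.frame(sample_id = long$sample_id,
               donor_id = design$donor_id[m],
               disease_group = design$disease_group[m],
               condition = design$condition[m],
               target = long$target,
               replicate = long$replicate,
               ct = long$ct,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a structured single-cell cohort
#'
#' Draws sparse per-cell counts with per-cell depth variation, designated
#' mitochondrial genes (identifier prefix "MT-"), per-cell-type and
#' per-richness planted marker shifts, and a configurable fraction of
#' planted low-quality cells (either very low depth, hence few detected
#' genes, or a high mitochondrial fraction). Cells are grouped into samples
#' labelled lymphocyte-rich or lymphocyte-poor.
#'
#' @param nSamples number of samples (donors).
#' @param cellsPerSample cells per sample.
#' @param cellTypes cell-type vocabulary.
#' @param richness per-sample labels in lymphocyte-rich / lymphocyte-poor;
#'   default: first half rich, second half poor.
#' @param markerEffects optional data.frame(gene, cell_type, richness,
#'   log2fc); NA in cell_type or richness matches everything.
#' @param nGenes total genes including mitochondrial.
#' @param nMito number of "MT-" genes.
#' @param mitoFraction expected mitochondrial count share in healthy cells.
#' @param lowQualityFrac fraction of planted low-quality cells.
#' @param meanDepth,depthSdLog lognormal depth of healthy cells.
#' @param lowDepth depth of planted low-depth cells.
#' @param highMitoFrac mitochondrial share of planted high-mito cells.
#' @param typeProbs optional matrix (richness levels x cell types) of type
#'   proportions; a lymphocyte-skewed default is used for the built-in type
#'   vocabulary.
#' @param seed RNG seed.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   `counts` assay and per-cell metadata (sample_id, cell_type, richness,
#'   planted_low_quality, low_quality_mode).
#' @export
simulateSingleCells <- function(nSamples = 10, cellsPerSample = 200,
                                cellTypes = c("fibroblast", "T_cell",
                                              "B_cell", "monocyte"),
                                richness = NULL, markerEffects = NULL,
                                nGenes = 1500, nMito = 10,
                                mitoFraction = 0.05,
                                lowQualityFrac = 0.05,
                                meanDepth = 2e4, depthSdLog = 0.25,
                                lowDepth = 300, highMitoFrac = 0.55,
                                typeProbs = NULL, seed = 1L) {
  if (cellsPerSample < 1) stop("cellsPerSample must be at least 1")
  if (!length(cellTypes)) stop("cellTypes must be non-empty")
  if (is.null(richness))
    richness <- rep(c("lymphocyte-rich", "lymphocyte-poor"),
                    c(ceiling(nSamples / 2), floor(nSamples / 2)))
  if (length(richness) != nSamples ||
      !all(richness %in% c("lymphocyte-rich", "lymphocyte-poor")))
    stop("richness must give lymphocyte-rich/-poor per sample")
  if (is.null(typeProbs)) {
    if (identical(cellTypes, c("fibroblast", "T_cell", "B_cell",
                               "monocyte"))) {
      typeProbs <- rbind(`lymphocyte-rich` = c(0.30, 0.40, 0.20, 0.10),
                         `lymphocyte-poor` = c(0.60, 0.15, 0.05, 0.20))
      colnames(typeProbs) <- cellTypes
    } else {
      typeProbs <- matrix(1 / length(cellTypes), 2, length(cellTypes),
                          dimnames = list(c("lymphocyte-rich",
                                            "lymphocyte-poor"), cellTypes))
    }
  }
  withSeed(seed, {
    geneIds <- c(sprintf("MT-%d", seq_len(nMito)),
                 sprintf("sc%05d", seq_len(nGenes - nMito)))
    isMito <- startsWith(geneIds, "MT-")
    w <- stats::rlnorm(nGenes, 0, 1)
    # scale mito abundances to the target healthy-cell share
    w[isMito] <- w[isMito] * (mitoFraction / (1 - mitoFraction)) *
      sum(w[!isMito]) / sum(w[isMito])

    nCells <- nSamples * cellsPerSample
    sampleId <- rep(sprintf("s%02d", seq_len(nSamples)),
                    each = cellsPerSample)
    rich <- rep(richness, each = cellsPerSample)
    cellType <- unlist(lapply(seq_len(nSamples), function(i) {
      sample(cellTypes, cellsPerSample, replace = TRUE,
             prob = typeProbs[richness[i], ])
    }))
    lowQ <- stats::runif(nCells) < lowQualityFrac
    mode <- ifelse(lowQ, sample(c("depth", "mito"), nCells, replace = TRUE),
                   "none")
    depth <- stats::rlnorm(nCells, log(meanDepth), depthSdLog)
    depth[mode == "depth"] <- stats::rlnorm(sum(mode == "depth"),
                                            log(lowDepth), 0.3)
    cols <- vector("list", nCells)
    for (j in seq_len(nCells)) {
      rel <- w
      if (!is.null(markerEffects)) {
        for (k in seq_len(nrow(markerEffects))) {
          me <- markerEffects[k, ]
          okType <- is.na(me$cell_type) || me$cell_type == cellType[j]
          okRich <- is.na(me$richness) || me$richness == rich[j]
          if (okType && okRich) {
            gi <- match(me$gene, geneIds)
            if (!is.na(gi)) rel[gi] <- rel[gi] * 2^me$log2fc
          }
        }
      }
      if (mode[j] == "mito")
        rel[isMito] <- rel[isMito] * (highMitoFrac / (1 - highMitoFrac)) *
          sum(rel[!isMito]) / sum(rel[isMito])
      cols[[j]] <- stats::rpois(nGenes, depth[j] * rel / sum(rel))
    }
    counts <- Matrix::Matrix(
      matrix(unlist(cols), nGenes, nCells,
             dimnames = list(geneIds,
                             sprintf("%s_c%04d", sampleId, seq_len(nCells)))),
      sparse = TRUE)
    SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(
        sample_id = sampleId,
        cell_type = cellType,
        richness = rich,
        planted_low_quality = lowQ,
        low_quality_mode = mode,
        row.names = colnames(counts)
      )
    )
  })
}
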