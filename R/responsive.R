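# The bespoke sPD1 reverse-signalling statistics: delta-log2FC dampening,
# the two-criterion responsive-gene caller with ligand attribution, the
# replicate-averaged z-score summary, and the truth-recovery harness.

alignTables <- function(a, b, what = c("tables")) {
  ta <- resultTable(a)
  tb <- resultTable(b)
  if (!setequal(ta$gene_id, tb$gene_id)) {
    nd <- length(union(setdiff(ta$gene_id, tb$gene_id),
                       setdiff(tb$gene_id, ta$gene_id)))
    stop("gene sets differ between contrast tables (symmetric difference ",
         "of ", nd, " genes)")
  }
  tb[match(ta$gene_id, tb$gene_id), , drop = FALSE]
}

#' Delta-log2FC dampening summary
#'
#' Per gene, delta = log2FC(TNF+sPD1 vs control) - log2FC(TNF vs control):
#' negative values mean sPD1 attenuated the TNF response. Genes with delta
#' at or below the threshold (default -0.5) count as dampened; genes at or
#' above the mirrored threshold as amplified.
#'
#' @param tableSpd1 [ContrastTable-class] of TNF+sPD1 vs control.
#' @param tableTnf [ContrastTable-class] of TNF vs control, same gene set.
#' @param threshold dampening cutoff on delta (default -0.5).
#' @param group disease group label carried into the summary.
#' @return a [DampeningSummary-class].
#' @export
deltaLog2Fc <- function(tableSpd1, tableTnf, threshold = -0.5,
                        group = "NI") {
  if (threshold >= 0) stop("the dampening threshold must be negative")
  ts <- resultTable(tableSpd1)
  tt <- alignTables(tableSpd1, tableTnf)
  delta <- stats::setNames(ts$log2fc - tt$log2fc, ts$gene_id)
  methods::new("DampeningSummary", group = group, delta = delta,
               threshold = threshold,
               dampenedFraction = mean(delta <= threshold),
               amplifiedFraction = mean(delta >= -threshold),
               meanDelta = mean(delta),
               medianDelta = stats::median(delta))
}

#' Call sPD1-responsive genes with ligand attribution
#'
#' The compound two-criterion filter: (1) at least a 50% change under sPD1
#' on the TNF background, |log2FC| >= `fcThreshold` with raw p <= `p1` in
#' the TNF+sPD1 vs TNF table; (2) small or unchanged expression in a
#' knockout arm, |log2FC| < `fcThreshold` with raw p >= `p2` in that
#' KO vs TNF table. A gene is responsive when criterion 1 holds and
#' criterion 2 holds for at least one ligand (both, when `requireBoth`);
#' the attribution records which knockout abolished the response ("both"
#' when both arms qualify). Boundaries follow the printed rules exactly:
#' |log2FC| equal to the threshold passes criterion 1 and fails criterion 2.
#'
#' @param tableSpd1 [ContrastTable-class] of TNF+sPD1 vs TNF.
#' @param tableKoL1 [ContrastTable-class] of PD-L1-KO+TNF+sPD1 vs TNF.
#' @param tableKoL2 [ContrastTable-class] of PD-L2-KO+TNF+sPD1 vs TNF.
#' @param fcThreshold absolute log2FC cutoff, default 0.585 (a 50% change).
#' @param p1 raw-p ceiling for criterion 1 (default 0.05, unadjusted).
#' @param p2 raw-p floor for criterion 2 (default 0.5, unadjusted).
#' @param requireBoth require both knockout arms to qualify.
#' @return a [ResponsiveCalls-class].
#' @export
callResponsive <- function(tableSpd1, tableKoL1, tableKoL2,
                           fcThreshold = 0.585, p1 = 0.05, p2 = 0.5,
                           requireBoth = FALSE) {
  if (fcThreshold <= 0) stop("fcThreshold must be positive")
  if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1)
    stop("p-value thresholds must lie in [0, 1]")
  ts <- resultTable(tableSpd1)
  t1 <- alignTables(tableSpd1, tableKoL1)
  t2 <- alignTables(tableSpd1, tableKoL2)
  c1 <- abs(ts$log2fc) >= fcThreshold & ts$p <= p1
  c2L1 <- abs(t1$log2fc) < fcThreshold & t1$p >= p2
  c2L2 <- abs(t2$log2fc) < fcThreshold & t2$p >= p2
  responsive <- c1 & if (requireBoth) (c2L1 & c2L2) else (c2L1 | c2L2)
  attribution <- rep("none", nrow(ts))
  attribution[responsive & c2L1 & c2L2] <- "both"
  attribution[responsive & c2L1 & !c2L2] <- "PD-L1"
  attribution[responsive & !c2L1 & c2L2] <- "PD-L2"
  calls <- data.frame(
    gene_id = ts$gene_id,
    log2fc = ts$log2fc,
    direction = ifelse(ts$log2fc >= 0, "up", "down"),
    passes_criterion1 = c1,
    criterion2_pdl1 = c2L1,
    criterion2_pdl2 = c2L2,
    responsive = responsive,
    attribution = attribution,
    stringsAsFactors = FALSE
  )
  methods::new("ResponsiveCalls", calls = calls, fcThreshold = fcThreshold,
               p1 = p1, p2 = p2, requireBoth = requireBoth)
}

#' Condition-averaged z-score matrix
#'
#' Standardizes each gene across the included samples (mean 0, SD 1 with the
#' n-1 denominator) and averages the z-scores within each condition, the
#' summary underlying replicate-averaged heatmaps. Genes with zero variance
#' are dropped with a warning.
#'
#' @param y expression matrix (genes x samples) or
#'   [NormalizedCounts-class].
#' @param design sample sheet matching the columns of `y`.
#' @param genes genes to include (must be rows of `y`).
#' @param conditions conditions to include (default: all in the design).
#' @return matrix of average z-scores, genes x conditions.
#' @export
zscoreSummary <- function(y, design, genes, conditions = NULL) {
  Y <- if (is(y, "NormalizedCounts")) log2Cpm(y) else as.matrix(y)
  design <- sampleTable(design)
  if (is.null(conditions))
    conditions <- intersect(conditionLevels(), unique(design$condition))
  keepS <- design$condition %in% conditions
  design <- design[keepS, , drop = FALSE]
  missing <- setdiff(genes, rownames(Y))
  if (length(missing))
    stop("gene(s) not present in the matrix: ",
         paste(missing, collapse = ", "))
  if (!all(conditions %in% design$condition))
    stop("every requested condition needs at least one sample")
  Z <- Y[genes, design$sample_id, drop = FALSE]
  sds <- apply(Z, 1L, stats::sd)
  zero <- sds < 1e-12
  if (any(zero)) {
    warning("dropping zero-variance gene(s): ",
            paste(genes[zero], collapse = ", "))
    Z <- Z[!zero, , drop = FALSE]
    sds <- sds[!zero]
  }
  Z <- (Z - rowMeans(Z)) / sds
  out <- vapply(conditions, function(cc) {
    rowMeans(Z[, design$condition == cc, drop = FALSE])
  }, numeric(nrow(Z)))
  matrix(out, nrow(Z), length(conditions),
         dimnames = list(rownames(Z), conditions))
}

#' Recovery of the planted responsive genes
#'
#' Compares a call set against the generator's ground truth: sensitivity is
#' the fraction of planted ligand-dependent genes that were called,
#' precision the fraction of calls that were planted, and attribution
#' accuracy the fraction of correctly called genes whose ligand label
#' matches the planted dependency. Precision is NA when nothing was called.
#'
#' @param calls a [ResponsiveCalls-class].
#' @param truth a [SyntheticTruth-class] sharing gene identifiers.
#' @return list with sensitivity, precision, attributionAccuracy, nPlanted,
#'   nCalled, nCorrect.
#' @export
recoverTruth <- function(calls, truth) {
  cl <- resultTable(calls)
  shared <- intersect(cl$gene_id, geneIds(truth))
  if (!length(shared))
    stop("calls and truth share no gene identifiers")
  planted <- intersect(responsiveGenes(truth), shared)
  called <- intersect(responsiveGenes(calls), shared)
  correct <- intersect(planted, called)
  sens <- if (length(planted)) length(correct) / length(planted) else NA_real_
  prec <- if (length(called)) length(correct) / length(called) else NA_real_
  attAcc <- NA_real_
  if (length(correct)) {
    truthDep <- stats::setNames(truth@ligandDependency, geneIds(truth))
    callAtt <- stats::setNames(cl$attribution, cl$gene_id)
    attAcc <- mean(callAtt[correct] == truthDep[correct])
  }
  list(sensitivity = sens, precision = prec, attributionAccuracy = attAcc,
       nPlanted = length(planted), nCalled = length(called),
       nCorrect = length(correct))
}
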