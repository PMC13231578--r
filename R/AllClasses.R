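# Central S4 classes for the sPD1 reverse-signalling analysis.

#' @include AllGenerics.R
NULL

# Condition vocabulary of the five-arm stimulation design:
# unstimulated mock-transfected control; TNF-primed mock; TNF-primed +
# soluble PD1; TNF + sPD1 on a PD-L1 knockout; TNF + sPD1 on a PD-L2 knockout.
conditionLevels <- function() {
  c("control", "TNF", "TNF_sPD1", "KO_PDL1_TNF_sPD1", "KO_PDL2_TNF_sPD1")
}

diseaseGroups <- function() c("NI", "RA")

contrastNames <- function() {
  c("TNF_vs_control", "TNFsPD1_vs_control", "TNFsPD1_vs_TNF",
    "KO_PDL1_vs_TNF", "KO_PDL2_vs_TNF")
}

ligandLevels <- function() c("none", "PD-L1", "PD-L2", "both")

#' SyntheticTruth: the recorded generative state of a simulated study
#'
#' Holds every planted quantity of the negative-binomial bulk generator:
#' per-gene baseline abundance and dispersion, per-donor log2 shifts, the
#' disease-group-specific TNF and sPD1 condition effects, the PD-L1/PD-L2
#' dependency label of each sPD1 effect, and the intended per-sample
#' sequencing depths. Downstream recovery tests compare estimates against
#' this record.
#'
#' @slot geneIds character, unique gene identifiers.
#' @slot baselineLog2Mean numeric, per-gene baseline expression (log2 scale,
#'   relative abundance).
#' @slot dispersion numeric, per-gene NB dispersion phi (variance mu+phi*mu^2).
#' @slot donorEffects matrix genes x donors of additive log2 shifts.
#' @slot tnfEffect matrix genes x groups: log2FC of TNF vs control.
#' @slot spd1Effect matrix genes x groups: log2FC of TNF+sPD1 vs TNF.
#' @slot ligandDependency character in none/PD-L1/PD-L2/both, per gene.
#' @slot librarySizes named numeric, intended depth per sample.
#' @slot seed integer RNG seed used by the generator.
#' @export
setClass("SyntheticTruth",
  representation(
    geneIds = "character",
    baselineLog2Mean = "numeric",
    dispersion = "numeric",
    donorEffects = "matrix",
    tnfEffect = "matrix",
    spd1Effect = "matrix",
    ligandDependency = "character",
    librarySizes = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticTruth", function(object) {
  g <- length(object@geneIds)
  msg <- character()
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, "gene identifiers must be unique")
  if (length(object@baselineLog2Mean) != g || length(object@dispersion) != g ||
      length(object@ligandDependency) != g)
    msg <- c(msg, "per-gene slots must match the number of genes")
  if (any(object@dispersion <= 0))
    msg <- c(msg, "dispersion must be strictly positive")
  if (any(object@librarySizes <= 0))
    msg <- c(msg, "library sizes must be strictly positive")
  if (nrow(object@donorEffects) != g || nrow(object@tnfEffect) != g ||
      nrow(object@spd1Effect) != g)
    msg <- c(msg, "effect matrices must have one row per gene")
  if (!all(object@ligandDependency %in% ligandLevels()))
    msg <- c(msg, "ligand dependency labels outside none/PD-L1/PD-L2/both")
  dep <- object@ligandDependency != "none"
  if (any(dep & apply(object@spd1Effect, 1L, function(x) all(x == 0))))
    msg <- c(msg, "ligand-dependent genes must carry a nonzero sPD1 effect")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@geneIds), "genes,",
      ncol(object@donorEffects), "donors,",
      length(object@librarySizes), "samples\n")
  cat("  sPD1-responsive (ligand-dependent) genes:",
      sum(object@ligandDependency != "none"), "\n")
  cat("  seed:", object@seed, "\n")
})

#' @rdname accessors
#' @export
setMethod("geneIds", "SyntheticTruth", function(object) object@geneIds)

#' @rdname accessors
#' @export
setMethod("responsiveGenes", "SyntheticTruth", function(object)
  object@geneIds[object@ligandDependency != "none"])

#' NormalizedCounts: filtered, TMM-normalized, precision-weighted expression
#'
#' Result of the normalization front-end: log2-CPM values for the kept genes,
#' per-sample TMM scaling factors (geometric mean 1), and voom-style
#' mean-variance precision weights on the same gene x sample grid.
#'
#' @slot log2Cpm matrix, kept genes x samples.
#' @slot normFactors named numeric, per-sample TMM factors.
#' @slot weights matrix, precision weights (strictly positive, finite).
#' @slot keptGenes character, genes surviving the CPM filter (input order).
#' @slot libSizes named numeric, raw library sizes.
#' @export
setClass("NormalizedCounts",
  representation(
    log2Cpm = "matrix",
    normFactors = "numeric",
    weights = "matrix",
    keptGenes = "character",
    libSizes = "numeric"
  )
)

setValidity("NormalizedCounts", function(object) {
  msg <- character()
  if (abs(mean(log(object@normFactors))) > 1e-8)
    msg <- c(msg, "TMM factors must have geometric mean 1")
  if (!all(is.finite(object@weights)) || any(object@weights <= 0))
    msg <- c(msg, "precision weights must be strictly positive and finite")
  if (!identical(dim(object@log2Cpm), dim(object@weights)))
    msg <- c(msg, "log2Cpm and weights must share dimensions")
  if (nrow(object@log2Cpm) != length(object@keptGenes))
    msg <- c(msg, "one log2Cpm row per kept gene required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NormalizedCounts", function(object) {
  cat("NormalizedCounts:", nrow(object@log2Cpm), "kept genes x",
      ncol(object@log2Cpm), "samples\n")
  cat("  TMM factors in [", round(min(object@normFactors), 3), ",",
      round(max(object@normFactors), 3), "]\n")
})

#' @rdname accessors
#' @export
setMethod("log2Cpm", "NormalizedCounts", function(object) object@log2Cpm)

#' @rdname accessors
#' @export
setMethod("normFactors", "NormalizedCounts", function(object) object@normFactors)

#' @rdname accessors
#' @export
setMethod("precisionWeights", "NormalizedCounts", function(object) object@weights)

#' @rdname accessors
#' @export
setMethod("keptGenes", "NormalizedCounts", function(object) object@keptGenes)

#' GlsFit: per-gene generalized least-squares fit under donor blocking
#'
#' Gene-wise GLS estimates under the block-exchangeable intra-donor
#' correlation structure combined with observation-level precision weights.
#'
#' @slot coefficients matrix genes x coefficients.
#' @slot covUnscaled array p x p x genes of unscaled coefficient covariances.
#' @slot sigma2 numeric, per-gene residual variances.
#' @slot df numeric, residual degrees of freedom (shared across genes).
#' @slot rho numeric, intra-donor correlation used.
#' @slot design design matrix used for the fit.
#' @slot blocks character, donor label per sample.
#' @slot avgExpr numeric, per-gene average log2-CPM.
#' @export
setClass("GlsFit",
  representation(
    coefficients = "matrix",
    covUnscaled = "array",
    sigma2 = "numeric",
    df = "numeric",
    rho = "numeric",
    design = "matrix",
    blocks = "character",
    avgExpr = "numeric"
  )
)

setMethod("show", "GlsFit", function(object) {
  cat("GlsFit:", nrow(object@coefficients), "genes,",
      ncol(object@coefficients), "coefficients, residual df",
      object@df, ", rho =", round(object@rho, 3), "\n")
})

#' EBayesState: empirical Bayes variance moderation state
#'
#' The estimated scaled-inverse-chi-square prior on gene-wise residual
#' variances: prior degrees of freedom d0 (1e6 encodes infinity) and prior
#' variance s0^2, plus the inputs and the consensus intra-donor correlation
#' when one was estimated. Posterior variances shrink each observed s_g^2
#' toward s0^2 with weight d0/(d0+d_g).
#'
#' @slot d0 numeric prior degrees of freedom (>= 0, capped at 1e6).
#' @slot s0Sq numeric prior variance.
#' @slot sGSq numeric per-gene residual variances.
#' @slot dG numeric per-gene residual degrees of freedom.
#' @slot consensusRho numeric, NA when not estimated.
#' @export
setClass("EBayesState",
  representation(
    d0 = "numeric",
    s0Sq = "numeric",
    sGSq = "numeric",
    dG = "numeric",
    consensusRho = "numeric"
  )
)

setValidity("EBayesState", function(object) {
  msg <- character()
  if (object@s0Sq <= 0) msg <- c(msg, "s0Sq must be positive")
  if (object@d0 < 0) msg <- c(msg, "d0 must be non-negative")
  post <- posteriorVarCalc(object)
  lo <- pmin(object@s0Sq, object@sGSq) - 1e-10
  hi <- pmax(object@s0Sq, object@sGSq) + 1e-10
  if (object@d0 > 0 && (any(post < lo) || any(post > hi)))
    msg <- c(msg, "posterior variances must lie between s0Sq and sGSq")
  if (length(msg)) msg else TRUE
})

posteriorVarCalc <- function(object) {
  (object@d0 * object@s0Sq + object@dG * object@sGSq) / (object@d0 + object@dG)
}

setMethod("show", "EBayesState", function(object) {
  cat("EBayesState: d0 =", signif(object@d0, 4),
      ", s0^2 =", signif(object@s0Sq, 4), "\n")
  if (!is.na(object@consensusRho))
    cat("  consensus intra-donor correlation:",
        round(object@consensusRho, 3), "\n")
})

#' @rdname accessors
#' @export
setMethod("priorDf", "EBayesState", function(object) object@d0)

#' @rdname accessors
#' @export
setMethod("priorVar", "EBayesState", function(object) object@s0Sq)

#' @rdname accessors
#' @export
setMethod("posteriorVar", "EBayesState", function(object) posteriorVarCalc(object))

#' @rdname accessors
#' @export
setMethod("consensusRho", "EBayesState", function(object) object@consensusRho)

#' ContrastTable: per-gene statistics for one named contrast
#'
#' One row per kept gene with the log2 fold-change, moderated t statistic,
#' total degrees of freedom, raw and Benjamini-Hochberg adjusted p-values,
#' and average expression.
#'
#' @slot contrast character, one of the five analysis contrasts.
#' @slot table data.frame with columns gene_id, log2fc, t, df, p, p_adj,
#'   avg_expr.
#' @export
setClass("ContrastTable",
  representation(contrast = "character", table = "data.frame")
)

setValidity("ContrastTable", function(object) {
  tab <- object@table
  need <- c("gene_id", "log2fc", "t", "df", "p", "p_adj", "avg_expr")
  msg <- character()
  if (!all(need %in% names(tab)))
    msg <- c(msg, paste("missing columns:",
                        paste(setdiff(need, names(tab)), collapse = ", ")))
  else {
    if (any(tab$p < 0 | tab$p > 1) || any(tab$p_adj < 0 | tab$p_adj > 1))
      msg <- c(msg, "p-values must lie in [0, 1]")
    if (any(tab$p_adj < tab$p - 1e-12))
      msg <- c(msg, "adjusted p must not fall below raw p")
    if (anyDuplicated(tab$gene_id))
      msg <- c(msg, "one row per gene required")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ContrastTable", function(object) {
  cat("ContrastTable:", object@contrast, "-", nrow(object@table), "genes,",
      sum(object@table$p_adj <= 0.05), "DEGs at FDR 0.05\n")
})

#' @rdname accessors
#' @export
setMethod("contrastName", "ContrastTable", function(object) object@contrast)

#' @rdname accessors
#' @export
setMethod("resultTable", "ContrastTable", function(object) object@table)

#' @rdname accessors
#' @export
setMethod("geneIds", "ContrastTable", function(object) object@table$gene_id)

#' @export
setMethod("as.data.frame", "ContrastTable",
          function(x, ...) x@table)

#' BootstrapStability: donor-resampling stability of a contrast ranking
#'
#' Spearman correlations between bootstrap-replicate and original log2FC
#' vectors, their median, and the stability category: stable when the median
#' exceeds 0.9, unstable below 0.8, intermediate otherwise (boundaries fall
#' to intermediate).
#'
#' @slot contrast character contrast name.
#' @slot rhos numeric per-replicate Spearman correlations.
#' @slot medianRho numeric.
#' @slot category character in stable/intermediate/unstable.
#' @slot nReplicates integer.
#' @slot redraws integer, replicates redrawn because a condition was lost.
#' @slot donorDraws matrix of resampled donor indices, replicates x donors.
#' @slot seed integer.
#' @export
setClass("BootstrapStability",
  representation(
    contrast = "character",
    rhos = "numeric",
    medianRho = "numeric",
    category = "character",
    nReplicates = "integer",
    redraws = "integer",
    donorDraws = "matrix",
    seed = "integer"
  )
)

setValidity("BootstrapStability", function(object) {
  msg <- character()
  if (any(object@rhos < -1 - 1e-12 | object@rhos > 1 + 1e-12))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  expect <- stabilityCategoryCalc(object@medianRho)
  if (!identical(object@category, expect))
    msg <- c(msg, "category inconsistent with median rho")
  if (length(msg)) msg else TRUE
})

stabilityCategoryCalc <- function(medianRho) {
  if (medianRho > 0.9) "stable"
  else if (medianRho < 0.8) "unstable"
  else "intermediate"
}

setMethod("show", "BootstrapStability", function(object) {
  cat("BootstrapStability:", object@contrast, "-", object@nReplicates,
      "replicates, median rho", round(object@medianRho, 3),
      paste0("(", object@category, ")"), "\n")
})

#' @rdname accessors
#' @export
setMethod("medianRho", "BootstrapStability", function(object) object@medianRho)

#' @rdname accessors
#' @export
setMethod("stabilityCategory", "BootstrapStability",
          function(object) object@category)

#' @rdname accessors
#' @export
setMethod("replicateRhos", "BootstrapStability", function(object) object@rhos)

#' @rdname accessors
#' @export
setMethod("contrastName", "BootstrapStability", function(object) object@contrast)

#' ResponsiveCalls: sPD1-responsive genes with ligand attribution
#'
#' Per-gene outcome of the two-criterion compound filter: criterion 1 flags a
#' >= 50% change under sPD1 on a TNF background; criterion 2 flags an
#' unchanged expression in a ligand-knockout arm. A gene is responsive when
#' criterion 1 holds and criterion 2 holds for at least one ligand (or both,
#' if so configured); the attribution records which.
#'
#' @slot calls data.frame with columns gene_id, log2fc, direction,
#'   passes_criterion1, criterion2_pdl1, criterion2_pdl2, responsive,
#'   attribution.
#' @slot fcThreshold numeric, |log2FC| cutoff (default log2(1.5)).
#' @slot p1 numeric, raw-p cutoff for criterion 1.
#' @slot p2 numeric, raw-p floor for criterion 2.
#' @slot requireBoth logical, TRUE demands both knockout arms qualify.
#' @export
setClass("ResponsiveCalls",
  representation(
    calls = "data.frame",
    fcThreshold = "numeric",
    p1 = "numeric",
    p2 = "numeric",
    requireBoth = "logical"
  )
)

setValidity("ResponsiveCalls", function(object) {
  cl <- object@calls
  msg <- character()
  bad <- cl$responsive & !(cl$passes_criterion1 &
                             (cl$criterion2_pdl1 | cl$criterion2_pdl2))
  if (any(bad))
    msg <- c(msg, "responsive calls must satisfy criterion 1 and a criterion 2")
  both <- cl$responsive & cl$criterion2_pdl1 & cl$criterion2_pdl2
  if (any(cl$attribution[both] != "both") ||
      any(cl$attribution[cl$responsive & !both] == "both"))
    msg <- c(msg, "attribution 'both' must match the two criterion-2 flags")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ResponsiveCalls", function(object) {
  cl <- object@calls
  cat("ResponsiveCalls:", sum(cl$responsive), "responsive of", nrow(cl),
      "genes (PD-L1:", sum(cl$attribution == "PD-L1"),
      ", PD-L2:", sum(cl$attribution == "PD-L2"),
      ", both:", sum(cl$attribution == "both"), ")\n")
})

#' @rdname accessors
#' @export
setMethod("responsiveGenes", "ResponsiveCalls", function(object)
  object@calls$gene_id[object@calls$responsive])

#' @rdname accessors
#' @export
setMethod("resultTable", "ResponsiveCalls", function(object) object@calls)

#' DampeningSummary: distribution of per-gene delta-log2FC
#'
#' Delta is the (TNF+sPD1 vs control) log2FC minus the (TNF vs control)
#' log2FC per gene; values at or below the threshold (default -0.5) count as
#' dampened, values at or above its mirror as amplified.
#'
#' @slot group character disease group label.
#' @slot delta named numeric per-gene deltas.
#' @slot threshold numeric dampening cutoff (negative).
#' @slot dampenedFraction numeric.
#' @slot amplifiedFraction numeric.
#' @slot meanDelta numeric.
#' @slot medianDelta numeric.
#' @export
setClass("DampeningSummary",
  representation(
    group = "character",
    delta = "numeric",
    threshold = "numeric",
    dampenedFraction = "numeric",
    amplifiedFraction = "numeric",
    meanDelta = "numeric",
    medianDelta = "numeric"
  )
)

setValidity("DampeningSummary", function(object) {
  msg <- character()
  d <- object@delta
  if (length(d)) {
    if (abs(object@dampenedFraction - mean(d <= object@threshold)) > 1e-12 ||
        abs(object@amplifiedFraction - mean(d >= -object@threshold)) > 1e-12)
      msg <- c(msg, "fractions inconsistent with the stored delta vector")
    if (abs(object@meanDelta - mean(d)) > 1e-8 ||
        abs(object@medianDelta - stats::median(d)) > 1e-8)
      msg <- c(msg, "mean/median inconsistent with the stored delta vector")
  }
  if (object@dampenedFraction < 0 || object@dampenedFraction > 1 ||
      object@amplifiedFraction < 0 || object@amplifiedFraction > 1)
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DampeningSummary", function(object) {
  cat("DampeningSummary (", object@group, "): ",
      round(100 * object@dampenedFraction, 1), "% dampened (delta <= ",
      object@threshold, "), ",
      round(100 * object@amplifiedFraction, 1), "% amplified\n", sep = "")
})

#' @rdname accessors
#' @export
setMethod("deltas", "DampeningSummary", function(object) object@delta)

#' @rdname accessors
#' @export
setMethod("dampenedFraction", "DampeningSummary",
          function(object) object@dampenedFraction)

#' @rdname accessors
#' @export
setMethod("amplifiedFraction", "DampeningSummary",
          function(object) object@amplifiedFraction)

#' EnrichmentResult: gene-set scores correlated with a marker
#'
#' Per-sample single-sample enrichment scores of a gene set, the paired
#' marker expression values, and their Spearman correlation with Fisher-z
#' 95% interval, p-value and strength band (|rho| boundaries at 0.2, 0.4,
#' 0.6, 0.8).
#'
#' @slot scores named numeric per-sample enrichment scores.
#' @slot marker named numeric per-sample marker expression.
#' @slot rho numeric Spearman correlation.
#' @slot ciLow,ciHigh numeric Fisher-z interval bounds.
#' @slot p numeric two-sided p-value.
#' @slot band character strength band.
#' @export
setClass("EnrichmentResult",
  representation(
    scores = "numeric",
    marker = "numeric",
    rho = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    p = "numeric",
    band = "character"
  )
)

setValidity("EnrichmentResult", function(object) {
  msg <- character()
  if (abs(object@rho) > 1 + 1e-12)
    msg <- c(msg, "rho must lie in [-1, 1]")
  if (!identical(object@band, correlationBand(object@rho)))
    msg <- c(msg, "band inconsistent with rho")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult:", length(object@scores), "samples, rho =",
      round(object@rho, 3),
      sprintf("[%.3f, %.3f]", object@ciLow, object@ciHigh),
      "p =", signif(object@p, 3), paste0("(", object@band, ")"), "\n")
})

#' Correlation strength band
#'
#' Maps an absolute correlation onto the conventional strength vocabulary:
#' negligible below 0.2, weak in [0.2, 0.4), moderate in [0.4, 0.6), strong
#' in [0.6, 0.8), very strong at or above 0.8.
#'
#' @param rho numeric correlation in [-1, 1].
#' @return character band label.
#' @export
correlationBand <- function(rho) {
  a <- abs(rho)
  if (a >= 0.8) "very strong"
  else if (a >= 0.6) "strong"
  else if (a >= 0.4) "moderate"
  else if (a >= 0.2) "weak"
  else "negligible"
}

#' @rdname accessors
#' @export
setMethod("strengthBand", "EnrichmentResult", function(object) object@band)

#' @rdname accessors
#' @export
setMethod("strengthBand", "numeric", function(object) correlationBand(object))
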