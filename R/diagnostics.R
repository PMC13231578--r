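# Variance diagnostics: sample-level PCA, residual PCA after removing
# cell-line (donor) fixed effects, and bootstrap stability of contrast
# fold-change rankings.

#' Principal component overview of samples
#'
#' PCA of the samples (columns) of an expression matrix, via
#' `stats::prcomp` on the transposed matrix. Components are ordered by
#' decreasing variance and the variance-explained vector sums to one.
#'
#' @param mat expression matrix, genes x samples (or
#'   [NormalizedCounts-class]).
#' @param center,scale passed to `prcomp`.
#' @return list with `scores` (samples x components), `loadings`,
#'   `varExplained`.
#' @export
pcaOverview <- function(mat, center = TRUE, scale = FALSE) {
  X <- if (is(mat, "NormalizedCounts")) log2Cpm(mat) else as.matrix(mat)
  if (ncol(X) < 2) stop("PCA needs at least 2 samples")
  tX <- t(X)
  if (all(apply(tX, 2L, stats::var) < 1e-24))
    stop("matrix is constant: no variance to decompose")
  if (scale) {
    keep <- apply(tX, 2L, stats::var) > 1e-24
    tX <- tX[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(tX, center = center, scale. = scale)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, varExplained = ve)
}

#' Residual PCA after donor fixed effects
#'
#' Removes per-gene donor (cell line) means and decomposes the residual
#' matrix, which contains the variance not captured by cell line. Within
#' each donor the residuals of that donor's samples sum to zero per gene.
#'
#' @param y expression matrix (genes x samples) or
#'   [NormalizedCounts-class].
#' @param donors donor label per sample (each donor needs >= 2 samples).
#' @return list with the `pca` result of [pcaOverview()] and the
#'   `residuals` matrix.
#' @export
residualPca <- function(y, donors) {
  Y <- if (is(y, "NormalizedCounts")) log2Cpm(y) else as.matrix(y)
  donors <- as.character(donors)
  sizes <- table(donors)
  if (any(sizes < 2))
    stop("singleton donor(s): ",
         paste(names(sizes)[sizes < 2], collapse = ", "),
         " (residuals undefined)")
  E <- Y
  for (d in names(sizes)) {
    idx <- which(donors == d)
    E[, idx] <- Y[, idx, drop = FALSE] -
      rowMeans(Y[, idx, drop = FALSE])
  }
  list(pca = pcaOverview(E, center = TRUE, scale = FALSE), residuals = E)
}

# run the pipeline on one (possibly resampled) group and return the
# log2FC vector of one contrast, named by gene
contrastLog2Fc <- function(se, contrast, keepGenes = NULL, ...) {
  res <- fitContrasts(se, group = NULL, keepGenes = keepGenes,
                      contrasts = contrast, ...)
  tab <- resultTable(res$tables[[contrast]])
  stats::setNames(tab$log2fc, tab$gene_id)
}

#' Bootstrap stability of a contrast's fold-change ranking
#'
#' Donors (cell lines) of one disease group are resampled with replacement;
#' each replicate carries all samples of every drawn donor (duplicates
#' relabelled as distinct pseudo-donors), the whole
#' filter-normalize-model-test pipeline is rerun on the resample restricted
#' to the originally kept genes, and the replicate log2FC vector is
#' compared to the original by Spearman correlation over the shared genes.
#' The median correlation is categorised as stable (> 0.9), unstable
#' (< 0.8) or intermediate.
#'
#' @param se SummarizedExperiment with counts and design column data.
#' @param group disease group to analyse.
#' @param contrast contrast name.
#' @param nReplicates bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param excludeDegenerate drop resamples consisting of a single donor
#'   repeated (kept by default: the model stays estimable after pseudo-donor
#'   relabelling).
#' @param ... normalization/model parameters forwarded to [fitContrasts()].
#' @return a [BootstrapStability-class] object.
#' @export
bootstrapStability <- function(se, group, contrast = "TNFsPD1_vs_TNF",
                               nReplicates = 1000, seed = 1L,
                               excludeDegenerate = FALSE, ...) {
  if (nReplicates < 50) stop("use at least 50 bootstrap replicates")
  sm <- sampleTable(se)
  sel <- sm$disease_group == group
  se <- se[, sel]
  sm <- sm[sel, , drop = FALSE]
  donors <- unique(as.character(sm$donor_id))
  if (length(donors) < 2) stop("need at least 2 donors in the group")
  conds <- unique(as.character(sm$condition))
  x <- countsMatrix(se)

  origKept <- cpmFilter(x)
  origFc <- contrastLog2Fc(se, contrast, ...)

  rhos <- numeric(nReplicates)
  draws <- matrix(NA_integer_, nReplicates, length(donors))
  redraws <- 0L
  withSeed(seed, {
    for (r in seq_len(nReplicates)) {
      repeat {
        idx <- sample.int(length(donors), length(donors), replace = TRUE)
        cols <- integer()
        newDonor <- character()
        for (k in seq_along(idx)) {
          dcols <- which(sm$donor_id == donors[idx[k]])
          cols <- c(cols, dcols)
          newDonor <- c(newDonor, rep(sprintf("bd%d", k), length(dcols)))
        }
        okCond <- all(conds %in% sm$condition[cols])
        okDeg <- !excludeDegenerate || length(unique(idx)) > 1L
        if (okCond && okDeg) break
        redraws <- redraws + 1L
      }
      draws[r, ] <- idx
      xr <- x[, cols, drop = FALSE]
      colnames(xr) <- sprintf("%s.s%02d", newDonor, seq_along(cols))
      smr <- data.frame(sample_id = colnames(xr),
                        donor_id = newDonor,
                        disease_group = sm$disease_group[cols],
                        condition = sm$condition[cols],
                        stringsAsFactors = FALSE)
      ser <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = xr),
        colData = S4Vectors::DataFrame(smr[, -1L],
                                       row.names = smr$sample_id))
      repFc <- contrastLog2Fc(ser, contrast, keepGenes = origKept, ...)
      shared <- intersect(names(repFc), names(origFc))
      rhos[r] <- stats::cor(repFc[shared], origFc[shared],
                            method = "spearman")
    }
  })
  med <- stats::median(rhos)
  methods::new("BootstrapStability", contrast = contrast, rhos = rhos,
               medianRho = med, category = stabilityCategoryCalc(med),
               nReplicates = as.integer(nReplicates),
               redraws = redraws, donorDraws = draws,
               seed = as.integer(seed))
}
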