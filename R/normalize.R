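# Expression filtering, TMM normalization, log2-CPM transformation and
# precision weights: the front-end every downstream model consumes.

#' CPM filter against the smallest library
#'
#' Keeps genes whose counts-per-million reach the threshold implied by
#' `minCount` reads in the smallest library (T = minCount * 1e6 / min
#' library size) in at least `minSamples` samples.
#'
#' @param counts count matrix or SummarizedExperiment with a `counts` assay.
#' @param minCount count threshold in the smallest library (default 10).
#' @param minSamples minimum number of samples at or above the CPM threshold
#'   (default 3, the smallest condition-by-group cell of the study design).
#' @return character vector of kept gene identifiers, in input order.
#' @export
cpmFilter <- function(counts, minCount = 10, minSamples = 3) {
  x <- countsMatrix(counts)
  if (minCount < 1 || minSamples < 1)
    stop("minCount and minSamples must be at least 1")
  lib <- colSums(x)
  if (any(lib == 0))
    stop("library is all zero for sample(s): ",
         paste(colnames(x)[lib == 0], collapse = ", "))
  thresh <- minCount * 1e6 / min(lib)
  cpm <- sweep(x, 2L, lib / 1e6, `/`)
  keep <- rowSums(cpm >= thresh) >= minSamples
  rownames(x)[keep]
}

#' Trimmed mean of M-values scaling factors
#'
#' Pairwise TMM factors against a reference sample: per sample, the
#' precision-weighted mean of gene-wise log2 expression ratios (M-values)
#' after two-sided trimming on M (`trimM`) and on average log intensity A
#' (`trimA`); genes with a zero count in either member of the pair are
#' excluded. The reference is the sample whose 75th-percentile count
#' fraction is closest to the across-sample mean. Factors are rescaled to
#' geometric mean 1.
#'
#' @param counts count matrix or SummarizedExperiment (at least 2 samples).
#' @param trimM two-sided trim fraction on M-values (default 0.30).
#' @param trimA two-sided trim fraction on A-values (default 0.05).
#' @param refColumn optional reference sample index.
#' @return named numeric vector of per-sample factors.
#' @export
tmmFactors <- function(counts, trimM = 0.30, trimA = 0.05,
                       refColumn = NULL) {
  x <- countsMatrix(counts)
  if (ncol(x) < 2) stop("TMM needs at least 2 samples")
  if (trimM < 0 || trimM >= 0.5 || trimA < 0 || trimA >= 0.5)
    stop("trim fractions must lie in [0, 0.5)")
  lib <- colSums(x)
  if (any(lib == 0))
    stop("library is all zero for sample(s): ",
         paste(colnames(x)[lib == 0], collapse = ", "))
  if (is.null(refColumn)) {
    f75 <- apply(x, 2L, function(v) stats::quantile(v, 0.75)) / lib
    refColumn <- which.min(abs(f75 - mean(f75)))
  }
  xr <- x[, refColumn]
  nr <- lib[refColumn]
  factors <- vapply(seq_len(ncol(x)), function(j) {
    xs <- x[, j]
    ns <- lib[j]
    ok <- xs > 0 & xr > 0
    if (sum(ok) < 2) {
      warning("fewer than 2 genes shared with the reference in sample ",
              colnames(x)[j], "; factor set to 1")
      return(1)
    }
    m <- log2((xs[ok] / ns) / (xr[ok] / nr))
    a <- 0.5 * log2((xs[ok] / ns) * (xr[ok] / nr))
    # delta-method variance of M, used as precision weight
    v <- (ns - xs[ok]) / (ns * xs[ok]) + (nr - xr[ok]) / (nr * xr[ok])
    if (max(abs(m)) < 1e-6) return(1)
    n <- length(m)
    loM <- floor(n * trimM) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * trimA) + 1
    hiA <- n + 1 - loA
    keep <- rank(m) >= loM & rank(m) <= hiM &
      rank(a) >= loA & rank(a) <= hiA
    f <- sum(m[keep] / v[keep], na.rm = TRUE) /
      sum(1 / v[keep], na.rm = TRUE)
    if (!is.finite(f)) f <- 0
    2^f
  }, numeric(1))
  factors <- factors / geometricMean(factors)
  names(factors) <- colnames(x)
  factors
}

#' log2 counts-per-million
#'
#' value = log2((count + prior) / (libSize * factor + 2 * prior) * 1e6).
#' With prior 0 the transform is invariant to joint scaling of counts and
#' library sizes; a positive prior keeps zero counts finite.
#'
#' @param object count matrix or SummarizedExperiment.
#' @param normFactors per-sample scaling factors (default 1).
#' @param priorCount non-negative pseudo-count (default 0.5).
#' @param libSizes optional library sizes (default column sums).
#' @return matrix of log2-CPM values.
#' @rdname accessors
#' @export
setMethod("log2Cpm", "matrix", function(object, normFactors = NULL,
                                        priorCount = 0.5, libSizes = NULL) {
  log2CpmMatrix(object, normFactors, priorCount, libSizes)
})

#' @rdname accessors
#' @export
setMethod("log2Cpm", "SummarizedExperiment",
          function(object, normFactors = NULL, priorCount = 0.5,
                   libSizes = NULL) {
  log2CpmMatrix(countsMatrix(object), normFactors, priorCount, libSizes)
})

log2CpmMatrix <- function(x, normFactors = NULL, priorCount = 0.5,
                          libSizes = NULL) {
  if (priorCount < 0) stop("priorCount must be non-negative")
  if (is.null(libSizes)) libSizes <- colSums(x)
  if (is.null(normFactors)) normFactors <- rep(1, ncol(x))
  if (any(normFactors <= 0)) stop("normalization factors must be positive")
  eff <- libSizes * normFactors
  t(log2(t(x + priorCount) / (eff + 2 * priorCount) * 1e6))
}

#' Mean-variance precision weights
#'
#' Observation-level weights from the voom mean-variance trend: per-gene
#' residual sqrt standard deviations are smoothed against average log2
#' count by lowess, and each observation's weight is the predicted standard
#' deviation at its fitted log-count raised to the power -4. The limma voom
#' machinery stands behind this computation; weights are clamped to a
#' positive finite range.
#'
#' @param counts count matrix or SummarizedExperiment (filtered genes).
#' @param design design matrix of full column rank.
#' @param normFactors per-sample TMM factors (default 1).
#' @param span lowess span (default 0.5).
#' @param clamp two-element positive range the weights are clamped to.
#' @return matrix of weights, genes x samples.
#' @export
voomWeights <- function(counts, design, normFactors = NULL, span = 0.5,
                        clamp = c(1e-6, 1e6)) {
  x <- countsMatrix(counts)
  if (qr(design)$rank < ncol(design))
    stop("design matrix must have full column rank")
  if (nrow(design) - ncol(design) <= 0)
    stop("no residual degrees of freedom for the mean-variance trend")
  lib <- colSums(x)
  if (is.null(normFactors)) normFactors <- rep(1, ncol(x))
  v <- limma::voom(x, design = design, lib.size = lib * normFactors,
                   span = span)
  w <- pmin(pmax(v$weights, clamp[1]), clamp[2])
  dimnames(w) <- dimnames(x)
  w
}

#' Filter, normalize and weight a count matrix
#'
#' Runs the full normalization front-end: CPM filter, TMM factors on the
#' kept genes, log2-CPM transform, and precision weights under the given
#' design.
#'
#' @param counts count matrix or SummarizedExperiment.
#' @param design design matrix for the weight trend; when NULL a condition
#'   model is built from the SummarizedExperiment column data (or an
#'   intercept-only model for bare matrices).
#' @param minCount,minSamples CPM filter parameters.
#' @param trimM,trimA TMM trim fractions.
#' @param priorCount log2-CPM pseudo-count.
#' @param span lowess span of the weight trend.
#' @return a [NormalizedCounts-class] object.
#' @export
normalizeCounts <- function(counts, design = NULL, minCount = 10,
                            minSamples = 3, trimM = 0.30, trimA = 0.05,
                            priorCount = 0.5, span = 0.5) {
  x <- countsMatrix(counts)
  kept <- cpmFilter(x, minCount = minCount, minSamples = minSamples)
  xk <- x[kept, , drop = FALSE]
  if (is.null(design)) {
    if (is(counts, "SummarizedExperiment") &&
        "condition" %in% names(SummarizedExperiment::colData(counts))) {
      cond <- factor(SummarizedExperiment::colData(counts)$condition,
                     levels = intersect(conditionLevels(),
                                        SummarizedExperiment::colData(counts)$condition))
      design <- stats::model.matrix(~cond)
    } else {
      design <- matrix(1, ncol(x), 1, dimnames = list(NULL, "(Intercept)"))
    }
  }
  # library sizes of the filtered matrix are used throughout, as in the
  # standard filter-then-normalize workflow
  nf <- tmmFactors(xk, trimM = trimM, trimA = trimA)
  lc <- log2CpmMatrix(xk, normFactors = nf, priorCount = priorCount)
  w <- voomWeights(xk, design = design, normFactors = nf, span = span)
  methods::new("NormalizedCounts", log2Cpm = lc, normFactors = nf,
               weights = w, keptGenes = kept, libSizes = colSums(xk))
}
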