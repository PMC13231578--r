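# Public-cohort arm: single-cell QC, percent-expressing, pseudobulk,
# single-sample gene-set enrichment, and marker correlation with strength
# banding.

cellCounts <- function(x) {
  if (is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x, "counts")
  x
}

#' Quality-control filter for single cells
#'
#' Removes cells with fewer than `minGenes` detected genes and/or a
#' mitochondrial count fraction above `maxMito` (a fraction exactly at the
#' threshold is retained), then removes genes with total UMI below
#' `minUmi`. Mitochondrial genes are identified by the "MT-" prefix.
#'
#' @param x cell-level count matrix (sparse or dense) or a
#'   SingleCellExperiment.
#' @param minGenes minimum detected genes per cell (default 1000).
#' @param maxMito maximum mitochondrial fraction (default 0.25).
#' @param minUmi minimum total UMI per gene (default 10).
#' @return list with `counts` (filtered matrix), `cells` (retained cell
#'   ids), `cellQC` (per-cell genes_detected, mito_fraction, pass),
#'   `removedLowGenes`, `removedHighMito`, `genesRemoved`, and `sce`
#'   (filtered SingleCellExperiment when one was supplied).
#' @export
qcFilterCells <- function(x, minGenes = 1000, maxMito = 0.25, minUmi = 10) {
  counts <- cellCounts(x)
  mito <- startsWith(rownames(counts), "MT-")
  detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mitoFrac <- if (any(mito))
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(total, 1)
  else rep(0, ncol(counts))
  passGenes <- detected >= minGenes
  passMito <- mitoFrac <= maxMito
  pass <- passGenes & passMito
  qc <- data.frame(cell_id = colnames(counts),
                   genes_detected = as.integer(detected),
                   mito_fraction = as.numeric(mitoFrac),
                   pass = pass,
                   stringsAsFactors = FALSE)
  kept <- counts[, pass, drop = FALSE]
  geneKeep <- Matrix::rowSums(kept) >= minUmi
  out <- list(counts = kept[geneKeep, , drop = FALSE],
              cells = colnames(counts)[pass],
              cellQC = qc,
              removedLowGenes = sum(!passGenes),
              removedHighMito = sum(!passMito),
              genesRemoved = sum(!geneKeep))
  if (is(x, "SummarizedExperiment"))
    out$sce <- x[geneKeep, pass]
  out
}

#' Percent of cells expressing a gene
#'
#' Proportion of cells with a nonzero count, per group, on the percent
#' scale.
#'
#' @param x cell-level counts or SingleCellExperiment.
#' @param gene gene identifier.
#' @param grouping group label per cell (e.g. cell type); a single label is
#'   recycled.
#' @return named numeric, percent expressing per group.
#' @export
percentExpressing <- function(x, gene, grouping) {
  counts <- cellCounts(x)
  if (!gene %in% rownames(counts)) stop("gene not found: ", gene)
  grouping <- rep_len(as.character(grouping), ncol(counts))
  v <- as.numeric(counts[gene, ] > 0)
  100 * vapply(split(v, grouping), mean, numeric(1))
}

#' Pseudobulk log2-CPM per sample
#'
#' Sums counts over all cells of each sample (one biological replicate per
#' sample) and applies the log2-CPM transform with unit factors and a 0.5
#' pseudo-count.
#'
#' @param x cell-level counts or SingleCellExperiment.
#' @param sampleIds sample label per cell; defaults to the `sample_id`
#'   column of the SingleCellExperiment metadata.
#' @param priorCount pseudo-count of the log2-CPM transform.
#' @return matrix of log2-CPM values, genes x samples.
#' @export
pseudobulk <- function(x, sampleIds = NULL, priorCount = 0.5) {
  counts <- cellCounts(x)
  if (is.null(sampleIds)) {
    if (!is(x, "SummarizedExperiment") ||
        !"sample_id" %in% names(SummarizedExperiment::colData(x)))
      stop("sampleIds required when the input carries no sample_id column")
    sampleIds <- SummarizedExperiment::colData(x)$sample_id
  }
  sampleIds <- as.character(sampleIds)
  if (length(sampleIds) != ncol(counts))
    stop("one sample label per cell required")
  samples <- unique(sampleIds)
  agg <- vapply(samples, function(s)
    Matrix::rowSums(counts[, sampleIds == s, drop = FALSE]),
    numeric(nrow(counts)))
  agg <- matrix(agg, nrow(counts), length(samples),
                dimnames = list(rownames(counts), samples))
  log2CpmMatrix(agg, priorCount = priorCount)
}

#' Two-group pseudobulk comparison
#'
#' Mann-Whitney U test (two-sided) of one gene's pseudobulk expression
#' between two sample groups; exact for small sample sizes without ties,
#' normal approximation with tie correction otherwise.
#'
#' @param pb pseudobulk matrix from [pseudobulk()].
#' @param gene gene identifier.
#' @param groups group label per sample (exactly two levels).
#' @return list with p, statistic, and the group medians.
#' @export
pseudobulkTest <- function(pb, gene, groups) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required")
  v <- pb[gene, ]
  a <- v[groups == lev[1L]]
  b <- v[groups == lev[2L]]
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                            correct = TRUE))
  list(p = wt$p.value, statistic = unname(wt$statistic),
       medians = stats::setNames(c(stats::median(a), stats::median(b)), lev))
}

#' Single-sample gene-set enrichment scores
#'
#' Per gene, expression values are transformed by a Gaussian-kernel
#' cumulative density estimated across samples (bandwidth: per-gene SD / 4);
#' per sample, genes are ranked by the transformed value and a weighted
#' Kolmogorov-Smirnov random walk is run down the ranked list, stepping up
#' at set genes in proportion to the symmetric rank statistic |N/2 - rank|
#' raised to `tau`, and down by a uniform penalty at off-set genes. The
#' score is the largest positive deviation of the walk minus the magnitude
#' of its largest negative deviation.
#'
#' @param x expression matrix (genes x samples, continuous, e.g. log2-CPM),
#'   at least 3 samples.
#' @param geneSet character vector of set members (must intersect the
#'   matrix genes).
#' @param tau weight exponent on the rank statistic (default 1).
#' @return named numeric, one enrichment score per sample.
#' @export
geneSetScore <- function(x, geneSet, tau = 1) {
  X <- as.matrix(x)
  if (ncol(X) < 3) stop("need at least 3 samples")
  inSet <- rownames(X) %in% geneSet
  if (!any(inSet)) stop("gene set does not intersect the matrix genes")
  G <- nrow(X)
  S <- ncol(X)
  Z <- matrix(0, G, S, dimnames = dimnames(X))
  for (g in seq_len(G)) {
    h <- stats::sd(X[g, ]) / 4
    if (h < 1e-12) {
      Z[g, ] <- 0.5
    } else {
      Z[g, ] <- colMeans(stats::pnorm(outer(X[g, ], X[g, ], function(a, b)
        (b - a) / h)))
    }
  }
  m <- sum(inSet)
  scores <- numeric(S)
  for (j in seq_len(S)) {
    ord <- order(Z[, j], decreasing = TRUE)
    rnk <- seq_len(G)
    t_i <- abs(G / 2 - rnk)^tau
    setSorted <- inSet[ord]
    up <- ifelse(setSorted, t_i, 0)
    up <- up / sum(up)
    down <- if (G > m) ifelse(setSorted, 0, 1 / (G - m)) else rep(0, G)
    walk <- cumsum(up - down)
    scores[j] <- max(c(walk, 0)) + min(c(walk, 0))
  }
  stats::setNames(scores, colnames(X))
}

#' Correlate enrichment scores with a marker
#'
#' Spearman correlation between per-sample gene-set scores and a marker's
#' expression, with a Fisher-z 95% confidence interval, two-sided p, and
#' the strength band at |rho| boundaries 0.2 / 0.4 / 0.6 / 0.8.
#'
#' @param scores named numeric per-sample scores.
#' @param marker named numeric per-sample marker expression (paired by
#'   position when unnamed).
#' @return an [EnrichmentResult-class].
#' @export
correlateWithMarker <- function(scores, marker) {
  if (!is.null(names(scores)) && !is.null(names(marker))) {
    shared <- intersect(names(scores), names(marker))
    scores <- scores[shared]
    marker <- marker[shared]
  }
  n <- length(scores)
  if (n < 4 || length(marker) != n)
    stop("need at least 4 paired observations")
  ct <- suppressWarnings(stats::cor.test(scores, marker,
                                         method = "spearman"))
  rho <- unname(ct$estimate)
  if (abs(rho) >= 1 - 1e-15) {
    ci <- c(rho, rho)
  } else {
    z <- atanh(rho)
    se <- 1 / sqrt(n - 3)
    ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  methods::new("EnrichmentResult", scores = scores, marker = marker,
               rho = rho, ciLow = ci[1L], ciHigh = ci[2L], p = ct$p.value,
               band = correlationBand(rho))
}

#' Read a GMT gene-set file
#'
#' @param path GMT path (set name, description, then member genes, tab
#'   separated).
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1))
  sets
}
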