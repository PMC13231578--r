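# Shared fixture builders. Everything is generated in code; no stored data.

# small study: 3 donors per group, reduced depth for speed
quickStudy <- function(nGenes = 500, groups = "NI", seed = 1L, ...) {
  design <- fiveConditionDesign(3, groups = groups)
  truth <- simulateTruth(design, nGenes = nGenes, libSize = 2e6,
                         seed = seed, ...)
  list(design = design, truth = truth,
       se = simulateBulkCounts(truth, design))
}

# a ContrastTable with hand-set fold changes and p-values
contrastTableFrom <- function(log2fc, p = rep(0.5, length(log2fc)),
                              geneIds = sprintf("g%03d", seq_along(log2fc)),
                              contrast = "TNFsPD1_vs_TNF") {
  methods::new("ContrastTable", contrast = contrast, table = data.frame(
    gene_id = geneIds, log2fc = log2fc, t = log2fc, df = 10,
    p = p, p_adj = pdlsig::bhAdjust(p), avg_expr = 5,
    stringsAsFactors = FALSE))
}

# overwrite planted sPD1 effects for chosen genes (test-only surgery)
plantSpd1 <- function(truth, genes, values, ligand = "PD-L1",
                      groups = colnames(truth@spd1Effect)) {
  idx <- match(genes, truth@geneIds)
  stopifnot(!anyNA(idx))
  truth@spd1Effect[idx, groups] <- values
  truth@ligandDependency[idx] <- ligand
  methods::validObject(truth)
  truth
}

# mean silhouette of a 2-group labelling in a score matrix (rows = samples)
silhouetteScore <- function(scores, labels) {
  d <- as.matrix(stats::dist(scores))
  vapply(seq_along(labels), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_along(labels) != i])
    b <- min(vapply(unique(labels[!own]), function(l)
      mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)) |> mean()
}

# independent straight-line evaluation of the kernel-CDF rank-walk score,
# written as plain loops (oracle for geneSetScore)
gsvaOracle <- function(X, geneSet, tau = 1) {
  G <- nrow(X); S <- ncol(X)
  Z <- matrix(0, G, S)
  for (g in 1:G) {
    h <- stats::sd(X[g, ]) / 4
    for (s in 1:S) {
      if (h < 1e-12) Z[g, s] <- 0.5
      else {
        acc <- 0
        for (k in 1:S) acc <- acc + stats::pnorm((X[g, s] - X[g, k]) / h)
        Z[g, s] <- acc / S
      }
    }
  }
  inSet <- rownames(X) %in% geneSet
  m <- sum(inSet)
  out <- numeric(S)
  for (s in 1:S) {
    ord <- order(Z[, s], decreasing = TRUE)
    num <- 0; den <- 0
    for (pos in 1:G) if (inSet[ord[pos]]) den <- den + abs(G / 2 - pos)^tau
    walk <- 0; mx <- 0; mn <- 0
    for (pos in 1:G) {
      if (inSet[ord[pos]]) walk <- walk + abs(G / 2 - pos)^tau / den
      else walk <- walk - 1 / (G - m)
      if (walk > mx) mx <- walk
      if (walk < mn) mn <- walk
    }
    out[s] <- mx + mn
  }
  stats::setNames(out, colnames(X))
}
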