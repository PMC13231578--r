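# Single-cell QC, percent-expressing, pseudobulk, gene-set scoring and
# marker correlation.

test_that("cell QC applies both rules with the printed boundaries", {
  G <- 1200
  genes <- c(paste0("MT-", 1:4), sprintf("g%04d", 1:(G - 4)))
  mk <- function(detected, mitoCount) {
    v <- integer(G)
    v[5:(4 + detected)] <- 1L
    v[1] <- mitoCount
    v
  }
  counts <- cbind(
    ok = mk(1100, 100),
    low = mk(999, 0),           # 999 detected genes: removed
    mitoEdge = mk(1098, 366),   # 366/1464 = exactly 25% mito: retained
    mitoHigh = mk(1100, 800)
  )
  rownames(counts) <- genes
  qc <- qcFilterCells(counts, minGenes = 1000, maxMito = 0.25, minUmi = 0)
  expect_false("low" %in% qc$cells)
  expect_true("ok" %in% qc$cells)
  expect_true("mitoEdge" %in% qc$cells)   # > 25% is strict
  expect_false("mitoHigh" %in% qc$cells)
  expect_equal(qc$cellQC$mito_fraction[qc$cellQC$cell_id == "mitoEdge"],
               0.25, tolerance = 1e-10)
})

test_that("planted low-quality cells are removed at the planted rate", {
  sce <- simulateSingleCells(nSamples = 5, cellsPerSample = 200,
                             lowQualityFrac = 0.1, seed = 97)
  qc <- qcFilterCells(sce)
  n <- ncol(sce)
  removed <- n - length(qc$cells)
  bounds <- qbinom(c(0.005, 0.995), n, 0.1)
  expect_gte(removed, bounds[1])
  expect_lte(removed, bounds[2])
  # removal agrees with the planted flags almost everywhere
  planted <- SummarizedExperiment::colData(sce)$planted_low_quality
  expect_gt(mean((!qc$cellQC$pass) == planted), 0.98)
})

test_that("percent expressing counts nonzero cells per group", {
  counts <- rbind(gA = c(0, 0, 3, 1), gB = rep(0, 4))
  colnames(counts) <- paste0("c", 1:4)
  expect_equal(unname(percentExpressing(counts, "gA", rep("x", 4))), 50)
  expect_equal(unname(percentExpressing(counts, "gB",
                                        c("x", "x", "y", "y"))), c(0, 0))
  # invariant under positive scaling
  expect_equal(percentExpressing(counts * 7L, "gA", rep("x", 4)),
               percentExpressing(counts, "gA", rep("x", 4)))
  expect_error(percentExpressing(counts, "gC", "x"), "not found")
})

test_that("pseudobulk is aggregation-invariant and matches single cells", {
  set.seed(101)
  counts <- matrix(rpois(50 * 6, 5), 50, 6,
                   dimnames = list(paste0("g", 1:50), paste0("c", 1:6)))
  # one cell per sample: pseudobulk equals that cell's log2-CPM
  pb1 <- pseudobulk(counts, paste0("s", 1:6))
  expect_equal(unname(pb1), unname(log2Cpm(counts, priorCount = 0.5)),
               tolerance = 1e-12)
  # merging halves of a sample changes nothing
  pbA <- pseudobulk(counts, c("s1", "s1", "s1", "s1", "s2", "s2"))
  pbB <- pseudobulk(counts[, c(3, 1, 4, 2, 6, 5)],
                    c("s1", "s1", "s1", "s1", "s2", "s2"))
  expect_equal(pbA, pbB, tolerance = 1e-12)
})

test_that("pseudobulk comparison detects a planted richness shift", {
  hits <- 0L
  nSim <- 15L
  for (r in seq_len(nSim)) {
    sce <- simulateSingleCells(
      nSamples = 12, cellsPerSample = 60, nGenes = 300, nMito = 5,
      meanDepth = 3000, lowQualityFrac = 0,
      markerEffects = data.frame(gene = "sc00010", cell_type = NA,
                                 richness = "lymphocyte-rich", log2fc = 2),
      seed = 200 + r)
    pb <- pseudobulk(sce)
    rich <- tapply(SummarizedExperiment::colData(sce)$richness,
                   SummarizedExperiment::colData(sce)$sample_id,
                   function(x) x[1])[colnames(pb)]
    pt <- pseudobulkTest(pb, "sc00010", rich)
    if (pt$p <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.85 * nSim))
})

test_that("gene-set scores match the straight-line oracle", {
  set.seed(103)
  X <- matrix(rnorm(10 * 4, 6, 2), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  setGenes <- c("g2", "g5", "g9")
  expect_equal(geneSetScore(X, setGenes), gsvaOracle(X, setGenes),
               tolerance = 1e-8)
  expect_error(geneSetScore(X, "absent"), "intersect")
  expect_error(geneSetScore(X[, 1:2], setGenes), "3 samples")
})

test_that("gene-set scores rank-dominate and degenerate sensibly", {
  G <- 20
  X <- matrix(0, G, 3, dimnames = list(paste0("g", 1:G),
                                       c("A", "B", "C")))
  set.seed(107)
  setGenes <- paste0("g", 1:5)
  # set genes at the top of sample A, at the bottom of sample B
  X[, "A"] <- c(seq(10, 9, length.out = 5), seq(5, 1, length.out = 15))
  X[, "B"] <- c(seq(1, 2, length.out = 5), seq(6, 10, length.out = 15))
  X[, "C"] <- rnorm(G, 5, 3)
  sc <- geneSetScore(X, setGenes)
  expect_gt(sc["A"], sc["B"])
  # the all-gene set cannot discriminate samples
  scAll <- geneSetScore(X, rownames(X))
  expect_lt(diff(range(scAll)), 1e-8)
  # invariant under per-gene increasing affine maps
  X2 <- X * rep(runif(G, 0.5, 3), 3) + rep(rnorm(G), 3)
  expect_equal(geneSetScore(X2, setGenes), geneSetScore(X, setGenes),
               tolerance = 1e-10)
})

test_that("marker correlation reports rho, interval and strength band", {
  sc <- c(s1 = 0.1, s2 = 0.4, s3 = 0.5, s4 = 0.9, s5 = 1.2)
  res <- correlateWithMarker(sc, sc * 3 + 1)
  expect_equal(res@rho, 1)
  expect_identical(strengthBand(res), "very strong")
  expect_identical(strengthBand(0.53), "moderate")
  expect_identical(strengthBand(-0.53), "moderate")
  expect_identical(strengthBand(0.19), "negligible")
  expect_identical(strengthBand(0.2), "weak")
  expect_identical(strengthBand(0.6), "strong")
  expect_identical(strengthBand(0.8), "very strong")
  expect_error(correlateWithMarker(sc[1:3], sc[1:3]), "at least 4")
})

test_that("a suppressive marker yields negative correlations", {
  set.seed(109)
  hits <- 0L
  nSim <- 20L
  for (r in seq_len(nSim)) {
    n <- 20
    marker <- runif(n, 0, 4)
    G <- 60
    X <- matrix(rnorm(G * n, 5, 1), G, n,
                dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
    setGenes <- paste0("g", 1:10)
    # the marker monotonically suppresses the set genes
    X[setGenes, ] <- X[setGenes, ] - rep(marker * 1.5, each = 10)
    sc <- geneSetScore(X, setGenes)
    res <- correlateWithMarker(sc, setNames(marker, colnames(X)))
    if (res@rho < 0) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * nSim))
})

test_that("GMT files round-trip", {
  p <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg9"), p)
  sets <- readGmt(p)
  expect_identical(sets, list(setA = c("g1", "g2", "g3"), setB = "g9"))
})
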