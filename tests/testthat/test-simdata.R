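# Generators: determinism, NB moment recovery, knockout suppression, and
# the qPCR / single-cell emulators.

test_that("bulk counts are bit-identical under a fixed seed", {
  st <- quickStudy(nGenes = 100, seed = 3)
  se2 <- simulateBulkCounts(st$truth, st$design)
  expect_identical(SummarizedExperiment::assay(st$se),
                   SummarizedExperiment::assay(se2))
  tr2 <- simulateTruth(st$design, nGenes = 100, libSize = 2e6, seed = 3)
  expect_identical(st$truth@baselineLog2Mean, tr2@baselineLog2Mean)
})

test_that("NB moments match the planted mean surface", {
  # one condition, many donors, no donor noise: mean must track the
  # library-scaled baseline and the variance mu + phi mu^2
  design <- fiveConditionDesign(5000, groups = "NI", conditions = "control")
  truth <- simulateTruth(design, nGenes = 5, donorSd = 0,
                         dispersionMeanLog = log(0.01), dispersionSdLog = 0,
                         libSize = 1e5, libSizeSdLog = 0, seed = 9)
  se <- simulateBulkCounts(truth, design)
  mu <- expectedCounts(truth, design)
  x <- SummarizedExperiment::assay(se)
  phi <- truth@dispersion
  for (g in 1:5) {
    m <- mu[g, 1]
    v <- m + phi[g] * m^2
    seMean <- sqrt(v / ncol(x))
    expect_lt(abs(mean(x[g, ]) - m), 3 * seMean)
    # variance within 5 relative SDs of its sampling distribution
    expect_lt(abs(var(x[g, ]) / v - 1), 0.2)
  }
})

test_that("knockout arms suppress the matched ligand's effect", {
  design <- fiveConditionDesign(1, groups = "NI")
  truth <- simulateTruth(design, nGenes = 50, nResponsive = 20,
                         responsiveLfc = 1.5, donorSd = 0, libSize = 1e6,
                         libSizeSdLog = 0, seed = 4)
  mu <- expectedCounts(truth, design)
  cond <- design$condition
  dep <- truth@ligandDependency
  l1 <- which(dep == "PD-L1")
  expect_true(length(l1) > 0)
  # PD-L1-dependent genes: expected count in the PD-L1-KO arm equals TNF
  expect_equal(mu[l1, cond == "KO_PDL1_TNF_sPD1"],
               mu[l1, cond == "TNF"], ignore_attr = TRUE)
  # ... but not in the PD-L2-KO arm (effect retained there)
  expect_false(isTRUE(all.equal(mu[l1, cond == "KO_PDL2_TNF_sPD1"],
                                mu[l1, cond == "TNF"],
                                check.attributes = FALSE)))
  both <- which(dep == "both")
  if (length(both)) {
    # each knockout removes half of a "both" gene's effect (log2 scale)
    g <- both[1]
    s <- truth@spd1Effect[g, "NI"]
    expect_equal(log2(mu[g, cond == "KO_PDL1_TNF_sPD1"] /
                        mu[g, cond == "TNF"]), s / 2, tolerance = 1e-10)
  }
})

test_that("generators reject bad designs and labels", {
  design <- fiveConditionDesign(2, groups = "NI")
  truth <- simulateTruth(design, nGenes = 20, libSize = 1e5, seed = 1)
  bad <- design
  bad$condition[2] <- "TNF_mystery"
  expect_error(simulateBulkCounts(truth, bad), "TNF_mystery")
  other <- fiveConditionDesign(3, groups = "NI")
  expect_error(simulateBulkCounts(truth, other), "missing from truth")
  expect_error(fiveConditionDesign(2, conditions = "bogus"), "bogus")
})

test_that("noiseless qPCR tables return planted fold changes exactly", {
  design <- fiveConditionDesign(2, groups = "NI")
  truth <- simulateTruth(design, nGenes = 60, nResponsive = 0,
                         fracTnf = 0, libSize = 1e6, seed = 6)
  truth <- plantSpd1(truth, truth@geneIds[1], 1, "PD-L1")
  ref <- truth@geneIds[2]
  ct <- simulateQpcr(truth, design, targets = truth@geneIds[1:3],
                     referenceGene = ref, noiseSd = 0)
  dd <- ddct(ct, referenceGene = ref, baselineCondition = "TNF")
  spd1 <- dd$records[dd$records$condition == "TNF_sPD1", ]
  # planted sPD1 log2FC of 1 recovered exactly
  expect_equal(spd1$log2fc[spd1$target == truth@geneIds[1]], c(1, 1),
               tolerance = 1e-12)
  # null gene: ddCt 0, relative expression 1 in every condition
  nullRec <- dd$records[dd$records$target == truth@geneIds[3], ]
  expect_equal(nullRec$rel_expr, rep(1, nrow(nullRec)), tolerance = 1e-12)
})

test_that("noisy qPCR is unbiased for the planted effect", {
  design <- fiveConditionDesign(1, groups = "NI")
  truth <- simulateTruth(design, nGenes = 20, fracTnf = 0, libSize = 1e6,
                         seed = 8)
  truth <- plantSpd1(truth, truth@geneIds[1], 0.8, "PD-L2")
  ref <- truth@geneIds[2]
  est <- vapply(1:500, function(r) {
    ct <- simulateQpcr(truth, design, targets = truth@geneIds[1],
                       referenceGene = ref, noiseSd = 0.2, seed = 100 + r)
    dd <- ddct(ct, referenceGene = ref)
    dd$records$log2fc[dd$records$condition == "TNF_sPD1"]
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.8), 3 * se)
})

test_that("qPCR rejects a reference gene with planted effects", {
  design <- fiveConditionDesign(1, groups = "NI")
  truth <- simulateTruth(design, nGenes = 20, fracTnf = 0.5, libSize = 1e6,
                         seed = 2)
  affected <- truth@geneIds[which(truth@tnfEffect[, "NI"] != 0)[1]]
  expect_error(simulateQpcr(truth, design, targets = truth@geneIds[1],
                            referenceGene = affected),
               "planted condition effect")
})

test_that("single-cell generator is deterministic and structured", {
  sce <- simulateSingleCells(nSamples = 4, cellsPerSample = 50,
                             nGenes = 300, seed = 21)
  sce2 <- simulateSingleCells(nSamples = 4, cellsPerSample = 50,
                              nGenes = 300, seed = 21)
  expect_identical(as.matrix(SummarizedExperiment::assay(sce)),
                   as.matrix(SummarizedExperiment::assay(sce2)))
  expect_true(any(startsWith(rownames(sce), "MT-")))
  expect_error(simulateSingleCells(cellsPerSample = 0), "at least 1")
  # a gene with no counts anywhere is 0% expressing in every group
  counts <- SummarizedExperiment::assay(sce)
  zeroGene <- rownames(counts)[Matrix::rowSums(counts) == 0]
  if (!length(zeroGene)) {
    counts[1, ] <- 0
    zeroGene <- rownames(counts)[1]
  }
  pe <- percentExpressing(counts, zeroGene[1],
                          SummarizedExperiment::colData(sce)$cell_type)
  expect_true(all(pe == 0))
})

test_that("counts, design, truth and Ct tables round-trip through disk", {
  st <- quickStudy(nGenes = 40, seed = 5)
  d <- withr::local_tempdir()
  writeCounts(st$se, file.path(d, "c.tsv"))
  expect_equal(readCounts(file.path(d, "c.tsv")),
               SummarizedExperiment::assay(st$se), ignore_attr = FALSE)
  writeCounts(st$se, file.path(d, "c.mtx"), format = "mtx")
  m <- readCounts(file.path(d, "c.mtx"))
  expect_equal(m, SummarizedExperiment::assay(st$se), ignore_attr = TRUE)
  expect_identical(dimnames(m), dimnames(SummarizedExperiment::assay(st$se)))
  writeDesignTable(st$design, file.path(d, "design.tsv"))
  expect_equal(readDesignTable(file.path(d, "design.tsv")), st$design)
  writeTruth(st$truth, file.path(d, "truth.json"))
  tr <- readTruth(file.path(d, "truth.json"))
  expect_equal(tr@baselineLog2Mean, st$truth@baselineLog2Mean)
  expect_equal(tr@spd1Effect, st$truth@spd1Effect)
  expect_identical(responsiveGenes(tr), responsiveGenes(st$truth))
})
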