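# Donor-blocked modelling: design construction, GLS reductions, consensus
# correlation recovery, empirical Bayes moderation, and the moderated test.

test_that("design construction gives the expected ranks and blocks", {
  d <- fiveConditionDesign(3, groups = "NI",
                           conditions = c("control", "TNF", "TNF_sPD1"))
  fx <- buildDesign(d, blocking = "fixed")
  expect_equal(qr(fx$design)$rank, 3 + (3 - 1))
  rd <- buildDesign(d, blocking = "random")
  expect_identical(rd$blocks, as.character(d$donor_id))
  full <- buildDesign(fiveConditionDesign(3, groups = "NI"))
  expect_equal(qr(full$design)$rank, 5)
  # a condition with a single sample is not estimable
  d1 <- fiveConditionDesign(1, groups = "NI")
  expect_error(buildDesign(d1), "only one sample")
  # two-group model: per-group intercepts and condition indicators
  d2 <- fiveConditionDesign(2)
  X2 <- buildDesign(d2)$design
  expect_equal(qr(X2)$rank, 2 * 5)
})

test_that("GLS at rho = 0 with unit weights equals per-gene OLS", {
  set.seed(23)
  d <- fiveConditionDesign(3, groups = "NI")
  bd <- buildDesign(d)
  G <- 50
  Y <- matrix(rnorm(G * nrow(d)), G, nrow(d),
              dimnames = list(paste0("g", 1:G), d$sample_id))
  fit <- fitGls(Y, bd$design, bd$blocks, rho = 0)
  cond <- factor(d$condition, levels = intersect(conditionLevels(),
                                                 d$condition))
  for (g in c(1, 25, 50)) {
    ref <- lm(Y[g, ] ~ cond)
    expect_equal(unname(fit@coefficients[g, ]), unname(coef(ref)),
                 tolerance = 1e-10)
    expect_equal(unname(fit@sigma2[g]), summary(ref)$sigma^2,
                 tolerance = 1e-10)
  }
})

test_that("intra-donor correlation shrinks within-donor contrast SEs", {
  set.seed(29)
  d <- data.frame(sample_id = paste0("s", 1:4),
                  donor_id = rep(c("a", "b"), each = 2),
                  disease_group = "NI",
                  condition = rep(c("control", "TNF"), 2))
  bd <- buildDesign(d)
  Y <- matrix(rnorm(20 * 4), 20, 4,
              dimnames = list(paste0("g", 1:20), d$sample_id))
  cvec <- contrastVector(bd$design, "TNF_vs_control")
  seOf <- function(rho) {
    fit <- fitGls(Y, bd$design, bd$blocks, rho = rho)
    cu <- matrix(fit@covUnscaled, 4, 20)
    sqrt(colSums(cu * as.vector(outer(cvec, cvec))))
  }
  # paired-design algebra: Var(contrast) scales with (1 - rho)
  expect_true(all(seOf(0.95) < seOf(0)))
  expect_equal(unname(seOf(0.95) / seOf(0)),
               rep(sqrt(1 - 0.95), 20), tolerance = 1e-8)
  expect_error(fitGls(Y, bd$design, bd$blocks, rho = -1.5),
               "positive definite")
})

test_that("coefficients approach planted effects in the noiseless limit", {
  d <- fiveConditionDesign(3, groups = "NI")
  bd <- buildDesign(d)
  eff <- ifelse(d$condition %in% c("TNF", "TNF_sPD1",
                                   "KO_PDL1_TNF_sPD1",
                                   "KO_PDL2_TNF_sPD1"), 1, 0)
  set.seed(31)
  Y <- matrix(rep(eff, each = 30), 30, nrow(d),
              dimnames = list(paste0("g", 1:30), d$sample_id)) +
    matrix(rnorm(30 * nrow(d), 0, 1e-6), 30, nrow(d))
  fit <- fitGls(Y, bd$design, bd$blocks, rho = 0)
  expect_equal(unname(fit@coefficients[, "condTNF"]), rep(1, 30),
               tolerance = 1e-4)
})

test_that("design rank deficiency is reported with the aliased column", {
  X <- cbind(a = c(1, 1, 1, 1), b = c(1, 0, 1, 0), c = c(1, 0, 1, 0))
  Y <- matrix(rnorm(8), 2, 4)
  expect_error(fitGls(Y, X, blocks = c("d1", "d1", "d2", "d2"), rho = 0),
               "aliased")
})

test_that("consensus correlation recovers planted values", {
  set.seed(37)
  d <- fiveConditionDesign(3, groups = "NI")
  bd <- buildDesign(d)
  G <- 1500
  donorIdx <- match(d$donor_id, unique(d$donor_id))
  for (rhoT in c(0.5, 0)) {
    De <- matrix(rnorm(G * 3, 0, sqrt(rhoT)), G, 3)
    Y <- De[, donorIdx] +
      matrix(rnorm(G * nrow(d), 0, sqrt(1 - rhoT)), G, nrow(d))
    colnames(Y) <- d$sample_id
    est <- consensusCorrelation(Y, bd$design, bd$blocks)
    expect_lt(abs(est - rhoT), 0.1)
    expect_true(est > -0.99 && est < 0.99)
  }
  expect_error(consensusCorrelation(matrix(rnorm(20), 5, 4),
                                    matrix(1, 4, 1),
                                    c("a", "b", "c", "d")),
               "at least 2 donors")
})

test_that("empirical Bayes moderation matches its generative model", {
  set.seed(41)
  d0T <- 4; s0T <- 2; dfT <- 10; G <- 5000
  sig2 <- d0T * s0T / rchisq(G, d0T)
  s2 <- sig2 * rchisq(G, dfT) / dfT
  eb <- ebayesModerate(s2, df = dfT)
  expect_lt(abs(priorDf(eb) - d0T), 1)
  expect_lt(abs(priorVar(eb) / s0T - 1), 0.1)
  # independent cross-check: limma's variance squeezing on the same input
  sv <- limma::squeezeVar(s2, df = dfT)
  expect_equal(priorDf(eb), sv$df.prior, tolerance = 1e-8)
  expect_equal(posteriorVar(eb), sv$var.post, tolerance = 1e-8)
  # identical variances: posterior collapses onto the common value
  ebc <- ebayesModerate(rep(1.7, 100), df = 8)
  expect_equal(unname(posteriorVar(ebc)), rep(1.7, 100), tolerance = 1e-10)
  expect_error(ebayesModerate(s2[1:5], df = 8), "fewer than 10")
})

test_that("d0 = 0 reproduces ordinary t-tests exactly", {
  set.seed(43)
  d <- fiveConditionDesign(3, groups = "NI")
  bd <- buildDesign(d)
  G <- 50
  Y <- matrix(rnorm(G * nrow(d)), G, nrow(d),
              dimnames = list(paste0("g", 1:G), d$sample_id))
  fit <- fitGls(Y, bd$design, bd$blocks, rho = 0)
  eb0 <- ebayesModerate(fit, d0 = 0)
  tab <- resultTable(contrastTest(fit, eb0, "TNF_vs_control"))
  cond <- factor(d$condition, levels = intersect(conditionLevels(),
                                                 d$condition))
  for (g in c(3, 30)) {
    ref <- summary(lm(Y[g, ] ~ cond))$coefficients
    expect_equal(tab$t[g], ref["condTNF", "t value"], tolerance = 1e-10)
    expect_equal(tab$p[g], ref["condTNF", "Pr(>|t|)"], tolerance = 1e-10)
  }
  expect_equal(unique(tab$df), fit@df)
})

test_that("contrast tests reject degenerate inputs", {
  st <- quickStudy(nGenes = 60, seed = 47)
  res <- fitContrasts(st$se, group = "NI")
  expect_error(contrastTest(res$fit, res$ebayes, rep(0, 5)), "nonzero")
  expect_error(contrastTest(res$fit, res$ebayes, c(1, 0, 0)), "length")
})

test_that("a strongly induced gene dominates the ranking", {
  d <- fiveConditionDesign(3, groups = "NI")
  hits <- 0L
  nSim <- 25L
  for (r in seq_len(nSim)) {
    truth <- simulateTruth(d, nGenes = 300, fracTnf = 0, nResponsive = 0,
                           dispersionMeanLog = log(0.05),
                           dispersionSdLog = 0, libSize = 2e6,
                           seed = 500 + r)
    truth <- plantSpd1(truth, truth@geneIds[1], 2, "PD-L1")
    se <- simulateBulkCounts(truth, d)
    res <- fitContrasts(se, group = "NI", contrasts = "TNFsPD1_vs_TNF")
    tab <- resultTable(res$tables$TNFsPD1_vs_TNF)
    rk <- rank(tab$p)[tab$gene_id == truth@geneIds[1]]
    if (length(rk) && rk <= ceiling(0.01 * nrow(tab))) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * nSim))
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(0.03, 7)), rep(0.03, 7))
  expect_equal(bhAdjust(0.2), 0.2)
  p <- runif(50)
  adj <- bhAdjust(p)
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})
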