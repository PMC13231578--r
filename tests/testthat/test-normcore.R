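# Filtering, TMM, log2-CPM and precision weights.

test_that("CPM filter applies the smallest-library threshold", {
  # smallest library 2e6 -> threshold 5 CPM for minCount 10
  x <- rbind(
    gA = c(10, 40, 40),   # 5 CPM in the small library: at threshold, kept
    gB = c(9, 40, 40),    # 4.5 CPM there, 10 CPM elsewhere: 2 samples only
    gC = c(0, 0, 0),      # never expressed
    gD = c(100, 500, 500)
  )
  colnames(x) <- c("s1", "s2", "s3")
  x <- rbind(x, filler = c(2e6, 4e6, 4e6) - colSums(x))
  stopifnot(colSums(x) == c(2e6, 4e6, 4e6))
  kept <- cpmFilter(x, minCount = 10, minSamples = 3)
  expect_true("gA" %in% kept)
  expect_false("gB" %in% kept)
  expect_false("gC" %in% kept)
  expect_true("gD" %in% kept)
  # gB reaches the threshold in 2 samples
  expect_true("gB" %in% cpmFilter(x, minCount = 10, minSamples = 2))
})

test_that("CPM filter matches exhaustive evaluation on a toy matrix", {
  set.seed(42)
  x <- matrix(rpois(20, 30), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  minCount <- 3; minSamples <- 2
  thr <- minCount * 1e6 / min(colSums(x))
  expected <- rownames(x)[vapply(1:5, function(g) {
    sum(vapply(1:4, function(s)
      x[g, s] / colSums(x)[s] * 1e6 >= thr, logical(1))) >= minSamples
  }, logical(1))]
  expect_identical(cpmFilter(x, minCount, minSamples), expected)
  # filtering is idempotent and never grows the gene set
  kept <- cpmFilter(x, minCount, minSamples)
  expect_identical(cpmFilter(x[kept, , drop = FALSE], minCount, minSamples),
                   kept)
  expect_error(cpmFilter(cbind(x, s5 = 0L)), "s5")
})

test_that("TMM factors are 1 for pure depth differences", {
  set.seed(7)
  base <- rpois(300, 50)
  x <- cbind(s1 = base, s2 = 3L * base)
  rownames(x) <- paste0("g", 1:300)
  expect_equal(unname(tmmFactors(x)), c(1, 1), tolerance = 1e-12)
  x2 <- cbind(s1 = base, s2 = base)
  expect_equal(unname(tmmFactors(x2)), c(1, 1), tolerance = 1e-12)
})

test_that("TMM matches an independent evaluation of the trimmed weighted mean", {
  set.seed(11)
  x <- matrix(rnbinom(200 * 4, mu = rep(exp(runif(200, 2, 8)), 4), size = 8),
              200, 4, dimnames = list(paste0("g", 1:200), paste0("s", 1:4)))
  x[1:20, 2] <- x[1:20, 2] * 8  # 20 genes 8-fold inflated in sample 2
  # straight-line oracle: the trimmed precision-weighted M-mean formula
  lib <- colSums(x)
  f75 <- apply(x, 2, function(v) quantile(v, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  oracle <- sapply(1:4, function(j) {
    ok <- x[, j] > 0 & x[, ref] > 0
    m <- log2((x[ok, j] / lib[j]) / (x[ok, ref] / lib[ref]))
    a <- 0.5 * log2((x[ok, j] / lib[j]) * (x[ok, ref] / lib[ref]))
    v <- (lib[j] - x[ok, j]) / (lib[j] * x[ok, j]) +
      (lib[ref] - x[ok, ref]) / (lib[ref] * x[ok, ref])
    if (max(abs(m)) < 1e-6) return(1)
    n <- length(m)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep <- rank(m) >= loM & rank(m) <= hiM & rank(a) >= loA & rank(a) <= hiA
    2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
  })
  oracle <- oracle / exp(mean(log(oracle)))
  expect_equal(unname(tmmFactors(x)), unname(oracle), tolerance = 1e-10)
  # independent cross-check against the reference implementation
  f2 <- edgeR::calcNormFactors(edgeR::DGEList(x), method = "TMM")
  expect_equal(unname(tmmFactors(x)),
               f2$samples$norm.factors, tolerance = 1e-10)
})

test_that("TMM is equivariant under sample relabelling", {
  set.seed(13)
  x <- matrix(rnbinom(400, mu = 60, size = 5), 100, 4,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
  perm <- c(3, 1, 4, 2)
  f <- tmmFactors(x)
  fp <- tmmFactors(x[, perm])
  expect_equal(unname(fp), unname(f[perm]), tolerance = 1e-12)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-10)
})

test_that("log2-CPM obeys its definition and invariances", {
  x <- matrix(c(10, 0, 90, 50), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  libs <- c(1e6, 1e6)
  lc <- log2Cpm(x, priorCount = 0, libSizes = libs)
  expect_equal(lc["g1", "s1"], log2(10), tolerance = 1e-12)
  # prior keeps zeros finite
  lc5 <- log2Cpm(x, priorCount = 0.5)
  expect_true(all(is.finite(lc5)))
  # joint doubling of counts and depth leaves prior-0 values unchanged
  expect_equal(log2Cpm(2 * x, priorCount = 0),
               log2Cpm(x, priorCount = 0), tolerance = 1e-12)
  # monotone in counts within a sample
  xx <- matrix(c(1, 5, 10, 1, 5, 10), 3, 2)
  expect_true(all(diff(log2Cpm(xx, priorCount = 0.5,
                               libSizes = c(100, 100))[, 1]) > 0))
  expect_error(log2Cpm(x, priorCount = -1), "non-negative")
})

test_that("precision weights flatten on homoskedastic data and track a trend", {
  set.seed(17)
  G <- 2000; n <- 10
  # constant log-scale spread across a wide mean range -> flat trend
  mu <- runif(G, 4, 12)
  x <- round(2^(matrix(rnorm(G * n, mu, 0.25), G, n)))
  rownames(x) <- paste0("g", 1:G); colnames(x) <- paste0("s", 1:n)
  X <- matrix(1, n, 1)
  w <- voomWeights(x, X)
  expect_true(all(is.finite(w)) && all(w > 0))
  expect_lt(sd(w) / mean(w), 0.1)
  # planted decreasing sd with mean -> weights increase with expression
  sds <- seq(0.8, 0.1, length.out = G)
  ord <- order(mu)
  x2 <- round(2^(matrix(rnorm(G * n, mu[ord], sds), G, n)))
  rownames(x2) <- paste0("g", 1:G); colnames(x2) <- paste0("s", 1:n)
  w2 <- voomWeights(x2, X)
  expect_gt(cor(mu[ord], rowMeans(w2), method = "spearman"), 0.9)
  expect_error(voomWeights(x[, 1:3], matrix(1, 3, 3)), "full column rank")
})

test_that("normalizeCounts assembles a valid NormalizedCounts object", {
  st <- quickStudy(nGenes = 300, seed = 19)
  norm <- normalizeCounts(st$se)
  expect_s4_class(norm, "NormalizedCounts")
  expect_true(all(keptGenes(norm) %in% rownames(st$se)))
  expect_equal(exp(mean(log(normFactors(norm)))), 1, tolerance = 1e-10)
  expect_identical(dim(log2Cpm(norm)), dim(precisionWeights(norm)))
})
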