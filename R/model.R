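# Donor-blocked linear modelling: design construction, consensus intra-donor
# correlation, gene-wise GLS under the block-exchangeable structure,
# empirical Bayes variance moderation, and moderated-t contrast tests.

#' Build the condition design matrix and block labels
#'
#' For a single disease group the model is an intercept plus condition
#' indicators with the unstimulated control as baseline. When both groups
#' are present, per-group intercepts and per-group condition indicators are
#' used so that every contrast stays within its group. With random blocking
#' the donor labels are returned for consensus-correlation estimation; with
#' fixed blocking donor indicator columns are appended (used by the residual
#' diagnostics).
#'
#' @param design sample sheet (sample_id, donor_id, disease_group,
#'   condition).
#' @param blocking "random" (donor as a random effect via a common
#'   intra-donor correlation) or "fixed" (donor indicator columns).
#' @return list with elements `design` (model matrix), `blocks` (donor label
#'   per sample) and `groups` (disease groups present).
#' @export
buildDesign <- function(design, blocking = c("random", "fixed")) {
  blocking <- match.arg(blocking)
  checkDesignTable(design)
  condTab <- table(as.character(design$condition))
  if (any(condTab == 1))
    stop("condition(s) present in only one sample: ",
         paste(names(condTab)[condTab == 1], collapse = ", "),
         " (contrast not estimable)")
  groups <- unique(as.character(design$disease_group))
  condLev <- intersect(conditionLevels(), unique(design$condition))
  cond <- factor(as.character(design$condition), levels = condLev)
  if (length(groups) == 1L) {
    X <- cbind(1, vapply(condLev[-1L],
                         function(l) as.numeric(cond == l),
                         numeric(nrow(design))))
    colnames(X) <- c("(Intercept)", paste0("cond", condLev[-1L]))
  } else {
    grp <- as.character(design$disease_group)
    base <- vapply(groups, function(g) as.numeric(grp == g),
                   numeric(nrow(design)))
    colnames(base) <- paste0("grp", groups)
    inter <- do.call(cbind, lapply(groups, function(g) {
      m <- vapply(condLev[-1L],
                  function(l) as.numeric(grp == g & cond == l),
                  numeric(nrow(design)))
      colnames(m) <- paste0("grp", g, ".cond", condLev[-1L])
      m
    }))
    X <- cbind(base, inter)
  }
  rownames(X) <- design$sample_id
  blocks <- as.character(design$donor_id)
  if (blocking == "fixed") {
    donors <- unique(blocks)
    D <- vapply(donors[-1L], function(d) as.numeric(blocks == d),
                numeric(nrow(design)))
    colnames(D) <- paste0("donor", donors[-1L])
    X <- cbind(X, D)
  }
  list(design = X, blocks = blocks, groups = groups)
}

#' Contrast vector for a named comparison
#'
#' Maps one of the five analysis contrasts onto a coefficient vector of the
#' matrix produced by [buildDesign()]. sPD1 contrasts are signed as
#' condition-of-interest minus TNF (or minus control), so positive log2FC
#' means higher expression under the first-named condition.
#'
#' @param X model matrix from [buildDesign()].
#' @param name contrast name, one of TNF_vs_control, TNFsPD1_vs_control,
#'   TNFsPD1_vs_TNF, KO_PDL1_vs_TNF, KO_PDL2_vs_TNF.
#' @param group disease group (required for the two-group model).
#' @return numeric contrast vector named by coefficient.
#' @export
contrastVector <- function(X, name, group = NULL) {
  name <- match.arg(name, contrastNames())
  cn <- colnames(X)
  pre <- if (any(startsWith(cn, "grp"))) {
    if (is.null(group))
      stop("the two-group model needs an explicit group for contrasts")
    paste0("grp", group, ".cond")
  } else "cond"
  pick <- function(condition) {
    col <- paste0(pre, condition)
    if (!col %in% cn)
      stop("condition ", condition, " not present in the fitted design")
    col
  }
  v <- stats::setNames(numeric(length(cn)), cn)
  switch(name,
    TNF_vs_control = { v[pick("TNF")] <- 1 },
    TNFsPD1_vs_control = { v[pick("TNF_sPD1")] <- 1 },
    TNFsPD1_vs_TNF = { v[pick("TNF_sPD1")] <- 1; v[pick("TNF")] <- -1 },
    KO_PDL1_vs_TNF = { v[pick("KO_PDL1_TNF_sPD1")] <- 1
                       v[pick("TNF")] <- -1 },
    KO_PDL2_vs_TNF = { v[pick("KO_PDL2_TNF_sPD1")] <- 1
                       v[pick("TNF")] <- -1 })
  v
}

#' Consensus intra-donor correlation
#'
#' Estimates a single correlation shared by all genes for repeated samples
#' of the same donor: per gene, a moment estimator of the within-block
#' residual correlation (mean cross-product of OLS residual pairs within a
#' block over the mean squared residual); the per-gene estimates are pooled
#' by a trimmed mean on the atanh scale and transformed back. The result is
#' clamped to (-0.99, 0.99).
#'
#' @param y expression matrix (genes x samples) or
#'   [NormalizedCounts-class].
#' @param X design matrix.
#' @param blocks donor label per sample.
#' @param trim trim fraction of the pooled atanh mean (default 0.15).
#' @return the consensus correlation, a single number in (-0.99, 0.99).
#' @export
consensusCorrelation <- function(y, X, blocks, trim = 0.15) {
  Y <- if (is(y, "NormalizedCounts")) log2Cpm(y) else as.matrix(y)
  blocks <- as.character(blocks)
  sizes <- table(blocks)
  if (sum(sizes >= 2) < 2)
    stop("need at least 2 donors with at least 2 samples each")
  qrX <- qr(X)
  E <- t(qr.resid(qrX, t(Y)))
  n <- ncol(E)
  cross <- 0
  npairs <- 0
  for (b in names(sizes)[sizes >= 2]) {
    idx <- which(blocks == b)
    S <- rowSums(E[, idx, drop = FALSE])
    cross <- cross + (S^2 - rowSums(E[, idx, drop = FALSE]^2))
    npairs <- npairs + length(idx) * (length(idx) - 1)
  }
  denom <- rowSums(E^2) / n
  rho <- (cross / npairs) / denom
  rho <- rho[is.finite(rho)]
  rho <- pmin(pmax(rho, -0.999), 0.999)
  pooled <- tanh(mean(atanh(rho), trim = trim))
  min(max(pooled, -0.99), 0.99)
}

#' Gene-wise GLS under block-exchangeable correlation
#'
#' Fits each gene by generalized least squares with covariance
#' sigma^2 * D^(1/2) [(1-rho) I + rho * same-donor indicator] D^(1/2), where
#' D holds the inverse precision weights. With rho = 0 and unit weights this
#' reduces exactly to ordinary least squares.
#'
#' @param y expression matrix (genes x samples) or
#'   [NormalizedCounts-class].
#' @param X design matrix.
#' @param blocks donor label per sample.
#' @param rho intra-donor correlation.
#' @param weights optional precision-weight matrix matching `y`; taken from
#'   the NormalizedCounts object when available.
#' @return a [GlsFit-class] object.
#' @export
fitGls <- function(y, X, blocks, rho = 0, weights = NULL) {
  if (is(y, "NormalizedCounts")) {
    if (is.null(weights)) weights <- precisionWeights(y)
    Y <- log2Cpm(y)
  } else {
    Y <- as.matrix(y)
  }
  blocks <- as.character(blocks)
  n <- ncol(Y)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  same <- outer(blocks, blocks, `==`)
  R <- (1 - rho) * diag(n) + rho * same
  eg <- eigen(R, symmetric = TRUE)
  if (min(eg$values) <= 1e-10)
    stop("correlation structure is not positive definite at rho = ", rho)
  Rinvsqrt <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
  G <- nrow(Y)
  coef <- matrix(NA_real_, G, p, dimnames = list(rownames(Y), colnames(X)))
  covU <- array(NA_real_, c(p, p, G))
  sigma2 <- numeric(G)
  unitW <- is.null(weights)
  if (unitW) {
    # shared whitened design: fully vectorized across genes
    Xw <- Rinvsqrt %*% X
    Yw <- Y %*% t(Rinvsqrt)
    qrW <- qr(Xw)
    coef[] <- t(qr.coef(qrW, t(Yw)))
    Ew <- t(qr.resid(qrW, t(Yw)))
    sigma2 <- rowSums(Ew^2) / (n - p)
    cu <- chol2inv(chol(crossprod(Xw)))
    covU[] <- cu
  } else {
    for (g in seq_len(G)) {
      sw <- sqrt(weights[g, ])
      Xg <- Rinvsqrt %*% (X * sw)
      yg <- Rinvsqrt %*% (Y[g, ] * sw)
      fit <- stats::lm.fit(Xg, yg)
      coef[g, ] <- fit$coefficients
      sigma2[g] <- sum(fit$residuals^2) / (n - p)
      covU[, , g] <- chol2inv(chol(crossprod(Xg)))
    }
  }
  methods::new("GlsFit", coefficients = coef, covUnscaled = covU,
               sigma2 = sigma2, df = as.numeric(n - p), rho = rho,
               design = X, blocks = blocks, avgExpr = rowMeans(Y))
}

#' Empirical Bayes moderation of residual variances
#'
#' Fits the scaled inverse-chi-square prior on gene-wise residual variances
#' by the method of moments on log variances (digamma/trigamma inversion)
#' and returns the moderation state. d0 = Inf (no excess spread) is encoded
#' as 1e6; passing `d0 = 0` disables pooling, reproducing ordinary t-tests.
#'
#' @param s2 per-gene residual variances (or a [GlsFit-class]).
#' @param df per-gene residual degrees of freedom (ignored when a fit is
#'   supplied).
#' @param d0 optional fixed prior degrees of freedom, bypassing estimation.
#' @param consensusRho optional consensus correlation to record.
#' @return an [EBayesState-class] object.
#' @export
ebayesModerate <- function(s2, df = NULL, d0 = NULL, consensusRho = NA_real_) {
  if (is(s2, "GlsFit")) {
    df <- s2@df
    s2 <- s2@sigma2
  }
  if (is.null(df)) stop("residual degrees of freedom required")
  if (any(df <= 0)) stop("all residual degrees of freedom must be positive")
  if (length(s2) < 10)
    stop("fewer than 10 genes: moment estimation of the prior is unreliable")
  dG <- rep_len(df, length(s2))
  cap <- 1e6
  ok <- is.finite(s2) & s2 > 0
  if (!all(ok)) {
    warning(sum(!ok), " nonpositive residual variance(s) excluded from ",
            "prior estimation")
  }
  if (is.null(d0)) {
    z <- log(s2[ok])
    e <- z - digamma(dG[ok] / 2) + log(dG[ok] / 2)
    emean <- mean(e)
    nOk <- sum(ok)
    spread <- mean((e - emean)^2) * nOk / (nOk - 1)
    evar <- spread - mean(trigamma(dG[ok] / 2))
    if (spread < 1e-15) {
      # degenerate input: all variances identical, nothing to pool over;
      # the prior collapses onto the common value
      d0 <- cap
      s0Sq <- exp(mean(z))
    } else if (evar > 0) {
      d0 <- 2 * trigammaInv(evar)
      s0Sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- cap
      s0Sq <- exp(emean)
    }
  } else {
    s0Sq <- if (d0 > 0) exp(mean(log(s2[ok]))) else mean(s2[ok])
  }
  d0 <- min(d0, cap)
  s2safe <- ifelse(ok, s2, s0Sq)
  methods::new("EBayesState", d0 = d0, s0Sq = s0Sq, sGSq = s2safe,
               dG = dG, consensusRho = consensusRho)
}

#' Moderated-t contrast test
#'
#' Tests a contrast of the GLS coefficients per gene with the empirical
#' Bayes moderated t statistic: estimate over (unscaled SE times posterior
#' SD), two-sided p from the t distribution on d_g + d0 degrees of freedom,
#' Benjamini-Hochberg adjusted across genes.
#'
#' @param fit a [GlsFit-class].
#' @param ebayes an [EBayesState-class] from the same fit.
#' @param contrast numeric contrast vector over the fit coefficients (or a
#'   contrast name resolvable by [contrastVector()]).
#' @param name label stored in the result.
#' @param group disease group, forwarded to [contrastVector()] when
#'   `contrast` is a name.
#' @return a [ContrastTable-class].
#' @export
contrastTest <- function(fit, ebayes, contrast, name = NULL, group = NULL) {
  if (is.character(contrast)) {
    if (is.null(name)) name <- contrast
    contrast <- contrastVector(fit@design, contrast, group = group)
  }
  if (is.null(name)) name <- "custom"
  p <- ncol(fit@coefficients)
  if (length(contrast) != p)
    stop("contrast length must equal the number of coefficients")
  if (all(contrast == 0)) stop("contrast vector must be nonzero")
  est <- as.vector(fit@coefficients %*% contrast)
  cu <- matrix(fit@covUnscaled, p * p, dim(fit@covUnscaled)[3L])
  cc <- as.vector(outer(contrast, contrast))
  seU <- sqrt(colSums(cu * cc))
  post <- posteriorVar(ebayes)
  tstat <- est / (seU * sqrt(post))
  dfTotal <- pmin(ebayes@dG + ebayes@d0, 1e6)
  praw <- 2 * stats::pt(-abs(tstat), df = dfTotal)
  tab <- data.frame(
    gene_id = rownames(fit@coefficients),
    log2fc = est,
    t = tstat,
    df = dfTotal,
    p = praw,
    p_adj = bhAdjust(praw),
    avg_expr = fit@avgExpr,
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  methods::new("ContrastTable", contrast = name, table = tab)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (via `stats::p.adjust`), capped
#' at 1, input order preserved.
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Full donor-blocked differential expression for one disease group
#'
#' Convenience wrapper chaining the pipeline on one group: CPM filter, TMM,
#' log2-CPM, precision weights, consensus intra-donor correlation, gene-wise
#' GLS, empirical Bayes moderation, and the moderated-t tables for every
#' contrast whose conditions are present.
#'
#' @param se SummarizedExperiment with a `counts` assay and donor_id /
#'   disease_group / condition column data.
#' @param group optional disease group to subset to (RA and NI are analysed
#'   separately in the primary workflow).
#' @param keepGenes optional gene set the analysis is restricted to after
#'   filtering (used by the bootstrap refits).
#' @param contrasts contrast names to compute (default: all five).
#' @param minCount,minSamples,trimM,trimA,priorCount,span normalization
#'   parameters, see [normalizeCounts()].
#' @param trim trim fraction of the consensus-correlation pool.
#' @return list with elements `tables` (named [ContrastTable-class] list),
#'   `fit`, `ebayes`, `norm`, `design`, and `group`.
#' @export
fitContrasts <- function(se, group = NULL, keepGenes = NULL,
                         contrasts = contrastNames(),
                         minCount = 10, minSamples = 3,
                         trimM = 0.30, trimA = 0.05, priorCount = 0.5,
                         span = 0.5, trim = 0.15) {
  sm <- sampleTable(se)
  if (!is.null(group)) {
    sel <- sm$disease_group == group
    se <- se[, sel]
    sm <- sm[sel, , drop = FALSE]
  }
  bd <- buildDesign(sm, blocking = "random")
  x <- countsMatrix(se)
  kept <- cpmFilter(x, minCount = minCount, minSamples = minSamples)
  if (!is.null(keepGenes)) kept <- intersect(kept, keepGenes)
  norm <- normalizeCounts(x[kept, , drop = FALSE], design = bd$design,
                          minCount = 1, minSamples = 1, trimM = trimM,
                          trimA = trimA, priorCount = priorCount,
                          span = span)
  rho <- consensusCorrelation(norm, bd$design, bd$blocks, trim = trim)
  fit <- fitGls(norm, bd$design, bd$blocks, rho = rho)
  eb <- ebayesModerate(fit, consensusRho = rho)
  tables <- list()
  for (cn in contrasts) {
    if (length(bd$groups) == 1L) {
      tables[[cn]] <- tryCatch(
        contrastTest(fit, eb, cn, group = NULL),
        error = function(e) NULL)
    } else {
      for (g in bd$groups) {
        tables[[paste(g, cn, sep = ".")]] <- tryCatch(
          contrastTest(fit, eb, cn, name = paste(g, cn, sep = "."),
                       group = g),
          error = function(e) NULL)
      }
    }
  }
  tables <- Filter(Negate(is.null), tables)
  list(tables = tables, fit = fit, ebayes = eb, norm = norm,
       design = bd, group = group)
}
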