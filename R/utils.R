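# Internal helpers.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic package code funnels
# through this so that every generator is a pure function of its seed.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

geometricMean <- function(x) exp(mean(log(x)))

# counts accessor tolerant of plain matrices and SummarizedExperiment input
countsMatrix <- function(x) {
  if (is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x, "counts")
  as.matrix(x)
}

sampleTable <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    cd$sample_id <- colnames(x)
    cd
  } else {
    as.data.frame(x)
  }
}

checkDesignTable <- function(design) {
  need <- c("sample_id", "donor_id", "disease_group", "condition")
  if (!all(need %in% names(design)))
    stop("design must provide columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(as.character(design$condition)), conditionLevels())
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design")
  dup <- duplicated(design[, c("donor_id", "condition")])
  if (any(dup))
    stop("each donor may contribute at most one sample per condition")
  grp <- tapply(as.character(design$disease_group), design$donor_id,
                function(x) length(unique(x)))
  if (any(grp > 1))
    stop("disease group must be constant within donor")
  invisible(design)
}

# Newton inversion of the trigamma function (solves trigamma(x) = y),
# used by the empirical Bayes moment estimator.
trigammaInv <- function(y) {
  vapply(y, function(yi) {
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in seq_len(50)) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1))
}
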