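# Plain-text readers and writers for the pipeline's artifacts: counts as
# TSV or MatrixMarket with name sidecars, designs and result tables as TSV,
# truth and summaries as JSON, Ct tables as CSV.

#' Write a count matrix
#'
#' TSV format: genes in rows, a leading `gene_id` column. MTX format:
#' MatrixMarket file plus `<prefix>.rownames.txt` / `<prefix>.colnames.txt`
#' sidecars.
#'
#' @param counts matrix or SummarizedExperiment.
#' @param path output path (for MTX, the `.mtx` path; sidecars are derived).
#' @param format "tsv" or "mtx".
#' @export
writeCounts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  x <- countsMatrix(counts)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(x, sparse = TRUE), path)
    prefix <- sub("\\.mtx$", "", path)
    writeLines(rownames(x), paste0(prefix, ".rownames.txt"))
    writeLines(colnames(x), paste0(prefix, ".colnames.txt"))
  }
  invisible(path)
}

#' Read a count matrix written by [writeCounts()]
#'
#' @param path TSV path or `.mtx` path with name sidecars.
#' @return integer matrix, genes x samples.
#' @export
readCounts <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    prefix <- sub("\\.mtx$", "", path)
    rownames(m) <- readLines(paste0(prefix, ".rownames.txt"))
    colnames(m) <- readLines(paste0(prefix, ".colnames.txt"))
    storage.mode(m) <- "integer"
    m
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
  }
}

#' Write / read a sample design table (TSV)
#'
#' @param design sample sheet data.frame.
#' @param path TSV path.
#' @export
writeDesignTable <- function(design, path) {
  utils::write.table(sampleTable(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeDesignTable
#' @export
readDesignTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a synthetic truth record as JSON
#'
#' Flat JSON serialization of every planted quantity, sufficient to rebuild
#' the object with [readTruth()].
#'
#' @param truth a [SyntheticTruth-class].
#' @param path JSON path.
#' @export
writeTruth <- function(truth, path) {
  obj <- list(
    gene_ids = truth@geneIds,
    baseline_log2_mean = truth@baselineLog2Mean,
    dispersion = truth@dispersion,
    donor_ids = colnames(truth@donorEffects),
    donor_effects = truth@donorEffects,
    groups = colnames(truth@tnfEffect),
    tnf_effect = truth@tnfEffect,
    spd1_effect = truth@spd1Effect,
    ligand_dependency = truth@ligandDependency,
    library_sizes = as.list(truth@librarySizes),
    seed = truth@seed
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  de <- as.matrix(o$donor_effects)
  dimnames(de) <- list(o$gene_ids, o$donor_ids)
  te <- as.matrix(o$tnf_effect)
  se <- as.matrix(o$spd1_effect)
  dimnames(te) <- dimnames(se) <- list(o$gene_ids, o$groups)
  methods::new("SyntheticTruth",
               geneIds = o$gene_ids,
               baselineLog2Mean = o$baseline_log2_mean,
               dispersion = o$dispersion,
               donorEffects = de, tnfEffect = te, spd1Effect = se,
               ligandDependency = o$ligand_dependency,
               librarySizes = unlist(o$library_sizes),
               seed = as.integer(o$seed))
}

#' Write / read a qPCR Ct table (CSV)
#'
#' @param records long Ct table from [simulateQpcr()].
#' @param path CSV path.
#' @export
writeCtTable <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCtTable
#' @export
readCtTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a contrast table as TSV
#'
#' Stable column names: gene_id, log2fc, t, df, p, p_adj, avg_expr.
#'
#' @param x a [ContrastTable-class].
#' @param path TSV path.
#' @export
writeContrastTable <- function(x, path) {
  utils::write.table(resultTable(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a bootstrap stability report
#'
#' TSV of per-replicate correlations plus a JSON summary (median, category,
#' redraw count, seed).
#'
#' @param x a [BootstrapStability-class].
#' @param tsvPath per-replicate TSV path.
#' @param jsonPath summary JSON path.
#' @export
writeStability <- function(x, tsvPath, jsonPath) {
  utils::write.table(
    data.frame(replicate = seq_along(x@rhos), rho = x@rhos),
    tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(contrast = x@contrast, median_rho = x@medianRho,
         category = x@category, n_replicates = x@nReplicates,
         redraws = x@redraws, seed = x@seed),
    jsonPath, digits = NA, auto_unbox = TRUE)
  invisible(jsonPath)
}

#' Write responsive-gene calls as TSV
#'
#' @param x a [ResponsiveCalls-class].
#' @param path TSV path.
#' @export
writeResponsiveCalls <- function(x, path) {
  utils::write.table(resultTable(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a dampening summary (JSON plus per-gene delta TSV)
#'
#' @param x a [DampeningSummary-class].
#' @param jsonPath summary JSON path.
#' @param tsvPath per-gene delta TSV path.
#' @export
writeDampening <- function(x, jsonPath, tsvPath) {
  utils::write.table(
    data.frame(gene_id = names(x@delta), delta_log2fc = x@delta),
    tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(group = x@group, threshold = x@threshold,
         dampened_fraction = x@dampenedFraction,
         amplified_fraction = x@amplifiedFraction,
         mean_delta = x@meanDelta, median_delta = x@medianDelta),
    jsonPath, digits = NA, auto_unbox = TRUE)
  invisible(jsonPath)
}
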