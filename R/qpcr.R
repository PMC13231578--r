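# Comparative-Ct (ddCt) quantification with the Ct >= 30 exclusion gate and
# cross-platform agreement against RNA-seq fold changes.

meanCtTable <- function(records) {
  records <- records[!is.na(records$ct), , drop = FALSE]
  if (!nrow(records)) stop("no usable Ct replicates")
  agg <- stats::aggregate(ct ~ sample_id + donor_id + condition + target,
                          data = records, FUN = mean)
  agg
}

#' Comparative-Ct relative quantification
#'
#' Technical duplicates are averaged on the Ct scale; per sample,
#' deltaCt = mean Ct(target) - mean Ct(reference); per donor,
#' ddCt = deltaCt(condition) - deltaCt(baseline condition); relative
#' expression = 2^(-ddCt) and log2FC = -ddCt (amplification efficiency
#' fixed at perfect doubling). The baseline's relative expression is exactly
#' 1. Samples without a usable reference Ct are excluded with a warning.
#'
#' @param records data.frame with columns sample_id, donor_id, condition,
#'   target, replicate, ct (missing Ct as NA).
#' @param referenceGene housekeeping target used for normalization.
#' @param baselineCondition condition each donor's ddCt is anchored to
#'   (default "TNF", matching the TNF-alone reference of the validation).
#' @return list with `records` (per donor x target x condition: delta_ct,
#'   ddct, rel_expr, log2fc) and `summary` (per target x condition: mean
#'   log2FC over donors and the corresponding relative expression).
#' @export
ddct <- function(records, referenceGene, baselineCondition = "TNF") {
  need <- c("sample_id", "donor_id", "condition", "target", "ct")
  if (!all(need %in% names(records)))
    stop("records must provide columns: ", paste(need, collapse = ", "))
  m <- meanCtTable(records)
  ref <- m[m$target == referenceGene, c("sample_id", "ct")]
  names(ref)[2L] <- "ref_ct"
  tgt <- m[m$target != referenceGene, , drop = FALSE]
  if (!nrow(tgt)) stop("no target genes besides the reference")
  mg <- merge(tgt, ref, by = "sample_id", all.x = TRUE)
  if (anyNA(mg$ref_ct)) {
    bad <- unique(mg$sample_id[is.na(mg$ref_ct)])
    warning("excluding sample(s) without reference Ct: ",
            paste(bad, collapse = ", "))
    mg <- mg[!is.na(mg$ref_ct), , drop = FALSE]
  }
  mg$delta_ct <- mg$ct - mg$ref_ct
  base <- mg[mg$condition == baselineCondition,
             c("donor_id", "target", "delta_ct")]
  names(base)[3L] <- "base_delta_ct"
  missingBase <- setdiff(unique(mg$target), unique(base$target))
  if (length(missingBase))
    stop("baseline condition '", baselineCondition,
         "' missing for gene(s): ", paste(missingBase, collapse = ", "))
  mg <- merge(mg, base, by = c("donor_id", "target"))
  mg$ddct <- mg$delta_ct - mg$base_delta_ct
  mg$rel_expr <- 2^(-mg$ddct)
  mg$log2fc <- -mg$ddct
  recs <- mg[order(mg$target, mg$condition, mg$donor_id),
             c("donor_id", "sample_id", "condition", "target", "delta_ct",
               "ddct", "rel_expr", "log2fc")]
  rownames(recs) <- NULL
  summ <- stats::aggregate(log2fc ~ target + condition, data = recs,
                           FUN = mean)
  summ$rel_expr <- 2^summ$log2fc
  list(records = recs, summary = summ)
}

#' Ct-based exclusion of weakly expressed genes
#'
#' Genes whose mean Ct in the gate condition reaches the threshold are
#' excluded from quantification (boundary exclusionary: mean Ct equal to
#' the threshold is excluded). The gate is evaluated on the mean over all
#' gate-condition samples; per-cell-line means are reported alongside so
#' that a per-donor gate can be inspected.
#'
#' @param records qPCR long table (sample_id, donor_id, condition, target,
#'   ct).
#' @param threshold Ct gate (default 30).
#' @param gateCondition condition the gate is evaluated in (default "TNF").
#' @return list with `retained` and `excluded` target vectors, `geneMeans`
#'   (mean gate-condition Ct per target) and `donorMeans` (per donor).
#' @export
ctExclusion <- function(records, threshold = 30, gateCondition = "TNF") {
  if (!gateCondition %in% records$condition)
    stop("gate condition '", gateCondition, "' absent from the records")
  gate <- records[records$condition == gateCondition & !is.na(records$ct), ,
                  drop = FALSE]
  geneMeans <- tapply(gate$ct, gate$target, mean)
  donorMeans <- stats::aggregate(ct ~ target + donor_id, data = gate,
                                 FUN = mean)
  excluded <- names(geneMeans)[geneMeans >= threshold]
  retained <- setdiff(unique(records$target), excluded)
  list(retained = retained, excluded = excluded,
       geneMeans = geneMeans, donorMeans = donorMeans)
}

#' Cross-platform agreement of fold changes
#'
#' Spearman correlation (two-sided) between qPCR-derived and RNA-seq-derived
#' log2 fold changes over the gene x condition pairs present on both
#' platforms.
#'
#' @param qpcrFc named numeric of qPCR log2FCs (names identify the pairs).
#' @param rnaseqFc named numeric of RNA-seq log2FCs.
#' @return list with rho, p, n.
#' @export
crossplatformAgreement <- function(qpcrFc, rnaseqFc) {
  shared <- intersect(names(qpcrFc), names(rnaseqFc))
  if (length(shared) < 3)
    stop("need at least 3 paired fold changes")
  ct <- suppressWarnings(
    stats::cor.test(qpcrFc[shared], rnaseqFc[shared], method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(shared))
}
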