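#' Screen transcription factors against transcriptional divergence
#'
#' @description
#' For every transcription factor in `tfs` that is present in the matrix,
#' computes (i) the Spearman correlation between its normalized expression
#' and per-cell divergence across all cells, and (ii) a two-sided Wilcoxon
#' rank-sum differential-expression test between the two treatment phases,
#' with a log2 fold change of the CP10k means. The two p-value columns are
#' Benjamini-Hochberg adjusted as two separate families over the tested
#' TFs. TFs expressed (count > 0) in fewer than `minCells` cells receive
#' missing statistics and are excluded from both adjustment families and
#' from the rank ordering.
#'
#' @param x a `SingleCellExperiment` with `"counts"`, `"cp10k"` and
#'   `"logcounts"` assays (see [logNormalizeCP10K()]).
#' @param divergence a [divergenceTable()] computed on the same cells.
#' @param tfs character vector of TF gene identifiers.
#' @param groupBy `colData` column holding the two phases (default
#'   `"phase"`).
#' @param minCells minimum expressing cells for a TF to be tested
#'   (default 3).
#' @param eps pseudo-count for the fold change,
#'   `log2((mu_post + eps) / (mu_naive + eps))` on the CP10k scale.
#' @return a [S4Vectors::DataFrame] sorted by `rho` (decreasing, `NA`
#'   last) with columns `tf_id`, `n_cells_expressing`, `rho`, `p_corr`,
#'   `fdr_corr`, `log2fc_phase`, `p_de`, `fdr_de`, `rank_by_rho`.
#' @export
tfScreen <- function(x, divergence, tfs, groupBy = "phase", minCells = 3,
                     eps = 1e-9) {
  stopifnot(methods::is(x, "SummarizedExperiment"))
  tfs <- unique(tfs)
  present <- intersect(tfs, rownames(x))
  if (length(present) == 0L) {
    stop("none of the ", length(tfs), " TFs are present in the matrix")
  }
  cells <- divergence$cell_id
  if (!all(cells %in% colnames(x))) {
    stop("divergence table contains cells absent from the matrix")
  }
  logc <- .assayOrStop(x, "logcounts", "tfScreen")[present, cells,
                                                   drop = FALSE]
  cp10k <- .assayOrStop(x, "cp10k", "tfScreen")[present, cells,
                                                drop = FALSE]
  counts <- .assayOrStop(x, "counts", "tfScreen")[present, cells,
                                                  drop = FALSE]
  div <- divergence$divergence
  grp <- as.character(SummarizedExperiment::colData(x)[cells, groupBy])
  isPost <- grp == "post"
  isNaive <- grp == "naive"

  nExpr <- as.integer(Matrix::rowSums(counts > 0))
  tested <- nExpr >= minCells

  rho <- pCorr <- lfc <- pDE <- rep(NA_real_, length(present))
  for (i in which(tested)) {
    ev <- as.numeric(logc[i, ])
    sp <- spearmanRho(ev, div)
    rho[i] <- sp$rho
    pCorr[i] <- sp$p_value
    if (any(isPost) && any(isNaive)) {
      de <- wilcoxonRankSum(ev[isPost], ev[isNaive],
                            alternative = "two.sided")
      pDE[i] <- if (de$degenerate) 1 else de$p_value
      cv <- as.numeric(cp10k[i, ])
      lfc[i] <- log2((mean(cv[isPost]) + eps) / (mean(cv[isNaive]) + eps))
    }
  }
  fdrCorr <- fdrDE <- rep(NA_real_, length(present))
  fdrCorr[tested] <- bhAdjust(pCorr[tested])
  fdrDE[tested] <- bhAdjust(pDE[tested])

  rankRho <- rep(NA_integer_, length(present))
  rankRho[tested][order(-rho[tested])] <- seq_len(sum(tested))

  out <- S4Vectors::DataFrame(
    tf_id = present,
    n_cells_expressing = nExpr,
    rho = rho, p_corr = pCorr, fdr_corr = fdrCorr,
    log2fc_phase = lfc, p_de = pDE, fdr_de = fdrDE,
    rank_by_rho = rankRho
  )
  out <- out[order(is.na(out$rho), -ifelse(is.na(out$rho), 0, out$rho)), ]
  S4Vectors::metadata(out) <- list(
    n_requested = length(tfs), n_present = length(present),
    n_tested = sum(tested), min_cells = minCells
  )
  out
}

#' Patient-paired pseudo-bulk comparison of one gene
#'
#' @description
#' Aggregates the normalized expression (`logcounts`) of one gene to a
#' per-patient mean within each treatment phase, then tests the paired
#' per-patient means with a two-sided Wilcoxon signed-rank test and counts
#' the patients whose mean increased post-treatment. Patients missing one
#' of the phases are excluded with a warning; with fewer than 3 complete
#' pairs the test is skipped (`p_value = NA`) but the means are still
#' reported.
#'
#' @param x a `SingleCellExperiment` with a `"logcounts"` assay and
#'   `colData` columns `patient_id` and the grouping column.
#' @param gene a single gene identifier.
#' @param groupBy `colData` column holding phases `naive`/`post`.
#' @return list with `table` (DataFrame: `patient_id`, `mean_naive`,
#'   `mean_post`, `increased`), `n_increased`, `n_patients`, `statistic`,
#'   `p_value`.
#' @export
pseudobulkPaired <- function(x, gene, groupBy = "phase") {
  stopifnot(methods::is(x, "SummarizedExperiment"), length(gene) == 1L)
  if (!gene %in% rownames(x)) stop("gene '", gene, "' not in the matrix")
  logc <- .assayOrStop(x, "logcounts", "pseudobulkPaired")
  cd <- SummarizedExperiment::colData(x)
  ev <- as.numeric(logc[gene, ])
  pat <- as.character(cd$patient_id)
  grp <- as.character(cd[[groupBy]])

  patients <- sort(unique(pat))
  meanPhase <- function(p, ph) {
    sel <- pat == p & grp == ph
    if (!any(sel)) NA_real_ else mean(ev[sel])
  }
  mNaive <- vapply(patients, meanPhase, numeric(1), ph = "naive")
  mPost <- vapply(patients, meanPhase, numeric(1), ph = "post")
  complete <- !is.na(mNaive) & !is.na(mPost)
  if (any(!complete)) {
    warning(sum(!complete), " patient(s) missing a phase, excluded: ",
            paste(patients[!complete], collapse = ", "))
  }
  tab <- S4Vectors::DataFrame(
    patient_id = patients[complete],
    mean_naive = unname(mNaive[complete]),
    mean_post = unname(mPost[complete]),
    increased = unname(mPost[complete] > mNaive[complete])
  )
  nInc <- sum(tab$increased)
  if (nrow(tab) >= 3L) {
    wt <- wilcoxonSignedRank(tab$mean_post, tab$mean_naive)
    stat <- wt$statistic
    p <- wt$p_value
  } else {
    stat <- NA_real_
    p <- NA_real_
  }
  list(table = tab, n_increased = nInc, n_patients = nrow(tab),
       statistic = stat, p_value = p)
}
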