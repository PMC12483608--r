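#' Cell-level QC thresholds
#'
#' @description
#' The filtering rule removes a cell when ANY criterion fails, with strict
#' inequalities: more than `maxCounts` or fewer than `minCounts` RNA (or,
#' when present, ATAC) counts, nucleosome signal greater than
#' `maxNucleosomeSignal`, TSS enrichment less than `minTSSEnrichment`, or
#' percent mitochondrial reads greater than `maxPctMito`. Cells sitting
#' exactly on a threshold are kept. Defaults are the standard multiome
#' cutoffs: 1e5 / 1,000 counts, nucleosome signal 2, TSS enrichment 1,
#' 50% mitochondrial reads.
#'
#' @param maxCounts,minCounts,maxNucleosomeSignal,minTSSEnrichment,maxPctMito
#'   numeric thresholds.
#' @return a `QCThresholds` object (a validated named list).
#' @export
qcThresholds <- function(maxCounts = 1e5, minCounts = 1000,
                         maxNucleosomeSignal = 2, minTSSEnrichment = 1,
                         maxPctMito = 50) {
  th <- list(maxCounts = maxCounts, minCounts = minCounts,
             maxNucleosomeSignal = maxNucleosomeSignal,
             minTSSEnrichment = minTSSEnrichment,
             maxPctMito = maxPctMito)
  if (!all(vapply(th, function(v) is.numeric(v) && length(v) == 1L &&
                    !is.na(v), logical(1)))) {
    stop("all thresholds must be single finite numbers (use Inf/-Inf to ",
         "disable a criterion)")
  }
  if (!(th$minCounts < th$maxCounts)) {
    stop("minCounts must be smaller than maxCounts")
  }
  structure(th, class = "QCThresholds")
}

#' Apply cell-level QC filters
#'
#' @description
#' Removes cells failing any criterion of [qcThresholds()], using the QC
#' metric columns of `colData(x)` (`rna_counts`, optional `atac_counts`,
#' `nucleosome_signal`, `tss_enrichment`, `pct_mito`). `rna_counts` is
#' computed from the counts assay when absent; `pct_mito` is computed from
#' genes whose symbol starts with `MT-` when absent (the human
#' mitochondrial naming convention). A criterion whose metric is missing
#' (`NA`) for a cell is skipped for that cell and tallied in the report —
#' RNA-only data are therefore not penalised for lacking ATAC metrics.
#'
#' @param x a `SingleCellExperiment` with a `"counts"` assay.
#' @param thresholds a [qcThresholds()] object.
#' @return a list with `experiment` (the filtered object; input untouched)
#'   and `report` (a list with the thresholds, per-criterion removal
#'   counts, counts of skipped criterion evaluations, the survivor cell
#'   ids, and `n_input`/`n_removed`/`n_survivors`).
#' @examples
#' coh <- simulateCohort(simConfig(nPatients = 2,
#'                                 cellsPerPatientPerPhase = 10,
#'                                 nGenes = 50, nTFs = 5, seed = 1))
#' res <- applyQC(coh, qcThresholds(minCounts = 0))
#' res$report$n_survivors
#' @export
applyQC <- function(x, thresholds = qcThresholds()) {
  stopifnot(methods::is(x, "SummarizedExperiment"))
  if (!inherits(thresholds, "QCThresholds")) {
    stop("thresholds must come from qcThresholds()")
  }
  counts <- .assayOrStop(x, "counts", "applyQC")
  cd <- SummarizedExperiment::colData(x)

  getMetric <- function(name, fallback = NULL) {
    if (name %in% colnames(cd)) as.numeric(cd[[name]]) else fallback
  }
  rna <- getMetric("rna_counts", as.numeric(Matrix::colSums(counts)))
  atac <- getMetric("atac_counts")
  nuc <- getMetric("nucleosome_signal")
  tss <- getMetric("tss_enrichment")
  mito <- getMetric("pct_mito", {
    mtGenes <- grepl("^MT-", rownames(x), ignore.case = FALSE)
    if (any(mtGenes)) {
      100 * as.numeric(Matrix::colSums(counts[mtGenes, , drop = FALSE])) /
        pmax(as.numeric(Matrix::colSums(counts)), 1)
    } else NULL
  })
  if (is.null(nuc) && is.null(tss) && is.null(mito) &&
      !"rna_counts" %in% colnames(cd)) {
    stop("no QC metrics found in colData(x); supply rna_counts / ",
         "nucleosome_signal / tss_enrichment / pct_mito")
  }

  n <- ncol(x)
  failOrSkip <- function(metric, fail) {
    if (is.null(metric)) {
      return(list(fail = rep(FALSE, n), skipped = rep(TRUE, n)))
    }
    f <- fail(metric)
    list(fail = !is.na(f) & f, skipped = is.na(metric))
  }
  crit <- list(
    rna_counts = failOrSkip(rna, function(v)
      v > thresholds$maxCounts | v < thresholds$minCounts),
    atac_counts = failOrSkip(atac, function(v)
      v > thresholds$maxCounts | v < thresholds$minCounts),
    nucleosome_signal = failOrSkip(nuc, function(v)
      v > thresholds$maxNucleosomeSignal),
    tss_enrichment = failOrSkip(tss, function(v)
      v < thresholds$minTSSEnrichment),
    pct_mito = failOrSkip(mito, function(v) v > thresholds$maxPctMito)
  )
  failAny <- Reduce(`|`, lapply(crit, `[[`, "fail"))
  survivors <- colnames(x)[!failAny]
  if (length(survivors) == 0L) {
    stop("QC removed every cell (", n, " of ", n, "); thresholds: ",
         paste(names(thresholds), unlist(thresholds), sep = "=",
               collapse = ", "))
  }
  report <- list(
    thresholds = thresholds,
    n_input = n,
    n_removed = sum(failAny),
    n_survivors = length(survivors),
    removed_by_criterion = vapply(crit, function(cc) sum(cc$fail),
                                  integer(1)),
    skipped_by_criterion = vapply(crit, function(cc) sum(cc$skipped),
                                  integer(1)),
    survivors = survivors
  )
  list(experiment = x[, !failAny], report = report)
}

#' Library-size normalization: counts per 10k, log1p
#'
#' @description
#' Scales each cell to 10,000 total counts and applies `log1p`:
#' `v -> ln(1 + v * 1e4 / T)` for a cell with total `T`. The result is
#' stored in two new assays, `"cp10k"` (linear scale, used for fold
#' changes) and `"logcounts"` (the log scale used by every rank-based
#' statistic downstream). Calling it on anything but raw counts is an
#' error — fractional values indicate already-normalized input, and a
#' silent double normalization is the classic failure mode.
#'
#' @param x a `SingleCellExperiment` with a nonnegative integer `"counts"`
#'   assay and no all-zero cell.
#' @return `x` with assays `"cp10k"` and `"logcounts"` added.
#' @examples
#' m <- Matrix::Matrix(c(10, 1990, 0, 5, 5, 10), nrow = 3, sparse = TRUE,
#'                     dimnames = list(paste0("g", 1:3), c("c1", "c2")))
#' sce <- SingleCellExperiment::SingleCellExperiment(list(counts = m))
#' SummarizedExperiment::assay(logNormalizeCP10K(sce), "logcounts")[1, 1]
#' # ln(1 + 10 * 1e4 / 2000) = ln(51)
#' @export
logNormalizeCP10K <- function(x) {
  stopifnot(methods::is(x, "SummarizedExperiment"))
  counts <- .assayOrStop(x, "counts", "logNormalizeCP10K")
  vals <- if (methods::is(counts, "sparseMatrix")) counts@x else
    as.numeric(counts)
  if (any(vals < 0)) stop("counts assay contains negative values")
  if (any(vals != floor(vals))) {
    stop("counts assay contains fractional values - input looks already ",
         "normalized; logNormalizeCP10K() only accepts raw counts")
  }
  tot <- as.numeric(Matrix::colSums(counts))
  zero <- which(tot == 0)
  if (length(zero)) {
    stop("all-zero cell(s): ",
         paste(colnames(x)[zero], collapse = ", "))
  }
  sf <- 1e4 / tot
  cp10k <- counts %*% Matrix::Diagonal(x = sf)
  dimnames(cp10k) <- dimnames(counts)
  logc <- cp10k
  if (methods::is(logc, "sparseMatrix")) {
    logc@x <- log1p(logc@x)
  } else {
    logc <- log1p(logc)
  }
  SummarizedExperiment::assay(x, "cp10k") <- cp10k
  SummarizedExperiment::assay(x, "logcounts") <- logc
  x
}
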