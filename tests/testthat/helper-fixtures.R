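# In-code fixtures: tiny SingleCellExperiment builders.

make_sce <- function(counts, meta = NULL, normalize = TRUE) {
  # force the general (non-symmetric, non-triangular) sparse class so
  # square fixtures keep their dimnames
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix")
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%d", seq_len(ncol(m)))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(m, "CsparseMatrix")))
  if (!is.null(meta)) {
    meta <- as.data.frame(lapply(meta, rep, length.out = ncol(m)))
    meta$cell_id <- colnames(m)
    sce <- attachCellMeta(sce, meta)
  }
  if (normalize) sce <- logNormalizeCP10K(sce)
  sce
}

# an SCE whose "logcounts" assay is set directly (no counts needed)
make_logcounts_sce <- function(logc, meta) {
  if (is.null(rownames(logc))) rownames(logc) <- sprintf("g%d", seq_len(nrow(logc)))
  if (is.null(colnames(logc))) colnames(logc) <- sprintf("c%d", seq_len(ncol(logc)))
  m <- methods::as(Matrix::Matrix(logc, sparse = TRUE), "generalMatrix")
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(logcounts = methods::as(m, "CsparseMatrix")))
  meta <- as.data.frame(lapply(meta, rep, length.out = ncol(m)))
  meta$cell_id <- colnames(m)
  attachCellMeta(sce, meta)
}

small_config <- function(seed = 1, ...) {
  simConfig(nPatients = 3, cellsPerPatientPerPhase = 25, nGenes = 300,
            nTFs = 20, seed = seed, ...)
}
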