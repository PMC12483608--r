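#' Read a gene-by-cell count matrix
#'
#' @description
#' Accepts either a 10x-style MatrixMarket directory (containing
#' `matrix.mtx` plus `features.tsv` — or `genes.tsv` — and `barcodes.tsv`)
#' or a dense tab-separated file. Output is always oriented genes-in-rows.
#'
#' For MTX input the 10x convention (genes in rows) is assumed and gene
#' identifiers are taken from the second column of the features file (the
#' gene symbol) when present, de-duplicated by appending `.1`, `.2`, ...;
#' module and TF lists in this field are symbol-based. A dense TSV must
#' declare its orientation through the name of its first header field:
#' `gene_id` means genes in rows, `cell_id` means cells in rows (the matrix
#' is transposed on read). Silent transposition is never performed.
#'
#' @param path an MTX directory or a dense TSV file.
#' @return a [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment]
#'   with the integer matrix in assay `"counts"` and gene ids as rownames.
#' @seealso [writeCounts()], [readCellMeta()]
#' @export
readCounts <- function(path) {
  if (dir.exists(path)) {
    return(.readCountsMTX(path))
  }
  if (!file.exists(path)) stop("no such file or directory: ", path)
  .readCountsTSV(path)
}

.dedupIDs <- function(ids) {
  dup <- duplicated(ids)
  if (!any(dup)) return(ids)
  make.unique(ids, sep = ".")
}

.readCountsMTX <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  feats <- file.path(dir, "features.tsv")
  if (!file.exists(feats)) feats <- file.path(dir, "genes.tsv")
  bcs <- file.path(dir, "barcodes.tsv")
  missing <- c(mtx, feats, bcs)[!file.exists(c(mtx, feats, bcs))]
  if (length(missing)) {
    stop("MTX directory is missing companion file(s): ",
         paste(basename(missing), collapse = ", "))
  }
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  ftab <- utils::read.delim(feats, header = FALSE, sep = "\t",
                            colClasses = "character")
  bar <- readLines(bcs)
  bar <- bar[nzchar(bar)]
  if (nrow(ftab) != nrow(m)) {
    stop("dimension mismatch: matrix.mtx declares ", nrow(m),
         " rows but the features file has ", nrow(ftab), " lines")
  }
  if (length(bar) != ncol(m)) {
    stop("dimension mismatch: matrix.mtx declares ", ncol(m),
         " columns but the barcodes file has ", length(bar), " lines")
  }
  if (anyDuplicated(bar)) {
    offenders <- unique(bar[duplicated(bar)])
    stop("duplicate barcodes: ", paste(offenders, collapse = ", "))
  }
  symbols <- if (ncol(ftab) >= 2) ftab[[2]] else ftab[[1]]
  rownames(m) <- .dedupIDs(symbols)
  colnames(m) <- bar
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

.readCountsTSV <- function(file) {
  tab <- utils::read.delim(file, header = TRUE, sep = "\t",
                           check.names = FALSE)
  token <- names(tab)[1]
  if (!token %in% c("gene_id", "cell_id")) {
    stop("dense TSV must declare its orientation: first header field ",
         "must be 'gene_id' (genes in rows) or 'cell_id' (cells in rows), ",
         "got '", token, "'")
  }
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate ", token, "s: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- ids
  if (token == "cell_id") m <- t(m)
  if (anyDuplicated(colnames(m))) {
    stop("duplicate barcodes: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  storage.mode(m) <- "double"
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

#' Write a count matrix as a 10x-style MTX directory
#'
#' Writes `matrix.mtx`, `features.tsv` (id, symbol, type) and
#' `barcodes.tsv` into `dir`, creating it if needed.
#'
#' @param x a `SingleCellExperiment` (or any `SummarizedExperiment`) with a
#'   `"counts"` assay, or a matrix.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeCounts <- function(x, dir) {
  m <- if (methods::is(x, "SummarizedExperiment")) {
    .assayOrStop(x, "counts", "writeCounts")
  } else x
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("writeCounts needs gene and cell identifiers as dimnames")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(m, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(rownames(m), rownames(m), "Gene Expression"),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

# columns of a cell-meta table parsed as numbers when present
.metaNumericCols <- c("rna_counts", "atac_counts", "nucleosome_signal",
                      "tss_enrichment", "pct_mito", "plasticity")

#' Read a per-cell metadata table
#'
#' @description
#' Reads a tab-separated table with a header. `cell_id` is required; any
#' subset of `patient_id`, `phase`, `cluster_label` and the QC metric
#' columns (`rna_counts`, `atac_counts`, `nucleosome_signal`,
#' `tss_enrichment`, `pct_mito`) is typed when present; unknown columns
#' are preserved untouched. Phase strings are case-normalized: any value
#' containing "post" becomes `post`, any containing "naive" becomes
#' `naive` (so `Post-NACT` and `Treatment-naive` both parse).
#'
#' @param path a TSV file.
#' @return a [S4Vectors::DataFrame] keyed by `cell_id`.
#' @export
readCellMeta <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL)
  if (!"cell_id" %in% names(tab)) {
    stop("metadata table lacks the required 'cell_id' column")
  }
  if (anyDuplicated(tab$cell_id)) {
    stop("duplicate cell_id values: ",
         paste(unique(tab$cell_id[duplicated(tab$cell_id)]), collapse = ", "))
  }
  for (cc in intersect(.metaNumericCols, names(tab))) {
    raw <- tab[[cc]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & nzchar(raw))
    if (length(bad)) {
      stop("unparsable numeric value '", raw[bad[1]], "' in row ", bad[1],
           ", column '", cc, "'")
    }
    tab[[cc]] <- val
  }
  if ("phase" %in% names(tab)) {
    tab$phase <- .normalizePhase(tab$phase)
  }
  out <- S4Vectors::DataFrame(tab, row.names = tab$cell_id,
                              check.names = FALSE)
  out
}

.normalizePhase <- function(x) {
  lx <- tolower(x)
  out <- rep(NA_character_, length(x))
  out[grepl("post", lx)] <- "post"
  out[grepl("naïve|naive", lx)] <- "naive"
  out[!nzchar(x)] <- NA_character_
  unknown <- which(is.na(out) & nzchar(x))
  if (length(unknown)) {
    stop("unrecognized phase label(s): ",
         paste(unique(x[unknown]), collapse = ", "),
         " (expected variants of 'naive' or 'post')")
  }
  out
}

#' Write a per-cell metadata (or any) table as TSV
#'
#' Tab-separated, UTF-8, Unix newlines, header row, missing values as
#' empty fields — the conventions every reader in this package expects.
#'
#' @param x a data.frame or DataFrame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCellMeta <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' Attach per-cell metadata to a count object
#'
#' Joins a metadata table onto the columns of a `SingleCellExperiment`.
#' The cell-id sets must match exactly; rows are reordered to the matrix
#' column order, and no row is ever silently dropped.
#'
#' @param x a `SingleCellExperiment`.
#' @param meta a `DataFrame`/data.frame with a `cell_id` column.
#' @return `x` with `colData` replaced by `meta` (in matrix order).
#' @export
attachCellMeta <- function(x, meta) {
  meta <- S4Vectors::DataFrame(meta, check.names = FALSE)
  if (!"cell_id" %in% colnames(meta)) stop("meta lacks 'cell_id'")
  onlyMeta <- setdiff(meta$cell_id, colnames(x))
  onlyMat <- setdiff(colnames(x), meta$cell_id)
  if (length(onlyMeta) || length(onlyMat)) {
    stop("cell-id sets differ: ", length(onlyMat),
         " cells without metadata, ", length(onlyMeta),
         " metadata rows without cells")
  }
  meta <- meta[match(colnames(x), meta$cell_id), , drop = FALSE]
  rownames(meta) <- meta$cell_id
  SummarizedExperiment::colData(x) <- meta
  x
}

#' Read a gene list (one symbol per line)
#'
#' Blank lines and `#` comments are ignored; leading/trailing whitespace
#' is trimmed.
#'
#' @param path text file, one gene symbol per line.
#' @return character vector of symbols.
#' @export
readGeneList <- function(path) {
  x <- readLines(path)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Write the ground-truth manifest of a synthetic cohort
#'
#' Flat `key<TAB>value` text file; multi-valued entries are
#' comma-separated, the per-cell plasticity factors are written as
#' `plasticity.<cell_id>` keys.
#'
#' @param cohort a [CohortExperiment-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTruthManifest <- function(cohort, path) {
  tr <- truthManifest(cohort)
  lines <- c(
    paste0("planted_tf\t", tr$planted_tf),
    paste0("tf_panel\t", paste(tr$tf_panel, collapse = ",")),
    paste0("module_genes\t", paste(tr$module_genes, collapse = ",")),
    paste0("rare_cluster_cells\t",
           paste(tr$rare_cluster_cells, collapse = ",")),
    paste0("generator\t", tr$generator),
    sprintf("plasticity.%s\t%.17g", names(tr$plasticity), tr$plasticity)
  )
  writeLines(lines, path)
  invisible(path)
}
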