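#' Per-cell transcriptional divergence (P50/P50)
#'
#' @description
#' Transcriptional divergence measures how unequally a cell distributes
#' its transcriptional output: after removing all non-expressed genes, it
#' is the ratio of the summed expression of the top 50% of detected genes
#' to the summed expression of the bottom 50%. High values indicate a
#' skewed, plastic transcriptional state — a property of stem-like and
#' drug-tolerant cells — and the statistic rises under cytotoxic stress.
#'
#' With `G` expressed genes sorted in decreasing order, the top sum is
#' over the first `floor(G/2)` values and the bottom sum over the last
#' `floor(G/2)`; for odd `G` the median value is excluded from both
#' halves, keeping the two sums the same size. The ratio is always
#' `>= 1` and is invariant to uniform rescaling of the cell, so raw
#' counts and library-size-normalized values give identically ranked
#' cells under any within-cell monotone transform.
#'
#' @param cellValues nonnegative numeric vector of per-gene values for one
#'   cell.
#' @return a list with `G` (number of expressed genes), `top_sum`,
#'   `bottom_sum`, and `divergence`. With fewer than 2 expressed genes all
#'   fields except `G` are `NA` and `flag = "too_few_expressed"` is set
#'   (never a silent 1).
#' @examples
#' transcriptionalDivergence(c(10, 5, 3, 2))$divergence  # (10+5)/(3+2) = 3
#' transcriptionalDivergence(c(9, 4, 1))$divergence      # odd G: 9/1 = 9
#' @export
transcriptionalDivergence <- function(cellValues) {
  if (any(cellValues < 0, na.rm = TRUE)) {
    stop("expression values must be nonnegative")
  }
  v <- cellValues[!is.na(cellValues) & cellValues > 0]
  G <- length(v)
  if (G < 2L) {
    return(list(G = G, top_sum = NA_real_, bottom_sum = NA_real_,
                divergence = NA_real_, flag = "too_few_expressed"))
  }
  s <- sort(v, decreasing = TRUE, method = "radix")  # stable: ties by index
  k <- G %/% 2L
  top <- sum(s[seq_len(k)])
  bottom <- sum(s[seq.int(G - k + 1L, G)])
  list(G = G, top_sum = top, bottom_sum = bottom, divergence = top / bottom,
       flag = NA_character_)
}

#' Divergence table for every cell of a matrix
#'
#' Computes [transcriptionalDivergence()] for each retained cell and joins
#' the per-cell annotations (`patient_id`, `phase`, `cluster_label`,
#' when present) from `colData`.
#'
#' @param x a `SingleCellExperiment`.
#' @param layer assay to use; `"counts"` (default — the statistic is
#'   defined on count sums) or `"logcounts"`.
#' @param cells optional character/logical/integer subset of cells (for
#'   example, the epithelial compartment).
#' @return a [S4Vectors::DataFrame] with one row per cell: `cell_id`, `G`,
#'   `top_sum`, `bottom_sum`, `divergence`, `flag`, plus annotations.
#' @export
divergenceTable <- function(x, layer = c("counts", "logcounts"),
                            cells = NULL) {
  stopifnot(methods::is(x, "SummarizedExperiment"))
  layer <- match.arg(layer)
  m <- .assayOrStop(x, layer, "divergenceTable")
  if (!is.null(cells)) {
    m <- m[, cells, drop = FALSE]
    if (ncol(m) == 0L) stop("cell subset is empty")
  }
  if (ncol(m) == 0L) stop("no cells in the matrix")
  profs <- if (methods::is(m, "CsparseMatrix")) {
    # the statistic drops zeros first, so the nonzero slice of each CSC
    # column is exactly its input; avoids materializing dense columns
    lapply(seq_len(ncol(m)), function(j) {
      idx <- seq.int(m@p[j] + 1L, length.out = m@p[j + 1L] - m@p[j])
      transcriptionalDivergence(m@x[idx])
    })
  } else {
    lapply(seq_len(ncol(m)), function(j)
      transcriptionalDivergence(.col(m, j)))
  }
  out <- S4Vectors::DataFrame(
    cell_id = colnames(m),
    G = vapply(profs, `[[`, integer(1), "G"),
    top_sum = vapply(profs, `[[`, numeric(1), "top_sum"),
    bottom_sum = vapply(profs, `[[`, numeric(1), "bottom_sum"),
    divergence = vapply(profs, `[[`, numeric(1), "divergence"),
    flag = vapply(profs, `[[`, character(1), "flag"),
    row.names = colnames(m)
  )
  cd <- SummarizedExperiment::colData(x)
  for (cc in intersect(c("patient_id", "phase", "cluster_label"),
                       colnames(cd))) {
    out[[cc]] <- cd[colnames(m), cc]
  }
  S4Vectors::metadata(out)$layer <- layer
  out
}

#' Compare divergence between two groups of cells
#'
#' Two-sided Wilcoxon rank-sum test of the divergence values between the
#' two levels of a grouping column (by default the treatment `phase`),
#' with group medians and the direction of the difference.
#'
#' @param table a [divergenceTable()] result (or any DataFrame with a
#'   `divergence` column and the grouping column).
#' @param groupBy name of the grouping column (default `"phase"`).
#' @return a list: `groups` (the two level names), `n`, `medians`,
#'   `statistic` (rank sum of the first group), `p_value`, `direction`
#'   (`"<name1> > <name2>"`, the reverse, or `"none"`), `degenerate`.
#' @examples
#' tbl <- S4Vectors::DataFrame(divergence = c(1, 1, 1, 3, 3, 3),
#'                             phase = rep(c("naive", "post"), each = 3))
#' compareDivergence(tbl)$p_value  # exact: 2 of choose(6,3) assignments
#' @export
compareDivergence <- function(table, groupBy = "phase") {
  if (!groupBy %in% colnames(table)) {
    stop("grouping column '", groupBy, "' not found")
  }
  g <- as.character(table[[groupBy]])
  d <- table$divergence
  keep <- !is.na(d) & !is.na(g)
  g <- g[keep]
  d <- d[keep]
  lev <- sort(unique(g))
  if (length(lev) != 2L) {
    stop("grouping must have exactly 2 nonempty levels, got ",
         length(lev))
  }
  xa <- d[g == lev[1]]
  xb <- d[g == lev[2]]
  if (length(xa) < 2L || length(xb) < 2L) {
    stop("each group needs at least 2 cells (", lev[1], ": ", length(xa),
         ", ", lev[2], ": ", length(xb), ")")
  }
  wt <- wilcoxonRankSum(xa, xb, alternative = "two.sided")
  med <- c(stats::median(xa), stats::median(xb))
  names(med) <- lev
  direction <- if (wt$degenerate || med[1] == med[2]) "none"
    else if (med[1] > med[2]) paste(lev[1], ">", lev[2])
    else paste(lev[2], ">", lev[1])
  list(groups = lev, n = stats::setNames(c(length(xa), length(xb)), lev),
       medians = med, statistic = wt$statistic, p_value = wt$p_value,
       direction = direction, degenerate = wt$degenerate)
}
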