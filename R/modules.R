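#' Control-bin gene-module score per cell
#'
#' @description
#' Scores the aggregate expression of a gene module in each cell against
#' expression-matched control genes, the standard construction for
#' single-cell signature scoring: all genes are binned into `nBins` bins
#' of equal size by their mean normalized expression; for each module
#' gene, `nCtrl` control genes are sampled from the non-module genes of
#' its bin (with replacement when the pool holds fewer than `nCtrl`
#' genes); the score of a cell is
#' the mean over module genes minus the mean over the sampled control
#' genes. The control term removes the depth/mean-expression component,
#' so a module drawn from the background distribution scores ~0 and
#' adding a constant to every value of a cell leaves its score unchanged.
#'
#' @param x a `SingleCellExperiment` with a `"logcounts"` assay.
#' @param module character vector of module gene identifiers. Genes absent
#'   from the matrix are reported via the `missing_genes` attribute of the
#'   result (error only if none is present). Note the antigen name
#'   `SSEA1` is not an HGNC symbol; its gene is `FUT4` — map aliases
#'   before calling.
#' @param nBins number of mean-expression bins (default 24).
#' @param nCtrl control genes sampled per module gene (default 100).
#' @param seed integer seed for the control sampling; the caller's RNG
#'   state is left untouched.
#' @param method `"control"` (the bin-matched difference, default) or
#'   `"mean"` (plain per-cell mean of the module genes, for sensitivity
#'   analysis).
#' @return named numeric vector of per-cell scores, with attributes
#'   `missing_genes` and `control_genes`.
#' @export
moduleScore <- function(x, module, nBins = 24, nCtrl = 100, seed = 0,
                        method = c("control", "mean")) {
  stopifnot(methods::is(x, "SummarizedExperiment"))
  method <- match.arg(method)
  logc <- .assayOrStop(x, "logcounts", "moduleScore")
  module <- unique(module)
  present <- intersect(module, rownames(x))
  missing <- setdiff(module, rownames(x))
  if (length(present) == 0L) {
    stop("no module gene present in the matrix; missing: ",
         paste(missing, collapse = ", "))
  }
  modMean <- Matrix::colMeans(logc[present, , drop = FALSE])

  if (method == "mean") {
    score <- as.numeric(modMean)
    names(score) <- colnames(x)
    attr(score, "missing_genes") <- missing
    attr(score, "control_genes") <- character(0)
    return(score)
  }

  geneMeans <- as.numeric(Matrix::rowMeans(logc))
  names(geneMeans) <- rownames(x)
  nBins <- min(nBins, length(geneMeans))
  bins <- cut(rank(geneMeans, ties.method = "first"),
              breaks = nBins, labels = FALSE)
  names(bins) <- rownames(x)

  ctrl <- .withSeed(seed, {
    unlist(lapply(present, function(g) {
      # module genes are excluded from their own control pool, otherwise
      # the correction partially subtracts the signal it should preserve
      pool <- setdiff(names(bins)[bins == bins[g]], present)
      if (length(pool) == 0L) {
        stop("control bin of module gene '", g, "' holds no non-module ",
             "gene; lower nBins")
      }
      sample(pool, nCtrl, replace = length(pool) < nCtrl)
    }), use.names = FALSE)
  })
  ctrlMean <- Matrix::colMeans(logc[ctrl, , drop = FALSE])
  score <- as.numeric(modMean - ctrlMean)
  names(score) <- colnames(x)
  attr(score, "missing_genes") <- missing
  attr(score, "control_genes") <- ctrl
  score
}

#' One-vs-each cluster enrichment of a per-cell feature
#'
#' @description
#' Tests a per-cell feature (a gene's expression or a module score)
#' between every unordered pair of clusters with a two-sided Wilcoxon
#' rank-sum test, adjusts all `k(k-1)/2` pairwise p-values as one
#' Benjamini-Hochberg family, and summarizes each cluster by its worst
#' (largest) adjusted value over its `k-1` pairs — the "highest FDR"
#' convention: a cluster is significantly enriched only if it beats every
#' other cluster. A cluster is flagged `enriched` when its median exceeds
#' the median of every other cluster.
#'
#' Singleton clusters are excluded with a warning.
#'
#' @param feature numeric per-cell vector.
#' @param clusters cluster labels, same length.
#' @return a [S4Vectors::DataFrame] with one row per cluster (`cluster`,
#'   `n`, `median`, `enriched`, `max_fdr`), sorted by `max_fdr`; the
#'   pairwise table (cluster_a, cluster_b, p, fdr) is in
#'   `metadata(result)$pairs`.
#' @export
clusterEnrichment <- function(feature, clusters) {
  if (length(feature) != length(clusters)) {
    stop("feature and clusters differ in length")
  }
  keep <- !is.na(feature) & !is.na(clusters)
  feature <- feature[keep]
  clusters <- as.character(clusters)[keep]
  sizes <- table(clusters)
  singletons <- names(sizes)[sizes < 2]
  if (length(singletons)) {
    warning("singleton cluster(s) excluded: ",
            paste(singletons, collapse = ", "))
    sel <- !clusters %in% singletons
    feature <- feature[sel]
    clusters <- clusters[sel]
  }
  labs <- sort(unique(clusters))
  k <- length(labs)
  if (k < 2L) stop("need at least 2 clusters with >= 2 cells")

  pairs <- utils::combn(labs, 2)
  pv <- apply(pairs, 2, function(pr) {
    wilcoxonRankSum(feature[clusters == pr[1]],
                    feature[clusters == pr[2]])$p_value
  })
  fdr <- bhAdjust(pv)
  pairTab <- S4Vectors::DataFrame(cluster_a = pairs[1, ],
                                  cluster_b = pairs[2, ],
                                  p = pv, fdr = fdr)

  med <- vapply(labs, function(l) stats::median(feature[clusters == l]),
                numeric(1))
  res <- S4Vectors::DataFrame(
    cluster = labs,
    n = as.integer(table(factor(clusters, levels = labs))),
    median = unname(med),
    enriched = unname(vapply(labs, function(l)
      all(med[l] > med[names(med) != l]), logical(1))),
    max_fdr = unname(vapply(labs, function(l) {
      max(fdr[pairs[1, ] == l | pairs[2, ] == l])
    }, numeric(1)))
  )
  res <- res[order(res$max_fdr), ]
  S4Vectors::metadata(res)$pairs <- pairTab
  res
}

# shared DE helper: per-gene two-sided rank-sum between two cell sets
.geneWiseRankSum <- function(m, selA, selB) {
  m <- as.matrix(m)  # row extraction from sparse storage is the bottleneck
  vapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    wilcoxonRankSum(v[selA], v[selB])$p_value
  }, numeric(1))
}

#' One-vs-rest differential expression for a cluster
#'
#' @description
#' Tests every gene between the target cluster and all remaining cells
#' (two-sided Wilcoxon rank-sum on `logcounts`), computes
#' `log2((mu_target + eps) / (mu_rest + eps))` on the CP10k scale,
#' adjusts across all tested genes (Benjamini-Hochberg), and returns the
#' genes passing `fdr < fdrMax` and `log2fc > lfcMin`. The defaults
#' (`fdrMax = 0.005`, `lfcMin = 0`) select significantly upregulated
#' marker genes of the cluster.
#'
#' @param x a `SingleCellExperiment` with `"cp10k"` and `"logcounts"`.
#' @param clusters per-cell labels (defaults to
#'   `colData(x)$cluster_label`).
#' @param target the cluster label of interest.
#' @param fdrMax,lfcMin selection thresholds.
#' @param eps fold-change pseudo-count (shared with [tfScreen()]).
#' @return a [S4Vectors::DataFrame] (`gene_id`, `log2fc`, `p`, `fdr`,
#'   `direction`), sorted by `p`; possibly 0 rows. The full per-gene
#'   table is in `metadata(result)$all_genes`.
#' @export
deOneVsRest <- function(x, clusters = NULL, target, fdrMax = 0.005,
                        lfcMin = 0, eps = 1e-9) {
  stopifnot(methods::is(x, "SummarizedExperiment"))
  if (is.null(clusters)) {
    clusters <- SummarizedExperiment::colData(x)$cluster_label
  }
  clusters <- as.character(clusters)
  if (!target %in% clusters) {
    stop("target cluster '", target, "' not present")
  }
  selA <- clusters == target
  selB <- !selA
  if (sum(selA) < 3L || sum(selB) < 3L) {
    stop("target cluster and complement each need >= 3 cells")
  }
  logc <- .assayOrStop(x, "logcounts", "deOneVsRest")
  cp10k <- .assayOrStop(x, "cp10k", "deOneVsRest")

  p <- .geneWiseRankSum(logc, selA, selB)
  muA <- as.numeric(Matrix::rowMeans(cp10k[, selA, drop = FALSE]))
  muB <- as.numeric(Matrix::rowMeans(cp10k[, selB, drop = FALSE]))
  lfc <- log2((muA + eps) / (muB + eps))
  fdr <- bhAdjust(p)
  all <- S4Vectors::DataFrame(
    gene_id = rownames(x), log2fc = lfc, p = p, fdr = fdr,
    direction = ifelse(lfc > 0, "up", "down")
  )
  pass <- all[all$fdr < fdrMax & all$log2fc > lfcMin, , drop = FALSE]
  pass <- pass[order(pass$p), , drop = FALSE]
  S4Vectors::metadata(pass)$all_genes <- all
  pass
}

#' Two-group differential expression on replicate tables
#'
#' @description
#' Per-gene two-sided Wilcoxon rank-sum test between two replicate groups
#' of a bulk expression table (log-scale values), direction by mean
#' difference, thresholded on the raw p-value (`p < pMax`) — the
#' convention for paired bulk contrasts whose significant sets are then
#' intersected.
#'
#' @param expr gene-by-replicate numeric matrix (log scale).
#' @param group factor/character of length `ncol(expr)` with exactly two
#'   levels; the first level is the reference, `direction = "up"` means
#'   higher in the second.
#' @param pMax raw p-value threshold (default 0.05).
#' @return a [S4Vectors::DataFrame] (`gene_id`, `log2fc`, `p`,
#'   `direction`) of the genes passing `p < pMax`.
#' @export
deTwoGroup <- function(expr, group, pMax = 0.05) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly 2 levels")
  if (length(group) != ncol(expr)) {
    stop("group length must match the number of replicate columns")
  }
  if (min(table(group)) < 3L) {
    stop("need at least 3 replicates per group")
  }
  selB <- group == levels(group)[2]
  selA <- !selB
  p <- .geneWiseRankSum(expr, which(selB), which(selA))
  lfc <- as.numeric(rowMeans(expr[, selB, drop = FALSE]) -
                      rowMeans(expr[, selA, drop = FALSE]))
  out <- S4Vectors::DataFrame(
    gene_id = rownames(expr), log2fc = lfc, p = p,
    direction = ifelse(lfc > 0, "up", "down")
  )
  out[!is.na(out$p) & out$p < pMax & out$log2fc != 0, , drop = FALSE]
}

#' Intersect two differential-expression signatures
#'
#' Genes called in the same direction in both tables; genes with opposite
#' directions are excluded.
#'
#' @param a,b DataFrames/data.frames with `gene_id` and `direction`
#'   (`"up"`/`"down"`) columns, e.g. from [deTwoGroup()].
#' @return list with `common_up`, `common_down` (character vectors) and
#'   `n_common_up`, `n_common_down`.
#' @examples
#' a <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
#'                 direction = c("up", "up", "up", "down"))
#' b <- data.frame(gene_id = c("g2", "g3", "g5", "g4", "g6"),
#'                 direction = c("up", "up", "up", "down", "down"))
#' intersectSignatures(a, b)$n_common_up  # 2
#' @export
intersectSignatures <- function(a, b) {
  pick <- function(tab, dir) as.character(tab$gene_id[tab$direction == dir])
  up <- intersect(pick(a, "up"), pick(b, "up"))
  down <- intersect(pick(a, "down"), pick(b, "down"))
  list(common_up = up, common_down = down,
       n_common_up = length(up), n_common_down = length(down))
}
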