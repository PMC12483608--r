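#' @include AllGenerics.R
NULL

#' Simulation parameters for a synthetic single-cell cohort
#'
#' @description
#' `SimConfig` bundles every tunable of the synthetic-data generator:
#' a longitudinal cohort of patients sampled in two treatment phases
#' (`naive` and `post`), negative-binomial counts with log-normal gene
#' means, a latent per-cell plasticity factor that drives transcriptional
#' divergence, a planted transcription factor whose mean expression
#' increases monotonically with that factor, a rare stem-like cell cluster
#' with elevated module-gene expression, per-cell DAB staining intensities
#' with a phase effect, and two bulk differential contrasts sharing a
#' planted true gene set.
#'
#' @details
#' Counts for gene g in cell c are drawn
#' `NB(mu = m_g * s_gc, size = nbDispersion)` where `m_g ~
#' LogNormal(meanLogexprMu, meanLogexprSigma)` and the scaling
#' `s_gc = 1 + (divergenceCoupling + postPhaseDivergenceShift * [c is
#' post]) * f_c` is applied to the top half of genes by mean expression.
#' The per-cell plasticity factor `f_c ~ Beta(plasticityShapeA,
#' plasticityShapeB)` therefore directly inflates the P50/P50 numerator, so
#' expected divergence increases with `f_c` in every cell and is higher
#' post-treatment. The planted TF's mean is
#' `m_tf * exp(3 * plantedTFCoupling * (f_c - E[f]))`, strictly increasing
#' in `f_c` whenever the coupling is positive.
#'
#' All outputs are fully determined by `seed`; each generator stage draws
#' from its own substream so adding a stage never perturbs earlier draws.
#'
#' Defaults emulate the scale of the longitudinal cohort the package's
#' analyses address (11 patients, two phases, a rare cluster at 0.6% of
#' cells, a 12-gene stem module) at a gene/cell count small enough for
#' routine simulation studies.
#'
#' @slot nPatients integer, patients in the cohort (default 11).
#' @slot cellsPerPatientPerPhase integer, cells per patient per phase (60).
#' @slot nGenes integer, genes (1000).
#' @slot nbDispersion positive real, negative-binomial size parameter (2).
#' @slot meanLogexprMu,meanLogexprSigma log-normal hyperparameters of the
#'   gene means (0, 1).
#' @slot plasticityShapeA,plasticityShapeB Beta shape parameters of the
#'   per-cell plasticity factor (2, 4).
#' @slot plantedTFCoupling real in `[0, 1]`, strength of the monotone
#'   coupling between the planted TF mean and the plasticity factor (0.8).
#' @slot divergenceCoupling nonnegative real, phase-independent scaling of
#'   the top-half gene means by the plasticity factor (0.5).
#' @slot postPhaseDivergenceShift nonnegative real, additional top-half
#'   scaling applied to post-phase cells (0.3).
#' @slot rareClusterFraction real in (0, 0.05), rare-cluster size as a
#'   fraction of base cells (0.006).
#' @slot rareClusterModuleFoldchange real >= 1, module-gene fold change in
#'   rare-cluster cells (4).
#' @slot moduleSize integer, planted module size (12).
#' @slot nTFs integer, size of the simulated TF panel, planted TF included
#'   (50).
#' @slot nBaseClusters integer, number of background cluster labels (5).
#' @slot ihcTissuesPerPatient integer, stained tissues per patient per
#'   phase (4).
#' @slot ihcCellsPerTissue integer, cells per stained tissue (100).
#' @slot ihcShape,ihcScale Gamma parameters of naive-phase DAB intensity
#'   (4, 0.25; mean 1).
#' @slot ihcPostShift real, additive shift of the post-phase mean DAB
#'   intensity (0.5).
#' @slot bulkReplicates integer >= 3, replicates per group per contrast (4).
#' @slot bulkSharedUp,bulkSharedDown integers, planted shared up/down gene
#'   set sizes (50, 50).
#' @slot bulkEffectLFC positive real, planted log2 effect size (2).
#' @slot bulkNoiseSD positive real, replicate noise SD on the log2 scale
#'   (0.5).
#' @slot seed integer, master seed.
#'
#' @seealso [simulateCohort()], [simulateIHC()], [simulateBulkContrasts()]
#' @export
setClass("SimConfig",
  representation(
    nPatients = "numeric",
    cellsPerPatientPerPhase = "numeric",
    nGenes = "numeric",
    nbDispersion = "numeric",
    meanLogexprMu = "numeric",
    meanLogexprSigma = "numeric",
    plasticityShapeA = "numeric",
    plasticityShapeB = "numeric",
    plantedTFCoupling = "numeric",
    divergenceCoupling = "numeric",
    postPhaseDivergenceShift = "numeric",
    rareClusterFraction = "numeric",
    rareClusterModuleFoldchange = "numeric",
    moduleSize = "numeric",
    nTFs = "numeric",
    nBaseClusters = "numeric",
    ihcTissuesPerPatient = "numeric",
    ihcCellsPerTissue = "numeric",
    ihcShape = "numeric",
    ihcScale = "numeric",
    ihcPostShift = "numeric",
    bulkReplicates = "numeric",
    bulkSharedUp = "numeric",
    bulkSharedDown = "numeric",
    bulkEffectLFC = "numeric",
    bulkNoiseSD = "numeric",
    seed = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  cnt <- c(
    nPatients = object@nPatients,
    cellsPerPatientPerPhase = object@cellsPerPatientPerPhase,
    nGenes = object@nGenes,
    moduleSize = object@moduleSize,
    nTFs = object@nTFs,
    nBaseClusters = object@nBaseClusters,
    ihcTissuesPerPatient = object@ihcTissuesPerPatient,
    ihcCellsPerTissue = object@ihcCellsPerTissue,
    bulkReplicates = object@bulkReplicates
  )
  bad <- names(cnt)[!vapply(cnt, .isCount, logical(1))]
  if (length(bad)) {
    msg <- c(msg, paste0("counts must be integers >= 1: ",
                         paste(bad, collapse = ", ")))
  }
  if (!(object@rareClusterFraction > 0 && object@rareClusterFraction < 0.05))
    msg <- c(msg, "rareClusterFraction must lie in (0, 0.05)")
  if (object@rareClusterModuleFoldchange < 1)
    msg <- c(msg, "rareClusterModuleFoldchange must be >= 1")
  if (object@plantedTFCoupling < 0 || object@plantedTFCoupling > 1)
    msg <- c(msg, "plantedTFCoupling must lie in [0, 1]")
  if (object@divergenceCoupling < 0)
    msg <- c(msg, "divergenceCoupling must be nonnegative")
  if (object@postPhaseDivergenceShift < 0)
    msg <- c(msg, "postPhaseDivergenceShift must be nonnegative")
  if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be > 0")
  if (object@plasticityShapeA <= 0 || object@plasticityShapeB <= 0)
    msg <- c(msg, "plasticity shape parameters must be > 0")
  if (object@moduleSize > object@nGenes)
    msg <- c(msg, "moduleSize cannot exceed nGenes")
  if (object@nTFs >= object@nGenes)
    msg <- c(msg, "nTFs must be smaller than nGenes")
  if (object@bulkReplicates < 3)
    msg <- c(msg, "bulkReplicates must be >= 3")
  if (object@bulkSharedUp + object@bulkSharedDown > object@nGenes)
    msg <- c(msg, "planted bulk gene sets cannot exceed nGenes")
  if (object@ihcShape <= 0 || object@ihcScale <= 0)
    msg <- c(msg, "ihcShape and ihcScale must be > 0")
  if (object@seed != round(object@seed))
    msg <- c(msg, "seed must be an integer")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param nPatients,cellsPerPatientPerPhase,nGenes,nbDispersion,meanLogexprMu,meanLogexprSigma,plasticityShapeA,plasticityShapeB,plantedTFCoupling,divergenceCoupling,postPhaseDivergenceShift,rareClusterFraction,rareClusterModuleFoldchange,moduleSize,nTFs,nBaseClusters,ihcTissuesPerPatient,ihcCellsPerTissue,ihcShape,ihcScale,ihcPostShift,bulkReplicates,bulkSharedUp,bulkSharedDown,bulkEffectLFC,bulkNoiseSD,seed see the slot documentation in [SimConfig-class].
#'
#' @return a validated `SimConfig` object.
#' @examples
#' cfg <- simConfig(nPatients = 3, cellsPerPatientPerPhase = 50,
#'                  nGenes = 200, seed = 7)
#' cfg
#' @export
simConfig <- function(nPatients = 11,
                      cellsPerPatientPerPhase = 60,
                      nGenes = 1000,
                      nbDispersion = 2,
                      meanLogexprMu = 0,
                      meanLogexprSigma = 1,
                      plasticityShapeA = 2,
                      plasticityShapeB = 4,
                      plantedTFCoupling = 0.8,
                      divergenceCoupling = 0.5,
                      postPhaseDivergenceShift = 0.3,
                      rareClusterFraction = 0.006,
                      rareClusterModuleFoldchange = 4,
                      moduleSize = 12,
                      nTFs = 50,
                      nBaseClusters = 5,
                      ihcTissuesPerPatient = 4,
                      ihcCellsPerTissue = 100,
                      ihcShape = 4,
                      ihcScale = 0.25,
                      ihcPostShift = 0.5,
                      bulkReplicates = 4,
                      bulkSharedUp = 50,
                      bulkSharedDown = 50,
                      bulkEffectLFC = 2,
                      bulkNoiseSD = 0.5,
                      seed = 1) {
  methods::new("SimConfig",
    nPatients = nPatients,
    cellsPerPatientPerPhase = cellsPerPatientPerPhase,
    nGenes = nGenes,
    nbDispersion = nbDispersion,
    meanLogexprMu = meanLogexprMu,
    meanLogexprSigma = meanLogexprSigma,
    plasticityShapeA = plasticityShapeA,
    plasticityShapeB = plasticityShapeB,
    plantedTFCoupling = plantedTFCoupling,
    divergenceCoupling = divergenceCoupling,
    postPhaseDivergenceShift = postPhaseDivergenceShift,
    rareClusterFraction = rareClusterFraction,
    rareClusterModuleFoldchange = rareClusterModuleFoldchange,
    moduleSize = moduleSize,
    nTFs = nTFs,
    nBaseClusters = nBaseClusters,
    ihcTissuesPerPatient = ihcTissuesPerPatient,
    ihcCellsPerTissue = ihcCellsPerTissue,
    ihcShape = ihcShape,
    ihcScale = ihcScale,
    ihcPostShift = ihcPostShift,
    bulkReplicates = bulkReplicates,
    bulkSharedUp = bulkSharedUp,
    bulkSharedDown = bulkSharedDown,
    bulkEffectLFC = bulkEffectLFC,
    bulkNoiseSD = bulkNoiseSD,
    seed = seed
  )
}

setMethod("show", "SimConfig", function(object) {
  nBase <- object@nPatients * 2 * object@cellsPerPatientPerPhase
  cat("SimConfig\n")
  cat("  cohort  : ", object@nPatients, " patients x 2 phases x ",
      object@cellsPerPatientPerPhase, " cells (+ rare cluster ",
      signif(100 * object@rareClusterFraction, 3), "% of ", nBase,
      " cells)\n", sep = "")
  cat("  genes   : ", object@nGenes, " (module ", object@moduleSize,
      ", TF panel ", object@nTFs, ")\n", sep = "")
  cat("  signal  : tf coupling ", object@plantedTFCoupling,
      ", divergence coupling ", object@divergenceCoupling,
      ", post shift ", object@postPhaseDivergenceShift, "\n", sep = "")
  cat("  seed    : ", object@seed, "\n", sep = "")
  invisible(NULL)
})

#' Synthetic cohort container
#'
#' @description
#' A `CohortExperiment` is a [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment]
#' holding the simulated counts (assay `"counts"`), per-cell annotations in
#' `colData` (`patient_id`, `phase`, `cluster_label`, QC metrics, the latent
#' `plasticity` factor), per-gene annotations in `rowData`, and the
#' ground-truth manifest in `metadata(x)$truth`. Use the
#' [truth accessors][truth-accessors] rather than reaching into metadata.
#'
#' @export
setClass("CohortExperiment",
         contains = "SingleCellExperiment")

setValidity("CohortExperiment", function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cm <- SummarizedExperiment::assay(object, "counts")
    neg <- if (methods::is(cm, "sparseMatrix")) any(cm@x < 0) else any(cm < 0)
    if (neg) msg <- c(msg, "counts must be nonnegative")
  }
  truth <- S4Vectors::metadata(object)$truth
  if (is.null(truth)) {
    msg <- c(msg, "metadata(x)$truth manifest is missing")
  } else {
    need <- c("planted_tf", "tf_panel", "module_genes",
              "rare_cluster_cells", "plasticity")
    miss <- setdiff(need, names(truth))
    if (length(miss))
      msg <- c(msg, paste0("truth manifest lacks: ",
                           paste(miss, collapse = ", ")))
    else {
      # cell subsetting (e.g. QC) may remove truth cells, but every cell
      # still present must be covered by the manifest
      if (!all(colnames(object) %in% names(truth$plasticity)))
        msg <- c(msg, "cells present that the truth manifest does not cover")
      if (!truth$planted_tf %in% rownames(object))
        msg <- c(msg, "planted TF absent from the matrix")
    }
  }
  need_cols <- c("patient_id", "phase", "cluster_label")
  miss <- setdiff(need_cols, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @rdname truth-accessors
#' @export
setMethod("truthManifest", "CohortExperiment", function(x)
  S4Vectors::metadata(x)$truth)

#' @rdname truth-accessors
#' @export
setMethod("plantedTF", "CohortExperiment", function(x)
  S4Vectors::metadata(x)$truth$planted_tf)

#' @rdname truth-accessors
#' @export
setMethod("tfPanel", "CohortExperiment", function(x)
  S4Vectors::metadata(x)$truth$tf_panel)

#' @rdname truth-accessors
#' @export
setMethod("moduleGenes", "CohortExperiment", function(x)
  S4Vectors::metadata(x)$truth$module_genes)

#' @rdname truth-accessors
#' @export
setMethod("rareClusterCells", "CohortExperiment", function(x)
  S4Vectors::metadata(x)$truth$rare_cluster_cells)

#' @rdname truth-accessors
#' @export
setMethod("plasticityFactors", "CohortExperiment", function(x)
  S4Vectors::metadata(x)$truth$plasticity)

setMethod("show", "CohortExperiment", function(object) {
  methods::callNextMethod()
  truth <- S4Vectors::metadata(object)$truth
  if (!is.null(truth)) {
    cat("planted TF: ", truth$planted_tf,
        " | module genes: ", length(truth$module_genes),
        " | rare cells: ", length(truth$rare_cluster_cells), "\n", sep = "")
  }
  invisible(NULL)
})
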