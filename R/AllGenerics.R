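#' @title Accessors for cohort ground truth
#'
#' @description
#' A [CohortExperiment] produced by [simulateCohort()] carries a ground-truth
#' manifest describing the planted signals: which gene is the
#' divergence-coupled transcription factor, which genes form the stem-like
#' module, which cells belong to the rare cluster, and the latent per-cell
#' plasticity factor. These generics expose the manifest without touching
#' slots directly.
#'
#' @param x a `CohortExperiment`.
#' @return `truthManifest()` returns the full manifest as a named list;
#'   `plantedTF()` a single gene identifier; `tfPanel()` the character vector
#'   of genes designated as transcription factors (planted TF included);
#'   `moduleGenes()` the character vector of module gene identifiers;
#'   `rareClusterCells()` the character vector of rare-cluster cell
#'   identifiers; `plasticityFactors()` a named numeric vector (one value per
#'   cell, in `(0, 1)`).
#' @name truth-accessors
#' @aliases truthManifest plantedTF tfPanel moduleGenes rareClusterCells
#'   plasticityFactors
NULL

#' @rdname truth-accessors
#' @export
setGeneric("truthManifest", function(x) standardGeneric("truthManifest"))

#' @rdname truth-accessors
#' @export
setGeneric("plantedTF", function(x) standardGeneric("plantedTF"))

#' @rdname truth-accessors
#' @export
setGeneric("tfPanel", function(x) standardGeneric("tfPanel"))

#' @rdname truth-accessors
#' @export
setGeneric("moduleGenes", function(x) standardGeneric("moduleGenes"))

#' @rdname truth-accessors
#' @export
setGeneric("rareClusterCells", function(x) standardGeneric("rareClusterCells"))

#' @rdname truth-accessors
#' @export
setGeneric("plasticityFactors", function(x) standardGeneric("plasticityFactors"))
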