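#' Simulate a longitudinal single-cell cohort with planted ground truth
#'
#' @description
#' Generates a gene-by-cell negative-binomial count matrix for a cohort of
#' patients sampled in two treatment phases, with three planted signals:
#'
#' * a latent per-cell plasticity factor `f ~ Beta(a, b)` that scales the
#'   top half of gene means, so expected transcriptional divergence
#'   (P50/P50) increases with `f` and is further elevated in post-treatment
#'   cells;
#' * a planted transcription factor whose mean expression is a strictly
#'   increasing function of `f`;
#' * a rare stem-like cluster (fraction `rareClusterFraction` of base
#'   cells, all treatment-naive) in which the planted module genes are
#'   scaled by `rareClusterModuleFoldchange`.
#'
#' Identical configurations (including `seed`) give bitwise-identical
#' output.
#'
#' @param config a [SimConfig-class] object from [simConfig()].
#'
#' @return a [CohortExperiment-class]: counts in assay `"counts"`,
#'   per-cell annotations (`patient_id`, `phase`, `cluster_label`,
#'   `plasticity`, and QC metrics `rna_counts`, `atac_counts`,
#'   `nucleosome_signal`, `tss_enrichment`, `pct_mito`) in `colData`,
#'   and the ground-truth manifest in `metadata(x)$truth`.
#'
#' @examples
#' coh <- simulateCohort(simConfig(nPatients = 2,
#'                                 cellsPerPatientPerPhase = 20,
#'                                 nGenes = 100, nTFs = 10, seed = 1))
#' coh
#' head(plasticityFactors(coh))
#' @export
simulateCohort <- function(config) {
  stopifnot(methods::is(config, "SimConfig"))
  methods::validObject(config)

  nGenes <- as.integer(config@nGenes)
  nPat <- as.integer(config@nPatients)
  nCellPP <- as.integer(config@cellsPerPatientPerPhase)
  nBase <- nPat * 2L * nCellPP
  nRare <- as.integer(ceiling(config@rareClusterFraction * nBase))
  nCells <- nBase + nRare

  ## stage 1: gene-level structure -------------------------------------
  geneIDs <- sprintf("G%05d", seq_len(nGenes))
  st1 <- .withSeed(.stageSeed(config@seed, 1L), {
    geneMeans <- stats::rlnorm(nGenes, config@meanLogexprMu,
                               config@meanLogexprSigma)
    names(geneMeans) <- geneIDs
    # planted TF: a well-expressed gene (upper quartile of means) so the
    # screen sees it above the dropout floor
    eligible <- geneIDs[geneMeans >= stats::quantile(geneMeans, 0.75)]
    planted <- sample(eligible, 1L)
    panel <- c(planted, sample(setdiff(geneIDs, planted),
                               as.integer(config@nTFs) - 1L))
    module <- sample(setdiff(geneIDs, planted),
                     as.integer(config@moduleSize))
    topHalf <- geneMeans >= stats::median(geneMeans)
    topHalf[planted] <- FALSE  # keep the TF mechanism separate
    list(geneMeans = geneMeans, planted = planted, panel = panel,
         module = module, topHalf = topHalf)
  })

  ## stage 2: cell-level structure ------------------------------------
  patientIDs <- sprintf("P%02d", seq_len(nPat))
  st2 <- .withSeed(.stageSeed(config@seed, 2L), {
    patient <- c(rep(rep(patientIDs, each = nCellPP), times = 2L),
                 sample(patientIDs, nRare, replace = TRUE))
    phase <- c(rep(c("naive", "post"), each = nPat * nCellPP),
               rep("naive", nRare))
    cluster <- c(sample(sprintf("C%d", seq_len(config@nBaseClusters)),
                        nBase, replace = TRUE),
                 rep("rare", nRare))
    f <- stats::rbeta(nCells, config@plasticityShapeA,
                      config@plasticityShapeB)
    list(patient = patient, phase = phase, cluster = cluster, f = f)
  })
  cellIDs <- sprintf("CELL%06d", seq_len(nCells))

  ## stage 3: counts ---------------------------------------------------
  fbar <- config@plasticityShapeA /
    (config@plasticityShapeA + config@plasticityShapeB)
  counts <- .withSeed(.stageSeed(config@seed, 3L), {
    mu <- matrix(st1$geneMeans, nrow = nGenes, ncol = nCells,
                 dimnames = list(geneIDs, cellIDs))
    isPost <- st2$phase == "post"
    fac <- 1 + (config@divergenceCoupling +
                  config@postPhaseDivergenceShift * isPost) * st2$f
    mu[st1$topHalf, ] <- mu[st1$topHalf, ] *
      rep(fac, each = sum(st1$topHalf))
    mu[st1$planted, ] <- st1$geneMeans[st1$planted] *
      exp(3 * config@plantedTFCoupling * (st2$f - fbar))
    isRare <- st2$cluster == "rare"
    if (any(isRare)) {
      mu[st1$module, isRare] <- mu[st1$module, isRare] *
        config@rareClusterModuleFoldchange
    }
    m <- matrix(stats::rnbinom(nGenes * nCells, size = config@nbDispersion,
                               mu = mu),
                nrow = nGenes, dimnames = list(geneIDs, cellIDs))
    methods::as(m, "CsparseMatrix")
  })

  ## stage 4 is reserved for simulateIHC, stage 5 for bulk contrasts ---
  qc <- .withSeed(.stageSeed(config@seed, 6L), {
    data.frame(
      atac_counts = as.integer(round(stats::rlnorm(nCells, 8.5, 0.5))),
      nucleosome_signal = stats::rgamma(nCells, shape = 8, scale = 0.12),
      tss_enrichment = stats::rgamma(nCells, shape = 6, scale = 0.6),
      pct_mito = stats::runif(nCells, 0, 20)
    )
  })

  cd <- S4Vectors::DataFrame(
    cell_id = cellIDs,
    patient_id = st2$patient,
    phase = st2$phase,
    cluster_label = st2$cluster,
    plasticity = st2$f,
    rna_counts = as.integer(Matrix::colSums(counts)),
    qc,
    row.names = cellIDs
  )
  rd <- S4Vectors::DataFrame(
    gene_id = geneIDs,
    base_mean = unname(st1$geneMeans),
    is_top_half = unname(st1$topHalf),
    is_module = geneIDs %in% st1$module,
    is_tf = geneIDs %in% st1$panel,
    row.names = geneIDs
  )
  truth <- list(
    planted_tf = st1$planted,
    tf_panel = st1$panel,
    module_genes = st1$module,
    rare_cluster_cells = cellIDs[st2$cluster == "rare"],
    plasticity = stats::setNames(st2$f, cellIDs),
    generator = "synthetic stand-in (no distributional claims inherited from real data)"
  )

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd, rowData = rd,
    metadata = list(truth = truth, config = config)
  )
  methods::new("CohortExperiment", sce)
}

#' Simulate per-cell immunohistochemistry staining intensities
#'
#' @description
#' Draws mean nuclear DAB intensities per cell from a Gamma distribution
#' (`shape = ihcShape`, `scale = ihcScale`; naive-phase mean
#' `ihcShape * ihcScale`). Post-phase tissues have their mean shifted by
#' exactly `ihcPostShift` (implemented by raising the Gamma shape, keeping
#' the scale). Each patient contributes `ihcTissuesPerPatient` tissues per
#' phase with `ihcCellsPerTissue` cells each.
#'
#' @param config a [SimConfig-class] object.
#' @return a `data.frame` stain table with columns `cell_id`, `tissue_id`,
#'   `patient_id`, `phase`, `compartment` (all `"nuclear"`), `dab_mean`.
#' @examples
#' st <- simulateIHC(simConfig(nPatients = 2, ihcTissuesPerPatient = 2,
#'                             ihcCellsPerTissue = 10, seed = 3))
#' nrow(st)  # 2 * 2 * 2 * 10
#' @export
simulateIHC <- function(config) {
  stopifnot(methods::is(config, "SimConfig"))
  methods::validObject(config)
  meanNaive <- config@ihcShape * config@ihcScale
  shapePost <- (meanNaive + config@ihcPostShift) / config@ihcScale
  if (shapePost <= 0) {
    stop("ihcPostShift = ", config@ihcPostShift,
         " drives the post-phase mean intensity to or below zero")
  }
  nPat <- as.integer(config@nPatients)
  nTis <- as.integer(config@ihcTissuesPerPatient)
  nCell <- as.integer(config@ihcCellsPerTissue)

  grid <- expand.grid(
    patient_id = sprintf("P%02d", seq_len(nPat)),
    phase = c("naive", "post"),
    tissue = seq_len(nTis),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[order(grid$patient_id, grid$phase, grid$tissue), ]
  tab <- data.frame(
    patient_id = rep(grid$patient_id, each = nCell),
    phase = rep(grid$phase, each = nCell),
    tissue_id = rep(sprintf("%s_%s_T%02d", grid$patient_id, grid$phase,
                            grid$tissue), each = nCell),
    stringsAsFactors = FALSE
  )
  n <- nrow(tab)
  tab$cell_id <- sprintf("IHC%06d", seq_len(n))
  tab$compartment <- "nuclear"
  tab$dab_mean <- .withSeed(.stageSeed(config@seed, 4L), {
    shp <- ifelse(tab$phase == "post", shapePost, config@ihcShape)
    stats::rgamma(n, shape = shp, scale = config@ihcScale)
  })
  # Gamma draws are nonnegative by construction; clip defensively anyway
  # so an exotic parameterisation can never emit negative optical density.
  nneg <- sum(tab$dab_mean < 0)
  if (nneg > 0) {
    warning(nneg, " negative intensities clipped to 0")
    tab$dab_mean <- pmax(tab$dab_mean, 0)
  }
  tab[, c("cell_id", "tissue_id", "patient_id", "phase", "compartment",
          "dab_mean")]
}

#' Simulate two bulk differential contrasts with a shared true gene set
#'
#' @description
#' Emulates two independent bulk expression experiments (for example, a
#' resistant-vs-naive cell-line pair and a perturbation-vs-control pair)
#' that share a planted set of truly regulated genes, perturbed in the
#' same direction in both contrasts. Values are log2-scale intensities:
#' per-gene baselines `N(5, 2)` (drawn separately per contrast), replicate
#' noise `N(0, bulkNoiseSD)`, and a `+/- bulkEffectLFC` shift of the
#' treatment group for planted genes.
#'
#' @param config a [SimConfig-class] object.
#' @return a list with elements `contrastA` and `contrastB` (each a list
#'   holding `expr`, a gene-by-replicate matrix, and `group`, a factor with
#'   levels `"ctrl"` and `"treat"`), and `truth` (list with `up` and
#'   `down` gene-id vectors shared by both contrasts).
#' @examples
#' bc <- simulateBulkContrasts(simConfig(nGenes = 200, bulkSharedUp = 10,
#'                                       bulkSharedDown = 10, seed = 2))
#' dim(bc$contrastA$expr)
#' @export
simulateBulkContrasts <- function(config) {
  stopifnot(methods::is(config, "SimConfig"))
  methods::validObject(config)
  nGenes <- as.integer(config@nGenes)
  nRep <- as.integer(config@bulkReplicates)
  geneIDs <- sprintf("G%05d", seq_len(nGenes))

  .withSeed(.stageSeed(config@seed, 5L), {
    up <- sample(geneIDs, config@bulkSharedUp)
    down <- sample(setdiff(geneIDs, up), config@bulkSharedDown)
    dir <- stats::setNames(numeric(nGenes), geneIDs)
    dir[up] <- 1
    dir[down] <- -1
    group <- factor(rep(c("ctrl", "treat"), each = nRep),
                    levels = c("ctrl", "treat"))
    mkContrast <- function(tag) {
      base <- stats::rnorm(nGenes, 5, 2)
      expr <- base +
        outer(dir * config@bulkEffectLFC, as.numeric(group == "treat")) +
        matrix(stats::rnorm(nGenes * 2L * nRep, 0, config@bulkNoiseSD),
               nrow = nGenes)
      dimnames(expr) <- list(geneIDs,
                             sprintf("%s_%s_R%d", tag, as.character(group),
                                     seq_len(2L * nRep)))
      list(expr = expr, group = group)
    }
    list(contrastA = mkContrast("A"), contrastB = mkContrast("B"),
         truth = list(up = up, down = down))
  })
}
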