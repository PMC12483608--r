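# Internal helpers shared across modules.

# Derive a per-stage RNG substream from the single user-facing seed, so that
# adding a simulation stage never perturbs the draws of earlier stages.
# Kept strictly below 2^31 - 1 so set.seed() always accepts it.
.stageSeed <- function(seed, stage) {
  base <- abs(as.double(seed)) %% 2147480000
  as.integer((base * 131 + as.double(stage) * 7919) %% 2147483647)
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

.isCount <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

# Dense column extraction that works for both base and Matrix matrices.
.col <- function(m, j) as.numeric(m[, j])

.assayOrStop <- function(x, name, caller) {
  if (!name %in% SummarizedExperiment::assayNames(x)) {
    stop(caller, ": assay '", name, "' not found; ",
         if (name %in% c("logcounts", "cp10k"))
           "run logNormalizeCP10K() first" else "supply a counts layer",
         call. = FALSE)
  }
  SummarizedExperiment::assay(x, name)
}
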