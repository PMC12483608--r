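test_that("module score is centered under the null and exact under a planted delta", {
  set.seed(31)
  # background genes drawn iid: a random module should score ~0 on average
  logc <- matrix(rnorm(200 * 80, 2, 0.5), 200, 80)
  sce <- make_logcounts_sce(logc, data.frame(patient_id = "P",
                                             phase = "naive"))
  mod <- sample(rownames(sce), 15)
  sc <- moduleScore(sce, mod, seed = 1)
  expect_lt(abs(mean(sc)), 0.05)

  # constructed delta: gene values equal their bin index in every cell,
  # except module genes which gain exactly delta in cell 1
  nBins <- 5
  base <- matrix(rep(rep(1:nBins, each = 8), 10), nrow = 40, ncol = 10)
  rownames(base) <- sprintf("g%d", 1:40)
  modGenes <- c("g1", "g9", "g17")  # one per bin, bins 1..3
  delta <- 0.75
  base[modGenes, 1] <- base[modGenes, 1] + delta
  sce2 <- make_logcounts_sce(base, data.frame(patient_id = "P",
                                              phase = "naive"))
  sc2 <- moduleScore(sce2, modGenes, nBins = nBins, nCtrl = 50, seed = 2)
  expect_equal(unname(sc2[1]), delta, tolerance = 1e-10)
  expect_equal(unname(sc2[2]), 0, tolerance = 1e-10)

  # missing genes reported; all-missing is an error; plain-mean variant
  scm <- moduleScore(sce2, c(modGenes, "NOPE"), nBins = nBins, seed = 3)
  expect_equal(attr(scm, "missing_genes"), "NOPE")
  expect_error(moduleScore(sce2, c("NO1", "NO2")), "no module gene")
  pm <- moduleScore(sce2, modGenes, method = "mean")
  expect_equal(unname(pm[2]), mean(base[modGenes, 2]))
})

test_that("module scoring is deterministic given a seed and ignores cell-wise shifts", {
  coh <- logNormalizeCP10K(simulateCohort(small_config(seed = 7)))
  s1 <- moduleScore(coh, moduleGenes(coh), seed = 9)
  s2 <- moduleScore(coh, moduleGenes(coh), seed = 9)
  expect_identical(s1, s2)
  # adding a constant to every value of one cell shifts its score by 0
  logc <- as.matrix(SummarizedExperiment::assay(coh, "logcounts"))
  logc[, 3] <- logc[, 3] + 5
  sh <- make_logcounts_sce(logc, data.frame(
    patient_id = "P", phase = "naive"))
  s3 <- moduleScore(sh, moduleGenes(coh), seed = 9)
  # the uniform shift moves every gene mean equally, so bins, controls,
  # and the module-minus-control difference are all unchanged
  expect_equal(unname(s3), unname(s1), tolerance = 1e-10)
})

test_that("rare stem-like cluster attains the top module score and enrichment", {
  coh <- logNormalizeCP10K(simulateCohort(simConfig(seed = 14)))
  sc <- moduleScore(coh, moduleGenes(coh), seed = 14)
  cl <- SummarizedExperiment::colData(coh)$cluster_label
  expect_equal(names(which.max(tapply(sc, cl, mean))), "rare")
  ce <- clusterEnrichment(sc, cl)
  expect_equal(ce$cluster[1], "rare")        # smallest max_fdr
  expect_true(ce$enriched[ce$cluster == "rare"])
})

test_that("pairwise cluster enrichment matches enumeration + step-up by hand", {
  feat <- c(3, 4, 5, 6, 1, 2, 2, 1, 0, 1, 1, 0)
  cl <- rep(c("A", "B", "C"), each = 4)
  ce <- clusterEnrichment(feat, cl)
  pairs <- S4Vectors::metadata(ce)$pairs
  pAB <- oracle_ranksum_p(c(3, 4, 5, 6), c(1, 2, 2, 1))
  pAC <- oracle_ranksum_p(c(3, 4, 5, 6), c(0, 1, 1, 0))
  pBC <- oracle_ranksum_p(c(1, 2, 2, 1), c(0, 1, 1, 0))
  expect_equal(pAB, 2 / 70)
  expect_equal(pairs$p, c(pAB, pAC, pBC))
  fdr <- oracle_bh(c(pAB, pAC, pBC))
  expect_equal(pairs$fdr, fdr)
  expect_equal(ce$max_fdr[ce$cluster == "A"], max(fdr[1:2]))
  expect_true(ce$enriched[ce$cluster == "A"])
  expect_false(any(ce$enriched[ce$cluster != "A"]))

  # relabeling clusters permutes but does not change the statistics
  relabeled <- clusterEnrichment(feat, c(A = "z9", B = "k2", C = "m5")[cl])
  expect_equal(sort(relabeled$max_fdr), sort(ce$max_fdr))

  # constant feature: every pairwise p and every max_fdr is 1
  cc <- clusterEnrichment(rep(2, 12), cl)
  expect_true(all(S4Vectors::metadata(cc)$pairs$p == 1))
  expect_true(all(cc$max_fdr == 1))

  expect_warning(clusterEnrichment(feat[1:9], c(rep("A", 4), rep("B", 4),
                                                "single")), "singleton")
  expect_error(clusterEnrichment(feat[1:4], rep("A", 4)), "at least 2")
})

test_that("one-vs-rest DE finds a cluster-exclusive gene and respects thresholds", {
  set.seed(41)
  cnt <- matrix(rpois(30 * 20, 5), 30, 20)
  cnt[7, ] <- c(rep(40, 6), rep(0, 14))  # expressed only in the target
  sce <- make_sce(cnt, meta = data.frame(
    patient_id = "P", phase = "naive",
    cluster_label = c(rep("t", 6), rep("o", 14))))
  de <- deOneVsRest(sce, target = "t", fdrMax = 0.05)
  expect_true("g7" %in% de$gene_id)
  expect_equal(de$direction[de$gene_id == "g7"], "up")

  # threshold no-op returns every tested gene
  all <- deOneVsRest(sce, target = "t", fdrMax = 1.01, lfcMin = -Inf)
  expect_equal(sort(all$gene_id), sort(rownames(sce)))
  # threshold monotonicity: stricter fdr is a subset
  strict <- deOneVsRest(sce, target = "t", fdrMax = 0.001)
  expect_true(all(strict$gene_id %in% de$gene_id))
  expect_error(deOneVsRest(sce, target = "zzz"), "not present")
})

test_that("two-group DE behaves on identical, separated, and planted data", {
  set.seed(43)
  ex <- matrix(rnorm(50 * 8, 5), 50, 8,
               dimnames = list(sprintf("g%d", 1:50), NULL))
  grp <- rep(c("ctrl", "treat"), each = 4)
  same <- cbind(ex[, 1:4], ex[, 1:4])
  expect_equal(nrow(deTwoGroup(same, grp)), 0L)

  ex2 <- ex
  ex2["g5", grp == "treat"] <- ex2["g5", grp == "treat"] + 10
  de <- deTwoGroup(ex2, grp)
  expect_true("g5" %in% de$gene_id)
  expect_equal(de$p[de$gene_id == "g5"], 2 / 70)
  expect_equal(de$direction[de$gene_id == "g5"], "up")
  expect_error(deTwoGroup(ex[, 1:5], c("a", "a", "b", "b", "b")),
               "3 replicates")
})

test_that("signature intersection is a direction-aware set intersection", {
  a <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                  direction = c("up", "up", "up", "down"))
  b <- data.frame(gene_id = c("g2", "g3", "g5", "g4", "g6"),
                  direction = c("up", "up", "up", "down", "down"))
  is1 <- intersectSignatures(a, b)
  expect_equal(is1$n_common_up, 2L)
  expect_equal(is1$n_common_down, 1L)
  expect_setequal(is1$common_up, c("g2", "g3"))

  # opposite directions are excluded
  flip <- data.frame(gene_id = "g2", direction = "down")
  expect_equal(intersectSignatures(a, flip)$n_common_down, 0L)
  # disjoint universes and idempotence
  dis <- data.frame(gene_id = c("x1", "x2"), direction = c("up", "down"))
  expect_equal(intersectSignatures(a, dis)$n_common_up, 0L)
  ii <- intersectSignatures(a, a)
  expect_equal(ii$n_common_up, 3L)
  expect_equal(ii$n_common_down, 1L)
})
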