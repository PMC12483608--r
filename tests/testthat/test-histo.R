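test_that("tertile binning uses nearest-rank pooled cut points", {
  st <- data.frame(dab_mean = 1:9)
  b <- assignStainBins(st)
  expect_equal(unname(attr(b, "cutpoints")), c(3, 6))
  expect_equal(as.integer(table(b$bin)), c(3L, 3L, 3L))
  expect_equal(as.character(b$bin),
               rep(c("low", "medium", "high"), each = 3))

  # all-identical intensities: degenerate, everything medium
  eq <- assignStainBins(data.frame(dab_mean = rep(2.5, 6)))
  expect_true(attr(eq, "degenerate"))
  expect_true(all(eq$bin == "medium"))

  # strictly increasing transform leaves the bins unchanged
  tr <- assignStainBins(data.frame(dab_mean = (1:9)^2 + 10))
  expect_equal(tr$bin, b$bin)

  # compartment filtering
  two <- data.frame(dab_mean = c(1:5, 100:104),
                    compartment = rep(c("nuclear", "cytoplasmic"), each = 5))
  nb <- assignStainBins(two, compartment = "nuclear")
  expect_equal(nrow(nb), 5L)
  expect_error(assignStainBins(data.frame(dab_mean = c(1, 2))), "at least 3")
  expect_error(assignStainBins(data.frame(dab_mean = c(-1, 2, 3))),
               "nonnegative")
})

test_that("binning partitions every table; bin counts always sum to cell count", {
  set.seed(61)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    v <- switch(sample(3, 1),
                round(runif(n, 0, 3), sample(0:2, 1)),
                rgamma(n, 2, 1),
                rep(runif(1), n))
    b <- assignStainBins(data.frame(dab_mean = v,
                                    tissue_id = sample(c("t1", "t2"), n,
                                                       replace = TRUE)))
    expect_false(any(is.na(b$bin)))
    expect_equal(sum(table(b$bin)), n)
    hs <- tissueHScore(b)
    expect_equal(sum(hs$total_n), n)
    expect_true(all(hs$low_n + hs$medium_n + hs$high_n == hs$total_n))
    expect_true(all(hs$h >= 50 - 1e-9 & hs$h <= 150 + 1e-9))
  }
})

test_that("h-score follows the verbatim formula with its compressed bounds", {
  mk <- function(bins) {
    d <- data.frame(tissue_id = "T", dab_mean = seq_along(bins))
    d$bin <- factor(bins, levels = c("low", "medium", "high"))
    d
  }
  expect_equal(tissueHScore(mk(rep(c("low", "medium", "high"), each = 2)))$h,
               100)  # 100 * (6+4+2)/12
  expect_equal(tissueHScore(mk(rep("high", 5)))$h, 150)
  expect_equal(tissueHScore(mk(rep("low", 5)))$h, 50)
  # classical variant spans the familiar 0-300 scale
  expect_equal(tissueHScore(mk(rep("high", 5)), classical = TRUE)$h, 300)
  expect_equal(tissueHScore(mk(rep("low", 5)), classical = TRUE)$h, 100)
  # moving one cell up a bin never lowers the score
  expect_gt(tissueHScore(mk(c("medium", rep("low", 4))))$h,
            tissueHScore(mk(rep("low", 5)))$h)
  expect_error(tissueHScore(data.frame(tissue_id = "T", dab_mean = 1)),
               "assign bins")
})

test_that("phase comparison of h-scores is the exact rank-sum test", {
  sc <- data.frame(h = c(60, 65, 70, 120, 125, 130),
                   phase = rep(c("naive", "post"), each = 3))
  ht <- hscoreGroupTest(sc)
  expect_equal(ht$p_value, 0.1)
  expect_equal(ht$direction, "post > naive")
  same <- data.frame(h = rep(c(80, 90), 2),
                     phase = rep(c("naive", "post"), each = 2))
  expect_equal(hscoreGroupTest(same)$p_value, 1)
  expect_error(hscoreGroupTest(data.frame(h = 1:3, phase = "naive")),
               "2 phases")
})

test_that("simulated staining with a positive shift yields higher post h-scores", {
  hits <- 0
  for (s in 1:5) {
    st <- simulateIHC(simConfig(nPatients = 6, ihcPostShift = 1, seed = s))
    hs <- tissueHScore(assignStainBins(st, compartment = "nuclear"))
    ht <- hscoreGroupTest(hs)
    hits <- hits + (ht$direction == "post > naive" && ht$p_value < 0.05)
  }
  expect_equal(hits, 5)
})

test_that("volume formulas are verbatim and cubic", {
  expect_equal(tumorVolume(2), pi)
  expect_equal(tumorVolume(0), 0)
  expect_equal(tumorVolume(10), 125 * pi)
  d <- c(0.5, 1, 3, 7)
  expect_equal(tumorVolume(2 * d), 8 * tumorVolume(d))
  expect_error(tumorVolume(-1), "nonnegative")
  expect_equal(spheroidVolumeFromArea(pi), pi)
  expect_equal(spheroidVolumeFromArea(0), 0)
  expect_equal(spheroidVolumeFromArea(25 * pi), 125 * pi)
  expect_error(spheroidVolumeFromArea(-2), "nonnegative")
})

test_that("percent-change series anchor at the baseline day", {
  m <- data.frame(animal_id = rep("m1", 3), flank = "NT",
                  day = c(7, 14, 21), volume = c(100, 150, 100))
  pc <- percentChangeSeries(m, baselineDay = 7)
  expect_equal(pc$pct_change, c(0, 50, 0))
  m2 <- data.frame(animal_id = "m2", flank = "S", day = c(7, 14),
                   volume = c(8, 2))
  expect_equal(percentChangeSeries(m2, 7)$pct_change, c(0, -75))
  expect_error(percentChangeSeries(m2, 6), "lacks a measurement")
  mz <- rbind(m, data.frame(animal_id = "m3", flank = "NT",
                            day = c(7, 14), volume = c(0, 5)))
  expect_warning(pcz <- percentChangeSeries(mz, 7), "zero-baseline")
  expect_false("m3" %in% pcz$animal_id)
  # diameters are converted through the volume formula
  md <- data.frame(animal_id = "m4", flank = "NT", day = c(7, 14),
                   diameter = c(2, 4))
  expect_equal(percentChangeSeries(md, 7)$pct_change, c(0, 700))
})
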