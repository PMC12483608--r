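#' Assign low/medium/high staining-intensity bins
#'
#' @description
#' Tertile cut points are computed on the pooled per-cell mean DAB
#' intensities of the requested compartment across ALL tissues
#' (nearest-rank quantiles, inclusive lower boundary): a cell is `low`
#' when its intensity is `<= q(1/3)`, `medium` when `<= q(2/3)`, else
#' `high`. Boundary ties therefore fall into the lower bin. When all
#' intensities are identical the binning is degenerate and every cell is
#' classified `medium`.
#'
#' @param stains a stain table (data.frame with at least `dab_mean` and,
#'   when `compartment` filtering is requested, a `compartment` column) —
#'   e.g. from [simulateIHC()].
#' @param compartment optional compartment to keep (`"nuclear"` /
#'   `"cytoplasmic"`).
#' @return the filtered table with a `bin` factor column
#'   (`low`/`medium`/`high`) added; cut points and the degenerate flag
#'   are in attributes `cutpoints` and `degenerate`.
#' @examples
#' st <- data.frame(dab_mean = 1:9)
#' table(assignStainBins(st)$bin)  # 3 low, 3 medium, 3 high
#' @export
assignStainBins <- function(stains, compartment = NULL) {
  if (!is.null(compartment)) {
    stains <- stains[stains$compartment == compartment, , drop = FALSE]
  }
  v <- stains$dab_mean
  if (length(v) < 3L) {
    stop("need at least 3 cells (of the requested compartment) pooled ",
         "across tissues")
  }
  if (any(v < 0)) stop("dab_mean must be nonnegative")
  degenerate <- length(unique(v)) == 1L
  if (degenerate) {
    stains$bin <- factor(rep("medium", length(v)),
                         levels = c("low", "medium", "high"))
    attr(stains, "cutpoints") <- c(q1 = unique(v), q2 = unique(v))
    attr(stains, "degenerate") <- TRUE
    return(stains)
  }
  q <- stats::quantile(v, c(1, 2) / 3, type = 1, names = FALSE)
  stains$bin <- factor(
    ifelse(v <= q[1], "low", ifelse(v <= q[2], "medium", "high")),
    levels = c("low", "medium", "high")
  )
  attr(stains, "cutpoints") <- c(q1 = q[1], q2 = q[2])
  attr(stains, "degenerate") <- FALSE
  stains
}

#' Per-tissue h-score from binned staining intensities
#'
#' @description
#' For each tissue, the counts of cells in the low/medium/high bins are
#' combined as
#'
#' `h = 100 * (3*high_n + 2*medium_n + 1*low_n) /
#'            (high_n + medium_n + low_n + total_n)`
#'
#' with `total_n` the number of classified cells in the tissue. This is
#' the formula applied verbatim: since every classified cell is binned,
#' `total_n` equals `low_n + medium_n + high_n`, the denominator is twice
#' the cell count and the score lives in `[50, 150]` (not the classical
#' `[0, 300]`). Set `classical = TRUE` for the textbook variant
#' `100 * (3*high_n + 2*medium_n + 1*low_n) / total_n`.
#'
#' @param binned output of [assignStainBins()].
#' @param classical use the textbook denominator (default `FALSE`).
#' @return a data.frame with one row per tissue: `tissue_id`, `phase`
#'   and `patient_id` (when present), `low_n`, `medium_n`, `high_n`,
#'   `total_n`, `h`.
#' @examples
#' st <- data.frame(tissue_id = "T1", dab_mean = 1:6)
#' tissueHScore(assignStainBins(st))$h  # balanced tertiles: 100
#' @export
tissueHScore <- function(binned, classical = FALSE) {
  if (is.null(binned$bin)) stop("assign bins first (assignStainBins)")
  if (is.null(binned$tissue_id)) binned$tissue_id <- "tissue"
  empty <- !nzchar(as.character(binned$tissue_id)) |
    is.na(binned$tissue_id)
  if (any(empty)) {
    warning(sum(empty), " cell(s) without tissue id skipped")
    binned <- binned[!empty, , drop = FALSE]
  }
  split_ <- split(binned, as.character(binned$tissue_id))
  rows <- lapply(split_, function(d) {
    cnt <- table(d$bin)
    lo <- as.integer(cnt["low"])
    me <- as.integer(cnt["medium"])
    hi <- as.integer(cnt["high"])
    total <- nrow(d)
    num <- 100 * (3 * hi + 2 * me + 1 * lo)
    h <- if (classical) num / total else num / (hi + me + lo + total)
    out <- data.frame(tissue_id = d$tissue_id[1], low_n = lo, medium_n = me,
                      high_n = hi, total_n = total, h = h,
                      stringsAsFactors = FALSE)
    for (cc in c("patient_id", "phase")) {
      if (!is.null(d[[cc]])) out[[cc]] <- d[[cc]][1]
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare tissue h-scores between treatment phases
#'
#' Two-sided Wilcoxon rank-sum test of the per-tissue h-scores between
#' the `naive` and `post` phases.
#'
#' @param scores a [tissueHScore()] table with a `phase` column.
#' @return as [compareDivergence()]: groups, n, medians, statistic,
#'   p_value, direction, degenerate.
#' @export
hscoreGroupTest <- function(scores) {
  if (is.null(scores$phase)) stop("scores table lacks a 'phase' column")
  lev <- sort(unique(as.character(scores$phase)))
  if (length(lev) != 2L) stop("need exactly 2 phases, got ", length(lev))
  ha <- scores$h[scores$phase == lev[1]]
  hb <- scores$h[scores$phase == lev[2]]
  if (length(ha) < 2L || length(hb) < 2L) {
    stop("each phase needs at least 2 tissues")
  }
  wt <- wilcoxonRankSum(ha, hb)
  med <- stats::setNames(c(stats::median(ha), stats::median(hb)), lev)
  direction <- if (wt$degenerate || med[1] == med[2]) "none"
    else if (med[1] > med[2]) paste(lev[1], ">", lev[2])
    else paste(lev[2], ">", lev[1])
  list(groups = lev, n = stats::setNames(c(length(ha), length(hb)), lev),
       medians = med, statistic = wt$statistic, p_value = wt$p_value,
       direction = direction, degenerate = wt$degenerate)
}

#' Tumor volume from caliper diameter
#'
#' `V = pi * (d/2)^3`, the caliper convention used here, applied
#' verbatim (note it is not the sphere volume `4/3 * pi * r^3`).
#'
#' @param d caliper diameter(s), nonnegative.
#' @return volume(s) in cubic diameter units.
#' @examples
#' tumorVolume(2)   # pi
#' tumorVolume(10)  # 125 * pi
#' @export
tumorVolume <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("diameter must be nonnegative")
  pi * (d / 2)^3
}

#' Spheroid volume from projected area
#'
#' Recovers an equivalent diameter from the circular projection,
#' `d = 2 * sqrt(A / pi)`, then applies the same volume convention as
#' [tumorVolume()].
#'
#' @param area projected area(s), nonnegative.
#' @return volume(s).
#' @examples
#' spheroidVolumeFromArea(pi)  # d = 2 -> pi
#' @export
spheroidVolumeFromArea <- function(area) {
  if (any(area < 0, na.rm = TRUE)) stop("area must be nonnegative")
  tumorVolume(2 * sqrt(area / pi))
}

#' Percent change in tumor volume relative to a baseline day
#'
#' @description
#' For each animal/flank series, computes
#' `100 * (V_day - V_baseline) / V_baseline` for every measurement day
#' after (or at) the baseline. Series lacking the baseline day are an
#' error; series with a zero baseline volume are flagged and excluded.
#'
#' @param measurements data.frame with columns `animal_id`, `flank`,
#'   `day`, and either `volume` or `diameter` (volumes are derived with
#'   [tumorVolume()] when absent).
#' @param baselineDay the reference day.
#' @return data.frame `animal_id`, `flank`, `day`, `volume`,
#'   `pct_change`; excluded zero-baseline series are listed in the
#'   `excluded` attribute.
#' @export
percentChangeSeries <- function(measurements, baselineDay) {
  m <- as.data.frame(measurements)
  if (is.null(m$volume)) {
    if (is.null(m$diameter)) stop("need a 'volume' or 'diameter' column")
    m$volume <- tumorVolume(m$diameter)
  }
  if (is.null(m$flank)) m$flank <- "NA"
  key <- paste(m$animal_id, m$flank, sep = "|")
  out <- list()
  excluded <- character(0)
  for (kk in unique(key)) {
    d <- m[key == kk, , drop = FALSE]
    base <- d$volume[d$day == baselineDay]
    if (length(base) == 0L) {
      stop("series ", kk, " lacks a measurement at baseline day ",
           baselineDay)
    }
    base <- base[1]
    if (base == 0) {
      excluded <- c(excluded, kk)
      next
    }
    d <- d[d$day >= baselineDay, , drop = FALSE]
    d <- d[order(d$day), , drop = FALSE]
    d$pct_change <- 100 * (d$volume - base) / base
    out[[kk]] <- d[, c("animal_id", "flank", "day", "volume",
                       "pct_change")]
  }
  if (length(excluded)) {
    warning("zero-baseline series excluded: ",
            paste(excluded, collapse = ", "))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}
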