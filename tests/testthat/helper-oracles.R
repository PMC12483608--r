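# Independent brute-force oracles used throughout the suite. These are
# deliberately naive (sort-and-sum, full enumeration, hand step-up) so they
# share no code path with the package implementation.

oracle_divergence <- function(v) {
  v <- v[v > 0]
  G <- length(v)
  if (G < 2) return(NA_real_)
  s <- sort(v, decreasing = TRUE)
  k <- floor(G / 2)
  sum(s[1:k]) / sum(s[(G - k + 1):G])
}

# exact two-sided rank-sum p by enumerating every assignment of the pooled
# values to the first group (valid under ties)
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  N <- length(pooled)
  n <- length(x)
  r <- rank(pooled)
  mu <- n * (N + 1) / 2
  obs <- abs(sum(r[seq_len(n)]) - mu)
  sets <- utils::combn(N, n)
  ws <- apply(sets, 2, function(ix) sum(r[ix]))
  mean(abs(ws - mu) >= obs - 1e-9)
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
oracle_signedrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  mu <- n * (n + 1) / 4
  obs <- abs(sum(r[d > 0]) - mu)
  vs <- vapply(seq_len(2^n) - 1, function(code) {
    bits <- as.logical(bitwAnd(bitwShiftR(code, seq_len(n) - 1), 1))
    sum(r[bits])
  }, numeric(1))
  mean(abs(vs - mu) >= obs - 1e-9)
}

# hand step-up BH: sort, multiply by m/i, running minimum from the top
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# per-cell QC keep/remove decision, written as a direct transcription of
# the filtering rule (strict inequalities, skip criteria with NA metrics)
oracle_qc_keep <- function(rna, atac, nuc, tss, mito, th) {
  fails <- c(
    if (!is.na(rna)) rna > th$maxCounts || rna < th$minCounts else FALSE,
    if (!is.na(atac)) atac > th$maxCounts || atac < th$minCounts else FALSE,
    if (!is.na(nuc)) nuc > th$maxNucleosomeSignal else FALSE,
    if (!is.na(tss)) tss < th$minTSSEnrichment else FALSE,
    if (!is.na(mito)) mito > th$maxPctMito else FALSE
  )
  !any(fails)
}
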