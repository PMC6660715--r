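# Independent reference implementations used as oracles. Each is written
# from the textbook definition, deliberately not sharing code with the
# package internals it checks.

# Benjamini-Hochberg step-up from first principles: adj_(i) for the i-th
# smallest p is min_{j >= i} p_(j) * m / j, capped at 1.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ranked[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Welch two-sample t from the closed form.
welchOracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- var(a); v2 <- var(b)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Pearson r and its two-sided t-based p from the closed form.
pearsonOracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(t), n - 2)
  list(r = r, t = t, p = p)
}

# Two-sided Fisher exact p for the 2x2 table [[a, b], [c, d]] by full
# hypergeometric enumeration: sum the probabilities of all tables with the
# same margins whose probability does not exceed the observed one.
fisherOracle <- function(a, b, c, d) {
  row1 <- a + b; col1 <- a + c; n <- a + b + c + d
  klo <- max(0, row1 + col1 - n)
  khi <- min(row1, col1)
  ks <- klo:khi
  probs <- choose(col1, ks) * choose(n - col1, row1 - ks) / choose(n, row1)
  pObs <- probs[ks == a]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Brute-force bump finder: walk the probes, growing a run while the probe
# qualifies, keeps the sign, stays on the chromosome and within the gap.
runsOracle <- function(delta, chrom, pos, cutoff, maxGap, minProbes) {
  runs <- list()
  cur <- integer(0)
  flush <- function() {
    if (length(cur) >= minProbes)
      runs[[length(runs) + 1]] <<- data.frame(
        chrom = chrom[cur[1]], start = pos[cur[1]],
        end = pos[cur[length(cur)]], n_probes = length(cur),
        mean_delta = mean(delta[cur]), score = sum(abs(delta[cur])))
    cur <<- integer(0)
  }
  for (i in seq_along(delta)) {
    qualifies <- abs(delta[i]) > cutoff
    if (!qualifies) { flush(); next }
    if (length(cur) > 0) {
      prev <- cur[length(cur)]
      sameChrom <- chrom[i] == chrom[prev]
      sameSign <- sign(delta[i]) == sign(delta[prev])
      inGap <- (pos[i] - pos[prev]) <= maxGap
      if (!(sameChrom && sameSign && inGap)) flush()
    }
    cur <- c(cur, i)
  }
  flush()
  if (length(runs) == 0) NULL else do.call(rbind, runs)
}

# Grid-search nonnegative least squares for a two-signature catalogue.
nnlsGridOracle <- function(S, f, by = 0.001) {
  best <- NULL; bestErr <- Inf
  for (w1 in seq(0, 1, by = by)) {
    for (w2 in seq(0, 1 - w1, by = by)) {
      err <- sum((f - S %*% c(w1, w2))^2)
      if (err < bestErr) { bestErr <- err; best <- c(w1, w2) }
    }
  }
  best
}

# Sliding-window pyrimidine-centered trinucleotide census by direct loop.
censusOracle <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  counts <- setNames(integer(32), pyrimidineContexts())
  chars <- strsplit(seq, "")[[1]]
  for (i in seq_len(length(chars) - 2)) {
    tri <- chars[i:(i + 2)]
    if (tri[2] %in% c("A", "G")) tri <- rev(comp[tri])
    key <- paste(tri, collapse = "")
    counts[key] <- counts[key] + 1L
  }
  counts
}
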