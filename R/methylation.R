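## Methylation stage: per-sample and cohort differential methylation, MVP
## classification, bump-hunting DMR detection with a permutation null,
## informative-probe selection, consensus clustering and promoter-gene
## mapping.

#' Per-sample count of differentially methylated probes
#'
#' For one tumor/normal pair, counts the probes whose beta difference
#' `beta_tumor - beta_normal` strictly exceeds `deltaThr` in absolute value.
#' This is the per-sample (figure-axis) notion of a DMP, monotone
#' nonincreasing in `deltaThr`.
#'
#' @param x a [BetaSet-class]
#' @param pairId pair identifier from the sample sheet
#' @param deltaThr absolute beta-difference threshold (default 0.2, strict)
#' @return integer count
#' @export
perSampleDmpCount <- function(x, pairId, deltaThr = 0.2) {
  cols <- pairColumns(x, pairId)
  b <- betaValues(x)
  sum(abs(b[, cols["tumor"]] - b[, cols["normal"]]) > deltaThr)
}

## vectorized row-wise Welch two-sample t on a matrix split by columns.
## Zero variance in both groups: p = 1 when the means agree, 0 otherwise.
.rowWelch <- function(mat, cols1, cols2) {
  x1 <- mat[, cols1, drop = FALSE]
  x2 <- mat[, cols2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    equal <- degenerate & (m1 == m2)
    p[equal] <- 1; tstat[equal] <- 0
    p[degenerate & !equal] <- 0
    tstat[degenerate & !equal] <- sign(m1 - m2)[degenerate & !equal] * Inf
  }
  list(delta = m1 - m2, t = tstat, df = df, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, capped at one and order-preserving with the
#' input. Input values must lie in `[0, 1]`.
#'
#' @param p numeric vector of p-values
#' @return adjusted p-values, same order as input
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Cohort-level differential methylation test
#'
#' Per-probe Welch two-sample t between tumor and normal beta values with
#' Benjamini-Hochberg adjustment across all tested probes. `delta_beta` is
#' the tumor-minus-normal group-mean difference. A probe with zero variance
#' in both groups and equal means gets p = 1 (never NaN).
#'
#' @param x a [BetaSet-class]
#' @param tumorSamples,normalSamples column sets to contrast; default the
#'   tissue split of the sample sheet. At least 2 samples per group.
#' @param alpha BH-adjusted significance cutoff recorded in `significant`
#'   (default 0.05)
#' @return data frame: `probe_id`, `delta_beta`, `t`, `p`, `adj_p`,
#'   `significant`
#' @export
cohortDmpTest <- function(x, tumorSamples = NULL, normalSamples = NULL,
                          alpha = 0.05) {
  if (is.null(tumorSamples)) tumorSamples <- tumorSamples(x)
  if (is.null(normalSamples)) normalSamples <- normalSamples(x)
  if (length(tumorSamples) < 2 || length(normalSamples) < 2)
    stop("need at least 2 samples per group", call. = FALSE)
  b <- betaValues(x)
  w <- .rowWelch(b, tumorSamples, normalSamples)
  adj <- bhAdjust(w$p)
  data.frame(probe_id = rownames(b), delta_beta = w$delta, t = w$t,
             p = w$p, adj_p = adj, significant = adj < alpha,
             row.names = NULL)
}

#' Classify methylation variable positions (MVPs)
#'
#' A probe is a hypermethylated MVP when `delta_beta > deltaThr` with
#' BH-adjusted p below `pThr`, a hypomethylated MVP when
#' `delta_beta < -deltaThr` with adjusted p below `pThr`, and `ns`
#' otherwise.
#'
#' @param records data frame from [cohortDmpTest()] (needs `delta_beta`,
#'   `adj_p`)
#' @param deltaThr absolute delta-beta threshold (default 0.2)
#' @param pThr adjusted-p threshold (default 0.01)
#' @return `records` with a `status` factor (`hyper`/`hypo`/`ns`) appended
#' @export
classifyMvp <- function(records, deltaThr = 0.2, pThr = 0.01) {
  status <- rep("ns", nrow(records))
  sig <- records$adj_p < pThr
  status[sig & records$delta_beta > deltaThr] <- "hyper"
  status[sig & records$delta_beta < -deltaThr] <- "hypo"
  records$status <- factor(status, levels = c("hyper", "hypo", "ns"))
  records
}

## maximal candidate runs: same chrom, |delta| > cutoff, same sign,
## inter-probe gap <= maxGapBp, at least minProbes members. Probes must be
## given sorted by (chrom, pos).
.findRuns <- function(delta, chrom, pos, deltaCutoff, maxGapBp, minProbes) {
  qual <- abs(delta) > deltaCutoff
  sgn <- sign(delta)
  n <- length(delta)
  ## break before i when: not qualifying, chrom change, sign change or gap
  newRun <- c(TRUE, chrom[-1] != chrom[-n] |
                    sgn[-1] != sgn[-n] |
                    (pos[-1] - pos[-n]) > maxGapBp)
  runId <- cumsum(newRun | !qual)       # non-qualifying probes isolate runs
  runId[!qual] <- NA
  keep <- !is.na(runId)
  if (!any(keep)) return(NULL)
  splitIdx <- split(which(keep), runId[keep])
  splitIdx <- splitIdx[lengths(splitIdx) >= minProbes]
  if (length(splitIdx) == 0) return(NULL)
  do.call(rbind, lapply(splitIdx, function(ii) {
    data.frame(chrom = chrom[ii[1]],
               start = pos[ii[1]], end = pos[ii[length(ii)]],
               n_probes = length(ii),
               mean_delta = mean(delta[ii]),
               score = sum(abs(delta[ii])))
  }))
}

#' Detect differentially methylated regions by bump hunting
#'
#' Candidate regions are maximal runs of probes whose tumor-minus-normal
#' group-mean beta difference exceeds `deltaCutoff` in absolute value with
#' a consistent sign, with at most `maxGapBp` between consecutive probes and
#' at least `minProbes` members. Each region is scored by the sum of
#' absolute deltas; the null distribution of the genome-wide maximum score
#' is built by permuting the tumor/normal group labels `nPerm` times, and
#' regions with permutation p at or below `pCutoff` are reported. Region
#' coordinates are the 1-based positions of the first and last member
#' probes (inclusive).
#'
#' @param x a [BetaSet-class] whose manifest has `chrom` and `pos`; probes
#'   must be sorted by (chrom, pos) or an error is raised
#' @param tumorSamples,normalSamples column sets to contrast; default the
#'   tissue split
#' @param deltaCutoff per-probe |delta-beta| cutoff (default 0.2)
#' @param maxGapBp maximum gap between consecutive member probes (default
#'   1000)
#' @param minProbes minimum probes per region (default 3)
#' @param nPerm label permutations for the null (default 200)
#' @param pCutoff permutation-p cutoff for reporting (default 0.05)
#' @param seed RNG seed for the permutations
#' @return data frame: `chrom`, `start`, `end`, `n_probes`, `mean_delta`,
#'   `score`, `p` (empty when no region passes)
#' @export
findDmrs <- function(x, tumorSamples = NULL, normalSamples = NULL,
                     deltaCutoff = 0.2, maxGapBp = 1000, minProbes = 3,
                     nPerm = 200, pCutoff = 0.05, seed = 1) {
  man <- probeManifest(x)
  if (!all(c("chrom", "pos") %in% colnames(man)))
    stop("manifest with chrom and pos is required for DMR detection",
         call. = FALSE)
  ord <- order(man$chrom, man$pos)
  if (!identical(ord, seq_len(nrow(man))))
    stop("probes must be sorted by (chrom, pos)", call. = FALSE)
  if (is.null(tumorSamples)) tumorSamples <- tumorSamples(x)
  if (is.null(normalSamples)) normalSamples <- normalSamples(x)
  b <- betaValues(x)
  delta <- rowMeans(b[, tumorSamples, drop = FALSE]) -
           rowMeans(b[, normalSamples, drop = FALSE])
  cand <- .findRuns(delta, man$chrom, man$pos, deltaCutoff, maxGapBp,
                    minProbes)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_probes = integer(),
                      mean_delta = numeric(), score = numeric(),
                      p = numeric())
  if (is.null(cand)) return(empty)
  ## permutation null: max genome-wide region score under label shuffling
  allCols <- c(tumorSamples, normalSamples)
  nT <- length(tumorSamples)
  set.seed(seed)
  maxScores <- vapply(seq_len(nPerm), function(i) {
    perm <- sample(allCols)
    d <- rowMeans(b[, perm[seq_len(nT)], drop = FALSE]) -
         rowMeans(b[, perm[-seq_len(nT)], drop = FALSE])
    r <- .findRuns(d, man$chrom, man$pos, deltaCutoff, maxGapBp, minProbes)
    if (is.null(r)) 0 else max(r$score)
  }, numeric(1))
  cand$p <- vapply(cand$score,
                   function(s) (1 + sum(maxScores >= s)) / (nPerm + 1),
                   numeric(1))
  rownames(cand) <- NULL
  cand[cand$p <= pCutoff, , drop = FALSE]
}

#' Select informative probes separating high and low TMB groups
#'
#' Works on per-pair delta-beta values (tumor minus normal within each
#' pair). A probe is informative when all four conditions hold: pooled
#' standard deviation of delta-beta across both groups above `sdBetween`;
#' within-group standard deviation below `sdWithin` in the high or the low
#' group; absolute difference of group-mean delta-beta above `deltaThr`;
#' and BH-adjusted Welch-t p-value (contrasting the groups' delta-beta)
#' below `pThr`.
#'
#' @param x a [BetaSet-class]
#' @param highPairs,lowPairs pair ids of the two TMB groups (>= 2 each)
#' @param sdBetween pooled s.d. lower bound (default 0.2)
#' @param sdWithin within-group s.d. upper bound (default 0.1)
#' @param deltaThr group-mean |delta-beta| difference bound (default 0.2)
#' @param pThr BH-adjusted p cutoff (default 0.05)
#' @return character vector of probe ids
#' @export
selectInformativeProbes <- function(x, highPairs, lowPairs,
                                    sdBetween = 0.2, sdWithin = 0.1,
                                    deltaThr = 0.2, pThr = 0.05) {
  if (length(highPairs) < 2 || length(lowPairs) < 2)
    stop("need at least 2 pairs per group", call. = FALSE)
  D <- pairDeltaBeta(x, c(highPairs, lowPairs))
  hi <- D[, highPairs, drop = FALSE]
  lo <- D[, lowPairs, drop = FALSE]
  sdAll <- apply(D, 1, sd)
  sdHi <- apply(hi, 1, sd)
  sdLo <- apply(lo, 1, sd)
  meanDiff <- abs(rowMeans(hi) - rowMeans(lo))
  w <- .rowWelch(D, highPairs, lowPairs)
  adj <- bhAdjust(w$p)
  keep <- sdAll > sdBetween & (sdHi < sdWithin | sdLo < sdWithin) &
          meanDiff > deltaThr & adj < pThr
  rownames(D)[keep]
}

#' Per-pair delta-beta matrix
#'
#' Tumor-minus-normal beta differences, one column per requested pair.
#'
#' @param x a [BetaSet-class]
#' @param pairIds pairs to include (default all)
#' @return numeric matrix probes x pairs
#' @export
pairDeltaBeta <- function(x, pairIds = NULL) {
  sh <- sampleSheet(x)
  if (is.null(pairIds)) pairIds <- unique(sh$pair_id)
  b <- betaValues(x)
  out <- vapply(pairIds, function(pid) {
    cols <- pairColumns(x, pid)
    b[, cols["tumor"]] - b[, cols["normal"]]
  }, numeric(nrow(b)))
  colnames(out) <- pairIds
  out
}

#' Consensus clustering by subsampled k-means
#'
#' Repeatedly runs k-means on a random subsample of the samples (rows) and
#' aggregates co-clustering: `consensus[i, j]` is the number of times i and
#' j landed in the same cluster divided by the number of times both were
#' sampled. The final assignment cuts an average-linkage tree of
#' `1 - consensus` into `k` groups. Deterministic given `seed`.
#'
#' @param mat samples x features numeric matrix (e.g. selected probes,
#'   transposed from a beta matrix); needs at least `2 * k` samples
#' @param k number of clusters (default 2)
#' @param nResample subsampling iterations (default 100)
#' @param subsampleFrac fraction of samples per iteration (default 0.8)
#' @param seed RNG seed
#' @return list with `consensus` (samples x samples, symmetric, unit
#'   diagonal), `assignments` (named integer cluster labels) and `k`
#' @export
consensusCluster <- function(mat, k = 2, nResample = 100,
                             subsampleFrac = 0.8, seed = 1) {
  n <- nrow(mat)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  if (n < 2 * k)
    stop("need at least 2*k samples for consensus clustering", call. = FALSE)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("S", seq_len(n))
  set.seed(seed)
  together <- matrix(0, n, n)
  sampled <- matrix(0, n, n)
  m <- max(k, round(subsampleFrac * n))
  for (rep in seq_len(nResample)) {
    idx <- sort(sample.int(n, m))
    sub <- mat[idx, , drop = FALSE]
    cl <- tryCatch(
      kmeans(sub, centers = k, nstart = 1)$cluster,
      error = function(e)    # duplicate rows can starve k-means of centers
        cutree(hclust(dist(sub), method = "average"), k = k))
    same <- outer(cl, cl, "==") * 1
    together[idx, idx] <- together[idx, idx] + same
    sampled[idx, idx] <- sampled[idx, idx] + 1
  }
  consensus <- ifelse(sampled > 0, together / pmax(sampled, 1), 0)
  diag(consensus) <- 1
  dimnames(consensus) <- list(rownames(mat), rownames(mat))
  assignments <- cutree(hclust(as.dist(1 - consensus), method = "average"),
                        k = k)
  list(consensus = consensus, assignments = assignments, k = k)
}

#' Map MVPs to genes with aberrant promoters
#'
#' Genes whose promoter-region probes (features TSS1500, TSS200, 5UTR,
#' 1stExon) carry more than `minMvp - 1` MVPs, i.e. at least `minMvp`.
#'
#' @param mvps data frame from [classifyMvp()] (uses rows with
#'   `status != "ns"`)
#' @param manifest probe manifest data frame (`probe_id`, `gene`, `feature`)
#' @param minMvp minimum promoter MVPs per gene (default 4, the "more than
#'   3" rule)
#' @return data frame `gene`, `n_promoter_mvps`, sorted by gene
#' @export
mapPromoterGenes <- function(mvps, manifest, minMvp = 4) {
  mvpIds <- mvps$probe_id[mvps$status != "ns"]
  sub <- manifest[manifest$probe_id %in% mvpIds &
                  manifest$feature %in% .PROMOTER_FEATURES &
                  !is.na(manifest$gene) & manifest$gene != "", , drop = FALSE]
  if (nrow(sub) == 0)
    return(data.frame(gene = character(), n_promoter_mvps = integer()))
  counts <- table(sub$gene)
  counts <- counts[counts >= minMvp]
  data.frame(gene = names(counts), n_promoter_mvps = as.integer(counts),
             row.names = NULL)[order(names(counts)), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Distance-to-TSS summary for hyper- vs hypomethylated MVPs
#'
#' Signed probe-to-TSS offsets (`pos - tss`) split by MVP status, compared
#' between the hyper- and hypomethylated groups by a two-sided Wilcoxon
#' rank-sum test.
#'
#' @param mvps data frame from [classifyMvp()]
#' @param manifest probe manifest with a `tss` coordinate column
#' @return list with `offsets` (data frame `probe_id`, `status`, `offset`)
#'   and `test` (list `statistic`, `p`)
#' @export
tssOffsetSummary <- function(mvps, manifest) {
  if (!"tss" %in% colnames(manifest))
    stop("manifest has no tss column", call. = FALSE)
  sub <- mvps[mvps$status %in% c("hyper", "hypo"), , drop = FALSE]
  idx <- match(sub$probe_id, manifest$probe_id)
  offsets <- data.frame(probe_id = sub$probe_id,
                        status = droplevels(sub$status),
                        offset = manifest$pos[idx] - manifest$tss[idx])
  hyper <- offsets$offset[offsets$status == "hyper"]
  hypo <- offsets$offset[offsets$status == "hypo"]
  test <- if (length(hyper) > 0 && length(hypo) > 0) {
    wt <- suppressWarnings(wilcox.test(hyper, hypo, alternative = "two.sided"))
    list(statistic = unname(wt$statistic), p = wt$p.value)
  } else list(statistic = NA_real_, p = NA_real_)
  list(offsets = offsets, test = test)
}
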