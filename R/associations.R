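## Association stage: the cross-cutting statistics — Pearson correlation,
## Welch two-sample t, pairwise Fisher exact mutation co-occurrence, and
## gene-set intersection.

#' Pearson correlation with two-sided t-based p-value
#'
#' Product-moment correlation between two equal-length vectors (n >= 3,
#' nonzero variance in each).
#'
#' @param x,y numeric vectors
#' @return list: `estimate` (r), `p`, `n`, `statistic` (t), `method`
#' @export
pearsonTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in input", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(estimate = unname(ct$estimate), p = ct$p.value, n = length(x),
       statistic = unname(ct$statistic), method = "pearson")
}

#' Welch unpaired two-sample t-test
#'
#' Two-sided unequal-variance t-test between two groups of at least 2
#' observations each. Swapping the groups flips the sign of the statistic
#' and leaves the p-value unchanged.
#'
#' @param a,b numeric vectors
#' @return list: `estimate` (t statistic), `p`, `df`, `n`, `means`
#' @export
unpairedT <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  tt <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(estimate = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), n = length(a) + length(b),
       means = unname(tt$estimate))
}

#' Pairwise Fisher exact tests for mutation co-occurrence
#'
#' Genes mutated in at least `minMutated` samples are retained and every
#' unordered gene pair is tested by a two-sided Fisher exact test on the
#' 2x2 presence/absence table across samples (two-sided by summation of
#' tables with probability at or below the observed one, the standard
#' convention). The direction is co-occurrence when the sample odds ratio
#' exceeds one and mutual exclusivity otherwise; p-values are BH-adjusted
#' across all tested pairs.
#'
#' @param mat binary genes x samples matrix (1 = mutated)
#' @param minMutated minimum mutated samples per retained gene (default 3)
#' @return data frame: `gene_a`, `gene_b`, `n11`, `n10`, `n01`, `n00`,
#'   `odds_ratio` (sample OR, `(n11*n00)/(n10*n01)`), `direction`, `p`,
#'   `adj_p`
#' @export
somaticInteractions <- function(mat, minMutated = 3) {
  stopifnot(all(mat %in% c(0, 1)))
  keep <- rowSums(mat) >= minMutated
  mat <- mat[keep, , drop = FALSE]
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      n11 = integer(), n10 = integer(), n01 = integer(),
                      n00 = integer(), odds_ratio = numeric(),
                      direction = character(), p = numeric(),
                      adj_p = numeric())
  if (nrow(mat) < 2) return(empty)
  genes <- rownames(mat) %||% paste0("gene", seq_len(nrow(mat)))
  pairs <- combn(seq_len(nrow(mat)), 2)
  n <- ncol(mat)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    a <- sum(mat[i, ] == 1 & mat[j, ] == 1)
    b <- sum(mat[i, ] == 1 & mat[j, ] == 0)
    c_ <- sum(mat[i, ] == 0 & mat[j, ] == 1)
    d <- n - a - b - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                      alternative = "two.sided")
    or <- (a * d) / (b * c_)            # sample OR; Inf/NaN handled below
    dir <- if (is.nan(or)) "co-occurrence"
           else if (or > 1) "co-occurrence" else "exclusivity"
    data.frame(gene_a = genes[i], gene_b = genes[j],
               n11 = a, n10 = b, n01 = c_, n00 = d,
               odds_ratio = or, direction = dir, p = ft$p.value)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bhAdjust(out$p)
  out
}

#' Gene-set intersection
#'
#' Exact set intersection with the sizes of both inputs and of the overlap.
#'
#' @param a,b character vectors of gene symbols
#' @return list: `intersection` (sorted), `n_a`, `n_b`, `n_common`
#' @export
geneSetIntersection <- function(a, b) {
  common <- sort(intersect(unique(a), unique(b)))
  list(intersection = common, n_a = length(unique(a)),
       n_b = length(unique(b)), n_common = length(common))
}
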