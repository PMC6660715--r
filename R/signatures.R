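## Signature stage: 96-context mutation spectra, trinucleotide censuses,
## context normalization, and nonnegative-least-squares exposure refitting.

#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   reverseComplement subseq trinucleotideFrequency
NULL

.revcompChar <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

#' Build the 96-context mutation spectrum of one sample
#'
#' Counts single-nucleotide substitutions by pyrimidine-normalized
#' trinucleotide context: purine-reference SNVs are reverse-complemented
#' (reference, alternate and flanks) into the six pyrimidine substitution
#' classes, so the spectrum is invariant to the strand a call was reported
#' on. Indels are skipped (the 96 classes are SNV-only) with a message
#' stating the count. The reference base at each position must match the
#' FASTA, otherwise an error lists the offending position.
#'
#' @param x a [MutationTable-class] (typically the calls of one sample,
#'   synonymous included)
#' @param ref a `DNAStringSet` (e.g. from `Biostrings::readDNAStringSet`)
#'   whose names match the `chrom` values of `x`
#' @return named numeric vector of 96 context counts in the canonical order
#'   of [mutationContexts()]; the counts sum to the number of usable SNVs.
#' @export
buildSpectrum <- function(x, ref) {
  df <- mutData(x)
  spec <- setNames(numeric(96), mutationContexts())
  if (nrow(df) == 0) return(spec)
  isSnv <- df$ref %in% .BASES & df$alt %in% .BASES
  nSkipped <- sum(!isSnv)
  if (nSkipped > 0)
    message("skipping ", nSkipped, " non-SNV record(s) in spectrum")
  df <- df[isSnv, , drop = FALSE]
  if (nrow(df) == 0) return(spec)
  missingChrom <- setdiff(unique(df$chrom), names(ref))
  if (length(missingChrom) > 0)
    stop("chromosome(s) absent from reference: ",
         paste(missingChrom, collapse = ", "), call. = FALSE)
  seqs <- setNames(as.character(ref), names(ref))
  lens <- nchar(seqs)
  offEdge <- df$pos < 2 | df$pos > lens[df$chrom] - 1
  if (any(offEdge))
    stop("position without full trinucleotide context: ",
         df$chrom[offEdge][1], ":", df$pos[offEdge][1], call. = FALSE)
  tri <- substring(seqs[df$chrom], df$pos - 1, df$pos + 1)
  refBase <- substr(tri, 2, 2)
  bad <- refBase != df$ref
  if (any(bad))
    stop("reference mismatch at ", df$chrom[bad][1], ":", df$pos[bad][1],
         " (table says ", df$ref[bad][1], ", FASTA has ",
         refBase[bad][1], ")", call. = FALSE)
  alt <- df$alt
  pur <- refBase %in% c("A", "G")          # purine: fold to pyrimidine
  if (any(pur)) {
    rc3 <- function(t) chartr("ACGT", "TGCA",
                              paste0(substr(t, 3, 3), substr(t, 2, 2),
                                     substr(t, 1, 1)))
    tri[pur] <- rc3(tri[pur])
    refBase[pur] <- substr(tri[pur], 2, 2)
    alt[pur] <- chartr("ACGT", "TGCA", alt[pur])
  }
  ctx <- paste0(substr(tri, 1, 1), "[", refBase, ">", alt, "]",
                substr(tri, 3, 3))
  counts <- table(factor(ctx, levels = mutationContexts()))
  spec + as.vector(counts)
}

#' Census of pyrimidine-centered trinucleotides in a region
#'
#' Sliding-window counts of all 32 pyrimidine-centered trinucleotides in a
#' sequence region, with purine-centered windows collapsed onto their
#' reverse complement (so a poly-A sequence of length L contributes L-2
#' counts to `TTT`).
#'
#' @param region a `DNAStringSet`, `DNAString` or character vector of
#'   sequences; total length of each sequence must be at least 3
#' @return named integer vector of 32 counts in the order of
#'   [pyrimidineContexts()].
#' @export
censusContexts <- function(region) {
  if (is.character(region)) region <- DNAStringSet(region)
  if (is(region, "DNAString")) region <- DNAStringSet(region)
  freq <- colSums(trinucleotideFrequency(region, step = 1))
  ctx <- pyrimidineContexts()
  out <- setNames(integer(32), ctx)
  rc <- .revcompChar(ctx)
  for (i in seq_along(ctx))
    out[i] <- freq[[ctx[i]]] + freq[[rc[i]]]
  out
}

#' Normalize a spectrum by trinucleotide context content
#'
#' Rescales each of the 96 entries by the ratio of target to observed
#' context frequency for its underlying trinucleotide (e.g. exome capture
#' region to whole genome), then renormalizes the result to sum to one.
#' With `observed == target` the output equals the frequency view of the
#' input.
#'
#' @param spec 96-vector of context counts or frequencies
#' @param observed [censusContexts()] of the region the mutations were
#'   called in
#' @param target [censusContexts()] of the region to normalize to
#' @return named numeric 96-vector summing to one.
#' @export
normalizeSpectrum <- function(spec, observed, target) {
  stopifnot(length(spec) == 96, length(observed) == 32, length(target) == 32)
  tri <- .contextTrinucs()
  if (sum(observed) == 0 || sum(target) == 0)
    stop("census has zero total count", call. = FALSE)
  obsFreq <- observed / sum(observed)
  tgtFreq <- target / sum(target)
  occupied <- unique(tri[spec > 0])
  zero <- occupied[obsFreq[occupied] == 0]
  if (length(zero) > 0)
    stop("observed census is zero for occupied context(s): ",
         paste(zero, collapse = ", "), call. = FALSE)
  scaled <- spec * ifelse(obsFreq[tri] > 0, tgtFreq[tri] / obsFreq[tri], 0)
  total <- sum(scaled)
  if (total == 0) return(setNames(scaled, mutationContexts()))
  setNames(scaled / total, mutationContexts())
}

#' Refit signature exposures by nonnegative least squares
#'
#' Solves `min || f - S w ||_2` subject to `w >= 0`, where `f` is the
#' frequency view of the spectrum and `S` the catalogue. Weights below
#' `pruneBelow` are zeroed and the survivors rescaled so their sum equals
#' the pre-pruning explained fraction (capped at one), matching the
#' established refitting convention; the residual is the unexplained
#' fraction `1 - sum(w)`. Plain unconstrained regression can produce
#' negative weights, which contradicts their interpretation as per-sample
#' signature contributions.
#'
#' @param spec 96-vector of context counts or frequencies (total > 0)
#' @param catalog a [SignatureCatalog-class]
#' @param pruneBelow weights below this are set to zero (default 0.06)
#' @return list with `weights` (named, length K), `residual`, and
#'   `explained` (pre-pruning sum of weights, capped at 1).
#' @export
fitExposures <- function(spec, catalog, pruneBelow = 0.06) {
  stopifnot(is(catalog, "SignatureCatalog"), length(spec) == 96)
  total <- sum(spec)
  if (total <= 0) stop("no mutations to fit", call. = FALSE)
  f <- as.vector(spec) / total
  S <- signatureMatrix(catalog)
  w <- pracma::lsqnonneg(S, f)$x
  explained <- min(sum(w), 1)
  w[w < pruneBelow] <- 0
  if (sum(w) > 0) w <- w * explained / sum(w)
  list(weights = setNames(w, colnames(S)),
       residual = 1 - sum(w),
       explained = explained)
}

#' Hierarchically cluster samples by signature exposures
#'
#' Average-linkage hierarchical clustering on Euclidean distances between
#' per-sample exposure vectors; the leaf order is deterministic given the
#' input row order.
#'
#' @param weights samples x K matrix of exposure weights
#' @return an object of class `hclust`
#' @export
clusterExposures <- function(weights) {
  if (nrow(weights) < 2)
    stop("need at least 2 samples to cluster", call. = FALSE)
  hclust(dist(weights, method = "euclidean"), method = "average")
}
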