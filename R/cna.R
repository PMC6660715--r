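## CNA stage: per-probe log2 intensity ratios (each tumor versus the
## average normal), arm-level -1/0/+1/NA calls, and aneuploidy scores.

#' Per-probe log2 intensity ratios, tumor versus average normal
#'
#' For each tumor sample, `log2(tumor / reference)` per probe, where the
#' reference is the mean of the normal columns, followed by per-sample
#' median centering to remove the global intensity scale. After centering a
#' uniform whole-genome gain is not callable (a documented limitation of
#' relative-ratio methods): a tumor at exactly twice the reference on every
#' probe yields all-zero centered ratios.
#'
#' @param intensities probes x samples matrix of strictly positive raw
#'   intensities
#' @param tumorSamples tumor column names
#' @param normalSamples normal column names (at least 2)
#' @param center median-center per sample (default TRUE)
#' @return probes x tumor-samples matrix of (centered) log2 ratios
#' @export
probeLogRatios <- function(intensities, tumorSamples, normalSamples,
                           center = TRUE) {
  if (length(normalSamples) < 2)
    stop("normal reference requires at least 2 samples", call. = FALSE)
  sub <- intensities[, c(tumorSamples, normalSamples), drop = FALSE]
  nonpos <- which(sub <= 0, arr.ind = TRUE)
  if (nrow(nonpos) > 0)
    stop("nonpositive intensity at probe ",
         rownames(sub)[nonpos[1, 1]] %||% nonpos[1, 1],
         ", sample ", colnames(sub)[nonpos[1, 2]], call. = FALSE)
  ref <- rowMeans(intensities[, normalSamples, drop = FALSE])
  lr <- log2(intensities[, tumorSamples, drop = FALSE] / ref)
  if (center) lr <- sweep(lr, 2, apply(lr, 2, median), "-")
  lr
}

#' Arm-level copy-number calls
#'
#' Mean centered log2 ratio per chromosome arm; an arm is called gained
#' (+1) when its mean exceeds `gainThr`, lost (-1) below `lossThr`, neutral
#' (0) in between, and `NA` when fewer than `minProbesPerArm` probes map to
#' it.
#'
#' @param ratios probes x samples log2-ratio matrix (see
#'   [probeLogRatios()])
#' @param manifest probe manifest mapping probes to arms (`probe_id`,
#'   `arm`); matched to `rownames(ratios)`
#' @param gainThr gain threshold on the arm mean (default +0.15)
#' @param lossThr loss threshold (default -0.15)
#' @param minProbesPerArm minimum probes for a callable arm (default 10)
#' @return an [ArmCallSet-class] (samples x arms)
#' @export
armCalls <- function(ratios, manifest, gainThr = 0.15, lossThr = -0.15,
                     minProbesPerArm = 10) {
  stopifnot(gainThr >= lossThr)
  arm <- manifest$arm[match(rownames(ratios), manifest$probe_id)]
  if (anyNA(arm))
    stop("probe(s) missing from manifest: ",
         rownames(ratios)[is.na(arm)][1], call. = FALSE)
  arms <- unique(arm)
  nProbes <- table(arm)[arms]
  armMeans <- vapply(arms, function(a)
    colMeans(ratios[arm == a, , drop = FALSE]),
    numeric(ncol(ratios)))
  if (ncol(ratios) == 1)
    armMeans <- matrix(armMeans, nrow = 1,
                       dimnames = list(colnames(ratios), arms))
  calls <- ifelse(armMeans > gainThr, 1L,
                  ifelse(armMeans < lossThr, -1L, 0L))
  calls[, nProbes < minProbesPerArm] <- NA_integer_
  dimnames(calls) <- list(colnames(ratios), arms)
  ArmCallSet(calls)
}

#' @rdname aneuploidyScore
#' @export
setGeneric("aneuploidyScore", function(x) standardGeneric("aneuploidyScore"))

#' Aneuploidy score
#'
#' Number of arms called gained or lost per sample (`NA` arms contribute
#' zero). Depends only on `|call|`, so relabeling gains as losses leaves it
#' unchanged; widening the neutral band can only decrease it.
#'
#' @param x an [ArmCallSet-class]
#' @return named integer vector, one score per sample
#' @export
setMethod("aneuploidyScore", "ArmCallSet", function(x) {
  calls <- armCallMatrix(x)
  out <- rowSums(abs(calls) == 1, na.rm = TRUE)
  setNames(as.integer(out), rownames(calls))
})
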