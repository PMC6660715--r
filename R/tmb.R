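## TMB stage: confidence filtering of somatic calls, nonsynonymous mutation
## counts (NOMs), per-megabase TMB, and tertile stratification.

#' Filter somatic calls by depth, allele fraction and supporting reads
#'
#' Retains exactly the calls with `depth >= minDepth`, `af >= minAf` and
#' `alt_reads >= minAltReads` (all bounds inclusive). The operation is
#' idempotent, its output is a subset of its input in the original row
#' order, and raising any threshold can only remove rows.
#'
#' @param x a [MutationTable-class]
#' @param minDepth minimum read depth (default 10)
#' @param minAf minimum allele fraction (default 0.05)
#' @param minAltReads minimum reads supporting the variant (default 3)
#' @return the filtered [MutationTable-class]
#' @export
filterSomatic <- function(x, minDepth = 10, minAf = 0.05, minAltReads = 3) {
  stopifnot(is(x, "MutationTable"),
            minDepth >= 0, minAf >= 0, minAltReads >= 0)
  df <- mutData(x)
  keep <- df$depth >= minDepth & df$af >= minAf & df$alt_reads >= minAltReads
  MutationTable(df[keep, , drop = FALSE])
}

#' Count nonsynonymous mutations (NOM) for one sample
#'
#' Counts the filtered calls for `sampleId` whose `variant_class` is
#' `nonsynonymous`; SNVs and short indels both count. The table is expected
#' to be filtered already (see [filterSomatic()]).
#'
#' @param x a filtered [MutationTable-class]
#' @param sampleId sample to count; must be present in the table
#' @return integer NOM count
#' @export
computeNom <- function(x, sampleId) {
  df <- mutData(x)
  if (!sampleId %in% df$sample_id)
    stop("unknown sample: ", sampleId, call. = FALSE)
  sum(df$sample_id == sampleId & df$variant_class == "nonsynonymous")
}

## per-sample NOMs against a fixed roster (samples without calls count 0)
.nomBySample <- function(x, samples) {
  df <- mutData(x)
  df <- df[df$variant_class == "nonsynonymous", , drop = FALSE]
  counts <- table(factor(df$sample_id, levels = samples))
  setNames(as.integer(counts), samples)
}

#' Mutations per megabase
#'
#' `nom / regionMb`, the second TMB definition (mutation count normalized to
#' the size of the annotated coding region, 33.4 Mb for UCSC Refseq). The
#' unrounded value is returned; printed values are conventionally rounded to
#' one decimal half-away-from-zero (see [roundHalfUp()]).
#'
#' @param nom nonsynonymous mutation count(s)
#' @param regionMb size of the annotated region in megabases (> 0)
#' @return numeric TMB per Mb (unrounded)
#' @export
#' @examples
#' roundHalfUp(tmbPerMb(139, 33.4), 1)  # 4.2
tmbPerMb <- function(nom, regionMb) {
  if (any(regionMb <= 0)) stop("regionMb must be > 0", call. = FALSE)
  stopifnot(all(nom >= 0))
  nom / regionMb
}

#' Round half away from zero
#'
#' Decimal rounding where ties go away from zero (so 2.45 -> 2.5), the
#' convention used for printed TMB values; `base::round()` rounds ties to
#' even.
#'
#' @param x numeric vector
#' @param digits decimal digits (default 1)
#' @export
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Stratify samples into TMB tertiles
#'
#' Samples are sorted by decreasing NOM (ties broken by `sample_id` order)
#' and split into `nGroups` contiguous groups. With `n = q * nGroups + r`,
#' the `r` extra samples are absorbed by the outer groups, high first and
#' then low, so a cohort of 89 splits 30/29/30 into high/medium/low.
#'
#' @param nom named numeric vector of NOM counts (names are sample ids)
#' @param nGroups number of groups (default 3: high/medium/low)
#' @return data frame with `sample_id`, `nom` and `tertile` (a factor with
#'   levels `high`, `medium`, `low` when `nGroups` is 3), in the input order.
#' @export
stratifyTertiles <- function(nom, nGroups = 3) {
  n <- length(nom)
  if (n < nGroups)
    stop("need at least ", nGroups, " samples to form ", nGroups,
         " groups", call. = FALSE)
  if (is.null(names(nom))) names(nom) <- paste0("S", seq_len(n))
  ord <- order(-nom, names(nom))
  q <- n %/% nGroups
  r <- n %% nGroups
  sizes <- rep(q, nGroups)
  if (r > 0) {
    # outer groups absorb extras: first (high), then last (low), then inward
    extraOrder <- c(1, nGroups)
    if (nGroups > 2)
      extraOrder <- c(extraOrder,
                      setdiff(order(pmin(seq_len(nGroups) - 1,
                                         nGroups - seq_len(nGroups))),
                              extraOrder))
    sizes[extraOrder[seq_len(r)]] <- q + 1
  }
  labels <- if (nGroups == 3) c("high", "medium", "low")
            else paste0("g", seq_len(nGroups))
  lab <- rep(labels, times = sizes)
  out <- data.frame(sample_id = names(nom)[ord],
                    nom = as.vector(nom[ord]),
                    tertile = factor(lab, levels = labels))
  out[match(names(nom), out$sample_id), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Full TMB stage for a cohort
#'
#' Filters calls, counts NOMs per sample against the roster in `samples`
#' (tumor sample ids; samples with no surviving calls count zero), computes
#' per-Mb TMB and assigns tertiles.
#'
#' @param x a [MutationTable-class] of raw calls
#' @param samples character vector of tumor sample ids defining the cohort
#' @param regionMb region size in megabases (e.g. 33.4)
#' @param minDepth,minAf,minAltReads filter thresholds, see [filterSomatic()]
#' @return data frame `sample_id`, `nom`, `tmb_per_mb`, `tmb_printed`,
#'   `tertile`
#' @export
tmbStage <- function(x, samples, regionMb,
                     minDepth = 10, minAf = 0.05, minAltReads = 3) {
  filt <- filterSomatic(x, minDepth, minAf, minAltReads)
  nom <- .nomBySample(filt, samples)
  strat <- stratifyTertiles(nom)
  strat$tmb_per_mb <- tmbPerMb(strat$nom, regionMb)
  strat$tmb_printed <- roundHalfUp(strat$tmb_per_mb, 1)
  strat[, c("sample_id", "nom", "tmb_per_mb", "tmb_printed", "tertile")]
}
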