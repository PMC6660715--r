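#' @import methods
#' @importFrom stats median p.adjust cor.test t.test fisher.test wilcox.test
#'   hclust cutree kmeans dist as.dist pt rnorm runif rbinom rlnorm rbeta
#'   rpois sd var setNames
#' @importFrom utils read.delim write.table head combn
NULL

## ---- canonical context orders -------------------------------------------

.SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.BASES <- c("A", "C", "G", "T")
.FEATURES <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "IGR")
.PROMOTER_FEATURES <- c("TSS1500", "TSS200", "5UTR", "1stExon")
.VARIANT_CLASSES <- c("nonsynonymous", "synonymous", "other")

#' Canonical 96 trinucleotide substitution contexts
#'
#' The canonical ordering of the 96 pyrimidine-normalized single-base
#' substitution classes: substitution-major (`C>A`, `C>G`, `C>T`, `T>A`,
#' `T>C`, `T>G`), then 5' flank, then 3' flank, flanks in alphabetical order.
#' Context labels follow the usual `"A[C>T]G"` convention.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(mutationContexts())
mutationContexts <- function() {
  unlist(lapply(.SUB_CLASSES, function(cl) {
    as.vector(t(outer(.BASES, .BASES, function(f5, f3)
      paste0(f5, "[", cl, "]", f3))))
  }))
}

#' Canonical 32 pyrimidine-centered trinucleotides
#'
#' Ordering: center `C` then center `T`, flanks alphabetical (5' major).
#'
#' @return Character vector of length 32.
#' @export
pyrimidineContexts <- function() {
  unlist(lapply(c("C", "T"), function(ctr)
    as.vector(t(outer(.BASES, .BASES, function(f5, f3)
      paste0(f5, ctr, f3))))))
}

## trinucleotide underlying each of the 96 classes, in canonical order
.contextTrinucs <- function() {
  ctx <- mutationContexts()
  paste0(substr(ctx, 1, 1), substr(ctx, 3, 3), substr(ctx, 7, 7))
}

.MUT_CONTEXTS <- NULL  # filled at load via .onLoad-free lazy pattern

## ---- MutationTable -------------------------------------------------------

.MUT_COLS <- c("sample_id", "chrom", "pos", "ref", "alt", "variant_class",
               "depth", "alt_reads", "af")

.validateMutationFrame <- function(df) {
  missing <- setdiff(.MUT_COLS, colnames(df))
  if (length(missing) > 0)
    stop("mutation table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) return(invisible(TRUE))
  bad <- function(idx, what) {
    if (any(idx, na.rm = TRUE) || anyNA(idx))
      stop("invalid mutation record at row ",
           which(idx | is.na(idx))[1], ": ", what, call. = FALSE)
  }
  bad(df$pos < 1, "pos must be >= 1")
  bad(df$depth < 0, "depth must be nonnegative")
  bad(df$alt_reads < 0, "alt_reads must be nonnegative")
  bad(df$alt_reads > df$depth, "alt_reads exceeds depth")
  bad(df$af < 0 | df$af > 1, "af outside [0, 1]")
  bad(df$ref == df$alt, "ref equals alt")
  bad(!df$variant_class %in% .VARIANT_CLASSES,
      paste0("variant_class not one of ",
             paste(.VARIANT_CLASSES, collapse = "/")))
  invisible(TRUE)
}

#' MutationTable: validated somatic mutation calls
#'
#' A thin S4 container around a data frame of MAF-like somatic calls, one row
#' per called variant, enforcing the record invariants (1-based positions,
#' `alt_reads <= depth`, allele fraction in `[0,1]`, `ref != alt`, a closed
#' variant-class vocabulary). Extra columns (e.g. a `gene` annotation) are
#' carried through untouched.
#'
#' @slot data the underlying `data.frame`.
#' @export
setClass("MutationTable", representation(data = "data.frame"))

setValidity("MutationTable", function(object) {
  tryCatch({ .validateMutationFrame(object@data); TRUE },
           error = function(e) conditionMessage(e))
})

#' Construct a MutationTable
#'
#' @param data data frame with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `variant_class`, `depth`, `alt_reads`, `af`.
#' @return A [MutationTable-class] object.
#' @export
MutationTable <- function(data) {
  .validateMutationFrame(data)
  rownames(data) <- NULL
  new("MutationTable", data = data)
}

#' @describeIn MutationTable-class number of mutation records
#' @param x,object a `MutationTable`
#' @export
setMethod("length", "MutationTable", function(x) nrow(x@data))

#' Access the underlying mutation data frame
#' @param x a [MutationTable-class]
#' @return `data.frame` of validated records.
#' @export
mutData <- function(x) {
  stopifnot(is(x, "MutationTable"))
  x@data
}

#' Sample identifiers present in an object
#' @param x a `MutationTable` or `BetaSet`
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "MutationTable",
          function(x) unique(x@data$sample_id))

setMethod("show", "MutationTable", function(object) {
  cat("MutationTable with", nrow(object@data), "records across",
      length(unique(object@data$sample_id)), "sample(s)\n")
  if (nrow(object@data) > 0) {
    cls <- table(object@data$variant_class)
    cat("  variant classes:",
        paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  }
})

## ---- BetaSet -------------------------------------------------------------

.SHEET_COLS <- c("sample_id", "pair_id", "tissue")

.validateSampleSheet <- function(sheet) {
  missing <- setdiff(.SHEET_COLS, colnames(sheet))
  if (length(missing) > 0)
    stop("sample sheet is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(duplicated(sheet$sample_id)))
    stop("duplicated sample_id in sample sheet: ",
         sheet$sample_id[duplicated(sheet$sample_id)][1], call. = FALSE)
  if (!all(sheet$tissue %in% c("tumor", "normal")))
    stop("tissue must be 'tumor' or 'normal'", call. = FALSE)
  tab <- table(sheet$pair_id, sheet$tissue)
  ok <- all(tab[, "tumor"] == 1) && all(tab[, "normal"] == 1)
  if (!ok)
    stop("every pair_id must have exactly one tumor and one normal sample",
         call. = FALSE)
  invisible(TRUE)
}

#' BetaSet: probes-by-samples methylation beta values
#'
#' A `SummarizedExperiment` subclass holding a `beta` assay of methylation
#' levels in `[0, 1]`, a tumor/normal paired sample sheet in `colData`
#' (`sample_id`, `pair_id`, `tissue`, optional `tmb_group`), and the probe
#' manifest (`probe_id`, `chrom`, `pos`, `gene`, `feature`, `arm`, optional
#' `tss`) in `rowData`.
#'
#' @export
setClass("BetaSet", contains = "SummarizedExperiment")

setValidity("BetaSet", function(object) {
  if (!"beta" %in% assayNames(object)) return("missing 'beta' assay")
  b <- assay(object, "beta")
  if (any(b < 0 | b > 1, na.rm = TRUE)) return("beta values outside [0, 1]")
  cd <- as.data.frame(colData(object))
  msg <- tryCatch({ .validateSampleSheet(cd); TRUE },
                  error = function(e) conditionMessage(e))
  if (!isTRUE(msg)) return(msg)
  TRUE
})

#' Construct a BetaSet
#'
#' @param beta numeric matrix, probes x samples, values in `[0, 1]`;
#'   rownames are probe ids, colnames are sample ids.
#' @param sampleSheet data frame with `sample_id`, `pair_id`, `tissue`
#'   (tumor/normal), optionally `tmb_group`; must cover every column of
#'   `beta` and pair each tumor with exactly one normal.
#' @param manifest optional probe manifest data frame (`probe_id`, `chrom`,
#'   `pos`, `gene`, `feature`, `arm`, optionally `tss`); matched to the rows
#'   of `beta` by `probe_id`.
#' @return A [BetaSet-class].
#' @export
BetaSet <- function(beta, sampleSheet, manifest = NULL) {
  .validateSampleSheet(sampleSheet)
  if (is.null(colnames(beta)))
    stop("beta matrix must have sample ids as column names", call. = FALSE)
  extra <- setdiff(colnames(beta), sampleSheet$sample_id)
  if (length(extra) > 0)
    stop("sample(s) in beta matrix absent from sample sheet: ",
         paste(extra, collapse = ", "), call. = FALSE)
  sheet <- sampleSheet[match(colnames(beta), sampleSheet$sample_id), ,
                       drop = FALSE]
  if (!"tmb_group" %in% colnames(sheet)) sheet$tmb_group <- "unassigned"
  rd <- NULL
  if (!is.null(manifest)) {
    idx <- match(rownames(beta), manifest$probe_id)
    if (anyNA(idx))
      stop("probe(s) missing from manifest: ",
           rownames(beta)[is.na(idx)][1], call. = FALSE)
    rd <- S4Vectors::DataFrame(manifest[idx, , drop = FALSE])
    rownames(rd) <- rownames(beta)
  }
  se <- SummarizedExperiment(assays = list(beta = beta),
                             colData = S4Vectors::DataFrame(sheet,
                               row.names = sheet$sample_id),
                             rowData = rd)
  new("BetaSet", se)
}

#' @rdname betaValues
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' Beta-value matrix of a BetaSet
#' @param x a [BetaSet-class]
#' @return numeric matrix probes x samples.
#' @export
setMethod("betaValues", "BetaSet", function(x) assay(x, "beta"))

#' @rdname sampleSheet
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))

#' Sample sheet of a BetaSet
#' @param x a [BetaSet-class]
#' @export
setMethod("sampleSheet", "BetaSet",
          function(x) as.data.frame(colData(x)))

#' @rdname probeManifest
#' @export
setGeneric("probeManifest", function(x) standardGeneric("probeManifest"))

#' Probe manifest of a BetaSet
#' @param x a [BetaSet-class]
#' @export
setMethod("probeManifest", "BetaSet",
          function(x) as.data.frame(rowData(x)))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "BetaSet", function(x) colnames(x))

#' Tumor / normal sample ids of a BetaSet
#' @param x a [BetaSet-class]
#' @export
tumorSamples <- function(x) {
  sh <- sampleSheet(x)
  sh$sample_id[sh$tissue == "tumor"]
}

#' @rdname tumorSamples
#' @export
normalSamples <- function(x) {
  sh <- sampleSheet(x)
  sh$sample_id[sh$tissue == "normal"]
}

#' Tumor/normal sample ids for one pair
#' @param x a [BetaSet-class]
#' @param pairId pair identifier from the sample sheet
#' @return named character vector with elements `tumor` and `normal`.
#' @export
pairColumns <- function(x, pairId) {
  sh <- sampleSheet(x)
  sub <- sh[sh$pair_id == pairId, , drop = FALSE]
  if (nrow(sub) == 0) stop("unknown pair_id: ", pairId, call. = FALSE)
  c(tumor = sub$sample_id[sub$tissue == "tumor"],
    normal = sub$sample_id[sub$tissue == "normal"])
}

setMethod("show", "BetaSet", function(object) {
  cat("BetaSet:", nrow(object), "probes x", ncol(object), "samples (",
      length(unique(colData(object)$pair_id)), "tumor/normal pairs )\n")
  callNextMethod()
})

## ---- SignatureCatalog ----------------------------------------------------

#' SignatureCatalog: 96-context mutational signature catalogue
#'
#' Holds a 96 x K nonnegative matrix whose rows follow the canonical context
#' order of [mutationContexts()] and whose columns each sum to one (each
#' column is a probability distribution over the 96 substitution classes).
#'
#' @slot signatures the 96 x K matrix.
#' @export
setClass("SignatureCatalog", representation(signatures = "matrix"))

setValidity("SignatureCatalog", function(object) {
  s <- object@signatures
  if (nrow(s) != 96) return("expected 96 contexts")
  if (!identical(rownames(s), mutationContexts()))
    return("rows must follow the canonical 96-context order")
  if (any(s < 0)) return("negative signature entry")
  cs <- colSums(s)
  if (any(abs(cs - 1) > 1e-6))
    return("signature columns must sum to 1 (within 1e-6)")
  TRUE
})

#' Construct a SignatureCatalog
#'
#' Columns whose sums deviate from one by at most `1e-3` are renormalized;
#' larger deviations are rejected.
#'
#' @param signatures 96 x K nonnegative matrix with rownames in canonical
#'   context order (or unnamed, in which case canonical order is assumed).
#' @return A [SignatureCatalog-class].
#' @export
SignatureCatalog <- function(signatures) {
  signatures <- as.matrix(signatures)
  if (nrow(signatures) != 96)
    stop("expected 96 contexts, got ", nrow(signatures), call. = FALSE)
  if (is.null(rownames(signatures))) rownames(signatures) <- mutationContexts()
  ord <- match(mutationContexts(), rownames(signatures))
  if (anyNA(ord))
    stop("signature rows do not cover the canonical 96 contexts",
         call. = FALSE)
  signatures <- signatures[ord, , drop = FALSE]
  if (any(signatures < 0))
    stop("negative signature entry", call. = FALSE)
  cs <- colSums(signatures)
  off <- abs(cs - 1) > 1e-3
  if (any(off))
    stop("signature column(s) do not sum to 1 (tolerance 1e-3): ",
         paste(colnames(signatures)[off] %||% which(off), collapse = ", "),
         call. = FALSE)
  signatures <- sweep(signatures, 2, cs, "/")
  if (is.null(colnames(signatures)))
    colnames(signatures) <- paste0("Signature", seq_len(ncol(signatures)))
  new("SignatureCatalog", signatures = signatures)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signature matrix of a catalogue
#' @param x a [SignatureCatalog-class]
#' @export
signatureMatrix <- function(x) {
  stopifnot(is(x, "SignatureCatalog"))
  x@signatures
}

#' @describeIn SignatureCatalog-class number of signatures
#' @param x,object a `SignatureCatalog`
#' @export
setMethod("length", "SignatureCatalog", function(x) ncol(x@signatures))

setMethod("show", "SignatureCatalog", function(object) {
  cat("SignatureCatalog with", ncol(object@signatures), "signatures:",
      paste(colnames(object@signatures), collapse = ", "), "\n")
})

## ---- ArmCallSet ----------------------------------------------------------

#' ArmCallSet: arm-level copy-number states
#'
#' Samples x arms integer matrix with entries -1 (lost), 0 (non-aneuploid),
#' +1 (gained) or `NA` (not assessable). The aneuploidy score of a sample is
#' the number of arms called gained or lost ([aneuploidyScore()]).
#'
#' @slot calls samples x arms integer matrix.
#' @export
setClass("ArmCallSet", representation(calls = "matrix"))

setValidity("ArmCallSet", function(object) {
  v <- object@calls
  if (!all(v %in% c(-1L, 0L, 1L, NA_integer_)))
    return("arm calls restricted to -1, 0, +1, NA")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("calls must carry sample (row) and arm (column) names")
  TRUE
})

#' Construct an ArmCallSet
#' @param calls samples x arms matrix of -1/0/+1/NA
#' @export
ArmCallSet <- function(calls) {
  mode(calls) <- "integer"
  new("ArmCallSet", calls = calls)
}

#' Arm-call matrix
#' @param x an [ArmCallSet-class]
#' @export
armCallMatrix <- function(x) {
  stopifnot(is(x, "ArmCallSet"))
  x@calls
}

setMethod("show", "ArmCallSet", function(object) {
  sc <- aneuploidyScore(object)
  cat("ArmCallSet:", nrow(object@calls), "samples x",
      ncol(object@calls), "arms; aneuploidy scores",
      paste(range(sc), collapse = "-"), "\n")
})
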