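## Readers/writers for the on-disk formats the pipeline touches. All
## coordinates on disk are 1-based inclusive (MAF convention); beta values
## are decimal in [0,1] with "NA" as the missing marker.

.readTsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a MAF-like somatic mutation table
#'
#' Expects a TSV whose header contains at least the nine record columns
#' `sample_id`, `chrom`, `pos`, `ref`, `alt`, `variant_class`, `depth`,
#' `alt_reads`, `af`. Rows are validated against the record invariants
#' (positions 1-based and positive, `alt_reads <= depth`, `af` in `[0,1]`,
#' `ref != alt`); the first violation is reported with its row number.
#' Row order is preserved. A header-only file yields an empty table.
#'
#' @param path path to the TSV file.
#' @return A [MutationTable-class].
#' @export
#' @seealso [writeMutationTable()]
readMutationTable <- function(path) {
  df <- .readTsv(path)
  MutationTable(df)
}

#' @rdname readMutationTable
#' @param x a [MutationTable-class]
#' @export
writeMutationTable <- function(x, path) {
  .writeTsv(mutData(x), path)
  invisible(path)
}

#' Read a tumor/normal sample sheet
#'
#' TSV with columns `sample_id`, `pair_id`, `tissue` (tumor/normal) and
#' optionally `tmb_group`; every `pair_id` must have exactly one tumor and
#' one normal sample.
#'
#' @param path path to the TSV file.
#' @return data frame.
#' @export
readSampleSheet <- function(path) {
  sheet <- .readTsv(path)
  .validateSampleSheet(sheet)
  if (!"tmb_group" %in% colnames(sheet)) sheet$tmb_group <- "unassigned"
  sheet
}

#' @rdname readSampleSheet
#' @param sheet sample-sheet data frame
#' @export
writeSampleSheet <- function(sheet, path) {
  .writeTsv(sheet, path)
  invisible(path)
}

#' Read a probe manifest
#'
#' TSV with columns `probe_id`, `chrom`, `pos`, `gene`, `feature`, `arm`
#' (optionally `tss`). `feature` must come from the closed vocabulary
#' TSS1500/TSS200/5UTR/1stExon/Body/IGR and `arm` must match the chromosome
#' (e.g. arm `3p` on chrom `3` or `chr3`).
#'
#' @param path path to the TSV file.
#' @return data frame.
#' @export
readProbeManifest <- function(path) {
  m <- .readTsv(path)
  required <- c("probe_id", "chrom", "pos", "gene", "feature", "arm")
  missing <- setdiff(required, colnames(m))
  if (length(missing) > 0)
    stop("probe manifest is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(duplicated(m$probe_id)))
    stop("duplicated probe_id in manifest: ",
         m$probe_id[duplicated(m$probe_id)][1], call. = FALSE)
  badf <- !m$feature %in% .FEATURES
  if (any(badf))
    stop("unknown feature at row ", which(badf)[1], ": ",
         m$feature[badf][1], call. = FALSE)
  chromBare <- sub("^chr", "", m$chrom)
  badArm <- sub("[pq]$", "", m$arm) != chromBare
  if (any(badArm))
    stop("arm does not match chrom at row ", which(badArm)[1], " (",
         m$arm[badArm][1], " on ", m$chrom[badArm][1], ")", call. = FALSE)
  m
}

#' @rdname readProbeManifest
#' @param manifest manifest data frame
#' @export
writeProbeManifest <- function(manifest, path) {
  .writeTsv(manifest, path)
  invisible(path)
}

#' Read a beta-value matrix into a BetaSet
#'
#' TSV whose first column is `probe_id` and whose remaining columns are
#' sample ids that must all appear in the sample sheet. Values must lie in
#' `[0, 1]` or be the missing marker `NA`; out-of-range values are reported
#' with their probe/sample coordinates, and duplicated probe ids are
#' rejected. Probes with any missing value are dropped (with a message
#' stating the count) before analysis.
#'
#' @param path path to the TSV file.
#' @param sheet sample sheet data frame (see [readSampleSheet()]).
#' @param manifest optional probe manifest (see [readProbeManifest()]).
#' @return A [BetaSet-class].
#' @export
readBetaMatrix <- function(path, sheet, manifest = NULL) {
  df <- .readTsv(path)
  if (colnames(df)[1] != "probe_id")
    stop("first column of a beta matrix must be 'probe_id'", call. = FALSE)
  dup <- duplicated(df$probe_id)
  if (any(dup))
    stop("duplicated probe_id in beta matrix: ",
         paste(unique(df$probe_id[dup]), collapse = ", "), call. = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- df$probe_id
  out <- which(mat < 0 | mat > 1, arr.ind = TRUE)
  if (nrow(out) > 0)
    stop("beta value outside [0, 1] at probe ", rownames(mat)[out[1, 1]],
         ", sample ", colnames(mat)[out[1, 2]], call. = FALSE)
  hasNA <- rowSums(is.na(mat)) > 0
  if (any(hasNA)) {
    message("dropping ", sum(hasNA), " probe(s) with missing beta values")
    mat <- mat[!hasNA, , drop = FALSE]
  }
  BetaSet(mat, sheet, manifest = manifest)
}

#' @rdname readBetaMatrix
#' @param x a [BetaSet-class]
#' @export
writeBetaMatrix <- function(x, path) {
  b <- betaValues(x)
  df <- data.frame(probe_id = rownames(b), b, check.names = FALSE)
  .writeTsv(df, path)
  invisible(path)
}

#' Read a 96-context signature catalogue
#'
#' TSV of 96 rows keyed by a `context` column in the canonical order of
#' [mutationContexts()] (any row order covering all 96 contexts is
#' accepted), one column per signature. Entries must be nonnegative; each
#' column must sum to one within `1e-3` (and is renormalized), otherwise the
#' file is rejected.
#'
#' @param path path to the TSV file.
#' @return A [SignatureCatalog-class].
#' @export
readSignatureCatalog <- function(path) {
  df <- .readTsv(path)
  if (colnames(df)[1] != "context")
    stop("first column of a signature catalogue must be 'context'",
         call. = FALSE)
  if (nrow(df) != 96)
    stop("expected 96 contexts, got ", nrow(df), call. = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- df$context
  SignatureCatalog(mat)
}

#' @rdname readSignatureCatalog
#' @param x a [SignatureCatalog-class]
#' @export
writeSignatureCatalog <- function(x, path) {
  s <- signatureMatrix(x)
  df <- data.frame(context = rownames(s), s, check.names = FALSE)
  .writeTsv(df, path)
  invisible(path)
}
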