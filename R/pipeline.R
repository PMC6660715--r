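## End-to-end orchestration: TMB -> signatures -> methylation -> CNA ->
## associations on a synthetic cohort, with a machine-readable report.

#' @importFrom rlang hash
NULL

.safePearson <- function(x, y) {
  tryCatch(c(pearsonTest(x, y), list(flag = NA_character_)),
           error = function(e)
             list(estimate = NA_real_, p = NA_real_, n = length(x),
                  statistic = NA_real_, method = "pearson",
                  flag = conditionMessage(e)))
}

#' Run the integrated TMB-methylation pipeline on a synthetic cohort
#'
#' Simulates (or accepts) a cohort and executes the stages in order: somatic
#' filtering, NOM/TMB and tertiles; per-sample and cohort differential
#' methylation with MVP classification, promoter-gene mapping and
#' TSS-offset contrast; optionally signature refitting, DMR detection,
#' informative-probe consensus clustering and arm-level CNA; and the
#' cross-stage association statistics (per-sample DMP count versus NOM —
#' both the threshold-only and the significance-filtered count, labelled —
#' aneuploidy score versus NOM, and high-versus-low-tertile NOM contrast).
#' Undefined correlations (zero variance) are reported with an `NA`
#' estimate and a `flag` rather than raising. Reruns with the same seed and
#' configuration return an identical report.
#'
#' @param config a [cohortConfig()]
#' @param seed integer seed for the cohort simulation
#' @param cohort optional pre-built `SyntheticCohort` (then `config`/`seed`
#'   are taken from it for provenance)
#' @param doSignatures,doDmr,doCluster,doCna stage switches (all TRUE);
#'   switching the heavier stages off is useful for replicate studies of
#'   the DMP-TMB association alone
#' @param dmrPerm label permutations for the DMR null (default 100)
#' @return a nested report list; see Details in the vignette
#' @export
runPipeline <- function(config = cohortConfig(), seed = 1, cohort = NULL,
                        doSignatures = TRUE, doDmr = TRUE,
                        doCluster = TRUE, doCna = TRUE, dmrPerm = 100) {
  if (is.null(cohort)) cohort <- simulateCohort(config, seed)
  config <- cohort$config
  truth <- cohort$truth
  tumorIds <- truth$tumorIds
  pairIds <- truth$pairIds

  ## --- TMB stage -------------------------------------------------------
  tmb <- tmbStage(cohort$mutations, tumorIds, config$regionMb)
  tertileOfPair <- setNames(as.character(tmb$tertile), pairIds)

  ## --- methylation stage ----------------------------------------------
  bs <- cohort$beta
  dmpCount <- vapply(pairIds, function(p) perSampleDmpCount(bs, p),
                     integer(1))
  highPairs <- pairIds[tertileOfPair == "high"]
  lowPairs <- pairIds[tertileOfPair == "low"]
  sh <- sampleSheet(bs)
  tumorOf <- function(pairs) sh$sample_id[sh$pair_id %in% pairs &
                                          sh$tissue == "tumor"]
  normalOf <- function(pairs) sh$sample_id[sh$pair_id %in% pairs &
                                           sh$tissue == "normal"]
  dmp <- cohortDmpTest(bs, tumorOf(highPairs), normalOf(highPairs),
                       alpha = 0.05)
  mvp <- classifyMvp(dmp, deltaThr = 0.2, pThr = 0.01)
  ## significance-filtered per-sample counts (the labelled alternative)
  sigProbes <- dmp$significant
  b <- betaValues(bs)
  dmpCountSig <- vapply(pairIds, function(p) {
    cols <- pairColumns(bs, p)
    sum(sigProbes & abs(b[, cols["tumor"]] - b[, cols["normal"]]) > 0.2)
  }, integer(1))
  promoterGenes <- mapPromoterGenes(mvp, cohort$manifest, minMvp = 4)
  tss <- tssOffsetSummary(mvp, cohort$manifest)
  dmrs <- NULL
  if (doDmr)
    dmrs <- findDmrs(bs, tumorOf(highPairs), normalOf(highPairs),
                     nPerm = dmrPerm, seed = seed + 1L)
  informative <- character(0)
  consensus <- NULL
  if (doCluster && length(highPairs) >= 2 && length(lowPairs) >= 2) {
    informative <- selectInformativeProbes(bs, highPairs, lowPairs)
    if (length(informative) >= 2) {
      tumorCols <- tumorOf(c(highPairs, lowPairs))
      consensus <- consensusCluster(t(b[informative, tumorCols,
                                        drop = FALSE]),
                                    k = 2, seed = seed + 2L)
    }
  }

  ## --- signature stage -------------------------------------------------
  exposures <- NULL
  if (doSignatures) {
    filt <- filterSomatic(cohort$mutations)
    df <- mutData(filt)
    K <- length(cohort$catalog)
    exposures <- matrix(NA_real_, length(tumorIds), K,
                        dimnames = list(tumorIds,
                          colnames(signatureMatrix(cohort$catalog))))
    for (s in tumorIds) {
      tab <- MutationTable(df[df$sample_id == s, , drop = FALSE])
      spec <- suppressMessages(buildSpectrum(tab, cohort$reference))
      if (sum(spec) > 0) {
        census <- censusContexts(cohort$reference[paste0("synth_", s)])
        norm <- normalizeSpectrum(spec, census, census)
        exposures[s, ] <- fitExposures(norm, cohort$catalog)$weights
      }
    }
  }

  ## --- CNA stage -------------------------------------------------------
  armSet <- NULL
  asScore <- rep(NA_integer_, length(tumorIds))
  if (doCna) {
    normCols <- normalOf(pairIds)
    ratios <- probeLogRatios(cohort$intensities, tumorIds, normCols)
    armSet <- armCalls(ratios, cohort$manifest)
    asScore <- aneuploidyScore(armSet)[tumorIds]
  }

  ## --- associations ----------------------------------------------------
  nom <- tmb$nom[match(tumorIds, tmb$sample_id)]
  assoc <- list(
    dmp_vs_nom = .safePearson(as.numeric(dmpCount), nom),
    dmp_significant_vs_nom = .safePearson(as.numeric(dmpCountSig), nom))
  if (doCna) assoc$aneuploidy_vs_nom <-
    .safePearson(as.numeric(asScore), nom)
  highNom <- tmb$nom[tmb$tertile == "high"]
  lowNom <- tmb$nom[tmb$tertile == "low"]
  assoc$nom_high_vs_low <-
    if (length(highNom) >= 2 && length(lowNom) >= 2)
      unpairedT(highNom, lowNom) else NULL
  interactions <- NULL
  if ("gene" %in% colnames(mutData(cohort$mutations))) {
    fdf <- mutData(filterSomatic(cohort$mutations))
    gm <- table(fdf$gene, factor(fdf$sample_id, levels = tumorIds)) > 0
    interactions <- somaticInteractions(gm * 1L, minMutated = 3)
  }

  samples <- data.frame(
    sample_id = tumorIds,
    pair_id = pairIds,
    nom = nom,
    tmb_per_mb = tmb$tmb_per_mb[match(tumorIds, tmb$sample_id)],
    tmb_printed = tmb$tmb_printed[match(tumorIds, tmb$sample_id)],
    tertile = as.character(tmb$tertile[match(tumorIds, tmb$sample_id)]),
    dmp_count = as.integer(dmpCount),
    dmp_count_significant = as.integer(dmpCountSig),
    aneuploidy_score = as.integer(asScore))

  list(provenance = list(seed = seed,
                         config_hash = rlang::hash(unclass(config)),
                         n_pairs = config$nPairs,
                         n_probes = config$nProbes),
       samples = samples,
       mvp = mvp,
       mvp_summary = list(n_mvp = sum(mvp$status != "ns"),
                          n_hyper = sum(mvp$status == "hyper"),
                          n_hypo = sum(mvp$status == "hypo")),
       dmrs = dmrs,
       promoter_genes = promoterGenes,
       tss_offsets = tss$test,
       informative_probes = informative,
       consensus = consensus,
       exposures = exposures,
       arm_calls = if (!is.null(armSet)) armCallMatrix(armSet) else NULL,
       interactions = interactions,
       associations = assoc)
}

#' Write a pipeline report to disk
#'
#' JSON summary (provenance, per-sample table, MVP counts, associations)
#' plus TSVs for the larger tables.
#'
#' @param report list from [runPipeline()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
writeReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summary <- list(provenance = report$provenance,
                  samples = report$samples,
                  mvp_summary = report$mvp_summary,
                  tss_offsets = report$tss_offsets,
                  associations = report$associations)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  .writeTsv(report$samples, file.path(dir, "samples.tsv"))
  .writeTsv(report$mvp, file.path(dir, "mvp.tsv"))
  if (!is.null(report$dmrs))
    .writeTsv(report$dmrs, file.path(dir, "dmrs.tsv"))
  if (!is.null(report$exposures))
    .writeTsv(data.frame(sample_id = rownames(report$exposures),
                         report$exposures, check.names = FALSE),
              file.path(dir, "exposures.tsv"))
  if (!is.null(report$arm_calls))
    .writeTsv(data.frame(sample_id = rownames(report$arm_calls),
                         report$arm_calls, check.names = FALSE),
              file.path(dir, "arm_calls.tsv"))
  invisible(dir)
}
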