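## Synthetic-cohort generator: paired tumor/normal cohorts with the
## statistical structure the analysis assumes — per-sample NOM drawn
## log-normally, a fraction of methylation probes shifted in the tumor that
## increases with z-scored log-NOM (hypomethylation-biased), aneuploid arm
## counts coupled to the same z, and mutational spectra drawn from known
## signature mixtures. A truth record accompanies every cohort for
## recovery testing. All draws run through the single R generator seeded
## once at the top, so a fixed seed reproduces the cohort bit for bit.

#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
.clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Synthetic cohort configuration
#'
#' Bundles every tunable of the generator. Defaults emulate the study
#' conditions the pipeline targets: a cohort of paired tumor/normal samples
#' whose NOMs are log-normal around a median of 104, whose per-sample
#' fraction of shifted probes rises with z-scored log-NOM, with 70% of
#' shifts losing methylation, and whose expected aneuploid-arm count rises
#' with the same z.
#'
#' @param nPairs tumor/normal pairs (default 29, a methylation-scale cohort)
#' @param nProbes methylation probes (default 20000; thresholds downstream
#'   are scale-free)
#' @param nArms chromosome arms (default 39)
#' @param regionMb coding-region size for per-Mb TMB (default 33.4)
#' @param tmbLogMean,tmbLogSd log-normal NOM parameters (default log(104),
#'   0.55)
#' @param dmpBase intercept a of `dmp_fraction = a + b z(log NOM)` (default
#'   0.15)
#' @param couplingDmp slope b (default 0.10; 0 decouples methylation from
#'   TMB)
#' @param dmpClamp clamp range for the dmp fraction (default c(0.01, 0.6))
#' @param hypoBias probability a shifted probe loses methylation (default
#'   0.7)
#' @param armBase,couplingArms intercept/slope of the expected aneuploid-arm
#'   count versus z (defaults 4 and 2)
#' @param noiseSd beta-value noise s.d. (default 0.01)
#' @param deltaRange range of the tumor beta shift magnitude (default
#'   c(0.25, 0.5), so shifted probes exceed the 0.2 threshold in
#'   expectation)
#' @param nonsynFraction fraction of calls that are nonsynonymous (default
#'   0.75)
#' @param filterFailFraction fraction of calls engineered to fail the
#'   confidence filters (default 0.2)
#' @param indelFraction fraction of calls that are short indels (default
#'   0.05)
#' @param intensityNoiseSd multiplicative (log-scale) intensity noise s.d.
#'   (default 0.1)
#' @param recurrentFraction fraction of each sample's shifted probes drawn
#'   from a cohort-shared, spatially blocked aberrant-probe pool (nested
#'   across samples, so heavily mutated samples recapitulate the
#'   aberrations of lightly mutated ones; default 0.6). This is what makes
#'   cohort-level MVPs, DMRs and informative probes detectable, as they are
#'   in real tumors; 0 makes every sample's aberrations private.
#' @param exposureProfiles 2 x K matrix of signature weights for the high-
#'   and low-NOM strata (rows "high", "low"); default a 3-signature pair of
#'   mirrored mixtures
#' @return a validated list of class `CohortConfig`
#' @export
cohortConfig <- function(nPairs = 29, nProbes = 20000, nArms = 39,
                         regionMb = 33.4,
                         tmbLogMean = log(104), tmbLogSd = 0.55,
                         dmpBase = 0.15, couplingDmp = 0.10,
                         dmpClamp = c(0.01, 0.6), hypoBias = 0.7,
                         armBase = 4, couplingArms = 2,
                         noiseSd = 0.01, deltaRange = c(0.25, 0.5),
                         nonsynFraction = 0.75, filterFailFraction = 0.2,
                         indelFraction = 0.05, intensityNoiseSd = 0.1,
                         recurrentFraction = 0.6, exposureProfiles = NULL) {
  if (is.null(exposureProfiles)) {
    exposureProfiles <- rbind(high = c(0.6, 0.3, 0.1),
                              low = c(0.1, 0.3, 0.6))
    colnames(exposureProfiles) <- paste0("Signature", 1:3)
  }
  stopifnot(nPairs >= 1, nProbes >= 1, nArms >= 1, regionMb > 0,
            hypoBias >= 0, hypoBias <= 1,
            dmpClamp[1] >= 0, dmpClamp[2] <= 1, dmpClamp[1] <= dmpClamp[2],
            deltaRange[1] >= 0.2, deltaRange[1] <= deltaRange[2],
            nonsynFraction > 0, nonsynFraction <= 1,
            filterFailFraction >= 0, filterFailFraction < 1,
            indelFraction >= 0, indelFraction < 1,
            noiseSd >= 0, intensityNoiseSd >= 0,
            recurrentFraction >= 0, recurrentFraction <= 1,
            all(abs(rowSums(exposureProfiles) - 1) < 1e-6))
  structure(list(nPairs = nPairs, nProbes = nProbes, nArms = nArms,
                 regionMb = regionMb, tmbLogMean = tmbLogMean,
                 tmbLogSd = tmbLogSd, dmpBase = dmpBase,
                 couplingDmp = couplingDmp, dmpClamp = dmpClamp,
                 hypoBias = hypoBias, armBase = armBase,
                 couplingArms = couplingArms, noiseSd = noiseSd,
                 deltaRange = deltaRange, nonsynFraction = nonsynFraction,
                 filterFailFraction = filterFailFraction,
                 indelFraction = indelFraction,
                 intensityNoiseSd = intensityNoiseSd,
                 recurrentFraction = recurrentFraction,
                 exposureProfiles = exposureProfiles),
            class = "CohortConfig")
}

#' Synthetic signature catalogue
#'
#' `k` signatures, each uniform over a disjoint block of the 96 contexts —
#' maximally separated, so mixtures of them are identifiable by refitting.
#'
#' @param k number of signatures (default 3; must divide into 96 blocks of
#'   at least 1)
#' @return a [SignatureCatalog-class]
#' @export
syntheticSignatures <- function(k = 3) {
  stopifnot(k >= 1, k <= 96)
  blocks <- split(seq_len(96), cut(seq_len(96), k, labels = FALSE))
  s <- matrix(0, 96, k,
              dimnames = list(mutationContexts(), paste0("Signature",
                                                         seq_len(k))))
  for (j in seq_len(k)) s[blocks[[j]], j] <- 1 / length(blocks[[j]])
  SignatureCatalog(s)
}

#' Synthetic probe manifest
#'
#' Assigns `nProbes` probes to `nArms` chromosome arms (two arms per
#' chromosome, zero-padded names so lexicographic and genomic order agree),
#' spaces them with a mixture of short and long gaps, groups consecutive
#' probes into genes of about 8 probes, samples a genomic feature per probe
#' and records a per-gene TSS coordinate. Draws from the current RNG
#' stream; seed upstream for reproducibility.
#'
#' @param nProbes number of probes
#' @param nArms number of arms
#' @return manifest data frame (`probe_id`, `chrom`, `pos`, `gene`,
#'   `feature`, `arm`, `tss`), sorted by (chrom, pos)
#' @export
syntheticManifest <- function(nProbes, nArms) {
  nChrom <- ceiling(nArms / 2)
  pad <- formatC(seq_len(nChrom), width = 2, flag = "0")
  armNames <- as.vector(t(outer(pad, c("p", "q"), paste0)))[seq_len(nArms)]
  armOf <- rep(armNames, length.out = nProbes)[order(rep(seq_len(nArms),
                                              length.out = nProbes))]
  chromOf <- paste0("chr", substr(armOf, 1, 2))
  ## positions: cumulative gaps within each chromosome, q arm after p
  gaps <- sample(c(150L, 400L, 5000L), nProbes, replace = TRUE,
                 prob = c(0.6, 0.3, 0.1))
  pos <- integer(nProbes)
  for (ch in unique(chromOf)) {
    idx <- which(chromOf == ch)
    pos[idx] <- cumsum(gaps[idx])
  }
  geneBlock <- ceiling(seq_len(nProbes) / 8)
  gene <- paste0("GENE", formatC(geneBlock, width = 5, flag = "0"))
  feature <- sample(.FEATURES, nProbes, replace = TRUE,
                    prob = c(0.15, 0.10, 0.10, 0.10, 0.35, 0.20))
  tss <- stats::ave(pos, geneBlock, FUN = min) -
    sample(0:500, nProbes, replace = TRUE)
  man <- data.frame(probe_id = paste0("cg", formatC(seq_len(nProbes),
                                                    width = 8, flag = "0")),
                    chrom = chromOf, pos = pos, gene = gene,
                    feature = feature, arm = armOf, tss = tss)
  man[order(man$chrom, man$pos), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

## one sample's mutation records plus its private reference chunked as
## [trinucleotide][AA] per record; center positions 5i - 3 (1-based)
.simulateSampleMutations <- function(n, exposures, catalog, sampleId,
                                     nonsynFraction, filterFailFraction,
                                     indelFraction) {
  chrom <- paste0("synth_", sampleId)
  cols <- data.frame(sample_id = character(), chrom = character(),
                     pos = integer(), ref = character(), alt = character(),
                     variant_class = character(), depth = integer(),
                     alt_reads = integer(), af = numeric(),
                     gene = character())
  if (n == 0)
    return(list(mutations = cols, reference = setNames("AAA", chrom),
                contexts = integer(0)))
  S <- signatureMatrix(catalog)
  mix <- as.vector(S %*% exposures)
  ctxIdx <- sample.int(96, n, replace = TRUE, prob = mix)
  ctx <- mutationContexts()[ctxIdx]
  tri <- paste0(substr(ctx, 1, 1), substr(ctx, 3, 3), substr(ctx, 7, 7))
  refBase <- substr(ctx, 3, 3)
  altBase <- substr(ctx, 5, 5)
  isIndel <- runif(n) < indelFraction
  ## a random half of the SNVs are reported on the purine strand
  flip <- !isIndel & runif(n) < 0.5
  rc3 <- function(t) chartr("ACGT", "TGCA",
                            paste0(substr(t, 3, 3), substr(t, 2, 2),
                                   substr(t, 1, 1)))
  tri[flip] <- rc3(tri[flip])
  refBase[flip] <- substr(tri[flip], 2, 2)
  altBase[flip] <- chartr("ACGT", "TGCA", altBase[flip])
  ## indels: insertion of one extra base after the (pyrimidine) center
  altBase[isIndel] <- paste0(refBase[isIndel],
                             sample(.BASES, sum(isIndel), replace = TRUE))
  pass <- runif(n) >= filterFailFraction
  depth <- integer(n); alt_reads <- integer(n)
  nP <- sum(pass)
  depth[pass] <- 60L + rpois(nP, 40)
  alt_reads[pass] <- pmin(depth[pass],
                          pmax(ceiling(0.05 * depth[pass]),
                               round(runif(nP, 0.06, 0.6) * depth[pass])))
  nF <- n - nP
  if (nF > 0) {
    mode <- sample.int(3, nF, replace = TRUE)
    fd <- integer(nF); fa <- integer(nF)
    fd[mode == 1] <- sample(5:9, sum(mode == 1), replace = TRUE)  # depth
    fa[mode == 1] <- pmin(3L, fd[mode == 1])
    fd[mode == 2] <- 200L                                          # af
    fa[mode == 2] <- sample(3:9, sum(mode == 2), replace = TRUE)
    fd[mode == 3] <- 40L                                           # alt
    fa[mode == 3] <- 2L
    depth[!pass] <- fd; alt_reads[!pass] <- fa
  }
  af <- alt_reads / depth
  vclass <- ifelse(runif(n) < nonsynFraction, "nonsynonymous", "synonymous")
  gene <- paste0("GENE", formatC(sample.int(12, n, replace = TRUE),
                                 width = 2, flag = "0"))
  refSeq <- paste0(paste0(tri, "AA"), collapse = "")
  pos <- 5L * seq_len(n) - 3L
  df <- data.frame(sample_id = sampleId, chrom = chrom, pos = pos,
                   ref = refBase, alt = altBase, variant_class = vclass,
                   depth = depth, alt_reads = alt_reads, af = af,
                   gene = gene)
  list(mutations = df, reference = setNames(refSeq, chrom),
       contexts = ctxIdx)
}

#' Simulate mutation calls from a signature mixture
#'
#' Draws `n` calls whose trinucleotide contexts follow the mixture
#' `S %*% exposures` of the catalogue columns, writes a private reference
#' sequence holding each context (a random half of the SNVs are reported on
#' the purine strand so strand folding is exercised), and draws
#' depth/allele fraction/supporting reads so that `filterFailFraction` of
#' the records fail the confidence filters and `nonsynFraction` are
#' nonsynonymous. A small `indelFraction` of records are single-base
#' insertions.
#'
#' @param n number of records
#' @param exposures nonnegative weights over the catalogue columns; must
#'   sum to 1 within 1e-6
#' @param catalog a [SignatureCatalog-class]
#' @param sampleId sample identifier (default "S1")
#' @param nonsynFraction,filterFailFraction,indelFraction record-level
#'   fractions (defaults 0.75 / 0.2 / 0.05)
#' @param seed optional seed; `NULL` draws from the current RNG stream
#' @return list: `mutations` (a [MutationTable-class]), `reference`
#'   (a `Biostrings::DNAStringSet` with the sample's private chromosome),
#'   `contexts` (true 96-class index per record)
#' @export
simulateMutations <- function(n, exposures, catalog, sampleId = "S1",
                              nonsynFraction = 0.75,
                              filterFailFraction = 0.2,
                              indelFraction = 0.05, seed = NULL) {
  if (abs(sum(exposures) - 1) > 1e-6)
    stop("exposures must sum to 1", call. = FALSE)
  stopifnot(n >= 0, all(exposures >= 0))
  if (!is.null(seed)) set.seed(seed)
  sim <- .simulateSampleMutations(n, exposures, catalog, sampleId,
                                  nonsynFraction, filterFailFraction,
                                  indelFraction)
  list(mutations = MutationTable(sim$mutations),
       reference = DNAStringSet(sim$reference),
       contexts = sim$contexts)
}

#' Simulate a paired beta-value matrix from a cohort truth
#'
#' Normal baselines are bimodal (an equal mixture of Beta(2, 18) and
#' Beta(18, 2), modes near 0.1 and 0.9). For pair i, a
#' `truth$dmpFraction[i]` subset of probes is shifted in the tumor by a
#' magnitude drawn from `config$deltaRange` (at least 0.25, so shifted
#' probes exceed the 0.2 delta-beta threshold in expectation); the shift
#' loses methylation with probability `config$hypoBias` (applied to
#' high-baseline probes, gains to low-baseline probes, so clipping does not
#' erase the shift). Gaussian noise of s.d. `config$noiseSd` is added to
#' every value and the result clipped to `[0, 1]`.
#'
#' @param truth cohort truth as built by [simulateCohort()] (needs
#'   `pairIds`, `dmpFraction`)
#' @param config a [cohortConfig()]
#' @param manifest probe manifest (see [syntheticManifest()])
#' @param seed optional seed; `NULL` draws from the current stream
#' @return a [BetaSet-class]; the per-pair shifted probe sets are stored in
#'   `metadata(x)$shifted` (list of `idx`/`direction` per pair)
#' @export
simulateMethylation <- function(truth, config, manifest, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nProbes <- nrow(manifest)
  nPairs <- length(truth$pairIds)
  stopifnot(length(truth$dmpFraction) == nPairs)
  ## spatially coherent baseline: blocks of ~10 consecutive probes share a
  ## methylation mode (island-like low vs body-like high)
  blockId <- ceiling(seq_len(nProbes) / 10)
  nBlocks <- max(blockId)
  blockHigh <- runif(nBlocks) < 0.5
  mode <- blockHigh[blockId]
  base <- ifelse(mode, rbeta(nProbes, 18, 2), rbeta(nProbes, 2, 18))
  ## cohort-shared aberrant pool: whole blocks, ordered at random, each
  ## block losing methylation when its baseline is high and gaining when
  ## low; high-baseline blocks are preferentially included so that the
  ## hypo share of the pool matches hypoBias. Samples take a nested prefix.
  recFrac <- config$recurrentFraction %||% 0
  poolTarget <- ceiling(recFrac * config$dmpClamp[2] * nProbes)
  w <- ifelse(blockHigh, config$hypoBias, 1 - config$hypoBias)
  poolBlocks <- if (poolTarget > 0 && any(w > 0)) {
    cand <- which(w > 0)
    cand[sample.int(length(cand), prob = w[cand])]
  } else integer(0)
  poolIdx <- unlist(lapply(poolBlocks, function(bk) which(blockId == bk)),
                    use.names = FALSE)
  poolIdx <- poolIdx[seq_len(min(poolTarget, length(poolIdx)))]
  poolDir <- ifelse(mode[poolIdx], "hypo", "hyper")
  privatePool <- setdiff(seq_len(nProbes), poolIdx)
  hiPriv <- privatePool[base[privatePool] > 0.55]
  loPriv <- privatePool[base[privatePool] < 0.45]
  beta <- matrix(NA_real_, nProbes, 2 * nPairs)
  ids <- as.vector(rbind(paste0(truth$pairIds, "_T"),
                         paste0(truth$pairIds, "_N")))
  shifted <- vector("list", nPairs)
  names(shifted) <- truth$pairIds
  for (i in seq_len(nPairs)) {
    normal <- .clip01(base + rnorm(nProbes, 0, config$noiseSd))
    tumor <- base
    ## each probe is shifted with probability dmpFraction, so the realized
    ## count carries binomial dispersion around dmpFraction * nProbes
    nShift <- rbinom(1, nProbes, truth$dmpFraction[i])
    nCore <- min(round(recFrac * nShift), length(poolIdx))
    coreIdx <- poolIdx[seq_len(nCore)]
    coreDir <- poolDir[seq_len(nCore)]
    nPriv <- nShift - nCore
    wantHypo <- rbinom(1, nPriv, config$hypoBias)
    nHypo <- min(wantHypo, length(hiPriv))
    nHyper <- min(nPriv - wantHypo, length(loPriv))
    privIdx <- c(sample(hiPriv, nHypo), sample(loPriv, nHyper))
    privDir <- rep(c("hypo", "hyper"), c(nHypo, nHyper))
    idx <- c(coreIdx, privIdx)
    dir <- c(coreDir, privDir)
    delta <- runif(length(idx), config$deltaRange[1], config$deltaRange[2])
    tumor[idx] <- tumor[idx] + ifelse(dir == "hypo", -delta, delta)
    tumor <- .clip01(tumor + rnorm(nProbes, 0, config$noiseSd))
    beta[, 2 * i - 1] <- tumor
    beta[, 2 * i] <- normal
    shifted[[i]] <- list(idx = idx, direction = dir)
  }
  colnames(beta) <- ids
  rownames(beta) <- manifest$probe_id
  sheet <- data.frame(sample_id = ids,
                      pair_id = rep(truth$pairIds, each = 2),
                      tissue = rep(c("tumor", "normal"), nPairs),
                      tmb_group = "unassigned")
  bs <- BetaSet(beta, sheet, manifest = manifest)
  metadata(bs)$shifted <- shifted
  bs
}

#' Simulate raw probe intensities carrying arm-level copy-number events
#'
#' Every probe has a shared baseline affinity; normal samples scatter
#' multiplicatively around it, and tumors additionally multiply the probes
#' of gained arms by 1.5 and of lost arms by 0.5 (per `truth$arms`).
#'
#' @param truth cohort truth (needs `pairIds` and the samples x arms
#'   `arms` matrix of -1/0/+1)
#' @param config a [cohortConfig()] (uses `intensityNoiseSd`)
#' @param manifest probe manifest assigning probes to arms
#' @param seed optional seed
#' @return probes x samples intensity matrix (tumor and normal columns
#'   named as in [simulateMethylation()])
#' @export
simulateIntensities <- function(truth, config, manifest, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nProbes <- nrow(manifest)
  nPairs <- length(truth$pairIds)
  baseline <- exp(rnorm(nProbes, 0, 0.05))
  armNames <- colnames(truth$arms)
  armIdx <- match(manifest$arm, armNames)
  out <- matrix(NA_real_, nProbes, 2 * nPairs)
  ids <- as.vector(rbind(paste0(truth$pairIds, "_T"),
                         paste0(truth$pairIds, "_N")))
  for (i in seq_len(nPairs)) {
    fac <- c(0.5, 1, 1.5)[truth$arms[i, armIdx] + 2L]
    out[, 2 * i - 1] <- baseline * fac *
      exp(rnorm(nProbes, 0, config$intensityNoiseSd))
    out[, 2 * i] <- baseline *
      exp(rnorm(nProbes, 0, config$intensityNoiseSd))
  }
  dimnames(out) <- list(manifest$probe_id, ids)
  out
}

#' Simulate a complete paired cohort with ground truth
#'
#' Orchestrates the generator: draws target NOMs from the configured
#' log-normal, simulates per-sample mutation tables (recording the realized
#' NOM — the count of nonsynonymous calls passing the confidence filters —
#' as the truth), couples the per-sample shifted-probe fraction and the
#' expected aneuploid-arm count to z-scored log-NOM, and emits the beta
#' matrix, intensity matrix, manifest and signature catalogue. A single
#' `set.seed(seed)` at the top threads one generator through all draws, so
#' the output is bit-identical across reruns with the same seed and
#' configuration.
#'
#' @param config a [cohortConfig()]
#' @param seed integer seed
#' @return list of class `SyntheticCohort`: `mutations`
#'   ([MutationTable-class], all samples), `reference` (DNAStringSet, one
#'   private chromosome per tumor sample), `beta` ([BetaSet-class]),
#'   `intensities` (matrix), `manifest`, `catalog`
#'   ([SignatureCatalog-class]), `config`, `truth` (list: `pairIds`,
#'   `tumorIds`, `nom`, `z`, `dmpFraction`, `exposures`, `arms`)
#' @export
simulateCohort <- function(config = cohortConfig(), seed = 1) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(seed)
  nPairs <- config$nPairs
  pairIds <- paste0("P", formatC(seq_len(nPairs), width = 2, flag = "0"))
  tumorIds <- paste0(pairIds, "_T")
  ## catalogue: one uniform-block signature per exposure-profile column
  catalog <- syntheticSignatures(ncol(config$exposureProfiles))
  nomTarget <- pmax(5, round(rlnorm(nPairs, config$tmbLogMean,
                                    config$tmbLogSd)))
  stratum <- ifelse(nomTarget > median(nomTarget), "high", "low")
  expTruth <- config$exposureProfiles[stratum, , drop = FALSE]
  rownames(expTruth) <- tumorIds
  yield <- config$nonsynFraction * (1 - config$filterFailFraction)
  mutList <- vector("list", nPairs)
  refList <- character(nPairs)
  for (i in seq_len(nPairs)) {
    sim <- .simulateSampleMutations(round(nomTarget[i] / yield),
                                    expTruth[i, ], catalog, tumorIds[i],
                                    config$nonsynFraction,
                                    config$filterFailFraction,
                                    config$indelFraction)
    mutList[[i]] <- sim$mutations
    refList[i] <- sim$reference
  }
  names(refList) <- paste0("synth_", tumorIds)
  mutations <- MutationTable(do.call(rbind, mutList))
  filt <- filterSomatic(mutations)
  nom <- .nomBySample(filt, tumorIds)
  z <- as.vector(scale(log(nom)))
  if (any(!is.finite(z))) z <- rep(0, nPairs)   # degenerate: equal NOMs
  dmpFraction <- .clamp(config$dmpBase + config$couplingDmp * z,
                        config$dmpClamp[1], config$dmpClamp[2])
  nAneu <- .clamp(round(config$armBase + config$couplingArms * z),
                  0, config$nArms)
  manifest <- syntheticManifest(config$nProbes, config$nArms)
  armNames <- unique(manifest$arm)
  arms <- matrix(0L, nPairs, config$nArms,
                 dimnames = list(tumorIds, armNames))
  for (i in seq_len(nPairs)) {
    if (nAneu[i] > 0) {
      which_ <- sample.int(config$nArms, nAneu[i])
      arms[i, which_] <- ifelse(runif(nAneu[i]) < 0.5, -1L, 1L)
    }
  }
  truth <- list(pairIds = pairIds, tumorIds = tumorIds, nom = nom, z = z,
                dmpFraction = setNames(dmpFraction, pairIds),
                exposures = expTruth, arms = arms)
  beta <- simulateMethylation(truth, config, manifest)
  intensities <- simulateIntensities(truth, config, manifest)
  structure(list(mutations = mutations,
                 reference = DNAStringSet(refList),
                 beta = beta, intensities = intensities,
                 manifest = manifest, catalog = catalog,
                 config = config, truth = truth),
            class = "SyntheticCohort")
}
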