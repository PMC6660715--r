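test_that("mutation simulation respects the exposure mixture", {
  zero <- simulateMutations(0, c(0.5, 0.5), toyCatalog2(), seed = 1)
  expect_equal(length(zero$mutations), 0L)

  sim <- simulateMutations(10000, c(1, 0), toyCatalog2(), seed = 2,
                           indelFraction = 0)
  spec <- buildSpectrum(sim$mutations, sim$reference)
  f <- spec / sum(spec)
  s1 <- signatureMatrix(toyCatalog2())[, 1]
  tv <- 0.5 * sum(abs(f - s1))
  expect_lt(tv, 0.05)

  expect_error(simulateMutations(10, c(0.6, 0.6), toyCatalog2()),
               "sum to 1")
})

test_that("the engineered filter-failure fraction shows up in filtering", {
  sim <- simulateMutations(1000, c(0.5, 0.5), toyCatalog2(), seed = 3)
  kept <- length(filterSomatic(sim$mutations))
  # Binomial(1000, 0.8): 800 +/- 4 sd
  expect_gt(kept, 800 - 4 * sqrt(1000 * 0.8 * 0.2))
  expect_lt(kept, 800 + 4 * sqrt(1000 * 0.8 * 0.2))
  # every record marked as failing violates at least one criterion
  df <- mutData(sim$mutations)
  failing <- !(df$depth >= 10 & df$af >= 0.05 & df$alt_reads >= 3)
  expect_equal(1000 - kept, sum(failing))
})

test_that("shifted-probe counts track the configured dmp fraction", {
  cfg <- cohortConfig(nPairs = 3, nProbes = 10000)
  truth0 <- list(pairIds = c("P01", "P02", "P03"),
                 dmpFraction = c(0, 0, 0))
  bs0 <- simulateMethylation(truth0, cfg, syntheticManifest(10000, 10),
                             seed = 5)
  for (p in truth0$pairIds)
    expect_equal(perSampleDmpCount(bs0, p), 0L)

  truth3 <- list(pairIds = c("P01", "P02", "P03"),
                 dmpFraction = c(0.3, 0.3, 0.3))
  bs3 <- simulateMethylation(truth3, cfg, syntheticManifest(10000, 10),
                             seed = 6)
  tol <- 4 * sqrt(10000 * 0.3 * 0.7)
  for (p in truth3$pairIds) {
    cnt <- perSampleDmpCount(bs3, p)
    expect_gt(cnt, 3000 - tol - 20)
    expect_lt(cnt, 3000 + tol + 20)
  }
})

test_that("a hypomethylation bias of one shifts every probe downward", {
  cfg <- cohortConfig(nPairs = 2, nProbes = 3000, hypoBias = 1)
  truth <- list(pairIds = c("P01", "P02"), dmpFraction = c(0.2, 0.2))
  bs <- simulateMethylation(truth, cfg, syntheticManifest(3000, 6),
                            seed = 7)
  shifted <- S4Vectors::metadata(bs)$shifted
  b <- betaValues(bs)
  for (p in names(shifted)) {
    cols <- pairColumns(bs, p)
    delta <- b[, cols["tumor"]] - b[, cols["normal"]]
    expect_true(all(delta[shifted[[p]]$idx] < 0))
    expect_true(all(shifted[[p]]$direction == "hypo"))
  }
})

test_that("intensity simulation encodes arm events as log ratios", {
  cfg <- cohortConfig(nPairs = 2, nProbes = 2000, nArms = 4,
                      intensityNoiseSd = 0.05)
  man <- local({ set.seed(8); syntheticManifest(2000, 4) })
  arms <- matrix(0L, 2, 4,
                 dimnames = list(c("P01_T", "P02_T"), unique(man$arm)))
  arms["P01_T", 2] <- 1L        # one gained arm in the first tumor
  truth <- list(pairIds = c("P01", "P02"), tumorIds = c("P01_T", "P02_T"),
                arms = arms)
  int <- simulateIntensities(truth, cfg, man, seed = 9)
  gained <- colnames(arms)[2]
  onArm <- man$arm == gained
  ref <- rowMeans(int[, c("P01_N", "P02_N")])
  lrGain <- mean(log2(int[onArm, "P01_T"] / ref[onArm]))
  expect_equal(lrGain, log2(1.5), tolerance = 0.05)
  lrNeutral <- mean(log2(int[!onArm, "P01_T"] / ref[!onArm]))
  expect_equal(lrNeutral, 0, tolerance = 0.05)
  lrOther <- mean(abs(log2(int[, "P02_T"] / ref)))
  expect_lt(mean(log2(int[onArm, "P02_T"] / ref[onArm])), 0.05)
  # fixed seed reproduces bit-identically
  int2 <- simulateIntensities(truth, cfg, man, seed = 9)
  expect_identical(int, int2)
})

test_that("a full cohort is bit-identical under the same seed and differs across seeds", {
  cfg <- cohortConfig(nPairs = 5, nProbes = 1500, nArms = 6)
  a <- simulateCohort(cfg, seed = 10)
  b <- simulateCohort(cfg, seed = 10)
  expect_identical(a, b)
  c <- simulateCohort(cfg, seed = 11)
  expect_false(identical(betaValues(a$beta), betaValues(c$beta)))
  # truth NOM equals the recoverable filtered nonsynonymous count
  filt <- filterSomatic(a$mutations)
  for (s in a$truth$tumorIds)
    expect_equal(computeNom(filt, s), unname(a$truth$nom[s]))
  # truth dimensions are consistent
  expect_length(a$truth$dmpFraction, 5)
  expect_equal(dim(a$truth$arms), c(5, 6))
  expect_equal(rowSums(a$truth$exposures), rep(1, 5), ignore_attr = TRUE)
})

test_that("the hypomethylation bias is reflected in cohort-level MVP calls", {
  co <- simulateCohort(cohortConfig(nPairs = 10, nProbes = 6000), seed = 12)
  sh <- sampleSheet(co$beta)
  res <- classifyMvp(cohortDmpTest(co$beta))
  nHypo <- sum(res$status == "hypo")
  nHyper <- sum(res$status == "hyper")
  expect_gt(nHypo, nHyper)   # hypoBias = 0.7 biases losses
})
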