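test_that("per-sample DMP counting is strict, pairwise, and monotone in the threshold", {
  normal <- matrix(0.25, 10, 1)
  shift <- matrix(0, 10, 1); shift[1:3, 1] <- 0.25   # exact dyadic delta
  bs <- makeBetaSet(normal, shift)
  expect_equal(perSampleDmpCount(bs, "P01"), 3L)
  expect_equal(perSampleDmpCount(bs, "P01", deltaThr = 0.25), 0L) # strict >
  expect_equal(perSampleDmpCount(bs, "P01", deltaThr = 0), 3L)
  same <- makeBetaSet(normal)
  expect_equal(perSampleDmpCount(same, "P01"), 0L)
  expect_error(perSampleDmpCount(bs, "P99"), "unknown pair")
  # monotone nonincreasing in the threshold
  set.seed(2)
  noisy <- makeBetaSet(matrix(runif(200), 100, 2),
                       matrix(rnorm(200, 0, 0.2), 100, 2))
  thr <- c(0, 0.1, 0.2, 0.3, 0.5)
  counts <- vapply(thr, function(t) perSampleDmpCount(noisy, "P01", t),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("BH adjustment matches the step-up oracle on permuted inputs", {
  expect_equal(bhAdjust(0.03), 0.03)                       # m = 1
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  for (i in 1:6) {
    p <- runif(6)
    for (j in 1:10) {
      perm <- sample(p)
      expect_equal(bhAdjust(perm), bhOracle(perm), tolerance = 1e-12)
    }
  }
})

test_that("cohort test matches per-probe Welch t and flags no NaN on flat probes", {
  set.seed(3)
  normal <- matrix(runif(40, 0.3, 0.7), 10, 4)
  shift <- matrix(0, 10, 4); shift[2, ] <- 0.5   # one strongly shifted probe
  bs <- makeBetaSet(normal, shift)
  sh <- sampleSheet(bs)
  res <- cohortDmpTest(bs)
  # row-by-row agreement with stats::t.test
  b <- betaValues(bs)
  tu <- sh$sample_id[sh$tissue == "tumor"]
  no <- sh$sample_id[sh$tissue == "normal"]
  for (i in c(1, 2, 7)) {
    tt <- t.test(b[i, tu], b[i, no])
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(res$delta_beta[i], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-12)
  }
  expect_equal(res$adj_p, bhOracle(res$p), tolerance = 1e-12)
  expect_true(res$significant[2])
  expect_equal(sum(res$significant), 1)

  flat <- makeBetaSet(matrix(0.4, 3, 2))
  resFlat <- cohortDmpTest(flat)
  expect_false(anyNA(resFlat$p))
  expect_equal(resFlat$p, rep(1, 3))
  expect_error(cohortDmpTest(makeBetaSet(matrix(0.4, 3, 1))), "at least 2")
})

test_that("single-probe matrices leave BH untouched (m = 1)", {
  set.seed(4)
  bs <- makeBetaSet(matrix(runif(4, 0.2, 0.8), 1, 4))
  res <- cohortDmpTest(bs)
  expect_equal(res$adj_p, res$p)
})

test_that("MVP classification applies both thresholds with correct signs", {
  rec <- data.frame(probe_id = c("a", "b", "c", "d", "e"),
                    delta_beta = c(0.25, -0.25, 0.15, 0.25, -0.21),
                    adj_p = c(0.001, 0.001, 1e-9, 0.02, 0.009))
  out <- classifyMvp(rec)
  expect_equal(as.character(out$status),
               c("hyper", "hypo", "ns", "ns", "hypo"))
})

test_that("bump hunting respects the minimum run length and the gap rule", {
  man <- makeManifest(30, spacing = 100L)
  normal <- matrix(0.5, 30, 8)
  shift <- matrix(0, 30, 8)
  shift[10, ] <- 0.4                 # isolated qualifying probe: no DMR
  shift[15:19, ] <- 0.3              # 5-probe run within 100-bp spacing
  bs <- makeBetaSet(normal, shift, manifest = man)
  dmrs <- findDmrs(bs, nPerm = 50, seed = 1)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$n_probes, 5)
  expect_equal(c(dmrs$start, dmrs$end), c(1500, 1900))

  # two runs separated by a 5-kb gap are never merged
  man2 <- makeManifest(10, spacing = 100L)
  man2$pos[6:10] <- man2$pos[6:10] + 5000L
  shift2 <- matrix(0.3, 10, 4)
  bs2 <- makeBetaSet(matrix(0.5, 10, 4), shift2, manifest = man2)
  dmrs2 <- findDmrs(bs2, nPerm = 50, pCutoff = 1, seed = 1)
  expect_equal(nrow(dmrs2), 2)
  expect_equal(dmrs2$n_probes, c(5, 5))

  # unsorted manifest is rejected
  man3 <- makeManifest(10)[c(2, 1, 3:10), ]
  expect_error(makeBetaSet(matrix(0.5, 10, 4), manifest = man3) |>
                 findDmrs(), "sorted")
})

test_that("bump boundaries agree with the brute-force run finder on random toys", {
  set.seed(21)
  for (i in 1:10) {
    n <- 200
    man <- makeManifest(n, spacing = 1L)
    man$pos <- cumsum(sample(c(100L, 900L, 2000L), n, replace = TRUE))
    delta <- rnorm(n, 0, 0.25)
    normal <- matrix(0.5, n, 2)
    bs <- makeBetaSet(normal, cbind(delta, delta), manifest = man)
    got <- findDmrs(bs, nPerm = 2, pCutoff = 1, seed = i)
    # clipping to [0, 1] caps the realized tumor-normal difference
    eff <- pmin(pmax(0.5 + delta, 0), 1) - 0.5
    want <- runsOracle(eff, man$chrom, man$pos, 0.2, 1000, 3)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[, c("chrom", "start", "end", "n_probes")],
                   want[, c("chrom", "start", "end", "n_probes")],
                   ignore_attr = TRUE)
      expect_equal(got$score, want$score, tolerance = 1e-9)
    }
  }
})

test_that("informative-probe screen needs separation, tightness and significance", {
  set.seed(8)
  nProbes <- 20
  nPairs <- 8                       # 4 high, 4 low
  normal <- matrix(runif(nProbes * nPairs, 0.25, 0.45), nProbes, nPairs)
  shift <- matrix(rnorm(nProbes * nPairs, 0, 0.01), nProbes, nPairs)
  shift[1, 1:4] <- 0.4 + rnorm(4, 0, 0.02)   # separates, tight: selected
  spread <- c(-0.2, -0.07, 0.07, 0.2)        # within-group s.d. ~0.17
  shift[2, 1:4] <- 0.3 + spread              # separates but loose in both
  shift[2, 5:8] <- spread                    # groups: excluded
  bs <- makeBetaSet(normal, shift)
  pairs <- sprintf("P%02d", 1:8)
  sel <- selectInformativeProbes(bs, pairs[1:4], pairs[5:8])
  expect_true("cg00001" %in% sel)
  expect_false("cg00002" %in% sel)
  # constant matrix selects nothing
  flat <- makeBetaSet(matrix(0.5, 5, 8))
  expect_length(selectInformativeProbes(flat, pairs[1:4], pairs[5:8]), 0)
  expect_error(selectInformativeProbes(bs, pairs[1], pairs[5:8]),
               "at least 2")
})

test_that("consensus clustering separates well-separated blocks and is seeded", {
  set.seed(12)
  blobs <- rbind(matrix(rnorm(40, 0, 0.1), 8, 5),
                 matrix(rnorm(40, 10, 0.1), 8, 5))
  rownames(blobs) <- paste0("s", 1:16)
  res <- consensusCluster(blobs, k = 2, nResample = 50, seed = 4)
  expect_true(isSymmetric(res$consensus))
  expect_equal(unname(diag(res$consensus)), rep(1, 16))
  truth <- rep(1:2, each = 8)
  # perfect agreement up to label switching
  expect_equal(length(unique(res$assignments[1:8])), 1)
  expect_equal(length(unique(res$assignments[9:16])), 1)
  expect_false(res$assignments[1] == res$assignments[16])
  # block consensus is 0/1
  expect_true(all(res$consensus[1:8, 1:8] == 1))
  expect_true(all(res$consensus[1:8, 9:16] == 0))
  res2 <- consensusCluster(blobs, k = 2, nResample = 50, seed = 4)
  expect_identical(res, res2)
  expect_error(consensusCluster(blobs[1:3, ], k = 4), "k exceeds|at least")
})

test_that("promoter mapping includes genes with more than 3 promoter MVPs", {
  man <- data.frame(probe_id = sprintf("cg%02d", 1:12),
                    chrom = "chr01", pos = 1:12 * 100,
                    gene = rep(c("GA", "GB", "GC"), each = 4),
                    feature = c(rep("TSS200", 4),         # GA: promoter
                                rep("TSS1500", 3), "Body", # GB: 3 promoter
                                rep("Body", 4)),           # GC: body only
                    arm = "01p")
  mvps <- data.frame(probe_id = sprintf("cg%02d", 1:12),
                     status = factor(rep("hypo", 12),
                                     levels = c("hyper", "hypo", "ns")))
  out <- mapPromoterGenes(mvps, man, minMvp = 4)
  expect_equal(out$gene, "GA")
  expect_equal(out$n_promoter_mvps, 4L)
})

test_that("TSS offsets split by status and compare by rank-sum", {
  man <- data.frame(probe_id = paste0("cg", 1:6),
                    chrom = "chr01", pos = c(0, 10, 50, 500, 800, 1200),
                    gene = "G", feature = "TSS200", arm = "01p",
                    tss = 0)
  mvps <- data.frame(probe_id = paste0("cg", 1:6),
                     status = factor(c("hyper", "hyper", "hyper",
                                       "hypo", "hypo", "hypo"),
                                     levels = c("hyper", "hypo", "ns")))
  out <- tssOffsetSummary(mvps, man)
  expect_equal(out$offsets$offset, c(0, 10, 50, 500, 800, 1200))
  wt <- wilcox.test(c(0, 10, 50), c(500, 800, 1200))
  expect_equal(out$test$p, wt$p.value)
  # probe exactly at the TSS has offset zero
  expect_equal(out$offsets$offset[1], 0)
  expect_error(tssOffsetSummary(mvps, man[, -7]), "tss")
  # identical offset sets give p = 1
  man2 <- man; man2$pos <- rep(c(5, 10, 20), 2)
  out2 <- tssOffsetSummary(mvps, man2)
  expect_equal(out2$test$p, 1)
})
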