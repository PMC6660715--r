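toyRef <- function() {
  Biostrings::DNAStringSet(c(chrT = "ATGCATGCATGCATGCATGC"))
}

test_that("spectrum folds purine-reference calls onto the pyrimidine strand", {
  # G>A at context TGC is the reverse strand of C>T at GCA: "G[C>T]A"
  df <- mutRow("S1", chrom = "chrT", pos = 3L, ref = "G", alt = "A")
  spec <- buildSpectrum(MutationTable(df), toyRef())
  expect_equal(sum(spec), 1)
  expect_equal(unname(spec["G[C>T]A"]), 1)
})

test_that("hand-placed mutations on a toy reference produce the hand-built spectrum", {
  df <- rbind(
    mutRow("S1", chrom = "chrT", pos = 2L, ref = "T", alt = "C"),
    mutRow("S1", chrom = "chrT", pos = 3L, ref = "G", alt = "A"),
    mutRow("S1", chrom = "chrT", pos = 6L, ref = "T", alt = "G"),
    mutRow("S1", chrom = "chrT", pos = 8L, ref = "C", alt = "G"))
  spec <- buildSpectrum(MutationTable(df), toyRef())
  expect_equal(sum(spec), 4)
  expect_equal(unname(spec[c("A[T>C]G", "G[C>T]A", "A[T>G]G", "G[C>G]A")]),
               rep(1, 4))
})

test_that("empty tables give all-zero spectra and indels are skipped with a count", {
  expect_equal(sum(buildSpectrum(MutationTable(mutRow()[0, ]), toyRef())), 0)
  df <- rbind(mutRow("S1", chrom = "chrT", pos = 2L, ref = "T", alt = "C"),
              mutRow("S1", chrom = "chrT", pos = 6L, ref = "T", alt = "TA"))
  expect_message(spec <- buildSpectrum(MutationTable(df), toyRef()),
                 "1 non-SNV")
  expect_equal(sum(spec), 1)
})

test_that("reference mismatches are reported with their position", {
  df <- mutRow("S1", chrom = "chrT", pos = 2L, ref = "C", alt = "A")
  expect_error(buildSpectrum(MutationTable(df), toyRef()),
               "mismatch at chrT:2")
})

test_that("spectrum is invariant under reverse-complementing the whole assay", {
  set.seed(11)
  sim <- simulateMutations(300, c(0.5, 0.5), toyCatalog2(), "S1",
                           indelFraction = 0)
  fwd <- buildSpectrum(sim$mutations, sim$reference)
  L <- nchar(as.character(sim$reference)[[1]])
  rcRef <- Biostrings::reverseComplement(sim$reference)
  names(rcRef) <- names(sim$reference)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  df <- mutData(sim$mutations)
  df$pos <- L - df$pos + 1L
  df$ref <- unname(comp[df$ref])
  df$alt <- unname(comp[df$alt])
  rev <- buildSpectrum(MutationTable(df), rcRef)
  expect_equal(rev, fwd)
})

test_that("context census matches a direct sliding-window count", {
  expect_equal(unname(censusContexts("ACA")["ACA"]), 1L)
  expect_equal(sum(censusContexts("ACA")), 1L)
  # purine-centered windows collapse onto their reverse complement
  polyA <- censusContexts("AAAAAA")
  expect_equal(unname(polyA["TTT"]), 4L)
  expect_equal(sum(polyA), 4L)
  set.seed(5)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
               collapse = "")
    expect_equal(censusContexts(s), censusOracle(s))
  }
})

test_that("census-based normalization has the self-normalization identity", {
  set.seed(9)
  spec <- setNames(rpois(96, 3), mutationContexts())
  for (i in 1:5) {
    census <- setNames(rpois(32, 50) + 1L, pyrimidineContexts())
    out <- normalizeSpectrum(spec, census, census)
    expect_equal(out, spec / sum(spec), tolerance = 1e-12)
  }
})

test_that("normalization rescales by target/observed context frequency", {
  spec <- setNames(numeric(96), mutationContexts())
  spec["A[C>A]A"] <- 4   # trinucleotide ACA
  spec["C[C>G]A"] <- 6   # trinucleotide CCA
  observed <- setNames(integer(32), pyrimidineContexts())
  observed[c("ACA", "CCA")] <- c(1L, 3L)
  target <- setNames(integer(32), pyrimidineContexts())
  target[c("ACA", "CCA")] <- c(1L, 1L)
  out <- normalizeSpectrum(spec, observed, target)
  # ratios 2 and 2/3 scale (4, 6) to (8, 4), renormalized to (2/3, 1/3)
  expect_equal(unname(out[c("A[C>A]A", "C[C>G]A")]), c(2 / 3, 1 / 3))
  expect_error(normalizeSpectrum(spec, target * 0L, target), "zero")
})

test_that("exposure refitting recovers pure and mixed signatures exactly", {
  cat2 <- toyCatalog2()
  S <- signatureMatrix(cat2)
  pure <- fitExposures(S[, 1], cat2)
  expect_equal(unname(pure$weights), c(1, 0), tolerance = 1e-9)
  expect_lt(pure$residual, 1e-9)

  mix <- 0.7 * S[, 1] + 0.3 * S[, 2]
  fit <- fitExposures(mix, cat2)
  expect_equal(unname(fit$weights), c(0.7, 0.3), tolerance = 1e-6)
  grid <- nnlsGridOracle(S, mix, by = 0.01)
  expect_equal(unname(fit$weights), grid, tolerance = 0.01)
})

test_that("mass outside the catalogue becomes residual and small weights prune", {
  s3 <- matrix(0, 96, 2, dimnames = list(mutationContexts(), c("A", "B")))
  s3[1:32, 1] <- 1 / 32
  s3[33:64, 2] <- 1 / 32
  cat3 <- SignatureCatalog(s3)
  orth <- setNames(numeric(96), mutationContexts())
  orth[65:96] <- 1 / 32
  fit <- fitExposures(orth, cat3)
  expect_equal(sum(fit$weights), 0)
  expect_equal(fit$residual, 1)

  nearPure <- 0.96 * signatureMatrix(toyCatalog2())[, 1] +
    0.04 * signatureMatrix(toyCatalog2())[, 2]
  pruned <- fitExposures(nearPure, toyCatalog2(), pruneBelow = 0.06)
  expect_equal(unname(pruned$weights), c(1, 0), tolerance = 1e-6)

  expect_error(fitExposures(numeric(96), toyCatalog2()), "no mutations")
})

test_that("exposure clustering is average linkage with deterministic merges", {
  w <- rbind(a = c(0, 0), b = c(3, 0), c = c(0, 4))
  hc <- clusterExposures(w)
  expect_equal(hc$height, c(3, 4.5))
  dup <- rbind(x = c(1, 1), y = c(1, 1), z = c(9, 9))
  expect_equal(clusterExposures(dup)$height[1], 0)
  expect_error(clusterExposures(w[1, , drop = FALSE]), "at least 2")
})
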