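# Small fixture builders shared across test files. Everything is generated
# in code; nothing is read from disk except through tempfiles the tests
# themselves write.

mutRow <- function(sample_id = "S1", chrom = "chr1", pos = 10L,
                   ref = "C", alt = "T", variant_class = "nonsynonymous",
                   depth = 100L, alt_reads = 20L, af = 0.2) {
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, variant_class = variant_class, depth = depth,
             alt_reads = alt_reads, af = af)
}

tmpTsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# paired beta fixture: nPairs tumor/normal pairs over the given matrix of
# normals; `shift` is a probes x pairs matrix added to the tumor columns
makeBetaSet <- function(normalBeta, shift = NULL, manifest = NULL) {
  nProbes <- nrow(normalBeta)
  nPairs <- ncol(normalBeta)
  if (is.null(shift)) shift <- matrix(0, nProbes, nPairs)
  pairIds <- sprintf("P%02d", seq_len(nPairs))
  ids <- as.vector(rbind(paste0(pairIds, "_T"), paste0(pairIds, "_N")))
  beta <- matrix(NA_real_, nProbes, 2 * nPairs)
  for (i in seq_len(nPairs)) {
    beta[, 2 * i - 1] <- pmin(pmax(normalBeta[, i] + shift[, i], 0), 1)
    beta[, 2 * i] <- normalBeta[, i]
  }
  colnames(beta) <- ids
  rownames(beta) <- if (!is.null(manifest)) manifest$probe_id
                    else sprintf("cg%05d", seq_len(nProbes))
  sheet <- data.frame(sample_id = ids,
                      pair_id = rep(pairIds, each = 2),
                      tissue = rep(c("tumor", "normal"), nPairs))
  BetaSet(beta, sheet, manifest = manifest)
}

# minimal sorted manifest on one or more chromosomes
makeManifest <- function(nProbes, chrom = "chr01", spacing = 100L,
                         arm = NULL, feature = "Body", gene = "") {
  if (is.null(arm)) arm <- paste0(sub("^chr", "", chrom), "p")
  data.frame(probe_id = sprintf("cg%05d", seq_len(nProbes)),
             chrom = rep(chrom, length.out = nProbes),
             pos = seq_len(nProbes) * spacing,
             gene = rep(gene, length.out = nProbes),
             feature = rep(feature, length.out = nProbes),
             arm = rep(arm, length.out = nProbes))
}

# two-signature toy catalogue concentrated on disjoint context blocks
toyCatalog2 <- function() {
  s <- matrix(0, 96, 2, dimnames = list(mutationContexts(), c("A", "B")))
  s[1:48, 1] <- 1 / 48
  s[49:96, 2] <- 1 / 48
  SignatureCatalog(s)
}
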