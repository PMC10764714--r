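# Builders and independent oracles shared across the test files.
# All fixtures are generated in code; nothing is read from disk except
# files the tests themselves write to tempdir().

suppressMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

testRanges <- function(n, chrom = "1", ref = "A", alt = "G") {
  GRanges(chrom, IRanges(seq_len(n) * 100L, width = 1L),
          ref = rep_len(ref, n), alt = rep_len(alt, n))
}

# build an ImputedGenotypes from a list of per-variant trio matrices
# (rows = samples) or from three matrices
makeImputed <- function(p0, p1, p2, samples = NULL, source = "test",
                        ranges = NULL) {
  p0 <- as.matrix(p0); p1 <- as.matrix(p1); p2 <- as.matrix(p2)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(p0)))
  if (is.null(ranges)) ranges <- testRanges(nrow(p0))
  ImputedGenotypes(p0, p1, p2, ranges, samples = samples, source = source)
}

makeTruth <- function(calls, samples = NULL, ranges = NULL) {
  calls <- as.matrix(calls)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(calls)))
  if (is.null(ranges)) ranges <- testRanges(nrow(calls))
  TruthGenotypes(calls, ranges, samples = samples)
}

# point-mass posteriors exactly reproducing a call matrix
pointMassImputed <- function(calls, samples = NULL, ranges = NULL) {
  toP <- function(k) {
    m <- (calls == k) * 1.0
    m[is.na(calls)] <- NA_real_
    m
  }
  makeImputed(toP(0), toP(1), toP(2), samples = samples, ranges = ranges)
}

# independent Cohen's-kappa oracle: explicit double loops, no margin
# vectorisation shared with the implementation under test
naiveKappa <- function(tab) {
  N <- 0
  for (j in 1:3) for (k in 1:3) N <- N + tab[j, k]
  po <- 0
  for (j in 1:3) po <- po + tab[j, j] / N
  pc <- 0
  for (j in 1:3) {
    rj <- 0; cj <- 0
    for (k in 1:3) {
      rj <- rj + tab[j, k]
      cj <- cj + tab[k, j]
    }
    pc <- pc + (rj / N) * (cj / N)
  }
  (po - pc) / (1 - pc)
}

# random fractional 3x3 table with positive mass
randomFractionalTable <- function() {
  tab <- matrix(stats::runif(9, 0, 10), 3, 3)
  attr(tab, "n") <- 9L
  tab
}

# write a small VCF with arbitrary FORMAT cells
writeTestVcf <- function(path, fix, cells, format = "GT:GP",
                         samples = paste0("s", seq_len(ncol(cells)))) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype probabilities\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- apply(cbind(fix, format, cells), 1, paste, collapse = "\t")
  writeLines(c(header, body), path)
  path
}

# a tiny seed-phasing set built directly from haplotype-A bit matrices
# (all sites heterozygous); bits: list of K matrices (sites x samples)
phasingFromBits <- function(bits) {
  K <- length(bits)
  d <- dim(bits[[1]])
  hapA <- array(NA_integer_, c(d[1], d[2], K))
  for (k in seq_len(K)) hapA[, , k] <- bits[[k]]
  SeedPhasingSet(hapA, 1L - hapA, seeds = seq_len(K))
}
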