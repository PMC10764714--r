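test_that("truth VCF parsing maps diploid calls and computes MAF", {
  path <- tempfile(fileext = ".vcf")
  fix <- cbind("1", c("100", "200"), ".", c("A", "C"), c("G", "T"),
               ".", ".", ".")
  # 4 samples, variant 1 calls 0,0,1,2 -> alt freq 3/8; variant 2 has a
  # missing and a half-missing call excluded from the MAF denominator
  cells <- rbind(c("0/0", "0|0", "0/1", "1/1"),
                 c("./.", "./1", "0/1", "0/0"))
  writeTestVcf(path, fix, cells, format = "GT",
               samples = paste0("s", 1:4))
  tr <- readTruthVcf(path)
  expect_equal(unname(genotypeCalls(tr)[1, ]), c(0L, 0L, 1L, 2L))
  expect_equal(unname(genotypeCalls(tr)[2, ]), c(NA, NA, 1L, 0L))
  expect_equal(unname(mafValues(tr)), c(3 / 8, 1 / 4))
  expect_equal(unname(macValues(tr)), c(3L, 1L))

  # haploid calls are a record-level error
  writeTestVcf(path, fix[1, , drop = FALSE],
               matrix(c("0", "1", "0/1", "0/0"), 1), format = "GT",
               samples = paste0("s", 1:4))
  expect_error(readTruthVcf(path), "non-diploid")
})

test_that("imputed VCF parsing keeps trios honest", {
  path <- tempfile(fileext = ".vcf")
  fix <- cbind("1", c("100", "200", "300", "400"), ".",
               c("A", "C", "G", "T"), c("G", "T,A", "A", "C"),
               ".", ".", ".")
  cells <- rbind(
    c("0/0:0.95,0.05,0.00", "0/1:0.33,0.33,0.33"),   # worked trio; renorm
    c("0/0:1,0,0", "0/0:1,0,0"),                     # multiallelic: dropped
    c("./.:.", "0/0:0.5,0.45,0"),                    # missing; bad sum
    c("0/1:0.1,0.8,0.1", "1/1:0,0.2,0.8"))
  writeTestVcf(path, fix, cells, format = "GT:GP", samples = c("s1", "s2"))
  expect_warning(imp <- readImputedVcf(path), "deviating")

  expect_equal(nrow(imp), 3L)  # multiallelic record excluded
  qc <- metadata(imp)$qc
  expect_equal(qc$n_excluded_multiallelic, 1L)
  expect_equal(qc$n_bad_sum_set_missing, 1L)
  expect_gte(qc$n_renormalized, 1L)

  expect_equal(unname(assay(imp, "p0")[1, "s1"]), 0.95)
  expect_equal(unname(gpArgmax(imp)[1, "s1"]), 0L)
  # renormalized trio sums to 1 within 1e-4
  s <- assay(imp, "p0") + assay(imp, "p1") + assay(imp, "p2")
  expect_true(all(abs(s - 1) < 1e-4, na.rm = TRUE))
  # missing entry and bad-sum entry are fully missing
  expect_true(is.na(assay(imp, "p0")["1:300_G/A", "s1"]))
  expect_true(is.na(assay(imp, "p0")["1:300_G/A", "s2"]))

  # absent probability field is a configuration error
  expect_error(readImputedVcf(path, gpField = "GX"), "configuration")
})

test_that("region filtering restricts to the 1-based inclusive window", {
  path <- tempfile(fileext = ".vcf")
  fix <- cbind("1", c("100", "200", "300"), ".", "A", "G", ".", ".", ".")
  cells <- matrix("0/0:1,0,0", 3, 1)
  writeTestVcf(path, fix, cells, samples = "s1")
  imp <- readImputedVcf(path, region = "1:100-200")
  expect_equal(nrow(imp), 2L)
})

test_that("write/read round trip preserves keys, samples and trios", {
  set.seed(2)
  sc <- simulateScenario(nVariants = 50, nPerGroup = 4, seed = 2)
  run <- sc$runA
  for (ext in c(".vcf", ".vcf.gz")) {
    path <- tempfile(fileext = ext)
    writeImputedVcf(run, path)
    back <- readImputedVcf(path, source = sourceLabel(run))
    expect_identical(rownames(back), rownames(run))
    expect_identical(colnames(back), colnames(run))
    for (ay in c("p0", "p1", "p2"))
      expect_equal(assay(back, ay), assay(run, ay), tolerance = 1e-4)
  }
})

test_that("written records carry dosage p1 + 2 p2 and argmax hard calls", {
  p0 <- matrix(c(0.2, 1), 2, 1); p1 <- matrix(c(0.5, 0), 2, 1)
  p2 <- matrix(c(0.3, 0), 2, 1)
  run <- makeImputed(p0, p1, p2)
  path <- tempfile(fileext = ".vcf")
  writeImputedVcf(run, path)
  lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  cell1 <- strsplit(strsplit(lines[1], "\t")[[1]][10], ":")[[1]]
  expect_identical(cell1[1], "0/1")          # argmax of (0.2, 0.5, 0.3)
  expect_equal(as.numeric(cell1[3]), 1.1)    # 0.5 + 2 * 0.3
  cell2 <- strsplit(strsplit(lines[2], "\t")[[1]][10], ":")[[1]]
  expect_identical(cell2[1], "0/0")
  expect_equal(as.numeric(cell2[3]), 0)
})

test_that("alignment matches exact keys and reports union and intersection", {
  callsA <- matrix(0L, 4, 2); callsB <- matrix(0L, 3, 2)
  a <- pointMassImputed(callsA, ranges = testRanges(4))
  rangesB <- GRanges("1", IRanges(c(200, 300, 900), width = 1),
                     ref = "A", alt = "G")
  b <- pointMassImputed(callsB, ranges = rangesB)
  al <- alignRuns(a, b)
  expect_length(al$intersection, 2)
  expect_length(al$union, 4 + 3 - 2)
  expect_true(all(al$intersection %in% rownames(a)))
  # key only in a is in the union but not the intersection
  expect_true("1:100_A/G" %in% al$union)
  expect_false("1:100_A/G" %in% al$intersection)
})

test_that("ref/alt swapped keys reconcile by trio reversal when opted in", {
  a <- pointMassImputed(matrix(0L, 1, 1),
                        ranges = GRanges("1", IRanges(500, width = 1),
                                         ref = "A", alt = "G"))
  p <- c(0.1, 0.2, 0.7)
  b <- makeImputed(matrix(p[1], 1, 1), matrix(p[2], 1, 1),
                   matrix(p[3], 1, 1),
                   ranges = GRanges("1", IRanges(500, width = 1),
                                    ref = "G", alt = "A"))
  # conservative default: no match
  expect_length(alignRuns(a, b)$intersection, 0)
  al <- alignRuns(a, b, matchSwaps = TRUE)
  expect_length(al$intersection, 1)
  expect_equal(al$swapped, "1:500_A/G")
  expect_equal(unname(assay(al$b, "p0")[1, 1]), 0.7)
  expect_equal(unname(assay(al$b, "p2")[1, 1]), 0.1)
  # applying the reversal twice is the identity
  al2 <- alignRuns(a, al$b, matchSwaps = TRUE)
  expect_length(al2$swapped, 0)
  expect_equal(assay(al2$b, "p0"), assay(al$b, "p0"))
})

test_that("empty sample intersection is an error", {
  a <- pointMassImputed(matrix(0L, 2, 1), samples = "x1")
  b <- pointMassImputed(matrix(0L, 2, 1), samples = "y1")
  expect_error(alignRuns(a, b), "sample intersection")
})

test_that("BED regions convert to 1-based inclusive coordinates", {
  path <- tempfile(fileext = ".bed")
  writeLines("1\t99\t200\tgeneA", path)
  gr <- readRegionsBed(path)
  expect_equal(start(gr), 100)
  expect_equal(end(gr), 200)
  expect_equal(names(gr), "geneA")
})
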