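test_that("contingency table places posterior mass by truth genotype", {
  # point masses: truth (0,0,1,2), predictions (0,0,1,1)
  tab <- buildContingency(c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 0, 0),
                          truth = c(0, 0, 1, 2))
  expect_equal(unname(tab["0", "0"]), 2)
  expect_equal(unname(tab["1", "1"]), 1)
  expect_equal(unname(tab["2", "1"]), 1)
  expect_equal(attr(tab, "n"), 4L)

  # fractional placement of a single trio
  tab1 <- buildContingency(0.2, 0.5, 0.3, truth = 1)
  expect_equal(unname(tab1["1", ]), c(0.2, 0.5, 0.3),
               ignore_attr = TRUE)
  expect_equal(attr(tab1, "n"), 1L)

  # row sums equal truth genotype counts exactly (trios sum to 1)
  set.seed(1)
  p1 <- runif(50, 0, 0.5); p2 <- runif(50, 0, 0.4)
  p0 <- 1 - p1 - p2
  truth <- sample(0:2, 50, replace = TRUE)
  tab <- buildContingency(p0, p1, p2, truth)
  expect_equal(unname(rowSums(tab)), as.numeric(table(factor(truth, 0:2))))

  # missing truth and missing trios are excluded
  tab <- buildContingency(c(1, NA, 1), c(0, NA, 0), c(0, NA, 0),
                          truth = c(0, 1, NA))
  expect_equal(attr(tab, "n"), 1L)

  # all missing -> empty sentinel, handled as undefined downstream
  empty <- buildContingency(c(1, 1), c(0, 0), c(0, 0), truth = c(NA, NA))
  expect_equal(attr(empty, "n"), 0L)
  expect_false(iqsFromTable(empty)$defined)
})

test_that("IQS is the chance-corrected agreement of the table", {
  tab <- buildContingency(c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 0, 0),
                          truth = c(0, 0, 1, 2))
  r <- iqsFromTable(tab)
  expect_equal(r$p_o, 0.75)
  expect_equal(r$p_c, 0.375)
  expect_equal(r$iqs, 0.6)
  expect_true(r$defined)
})

test_that("IQS limits: perfect imputation scores 1, constant scores 0", {
  truth <- c(0, 0, 1, 2, 1, 0, 2)
  perfect <- iqsFromTable(buildContingency(
    as.numeric(truth == 0), as.numeric(truth == 1),
    as.numeric(truth == 2), truth))
  expect_identical(perfect$p_o, 1)
  expect_identical(perfect$iqs, 1)

  n <- length(truth)
  constant <- iqsFromTable(buildContingency(
    rep(1, n), rep(0, n), rep(0, n), truth))
  expect_equal(constant$iqs, 0)

  # monomorphic stratum predicted monomorphic: 1 - p_c vanishes
  mono <- iqsFromTable(buildContingency(c(1, 1), c(0, 0), c(0, 0),
                                        truth = c(0, 0)))
  expect_false(mono$defined)
  expect_true(is.na(mono$iqs))
})

test_that("iqsFromTable matches an independently coded kappa", {
  set.seed(7)
  for (i in 1:200) {
    tab <- randomFractionalTable()
    expect_equal(iqsFromTable(tab)$iqs, naiveKappa(tab), tolerance = 1e-10)
  }
})

test_that("IQS is invariant to genotype ordering and pooling sums tables", {
  set.seed(11)
  n <- 60
  p1 <- runif(n, 0, 0.5); p2 <- runif(n, 0, 0.4); p0 <- 1 - p1 - p2
  truth <- sample(0:2, n, replace = TRUE)
  base <- buildContingency(p0, p1, p2, truth)
  perm <- sample(n)
  expect_equal(buildContingency(p0[perm], p1[perm], p2[perm], truth[perm]),
               base)
  # pooled stratum table = cell-wise sum of per-stratum tables
  half <- seq_len(n / 2)
  t1 <- buildContingency(p0[half], p1[half], p2[half], truth[half])
  t2 <- buildContingency(p0[-half], p1[-half], p2[-half], truth[-half])
  expect_equal(unclass(base)[1:3, 1:3], unclass(t1 + t2)[1:3, 1:3])
})

test_that("hard-call observed agreement recovers the accuracy parameter", {
  n <- 10000
  set.seed(23)
  a <- 0.9
  truth <- makeTruth(matrix(sample(0:2, n, replace = TRUE,
                                   prob = c(0.49, 0.42, 0.09)), ncol = 1))
  rowRanges(truth)$true_f <- rep(0.3, n)
  imp <- simulatePosteriors(truth, accuracy = a, calibrated = TRUE)
  r <- iqsStratified(imp, truth, "individual", mode = "hardcall")
  se <- sqrt(a * (1 - a) / n)
  expect_lt(abs(r$p_o - a), 3 * se)
})

test_that("stratified IQS pools tables along the requested axis", {
  calls <- matrix(c(0, 1, 2, 0, 1, 2), nrow = 3)
  truth <- makeTruth(calls)
  # sample 1 imputed perfectly, sample 2 by constant prediction
  p0 <- cbind(as.numeric(calls[, 1] == 0), rep(1, 3))
  p1 <- cbind(as.numeric(calls[, 1] == 1), rep(0, 3))
  p2 <- cbind(as.numeric(calls[, 1] == 2), rep(0, 3))
  imp <- makeImputed(p0, p1, p2)
  perInd <- iqsStratified(imp, truth, "individual")
  expect_equal(perInd$iqs, c(1, 0))

  # per-variant result equals iqsFromTable on the variant's pooled row
  perVar <- iqsStratified(imp, truth, "variant")
  v1 <- iqsFromTable(buildContingency(p0[1, ], p1[1, ], p2[1, ],
                                      calls[1, ]))
  expect_equal(perVar$iqs[1], v1$iqs)
  expect_equal(perVar$n_genotypes[1], v1$n_genotypes)
})

test_that("MAF binning uses truth-set frequencies with a 0.01 threshold", {
  set.seed(3)
  nv <- 40; ns <- 50
  f <- c(rep(0.003, 20), rep(0.3, 20))
  truth <- simulateTruth(nv, ns, maf = f, seed = 4)
  imp <- simulatePosteriors(truth, accuracy = 0.9, seed = 5)
  tab <- iqsStratified(imp, truth, "maf_bin")
  expect_setequal(tab$stratum, c("maf_lt_0.01", "maf_ge_0.01"))
  maf <- mafValues(truth)
  expect_equal(tab$n_genotypes[tab$stratum == "maf_lt_0.01"],
               sum(maf < 0.01) * ns)
})

test_that("region strata follow overlaps, duplicating shared variants", {
  calls <- matrix(sample(0:2, 20, replace = TRUE), nrow = 10)
  truth <- makeTruth(calls)
  imp <- pointMassImputed(calls)
  regions <- GRanges("1", IRanges(c(100, 250, 1), c(500, 1000, 2000)))
  names(regions) <- c("r1", "r2", "both")
  tab <- iqsStratified(imp, truth, "region", regions = regions)
  expect_equal(tab$n_genotypes[tab$stratum == "both"], 20L)
  # r1 covers positions 100..500 (variants 1..5), r2 300..1000 (3..10)
  expect_equal(tab$n_genotypes[tab$stratum == "r1"], 5L * 2L)
  expect_gt(sum(tab$n_genotypes[1:2]), 20L)  # overlap duplicates
})

test_that("het dosage histograms split by mask with dosage p1 + 2 p2", {
  calls <- matrix(1L, 4, 2)
  truth <- makeTruth(calls)
  p0 <- matrix(0, 4, 2); p1 <- matrix(1, 4, 2); p2 <- matrix(0, 4, 2)
  p0[1, 1] <- 0.5; p1[1, 1] <- 0.5  # one het at dosage 0.5
  imp <- makeImputed(p0, p1, p2)
  mask <- matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                 4, 2)
  h <- hetDosageDistribution(imp, truth, mask, binWidth = 0.05)
  expect_equal(sum(h$count_inside), 4)
  expect_equal(sum(h$count_outside), 4)
  # perfectly imputed hets all land in the bin containing 1.0
  binOf <- function(x) which(h$bin_left <= x & x < h$bin_right)
  expect_equal(h$count_outside[binOf(1.0)], 4)
  expect_equal(h$count_inside[binOf(1.0)], 3)
  expect_equal(h$count_inside[binOf(0.5)], 1)
})

test_that("no heterozygotes yields empty histograms, not an error", {
  calls <- matrix(c(0L, 2L), 2, 2)
  h <- hetDosageDistribution(pointMassImputed(calls), makeTruth(calls),
                             matrix(TRUE, 2, 2))
  expect_equal(sum(h$count_inside) + sum(h$count_outside), 0)
})
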