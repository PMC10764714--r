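test_that("most-confident-vote rule retains the clearly more certain trio", {
  a <- c(0.95, 0.05, 0.00)
  b <- c(0.85, 0.15, 0.00)
  r <- selectTrio(a, b, hybridConfig(delta = 0.05))
  expect_identical(r$trio, a)       # 0.95 > 0.85 + 0.05
  expect_identical(r$source, "A_selected")

  # the inequality is strict: equality at the margin goes to priority B
  r2 <- selectTrio(c(0.90, 0.10, 0), b, hybridConfig(delta = 0.05))
  expect_identical(r2$source, "B_selected")
  expect_identical(r2$trio, b)
})

test_that("missing trios fall through to the available source", {
  b <- c(0.4, 0.6, 0)
  r <- selectTrio(NULL, b)
  expect_identical(r$source, "B_only")
  expect_identical(r$trio, b)
  r <- selectTrio(b, rep(NA_real_, 3))
  expect_identical(r$source, "A_only")
  r <- selectTrio(NULL, NULL)
  expect_identical(r$source, "missing")
  expect_true(all(is.na(r$trio)))
})

test_that("selection at delta = 0 is antisymmetric except exact ties", {
  set.seed(5)
  cfg <- hybridConfig(delta = 0)
  for (i in 1:50) {
    a <- runif(3); a <- a / sum(a)
    b <- runif(3); b <- b / sum(b)
    r1 <- selectTrio(a, b, cfg)
    r2 <- selectTrio(b, a, cfg)
    if (max(a) != max(b)) {
      expect_identical(r1$trio, r2$trio)  # same winner either way round
    } else {
      expect_identical(r1$source, "B_selected")  # ties to priority source
    }
  }
})

test_that("concordance compares argmax genotypes with a deterministic tie-break", {
  expect_identical(classifyConcordance(c(0.95, 0.05, 0), c(0.85, 0.15, 0)),
                   "Accord")
  expect_identical(classifyConcordance(c(0.2, 0.7, 0.1), c(0.6, 0.3, 0.1)),
                   "Discord")
  # within-trio tie broken toward the smaller genotype code
  expect_identical(classifyConcordance(c(0.5, 0.5, 0), c(0.9, 0.1, 0)),
                   "Accord")
  expect_identical(classifyConcordance(c(0.5, 0.5, 0), NULL), "n/a")
})

test_that("merge covers the union once and never alters a trio", {
  set.seed(9)
  sc <- simulateScenario(nVariants = 300, nPerGroup = 10, seed = 9)
  mg <- mergeRuns(sc$runA, sc$runB)
  keysU <- union(rownames(sc$runA), rownames(sc$runB))
  expect_setequal(rownames(mg$merged), keysU)
  expect_false(anyDuplicated(rownames(mg$merged)) > 0)

  # every retained trio is byte-identical to one of its sources
  m0 <- assay(mg$merged, "p0"); m1 <- assay(mg$merged, "p1")
  m2 <- assay(mg$merged, "p2")
  src <- mg$source
  for (run in list(c("A_selected", "A_only"), c("B_selected", "B_only"))) {
    obj <- if (run[1] == "A_selected") sc$runA else sc$runB
    sel <- matrix(src %in% run, nrow(src), dimnames = dimnames(src))
    sel[!(rownames(mg$merged) %in% rownames(obj)), ] <- FALSE
    keys <- rownames(mg$merged)
    for (ss in colnames(mg$merged)[1:3]) {
      rows <- which(sel[, ss])
      if (!length(rows)) next
      kk <- keys[rows]
      expect_identical(m0[kk, ss], assay(obj, "p0")[kk, ss])
      expect_identical(m1[kk, ss], assay(obj, "p1")[kk, ss])
      expect_identical(m2[kk, ss], assay(obj, "p2")[kk, ss])
    }
  }

  # variants absent from A are all B_only; concordance only on the overlap
  onlyB <- setdiff(rownames(sc$runB), rownames(sc$runA))
  expect_true(all(mg$source[onlyB, ] == "B_only"))
  expect_true(all(mg$concordance[onlyB, ] == "n/a"))
  inter <- intersect(rownames(sc$runA), rownames(sc$runB))
  expect_true(all(mg$concordance[inter, ] %in% c("Accord", "Discord")))
})

test_that("selection favours the local run where it is more confident", {
  sc <- simulateScenario(nVariants = 1000, nPerGroup = 30, seed = 21)
  mg <- mergeRuns(sc$runA, sc$runB)
  inter <- intersect(rownames(sc$runA), rownames(sc$runB))
  maf <- mafValues(sc$truth)[inter]
  rare <- inter[maf < 0.01]; common <- inter[maf >= 0.01]
  fracA <- function(k) mean(mg$source[k, ] == "A_selected")
  expect_gt(fracA(rare), fracA(common))
})

test_that("accord fractions and concordance labels partition each individual", {
  sc <- simulateScenario(nVariants = 400, nPerGroup = 10, seed = 33)
  mg <- mergeRuns(sc$runA, sc$runB)
  inter <- intersect(rownames(sc$runA), rownames(sc$runB))
  lbl <- mg$concordance[inter, ]
  fr <- (colSums(lbl == "Accord") + colSums(lbl == "Discord") +
           colSums(lbl == "n/a")) / length(inter)
  expect_equal(unname(fr), rep(1, ncol(lbl)))
})

test_that("identical runs are all Accord with an undefined Discord set", {
  calls <- matrix(sample(0:2, 40, replace = TRUE), 20, 2)
  truth <- makeTruth(calls)
  run <- pointMassImputed(calls)
  mg <- mergeRuns(run, run)
  acc <- accordSplitIqs(run, run, mg, truth)
  expect_equal(acc$accord_frac, c(1, 1))
  expect_false(any(acc$discord_defined))
  expect_true(all(is.na(acc$discord_correct_merged)))
})

test_that("discord correctness of the merge matches brute-force selection", {
  # runs disagree at every genotype; A is always right with p_max 0.9,
  # B is wrong with p_max alternating 0.8 (A wins) and 0.97 (B wins)
  n <- 10
  truth <- makeTruth(matrix(0L, n, 1))
  pA <- c(0.9, 0.1, 0)
  a <- makeImputed(matrix(pA[1], n, 1), matrix(pA[2], n, 1),
                   matrix(pA[3], n, 1))
  pmB <- rep(c(0.8, 0.97), length.out = n)
  b <- makeImputed(matrix(1 - pmB, n, 1), matrix(pmB, n, 1),
                   matrix(0, n, 1))
  mg <- mergeRuns(a, b, hybridConfig(delta = 0.05))
  acc <- accordSplitIqs(a, b, mg, truth)
  expect_equal(acc$accord_frac, 0)
  expect_equal(acc$discord_correct_a, 1)
  expect_equal(acc$discord_correct_b, 0)
  # brute force: merged is correct exactly where A was selected
  expected <- mean(pA[1] > pmB + 0.05)
  expect_equal(acc$discord_correct_merged, expected)
})

test_that("calibrated merging is not worse than either source at delta 0", {
  sc <- simulateScenario(nVariants = 1500, nPerGroup = 40, seed = 17)
  mg <- mergeRuns(sc$runA, sc$runB, hybridConfig(delta = 0))
  keys <- intersect(rownames(sc$runA), rownames(sc$runB))
  tr <- sc$truth[keys, ]
  po <- function(run) {
    iqsStratified(run[keys, ], tr, "individual", mode = "hardcall")$p_o
  }
  poA <- po(sc$runA); poB <- po(sc$runB); poH <- po(mg$merged)
  d <- poH - pmax(poA, poB)
  se <- sd(d) / sqrt(length(d))
  expect_gt(mean(d), -2 * se)
})
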