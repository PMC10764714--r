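#' Simulate truth genotypes under Hardy-Weinberg equilibrium
#'
#' Draws a per-variant alternate allele frequency from the requested MAF
#' model and then samples genotypes independently per variant and sample
#' with HWE probabilities \eqn{((1-f)^2, 2f(1-f), f^2)}.  Variants are
#' simulated without linkage disequilibrium: every downstream contract in
#' the package is genotype-wise, so independence is sufficient (and keeps
#' the chance-level IQS exactly analysable).  The true frequency is stored
#' in \code{rowRanges()$true_f}.
#'
#' @param nVariants,nSamples problem size.
#' @param maf either a numeric vector of per-variant frequencies (recycled),
#'   a length-2 range from which frequencies are drawn log-uniformly (a
#'   crude allele-frequency spectrum: rare variants outnumber common ones),
#'   or a function \code{function(n)} returning \code{n} frequencies.
#'   Values must lie in (0, 0.5] except for explicit per-variant vectors,
#'   which may include 0.
#' @param groups optional character vector of group labels per sample
#'   (stored in \code{colData()$group}; used by [simulatePosteriors()]).
#' @param seed RNG seed for reproducibility.
#' @param chrom chromosome label for the synthetic variants.
#' @return A [TruthGenotypes] object.
#' @export
simulateTruth <- function(nVariants, nSamples, maf = c(0.001, 0.5),
                          groups = NULL, seed = NULL, chrom = "1") {
  if (!is.null(seed)) set.seed(seed)
  f <- if (is.function(maf)) {
    maf(nVariants)
  } else if (length(maf) == nVariants) {
    maf
  } else if (length(maf) == 2) {
    exp(stats::runif(nVariants, log(maf[1]), log(maf[2])))
  } else {
    rep_len(maf, nVariants)
  }
  stopifnot(all(f >= 0 & f <= 0.5))
  calls <- matrix(stats::rbinom(nVariants * nSamples, 2, rep(f, nSamples)),
                  nrow = nVariants)
  pos <- seq_len(nVariants) * 1000L
  gr <- GRanges(chrom, IRanges(pos, width = 1L),
                ref = rep("A", nVariants), alt = rep("G", nVariants),
                true_f = f)
  smp <- sprintf("S%03d", seq_len(nSamples))
  tr <- TruthGenotypes(calls, gr, samples = smp)
  if (!is.null(groups)) {
    stopifnot(length(groups) == nSamples)
    colData(tr)$group <- groups
  }
  tr
}

# resolve per-genotype correctness probability from an accuracy spec:
# scalar, or matrix with rownames c("rare","common") x group labels
.accuracyMatrix <- function(accuracy, f, groups, mafThreshold) {
  nV <- length(f); nS <- length(groups)
  if (is.numeric(accuracy) && length(accuracy) == 1)
    return(matrix(accuracy, nV, nS))
  stopifnot(is.matrix(accuracy),
            all(rownames(accuracy) %in% c("rare", "common")))
  maf <- pmin(f, 1 - f)
  bin <- ifelse(maf < mafThreshold, "rare", "common")
  g <- as.character(groups)
  if (!all(g %in% colnames(accuracy)))
    stop("accuracy matrix lacks a column for group(s): ",
         paste(setdiff(unique(g), colnames(accuracy)), collapse = ", "))
  accuracy[cbind(rep(match(bin, rownames(accuracy)), nS),
                 rep(match(g, colnames(accuracy)), each = nV))] |>
    matrix(nrow = nV)
}

#' Simulate posterior genotype probabilities for an imputation strategy
#'
#' Emulates an imputation run against a known truth set.  Under the
#' accuracy model, each genotype's most likely call equals the truth with
#' probability \eqn{a} (looked up per strategy from the variant's MAF bin
#' and the sample's group); a miscall draws the argmax from the two other
#' genotypes proportional to their HWE prior at the variant's true
#' frequency, which makes chance-level performance score IQS = 0 by
#' construction.  With \code{calibrated = TRUE} the emitted maximum
#' probability equals \eqn{a}, so the trio's confidence is numerically the
#' probability that its best guess is right; with \code{calibrated =
#' FALSE} the maximum is the fixed \code{confidence} value regardless of
#' \eqn{a} (an overconfident or underconfident run).  The non-argmax mass
#' is split between the two other genotypes proportional to their HWE
#' priors (falling back to an equal split whenever the proportional split
#' would overtake the argmax, which keeps the argmax invariant; always
#' feasible for \eqn{p_{max} \ge 1/3}).  Under the chance model the trio
#' is exactly the HWE prior trio, independent of the truth.
#'
#' @param truth a [TruthGenotypes] from [simulateTruth()] (needs
#'   \code{true_f}; group labels in \code{colData()$group} when the
#'   accuracy spec is group-dependent).
#' @param accuracy scalar correctness probability in (0, 1], or a matrix
#'   with rows \code{"rare"}/\code{"common"} and one column per sample
#'   group.
#' @param calibrated logical: emit \eqn{p_{max} = a} (default) or the
#'   fixed \code{confidence}.
#' @param confidence \eqn{p_{max}} used when \code{calibrated = FALSE}.
#' @param model \code{"accuracy"} (default) or \code{"chance"} (HWE prior
#'   trios, truth-independent).
#' @param macThreshold drop variants whose truth minor allele count is
#'   below this value before imputation, emulating a reference panel
#'   filtered at a minimum MAC (default 0 = keep all).
#' @param keepVariants optional character vector of variant keys to
#'   retain (applied after the MAC filter), emulating a panel that only
#'   carries a subset of sites.
#' @param source strategy label for the returned run.
#' @param mafThreshold rare/common boundary for the accuracy lookup.
#' @param seed RNG seed.
#' @return An [ImputedGenotypes] object.
#' @export
simulatePosteriors <- function(truth, accuracy = 0.95, calibrated = TRUE,
                               confidence = 0.99,
                               model = c("accuracy", "chance"),
                               macThreshold = 0, keepVariants = NULL,
                               source = "simulated",
                               mafThreshold = 0.01, seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  if (macThreshold > 0)
    truth <- truth[!is.na(macValues(truth)) &
                     macValues(truth) >= macThreshold, ]
  if (!is.null(keepVariants))
    truth <- truth[rownames(truth) %in% keepVariants, ]
  f <- mcols(rowRanges(truth))$true_f
  if (is.null(f)) f <- 2 * mafValues(truth)  # fall back to observed
  nV <- nrow(truth); nS <- ncol(truth)
  hwe <- cbind((1 - f)^2, 2 * f * (1 - f), f^2)

  if (model == "chance") {
    p0 <- matrix(hwe[, 1], nV, nS); p1 <- matrix(hwe[, 2], nV, nS)
    p2 <- matrix(hwe[, 3], nV, nS)
    return(ImputedGenotypes(p0, p1, p2, rowRanges(truth),
                            samples = colnames(truth), source = source))
  }

  groups <- colData(truth)$group
  if (is.null(groups)) groups <- rep("all", nS)
  a <- .accuracyMatrix(accuracy, f, groups, mafThreshold)
  if (any(a <= 0 | a > 1))
    stop("config error: accuracy values must lie in (0, 1]")

  g <- genotypeCalls(truth)
  correct <- matrix(stats::runif(nV * nS) < a, nV, nS)
  argmax <- g
  wrong <- which(!correct & !is.na(g))
  if (length(wrong)) {
    vi <- ((wrong - 1) %% nV) + 1
    others <- matrix(c(1L, 2L, 0L, 2L, 0L, 1L), nrow = 3, byrow = TRUE)
    o1 <- others[g[wrong] + 1L, 1]; o2 <- others[g[wrong] + 1L, 2]
    w1 <- hwe[cbind(vi, o1 + 1L)]; w2 <- hwe[cbind(vi, o2 + 1L)]
    tot <- w1 + w2
    pr1 <- ifelse(tot > 0, w1 / tot, 0.5)
    pickFirst <- stats::runif(length(wrong)) < pr1
    argmax[wrong] <- ifelse(pickFirst, o1, o2)
  }

  pmaxM <- if (calibrated) a else matrix(confidence, nV, nS)
  rest <- 1 - pmaxM
  p <- list(matrix(0, nV, nS), matrix(0, nV, nS), matrix(0, nV, nS))
  othersOf <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L))
  for (gcode in 0:2) {
    idx <- which(argmax == gcode)
    if (!length(idx)) next
    vi <- ((idx - 1) %% nV) + 1
    oo <- othersOf[[gcode + 1]]
    w1 <- hwe[cbind(vi, oo[1])]; w2 <- hwe[cbind(vi, oo[2])]
    tot <- w1 + w2
    s1 <- ifelse(tot > 0, w1 / tot, 0.5) * rest[idx]
    s2 <- rest[idx] - s1
    # proportional split must not overtake the argmax; equal split is
    # always feasible for p_max >= 1/3
    viol <- pmax(s1, s2) > pmaxM[idx]
    s1[viol] <- rest[idx][viol] / 2
    s2[viol] <- rest[idx][viol] / 2
    p[[gcode + 1]][idx] <- pmaxM[idx]
    p[[oo[1]]][idx] <- s1
    p[[oo[2]]][idx] <- s2
  }
  miss <- is.na(g)
  for (k in 1:3) p[[k]][miss] <- NA_real_
  ImputedGenotypes(p[[1]], p[[2]], p[[3]], rowRanges(truth),
                   samples = colnames(truth), source = source)
}

#' Simulate seed-perturbed phasing replicates with a known switch rate
#'
#' Builds, per individual, a chain of heterozygous sites whose true
#' relative orientations are drawn uniformly; each of the K replicates
#' then flips every adjacent-pair orientation independently with
#' probability \code{s}, and haplotype matrices consistent with the
#' resulting orientations are emitted.  For \eqn{s < 0.5} and odd K the
#' majority-vote consensus recovers the truth with probability approaching
#' 1, so [estimateSer()] is a parameter-recovery check of \code{s}.
#' \eqn{s \ge 0.5} is rejected: the consensus orientation is then no
#' better than a coin flip and the estimator is meaningless.
#'
#' @param nIndividuals,nHetPairs problem size (each individual is
#'   heterozygous at \code{nHetPairs + 1} sites).
#' @param s per-pair, per-replicate switch probability in [0, 0.5).
#' @param K number of phasing replicates (odd, default 21).
#' @param seed RNG seed.
#' @return list with \code{set} (a [SeedPhasingSet]), and
#'   \code{truthOrientation} (logical pairs x individuals matrix,
#'   \code{TRUE} = "same") plus \code{truth} (the error-free phasing as
#'   \code{hapA}/\code{hapB} matrices, for [trueSer()]).
#' @export
simulateSeedPhasings <- function(nIndividuals, nHetPairs, s, K = 21,
                                 seed = NULL) {
  if (s >= 0.5 || s < 0) stop("s must lie in [0, 0.5)")
  if (K < 3 || K %% 2 == 0) stop("K must be odd and >= 3")
  if (!is.null(seed)) set.seed(seed)
  nSites <- nHetPairs + 1
  # truth haplotype-A alleles as bits; orientation(i) = bit[i] == bit[i+1]
  bits <- matrix(stats::rbinom(nSites * nIndividuals, 1, 0.5), nSites)
  orient <- bits[-nSites, , drop = FALSE] == bits[-1, , drop = FALSE]
  hapA <- array(NA_integer_, c(nSites, nIndividuals, K))
  for (k in seq_len(K)) {
    flips <- matrix(stats::runif(nHetPairs * nIndividuals) < s, nHetPairs)
    ok <- orient != flips  # flipped orientation for this replicate
    bk <- matrix(0L, nSites, nIndividuals)
    bk[1, ] <- bits[1, ]
    for (i in seq_len(nHetPairs))
      bk[i + 1, ] <- ifelse(ok[i, ], bk[i, ], 1L - bk[i, ])
    hapA[, , k] <- bk
  }
  hapB <- 1L - hapA
  smp <- sprintf("I%03d", seq_len(nIndividuals))
  set <- SeedPhasingSet(hapA, hapB, seeds = seq_len(K),
                        positions = seq_len(nSites) * 1000,
                        samples = smp)
  truth <- list(hapA = matrix(bits, nSites, dimnames = list(NULL, smp)),
                hapB = matrix(1L - bits, nSites,
                              dimnames = list(NULL, smp)))
  list(set = set, truthOrientation = orient, truth = truth)
}

#' Simulate group-structured IBD segments
#'
#' For every (target individual, reference individual) pair, the number of
#' shared segments is Poisson with the rate of the pair's (target group,
#' reference cluster) cell; genetic lengths are a minimum detectable
#' length plus an exponential tail (mimicking detector limits), and
#' physical spans are placed uniformly on one chromosome with 1 cM
#' approximated as 1 Mb.
#'
#' @param targets named character vector: target group per sample.
#' @param refs named character vector: reference cluster per sample.
#' @param rates matrix of expected segment counts per pair, target groups
#'   x reference clusters (dimnames required).
#' @param meanLengthCm mean segment length in cM (must exceed
#'   \code{minLengthCm}).
#' @param minLengthCm detector minimum length (default 1 cM).
#' @param chromLengthBp chromosome length for span placement.
#' @param seed RNG seed.
#' @return IBD segment data.frame as from [readIbdSegments()].
#' @export
simulateIbdSegments <- function(targets, refs, rates, meanLengthCm = 4,
                                minLengthCm = 1, chromLengthBp = 2.5e8,
                                seed = NULL) {
  stopifnot(is.matrix(rates), !is.null(dimnames(rates)),
            all(rates >= 0), meanLengthCm > minLengthCm)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(t = names(targets), r = names(refs),
                      stringsAsFactors = FALSE)
  lam <- rates[cbind(unname(targets[grid$t]), unname(refs[grid$r]))]
  counts <- stats::rpois(nrow(grid), lam)
  idx <- rep(seq_len(nrow(grid)), counts)
  n <- length(idx)
  if (n == 0)
    return(data.frame(sample1 = character(), hap1 = integer(),
                      sample2 = character(), hap2 = integer(),
                      chrom = character(), start = numeric(),
                      end = numeric(), lod = numeric(),
                      length_cm = numeric()))
  self <- grid$t[idx] == grid$r[idx]
  idx <- idx[!self]
  n <- length(idx)
  len <- minLengthCm + stats::rexp(n, 1 / (meanLengthCm - minLengthCm))
  spanBp <- pmin(len * 1e6, chromLengthBp - 1)
  start <- floor(stats::runif(n, 1, chromLengthBp - spanBp))
  data.frame(sample1 = grid$t[idx],
             hap1 = sample(1:2, n, replace = TRUE),
             sample2 = grid$r[idx],
             hap2 = sample(1:2, n, replace = TRUE),
             chrom = "1", start = start, end = start + spanBp,
             lod = stats::runif(n, 3, 30), length_cm = len)
}

#' Two-strategy benchmark scenario with group-structured accuracy
#'
#' Generates the full synthetic comparison used by the package's tests: a
#' truth set over a rare/common MAF mix for two sample groups, plus two
#' calibrated imputation runs.  Strategy A emulates a local run against a
#' small population-matched panel: most accurate on rare variants of
#' group-1 samples, restricted to variants above a minor-allele-count
#' panel filter.  Strategy B emulates a server run against a large
#' cosmopolitan panel: more accurate for group-2 samples and on common
#' variants, and imputing a superset of common variants.  The defaults
#' encode that qualitative structure; per-group accuracies are correctness
#' probabilities in (0, 1].
#'
#' @param nVariants total variant count (half rare, half common).
#' @param nPerGroup samples per group.
#' @param accA,accB accuracy matrices (rows \code{rare}/\code{common},
#'   columns \code{g1}/\code{g2}) for the two strategies.
#' @param panelSize number of individuals in strategy A's emulated
#'   reference panel; a variant enters the panel only if its simulated
#'   panel minor allele count (binomial at the true frequency) reaches
#'   \code{panelMacMin}, so strategy A imputes a frequency-dependent
#'   subset of sites while strategy B imputes them all.
#' @param panelMacMin panel minor-allele-count filter (default 5).
#' @param calibrated passed to [simulatePosteriors()].
#' @param seed RNG seed.
#' @return list with \code{truth}, \code{runA}, \code{runB},
#'   \code{groups} (named vector of group labels).
#' @export
simulateScenario <- function(nVariants = 3000, nPerGroup = 60,
    accA = matrix(c(0.95, 0.70, 0.97, 0.90), 2, 2, byrow = TRUE,
                  dimnames = list(c("rare", "common"), c("g1", "g2"))),
    accB = matrix(c(0.80, 0.85, 0.97, 0.96), 2, 2, byrow = TRUE,
                  dimnames = list(c("rare", "common"), c("g1", "g2"))),
    panelSize = 850, panelMacMin = 5, calibrated = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nRare <- floor(nVariants / 2)
  maf <- c(stats::runif(nRare, 0.002, 0.009),
           stats::runif(nVariants - nRare, 0.05, 0.5))
  groups <- rep(c("g1", "g2"), each = nPerGroup)
  truth <- simulateTruth(nVariants, 2 * nPerGroup, maf = maf,
                         groups = groups)
  panelAc <- stats::rbinom(nVariants, 2 * panelSize, maf)
  inPanel <- pmin(panelAc, 2 * panelSize - panelAc) >= panelMacMin
  runA <- simulatePosteriors(truth, accuracy = accA,
                             calibrated = calibrated,
                             keepVariants = rownames(truth)[inPanel],
                             source = "local-ssp")
  runB <- simulatePosteriors(truth, accuracy = accB,
                             calibrated = calibrated,
                             source = "server-public")
  list(truth = truth, runA = runA, runB = runB,
       groups = stats::setNames(groups, colnames(truth)))
}
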