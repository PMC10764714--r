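#' Relative phase orientation of two heterozygous genotypes
#'
#' For one individual heterozygous at two adjacent sites, the pair is
#' \code{"same"} when the alternate alleles lie on the same haplotype and
#' \code{"opposite"} otherwise.  The orientation is invariant to which
#' haplotype is written first (\code{0|1} vs \code{1|0} globally flipped).
#'
#' @param gtI,gtJ phased genotype strings (\code{"0|1"} or \code{"1|0"}).
#' @return \code{"same"}, \code{"opposite"}, or \code{NA} if either
#'   genotype is unphased, missing or not heterozygous.
#' @examples
#' relativePhase("0|1", "0|1")  # same
#' relativePhase("0|1", "1|0")  # opposite
#' @export
relativePhase <- function(gtI, gtJ) {
  parse1 <- function(g) {
    if (is.na(g) || !grepl("|", g, fixed = TRUE)) return(NA_integer_)
    al <- strsplit(g, "|", fixed = TRUE)[[1]]
    if (length(al) != 2 || any(al == ".") || sum(al == "1") != 1)
      return(NA_integer_)
    as.integer(al[1])
  }
  ai <- parse1(gtI); aj <- parse1(gtJ)
  if (is.na(ai) || is.na(aj)) return(NA_character_)
  if (ai == aj) "same" else "opposite"
}

# genotype content of a set (constant across replicates by validity)
.setGenotypes <- function(set) .firstNonNA(set@hapA + set@hapB)

# orientation matrix for one sample: adjacent-het-pairs x K, TRUE = "same",
# NA where either endpoint is unphased in that replicate; genotype content
# may be passed precomputed to avoid rescanning the whole replicate array
.orientations <- function(set, sample, genoCol = NULL) {
  g <- if (is.null(genoCol)) .setGenotypes(set)[, sample] else genoCol
  het <- which(!is.na(g) & g == 1L)
  if (length(het) < 2)
    return(matrix(logical(), 0, nReplicates(set)))
  A <- set@hapA[, sample, , drop = TRUE]
  if (is.null(dim(A))) A <- matrix(A, ncol = nReplicates(set))
  A[het[-length(het)], , drop = FALSE] == A[het[-1], , drop = FALSE]
}

#' Majority-vote consensus phase orientation
#'
#' For one individual, takes the orientation of each adjacent heterozygous
#' site pair in every phasing replicate and declares the orientation chosen
#' by the majority of replicates the consensus (assumed correct) phase.
#' K is odd, so with all replicates voting the majority is unique; when
#' replicate-level exclusions leave an exact tie the pair is dropped and
#' counted.
#'
#' @param set a [SeedPhasingSet].
#' @param sample sample identifier or index.
#' @return data.frame with one row per adjacent het pair: \code{n_same},
#'   \code{n_opposite}, and \code{consensus} (\code{"same"},
#'   \code{"opposite"} or \code{NA} for dropped ties/unevaluable pairs).
#' @export
consensusPhase <- function(set, sample) {
  stopifnot(is(set, "SeedPhasingSet"))
  o <- .orientations(set, sample)
  nSame <- rowSums(o, na.rm = TRUE)
  nOpp <- rowSums(!o, na.rm = TRUE)
  cons <- ifelse(nSame > nOpp, "same",
                 ifelse(nOpp > nSame, "opposite", NA_character_))
  data.frame(n_same = nSame, n_opposite = nOpp, consensus = cons)
}

#' Estimate switch error rate from repeated phasings
#'
#' Approximates the switch error rate (SER) without known truth haplotypes
#' by running the phasing K times with different random seeds: the
#' orientation assigned to each adjacent heterozygous pair by the majority
#' of seeds is assumed correct, each replicate's SER is the fraction of its
#' evaluable pairs that disagree with that consensus, and the per-individual
#' estimate is the arithmetic mean across the K replicates.
#'
#' @param set a [SeedPhasingSet] (K odd, enforced at construction).
#' @return list with \code{perIndividual} (data.frame: \code{sample},
#'   \code{n_pairs} evaluable, \code{n_dropped_ties}, \code{mean_ser};
#'   individuals with no evaluable pair get \code{NA}, flagged by
#'   \code{defined}), \code{perReplicate} (samples x K matrix of
#'   replicate SERs), and \code{consensus} (per sample, the consensus
#'   orientation of each adjacent het pair: \code{TRUE} = "same",
#'   \code{NA} = dropped/unevaluable).
#' @export
estimateSer <- function(set) {
  stopifnot(is(set, "SeedPhasingSet"))
  K <- nReplicates(set)
  smp <- set@samples
  perRep <- matrix(NA_real_, length(smp), K,
                   dimnames = list(smp, set@seeds))
  nPairs <- integer(length(smp))
  nTies <- integer(length(smp))
  consensus <- stats::setNames(vector("list", length(smp)), smp)
  geno <- .setGenotypes(set)
  for (i in seq_along(smp)) {
    o <- .orientations(set, smp[i], genoCol = geno[, i])
    if (nrow(o) == 0) next
    nSame <- rowSums(o, na.rm = TRUE)
    nOpp <- rowSums(!o, na.rm = TRUE)
    cons <- nSame > nOpp
    cons[nSame == nOpp] <- NA
    nTies[i] <- sum(nSame == nOpp & nSame + nOpp > 0)
    ok <- !is.na(cons)
    nPairs[i] <- sum(ok)
    consensus[[i]] <- cons
    if (!any(ok)) next
    for (k in seq_len(K)) {
      ev <- ok & !is.na(o[, k])
      if (any(ev)) perRep[i, k] <- mean(o[ev, k] != cons[ev])
    }
  }
  meanSer <- rowMeans(perRep, na.rm = TRUE)
  meanSer[nPairs == 0] <- NA_real_
  perInd <- data.frame(sample = smp, n_pairs = nPairs,
                       n_dropped_ties = nTies, mean_ser = meanSer,
                       defined = nPairs > 0)
  rownames(perInd) <- NULL
  list(perIndividual = perInd, perReplicate = perRep,
       consensus = consensus)
}

#' One phasing replicate as haplotype matrices
#'
#' @param set a [SeedPhasingSet].
#' @param k replicate index.
#' @return list with \code{hapA} and \code{hapB} (variants x samples 0/1
#'   matrices).
#' @export
phasingReplicate <- function(set, k) {
  stopifnot(is(set, "SeedPhasingSet"))
  list(hapA = set@hapA[, , k, drop = TRUE],
       hapB = set@hapB[, , k, drop = TRUE])
}

#' True switch error rate against known haplotypes
#'
#' Standard SER: the fraction of adjacent heterozygous site pairs whose
#' relative orientation in the estimated phasing differs from the truth.
#' Used as the validation oracle for the consensus-based approximation.
#'
#' @param estimate,truth phasings as lists with \code{hapA}/\code{hapB}
#'   matrices (variants x samples), e.g. from [phasingReplicate()].
#' @return data.frame with \code{sample}, \code{n_pairs}, \code{ser}
#'   (\code{NA} when no pair is evaluable).
#' @export
trueSer <- function(estimate, truth) {
  eA <- estimate$hapA; tA <- truth$hapA
  g <- estimate$hapA + estimate$hapB
  stopifnot(identical(dim(eA), dim(tA)))
  smp <- colnames(eA)
  if (is.null(smp)) smp <- paste0("S", seq_len(ncol(eA)))
  out <- lapply(seq_len(ncol(eA)), function(j) {
    het <- which(!is.na(g[, j]) & g[, j] == 1L)
    if (length(het) < 2)
      return(data.frame(sample = smp[j], n_pairs = 0L, ser = NA_real_))
    oe <- eA[het[-length(het)], j] == eA[het[-1], j]
    ot <- tA[het[-length(het)], j] == tA[het[-1], j]
    ok <- !is.na(oe) & !is.na(ot)
    data.frame(sample = smp[j], n_pairs = sum(ok),
               ser = if (any(ok)) mean(oe[ok] != ot[ok]) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read K phased VCFs into a SeedPhasingSet
#'
#' Each file must contain the same variants and samples; genotype content
#' must be identical across replicates (phasing must not change
#' genotypes — a disagreement is a hard error at construction).  Unphased
#' genotypes (\code{/} separator) are missing for that replicate only.
#'
#' @param paths character vector of VCF paths, one per phasing replicate
#'   (odd count, at least 3).
#' @return A [SeedPhasingSet].
#' @export
readPhasedVcfs <- function(paths) {
  K <- length(paths)
  if (K < 3 || K %% 2 == 0)
    stop("an odd number (>= 3) of phasing replicates is required")
  hapA <- NULL; hapB <- NULL; pos <- NULL; smp <- NULL
  for (k in seq_len(K)) {
    vcf <- vcfR::read.vcfR(paths[k], verbose = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    if (k == 1) {
      pos <- as.numeric(vcf@fix[, "POS"])
      smp <- colnames(gt)
      hapA <- array(NA_integer_, c(nrow(gt), length(smp), K))
      hapB <- hapA
    } else if (nrow(gt) != dim(hapA)[1] ||
               !identical(colnames(gt), smp)) {
      stop("replicate ", k, " differs in variants or samples")
    }
    phased <- grepl("|", gt, fixed = TRUE)
    a1 <- suppressWarnings(
      as.integer(sub("^([0-9.])\\|.*$", "\\1", gt)))
    a2 <- suppressWarnings(
      as.integer(sub("^[0-9.]\\|([0-9.]).*$", "\\1", gt)))
    a1[!phased] <- NA_integer_
    a2[!phased] <- NA_integer_
    hapA[, , k] <- a1
    hapB[, , k] <- a2
  }
  SeedPhasingSet(hapA, hapB, seeds = seq_len(K), positions = pos,
                 samples = smp)
}
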