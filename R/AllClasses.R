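#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowRanges colData colData<- rowData
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

setClass("ImputedGenotypes",
  contains = "RangedSummarizedExperiment",
  representation(source = "character"))

setClass("TruthGenotypes",
  contains = "RangedSummarizedExperiment")

#' Container for posterior genotype probabilities from one imputation run
#'
#' An \code{ImputedGenotypes} object holds, for each biallelic variant and
#' each sample, the trio of posterior probabilities \eqn{(p_0, p_1, p_2)} of
#' carrying 0, 1 or 2 copies of the alternate allele, as emitted by genotype
#' imputation software (the VCF \code{GP} FORMAT field).  It extends
#' \code{RangedSummarizedExperiment} with three numeric assays \code{p0},
#' \code{p1} and \code{p2}; a genotype with no usable trio is \code{NA} in
#' all three.  Variant identity is the exact tuple (chrom, pos, ref, alt),
#' carried in \code{rowRanges} with \code{ref}/\code{alt} metadata columns.
#'
#' @param p0,p1,p2 numeric matrices (variants x samples) of posterior
#'   probabilities for genotypes 0, 1 and 2.  Each non-missing trio must sum
#'   to 1 within 1e-4.
#' @param rowRanges a \code{GRanges} with one range per variant and metadata
#'   columns \code{ref} and \code{alt} (uppercase ACGT strings); an optional
#'   \code{quality} column carries a per-variant score from the imputation
#'   run (e.g. the RSQ emitted by the software), which is read as metadata
#'   and never recomputed.
#' @param samples character vector of sample identifiers (unique).
#' @param source free-text label of the imputation strategy that produced
#'   the run.
#'
#' @return An \code{ImputedGenotypes} object.
#' @seealso [readImputedVcf()], [writeImputedVcf()], [pMax()], [dosage()]
#' @examples
#' gr <- GenomicRanges::GRanges("1", IRanges::IRanges(c(100, 200), width = 1),
#'                              ref = c("A", "C"), alt = c("G", "T"))
#' p0 <- matrix(c(0.95, 0.1, 1, 0), 2, 2)
#' p1 <- matrix(c(0.05, 0.7, 0, 1), 2, 2)
#' p2 <- 1 - p0 - p1
#' ig <- ImputedGenotypes(p0, p1, p2, gr, samples = c("s1", "s2"),
#'                        source = "demo")
#' dosage(ig)
#' @export
ImputedGenotypes <- function(p0, p1, p2, rowRanges,
                             samples = colnames(p0), source = "unknown") {
  stopifnot(is.matrix(p0), is.matrix(p1), is.matrix(p2))
  if (is.null(samples))
    samples <- paste0("S", seq_len(ncol(p0)))
  rowRanges <- .checkVariantRanges(rowRanges)
  keys <- variantKeys(rowRanges)
  names(rowRanges) <- keys
  dimnames(p0) <- dimnames(p1) <- dimnames(p2) <- list(keys, samples)
  se <- SummarizedExperiment(
    assays = list(p0 = p0, p1 = p1, p2 = p2),
    rowRanges = rowRanges)
  new("ImputedGenotypes", se, source = source)
}

#' Container for truth (hard-call) genotypes
#'
#' Hard diploid genotypes coded as alternate-allele counts 0/1/2 (\code{NA}
#' for missing), typically taken from sequence data and used as the truth
#' set when evaluating an imputation run.  Per-variant minor allele
#' frequency (\code{maf}) and minor allele count (\code{mac}) are computed
#' over non-missing calls at construction and stored in \code{rowData}.
#'
#' @param calls integer/numeric matrix (variants x samples) with values in
#'   \{0, 1, 2, NA\}.
#' @param rowRanges a \code{GRanges} with \code{ref}/\code{alt} metadata
#'   columns, as for [ImputedGenotypes()].
#' @param samples character vector of sample identifiers.
#'
#' @return A \code{TruthGenotypes} object.
#' @seealso [readTruthVcf()], [mafValues()], [macValues()]
#' @export
TruthGenotypes <- function(calls, rowRanges, samples = colnames(calls)) {
  stopifnot(is.matrix(calls))
  if (is.null(samples))
    samples <- paste0("S", seq_len(ncol(calls)))
  storage.mode(calls) <- "integer"
  rowRanges <- .checkVariantRanges(rowRanges)
  keys <- variantKeys(rowRanges)
  names(rowRanges) <- keys
  dimnames(calls) <- list(keys, samples)
  nonmiss <- rowSums(!is.na(calls))
  altc <- rowSums(calls, na.rm = TRUE)
  af <- ifelse(nonmiss > 0, altc / (2 * nonmiss), NA_real_)
  mcols(rowRanges)$maf <- pmin(af, 1 - af)
  mcols(rowRanges)$mac <- as.integer(pmin(altc, 2 * nonmiss - altc))
  se <- SummarizedExperiment(assays = list(geno = calls),
                             rowRanges = rowRanges)
  new("TruthGenotypes", se)
}

setValidity("ImputedGenotypes", function(object) {
  msg <- character()
  if (!all(c("p0", "p1", "p2") %in% assayNames(object)))
    msg <- c(msg, "assays 'p0', 'p1', 'p2' are required")
  else {
    p0 <- assay(object, "p0"); p1 <- assay(object, "p1")
    p2 <- assay(object, "p2")
    pr <- c(p0, p1, p2)
    if (any(pr < -1e-9 | pr > 1 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "probabilities must lie in [0, 1]")
    s <- p0 + p1 + p2
    if (any(abs(s - 1) > 1e-4, na.rm = TRUE))
      msg <- c(msg, "each non-missing trio must sum to 1 within 1e-4")
    miss <- is.na(p0) + is.na(p1) + is.na(p2)
    if (any(miss %in% c(1L, 2L)))
      msg <- c(msg, "a trio must be missing in all three assays or none")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "variant keys must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample IDs must be unique")
  if (length(msg)) msg else TRUE
})

setValidity("TruthGenotypes", function(object) {
  msg <- character()
  if (!"geno" %in% assayNames(object))
    msg <- c(msg, "assay 'geno' is required")
  else {
    g <- assay(object, "geno")
    if (!all(g %in% c(0L, 1L, 2L, NA)))
      msg <- c(msg, "genotype calls must be in {0, 1, 2, NA}")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "variant keys must be unique")
  if (length(msg)) msg else TRUE
})

.checkVariantRanges <- function(gr) {
  if (!is(gr, "GRanges"))
    stop("rowRanges must be a GRanges")
  m <- mcols(gr)
  if (is.null(m$ref) || is.null(m$alt))
    stop("rowRanges must carry 'ref' and 'alt' metadata columns")
  ref <- as.character(m$ref); alt <- as.character(m$alt)
  bad <- !grepl("^[ACGT]+$", ref) | !grepl("^[ACGT]+$", alt) | ref == alt
  if (any(bad))
    stop(sum(bad), " variant(s) with invalid or identical ref/alt alleles ",
         "(symbolic and non-ACGT alleles are rejected)")
  if (any(start(gr) < 1))
    stop("variant positions must be >= 1 (1-based)")
  gr
}

#' Variant keys (chrom:pos_ref/alt)
#'
#' The exact-identity key used to match variants across runs and against a
#' truth set.  No strand flipping or allele normalisation is attempted.
#'
#' @param x a \code{GRanges} with \code{ref}/\code{alt} metadata columns, or
#'   an \code{ImputedGenotypes}/\code{TruthGenotypes} object.
#' @return character vector of keys, one per variant.
#' @export
variantKeys <- function(x) {
  if (is(x, "SummarizedExperiment")) x <- rowRanges(x)
  paste0(as.character(seqnames(x)), ":", start(x), "_",
         mcols(x)$ref, "/", mcols(x)$alt)
}

#' @rdname accessors
#' @export
setGeneric("pMax", function(x) standardGeneric("pMax"))
#' @rdname accessors
#' @export
setGeneric("gpArgmax", function(x) standardGeneric("gpArgmax"))
#' @rdname accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))
#' @rdname accessors
#' @export
setGeneric("sourceLabel", function(x) standardGeneric("sourceLabel"))
#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
#' @rdname accessors
#' @export
setGeneric("mafValues", function(x) standardGeneric("mafValues"))
#' @rdname accessors
#' @export
setGeneric("macValues", function(x) standardGeneric("macValues"))

#' Accessors for genotype containers
#'
#' \code{pMax} returns the per-genotype maximum posterior probability;
#' \code{gpArgmax} the most likely genotype (0/1/2; ties broken toward the
#' smaller genotype code); \code{dosage} the expected alternate-allele
#' dosage \eqn{p_1 + 2 p_2}; \code{sourceLabel} the strategy label of the
#' run; \code{genotypeCalls} the truth hard-call matrix; \code{mafValues}
#' and \code{macValues} the per-variant minor allele frequency and count of
#' a truth set (computed over non-missing calls).
#'
#' @param x an \code{ImputedGenotypes} or \code{TruthGenotypes} object.
#' @return A matrix (variants x samples) for the genotype-level accessors;
#'   a vector for the variant-level ones.
#' @name accessors
NULL

#' @rdname accessors
setMethod("pMax", "ImputedGenotypes", function(x) {
  pmax(assay(x, "p0"), assay(x, "p1"), assay(x, "p2"))
})

#' @rdname accessors
setMethod("gpArgmax", "ImputedGenotypes", function(x) {
  .argmaxTrio(assay(x, "p0"), assay(x, "p1"), assay(x, "p2"))
})

#' @rdname accessors
setMethod("dosage", "ImputedGenotypes", function(x) {
  assay(x, "p1") + 2 * assay(x, "p2")
})

#' @rdname accessors
setMethod("sourceLabel", "ImputedGenotypes", function(x) x@source)

#' @rdname accessors
setMethod("genotypeCalls", "TruthGenotypes", function(x) assay(x, "geno"))

#' @rdname accessors
setMethod("mafValues", "TruthGenotypes", function(x) {
  stats::setNames(mcols(rowRanges(x))$maf, rownames(x))
})

#' @rdname accessors
setMethod("macValues", "TruthGenotypes", function(x) {
  stats::setNames(mcols(rowRanges(x))$mac, rownames(x))
})

# argmax over three probability matrices/vectors; ties go to the smaller
# genotype code; NA trios stay NA
.argmaxTrio <- function(p0, p1, p2) {
  am <- ifelse(p0 >= p1 & p0 >= p2, 0L, ifelse(p1 >= p2, 1L, 2L))
  am[is.na(p0)] <- NA_integer_
  am
}

setMethod("show", "ImputedGenotypes", function(object) {
  cat("ImputedGenotypes:", nrow(object), "variants x", ncol(object),
      "samples\n")
  cat("  source:", object@source, "\n")
  miss <- sum(is.na(assay(object, "p0")))
  cat("  missing trios:", miss,
      sprintf("(%.2f%%)\n", 100 * miss / max(1, length(object) * ncol(object))))
  qc <- metadata(object)$qc
  if (!is.null(qc))
    cat("  QC:", paste(names(qc), unlist(qc), sep = "=", collapse = ", "),
        "\n")
})

setMethod("show", "TruthGenotypes", function(object) {
  cat("TruthGenotypes:", nrow(object), "variants x", ncol(object),
      "samples\n")
  maf <- mafValues(object)
  cat("  rare variants (MAF < 0.01):", sum(maf < 0.01, na.rm = TRUE), "\n")
})

#' Set of phased haplotype configurations from repeated phasing runs
#'
#' Holds K phasings of the same genotypes produced by running a phasing
#' algorithm K times with different random seeds.  Each replicate stores,
#' per variant and sample, the allele carried by each of the two haplotypes
#' (0 = ref, 1 = alt); an unphased or missing genotype in a replicate is
#' \code{NA} on both haplotypes for that replicate.  Phasing must not alter
#' genotype content, so \code{hapA + hapB} is required to be identical
#' across replicates wherever observed; K must be odd (and at least 3) so
#' that the majority-vote consensus orientation is unique.
#'
#' @param hapA,hapB integer arrays of dimension (variants, samples, K) with
#'   values 0/1/NA.
#' @param seeds replicate identifiers (defaults to 1..K).
#' @param positions optional variant positions (defaults to the row index).
#' @param samples optional sample identifiers.
#' @return A \code{SeedPhasingSet} object.
#' @seealso [estimateSer()], [consensusPhase()], [simulateSeedPhasings()]
#' @export
SeedPhasingSet <- function(hapA, hapB, seeds = seq_len(dim(hapA)[3]),
                           positions = seq_len(dim(hapA)[1]),
                           samples = NULL) {
  stopifnot(length(dim(hapA)) == 3, identical(dim(hapA), dim(hapB)))
  if (is.null(samples)) {
    samples <- dimnames(hapA)[[2]]
    if (is.null(samples)) samples <- paste0("S", seq_len(dim(hapA)[2]))
  }
  storage.mode(hapA) <- "integer"
  storage.mode(hapB) <- "integer"
  dimnames(hapA) <- dimnames(hapB) <-
    list(NULL, samples, as.character(seeds))
  new("SeedPhasingSet", hapA = hapA, hapB = hapB,
      seeds = as.character(seeds), positions = as.numeric(positions),
      samples = samples)
}

setClass("SeedPhasingSet",
  representation(hapA = "array", hapB = "array", seeds = "character",
                 positions = "numeric", samples = "character"))

setValidity("SeedPhasingSet", function(object) {
  msg <- character()
  K <- dim(object@hapA)[3]
  if (K < 3 || K %% 2 == 0)
    msg <- c(msg, "K must be odd and >= 3 for a unique majority consensus")
  ok <- object@hapA %in% c(0L, 1L, NA) & object@hapB %in% c(0L, 1L, NA)
  if (!all(ok))
    msg <- c(msg, "haplotype alleles must be 0/1/NA")
  g <- object@hapA + object@hapB
  ref <- .firstNonNA(g)
  for (k in seq_len(K)) {
    gk <- g[, , k]
    bad <- !is.na(gk) & !is.na(ref) & gk != ref
    if (any(bad)) {
      msg <- c(msg, sprintf(
        "replicate %d disagrees on genotype content at %d site(s); phasing must preserve genotypes",
        k, sum(bad)))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

# per-cell first non-NA slice of a 3d array along the third margin;
# always returns a matrix with the array's row/column dimnames
.firstNonNA <- function(a) {
  d <- dim(a)
  out <- matrix(a[, , 1], d[1], d[2], dimnames = dimnames(a)[1:2])
  if (d[3] > 1) {
    for (k in 2:d[3]) {
      idx <- is.na(out)
      if (!any(idx)) break
      slice <- matrix(a[, , k], d[1], d[2])
      out[idx] <- slice[idx]
    }
  }
  out
}

#' @rdname SeedPhasingSet
#' @param object,x a \code{SeedPhasingSet}.
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))

#' @rdname SeedPhasingSet
setMethod("nReplicates", "SeedPhasingSet", function(x) dim(x@hapA)[3])

setMethod("show", "SeedPhasingSet", function(object) {
  d <- dim(object@hapA)
  cat("SeedPhasingSet:", d[1], "variants x", d[2], "samples x", d[3],
      "phasing replicates\n")
})

setClass("SharingMatrix",
  representation(all = "matrix", long = "matrix", short = "matrix",
                 threshold = "numeric"))

setMethod("show", "SharingMatrix", function(object) {
  cat("SharingMatrix:", nrow(object@all), "target group(s) x",
      ncol(object@all), "reference cluster(s); length threshold",
      object@threshold, "cM\n")
  cat("mean total sharing (all segments, cM):\n")
  print(round(object@all, 3))
})

#' Extract one length class from a sharing matrix
#'
#' @param x a \code{SharingMatrix} from [groupSharingMatrix()].
#' @param lengthClass \code{"all"}, \code{"long"} (> threshold) or
#'   \code{"short"} (<= threshold).
#' @return numeric matrix, target groups x reference clusters, of mean total
#'   shared length in cM.
#' @export
sharingCells <- function(x, lengthClass = c("all", "long", "short")) {
  stopifnot(is(x, "SharingMatrix"))
  slot(x, match.arg(lengthClass))
}
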