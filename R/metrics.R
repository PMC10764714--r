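#' Build a 3x3 truth-vs-imputed contingency table
#'
#' Cross-tabulates truth genotypes against imputed genotype probability
#' mass.  In the default posterior mode, the genotype with truth \eqn{j}
#' contributes its full trio to row \eqn{j}: cell \eqn{n_{jk}} is the summed
#' posterior probability of genotype \eqn{k} over all genotypes whose truth
#' is \eqn{j} (fractional counts).  In hard-call mode each trio is first
#' collapsed to a point mass on its most likely genotype, giving an integer
#' table of best-guess concordance.  Genotypes with missing truth or a
#' missing trio are excluded, so table totals only count evaluable
#' genotypes.
#'
#' @param p0,p1,p2 numeric vectors (or matrices, flattened) of posterior
#'   probabilities for genotypes 0, 1, 2.
#' @param truth integer vector of matching truth calls in \{0, 1, 2, NA\}.
#' @param mode \code{"posterior"} (fractional, the default) or
#'   \code{"hardcall"} (argmax point masses).
#' @return A 3x3 numeric matrix with rows = truth genotype, columns =
#'   imputed genotype, and attribute \code{n} giving the number of included
#'   genotypes.  An all-zero table with \code{n = 0} is the empty sentinel.
#' @seealso [iqsFromTable()]
#' @examples
#' buildContingency(c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 0, 0),
#'                  truth = c(0, 0, 1, 2))
#' @export
buildContingency <- function(p0, p1, p2, truth,
                             mode = c("posterior", "hardcall")) {
  mode <- match.arg(mode)
  p0 <- as.vector(p0); p1 <- as.vector(p1); p2 <- as.vector(p2)
  truth <- as.vector(truth)
  stopifnot(length(p0) == length(truth), length(p1) == length(truth),
            length(p2) == length(truth))
  keep <- !is.na(truth) & !is.na(p0) & !is.na(p1) & !is.na(p2)
  tab <- matrix(0, 3, 3, dimnames = list(truth = 0:2, imputed = 0:2))
  if (!any(keep)) {
    attr(tab, "n") <- 0L
    return(tab)
  }
  p0 <- p0[keep]; p1 <- p1[keep]; p2 <- p2[keep]; truth <- truth[keep]
  if (mode == "hardcall") {
    am <- .argmaxTrio(p0, p1, p2)
    p0 <- as.numeric(am == 0L)
    p1 <- as.numeric(am == 1L)
    p2 <- as.numeric(am == 2L)
  }
  for (j in 0:2) {
    idx <- truth == j
    tab[j + 1, ] <- c(sum(p0[idx]), sum(p1[idx]), sum(p2[idx]))
  }
  attr(tab, "n") <- length(truth)
  tab
}

#' Imputation Quality Score from a contingency table
#'
#' The IQS is Cohen's kappa applied to the truth-vs-imputed genotype table:
#' the observed agreement \eqn{P_o = \sum_j n_{jj} / N} corrected for the
#' agreement expected by chance from the table margins,
#' \eqn{P_c = \sum_j r_j c_j / N^2}, giving
#' \eqn{IQS = (P_o - P_c) / (1 - P_c)}.  A perfectly imputed set scores 1;
#' a predictor carrying no information beyond the genotype frequencies
#' scores 0.  When \eqn{1 - P_c} vanishes (e.g. a monomorphic stratum
#' predicted monomorphic) the score is undefined and flagged rather than
#' coerced to 0 or 1.
#'
#' @param tab a 3x3 table from [buildContingency()].
#' @return A list with elements \code{p_o}, \code{p_c}, \code{iqs},
#'   \code{n_genotypes} and \code{defined}.  \code{iqs} is \code{NA} when
#'   undefined (including the empty table).
#' @examples
#' tab <- buildContingency(c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 0, 0),
#'                         truth = c(0, 0, 1, 2))
#' iqsFromTable(tab)$iqs   # 0.6
#' @export
iqsFromTable <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(3, 3)))
  n <- attr(tab, "n")
  if (is.null(n)) n <- sum(tab)
  N <- sum(tab)
  if (N <= 0)
    return(list(p_o = NA_real_, p_c = NA_real_, iqs = NA_real_,
                n_genotypes = 0L, defined = FALSE))
  p_o <- sum(diag(tab)) / N
  p_c <- sum(rowSums(tab) * colSums(tab)) / N^2
  defined <- (1 - p_c) >= 1e-12
  iqs <- if (defined) (p_o - p_c) / (1 - p_c) else NA_real_
  list(p_o = p_o, p_c = p_c, iqs = iqs, n_genotypes = as.integer(n),
       defined = defined)
}

# check/align an imputed run against a truth set on shared keys and samples
.alignToTruth <- function(imputed, truth) {
  vk <- intersect(rownames(imputed), rownames(truth))
  sk <- intersect(colnames(imputed), colnames(truth))
  if (length(vk) == 0) stop("no shared variants between run and truth set")
  if (length(sk) == 0) stop("no shared samples between run and truth set")
  list(imputed = imputed[vk, sk], truth = truth[vk, sk])
}

#' Stratified IQS
#'
#' Computes the IQS separately within strata along one axis: per individual
#' (all of one sample's genotypes pooled into one table, the per-individual
#' score used for geographic gradients), per variant (pooled across
#' samples), per genomic region (all genotypes of variants inside each
#' region; overlapping regions each receive a copy), per MAF bin
#' (rare/common split of truth-set minor allele frequency at a threshold,
#' default 0.01), or by an arbitrary genotype-level logical mask
#' (inside/outside strata).  MAF always comes from the truth set, never
#' from imputed dosages.  A stratum with no evaluable genotypes yields an
#' undefined score, flagged in the \code{defined} column.
#'
#' @param imputed an [ImputedGenotypes] object.
#' @param truth a [TruthGenotypes] object; the two are intersected on
#'   variant keys and sample IDs.
#' @param axis stratification axis: \code{"individual"}, \code{"variant"},
#'   \code{"maf_bin"}, \code{"region"} or \code{"mask"}.
#' @param regions a \code{GRanges} of regions (required for the region
#'   axis); names are used as stratum labels.
#' @param mask logical matrix (variants x samples, aligned dimensions) for
#'   the mask axis.
#' @param mafThreshold rare/common MAF boundary (default 0.01).
#' @param mode passed to [buildContingency()].
#' @return A data.frame with columns \code{stratum}, \code{n_genotypes},
#'   \code{p_o}, \code{p_c}, \code{iqs}, \code{defined}.
#' @export
iqsStratified <- function(imputed, truth,
                          axis = c("individual", "variant", "maf_bin",
                                   "region", "mask"),
                          regions = NULL, mask = NULL, mafThreshold = 0.01,
                          mode = c("posterior", "hardcall")) {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  al <- .alignToTruth(imputed, truth)
  imputed <- al$imputed; truth <- al$truth
  p0 <- assay(imputed, "p0"); p1 <- assay(imputed, "p1")
  p2 <- assay(imputed, "p2")
  g <- genotypeCalls(truth)

  strata <- switch(axis,
    individual = lapply(stats::setNames(seq_len(ncol(g)), colnames(g)),
      function(j) cbind(seq_len(nrow(g)), j)),
    variant = lapply(stats::setNames(seq_len(nrow(g)), rownames(g)),
      function(i) cbind(i, seq_len(ncol(g)))),
    maf_bin = {
      maf <- mafValues(truth)
      rare <- which(!is.na(maf) & maf < mafThreshold)
      common <- which(!is.na(maf) & maf >= mafThreshold)
      lbl <- c(sprintf("maf_lt_%g", mafThreshold),
               sprintf("maf_ge_%g", mafThreshold))
      stats::setNames(lapply(list(rare, common), function(rows)
        if (length(rows)) cbind(rep(rows, ncol(g)),
                                rep(seq_len(ncol(g)), each = length(rows)))
        else matrix(integer(), 0, 2)), lbl)
    },
    region = {
      if (is.null(regions)) stop("axis 'region' requires a GRanges of regions")
      lbl <- names(regions)
      if (is.null(lbl)) lbl <- paste0("region_", seq_along(regions))
      hits <- GenomicRanges::findOverlaps(rowRanges(imputed), regions)
      stats::setNames(lapply(seq_along(regions), function(r) {
        rows <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == r]
        if (length(rows)) cbind(rep(rows, ncol(g)),
                                rep(seq_len(ncol(g)), each = length(rows)))
        else matrix(integer(), 0, 2)
      }), lbl)
    },
    mask = {
      if (is.null(mask) || !identical(dim(mask), dim(g)))
        stop("axis 'mask' requires a logical matrix matching the aligned ",
             "variants x samples dimensions")
      list(inside = which(mask, arr.ind = TRUE),
           outside = which(!mask, arr.ind = TRUE))
    })

  res <- lapply(strata, function(idx) {
    r <- iqsFromTable(buildContingency(p0[idx], p1[idx], p2[idx],
                                       g[idx], mode = mode))
    data.frame(n_genotypes = r$n_genotypes, p_o = r$p_o, p_c = r$p_c,
               iqs = r$iqs, defined = r$defined)
  })
  out <- do.call(rbind, res)
  out <- cbind(stratum = names(strata), out)
  rownames(out) <- NULL
  out
}

#' Dosage distribution at truth-heterozygous genotypes, split by a mask
#'
#' For every genotype whose truth call is heterozygous, tabulates the
#' imputed dosage \eqn{p_1 + 2 p_2} into histograms inside and outside a
#' genotype-level mask (typically: variants lying within long IBD segments
#' shared with a reference cluster, versus outside them).  A perfectly
#' imputed heterozygote contributes at dosage 1, so the mass near 1 is a
#' direct readout of rare-heterozygote imputation success.
#'
#' @param imputed an [ImputedGenotypes] object.
#' @param truth a [TruthGenotypes] object (intersected with the run).
#' @param mask logical matrix matching the aligned variants x samples
#'   dimensions; \code{TRUE} = inside.
#' @param binWidth histogram bin width on [0, 2] (default 0.05).
#' @return data.frame with columns \code{bin_left}, \code{bin_right},
#'   \code{count_inside}, \code{count_outside}.
#' @export
hetDosageDistribution <- function(imputed, truth, mask, binWidth = 0.05) {
  al <- .alignToTruth(imputed, truth)
  imputed <- al$imputed; truth <- al$truth
  if (!identical(dim(mask), dim(imputed)))
    stop("mask dimensions must match the aligned variants x samples grid")
  ds <- dosage(imputed)
  g <- genotypeCalls(truth)
  het <- !is.na(g) & g == 1L & !is.na(ds)
  breaks <- seq(0, 2, by = binWidth)
  if (breaks[length(breaks)] < 2) breaks <- c(breaks, 2)
  clampCut <- function(x) {
    x <- pmin(pmax(x, 0), 2)
    table(cut(x, breaks = breaks, include.lowest = TRUE, right = FALSE,
              labels = FALSE))
  }
  count <- function(sel) {
    out <- numeric(length(breaks) - 1)
    if (any(sel)) {
      tb <- clampCut(ds[sel])
      out[as.integer(names(tb))] <- as.numeric(tb)
    }
    out
  }
  data.frame(bin_left = breaks[-length(breaks)], bin_right = breaks[-1],
             count_inside = count(het & mask),
             count_outside = count(het & !mask))
}
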