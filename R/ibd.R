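#' Read pairwise IBD segments
#'
#' Reads a RefinedIBD-style tab-delimited segment list with columns
#' sample1, hap1, sample2, hap2, chrom, start, end, LOD, length_cM.
#' Physical coordinates are 1-based inclusive base pairs; the genetic
#' length column is required (no genetic map is ever consulted).
#' Malformed rows (non-numeric coordinates, end < start, non-positive
#' length, identical samples) are rejected with their line numbers.
#'
#' @param path file path (plain or gzipped tab-delimited text).
#' @return data.frame with columns \code{sample1}, \code{hap1},
#'   \code{sample2}, \code{hap2}, \code{chrom}, \code{start}, \code{end},
#'   \code{lod}, \code{length_cm}.
#' @export
readIbdSegments <- function(path) {
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = "character", quote = "",
                      blank.lines.skip = FALSE),
    error = function(e) data.frame())
  if (nrow(raw) == 0)
    return(data.frame(sample1 = character(), hap1 = integer(),
                      sample2 = character(), hap2 = integer(),
                      chrom = character(), start = numeric(),
                      end = numeric(), lod = numeric(),
                      length_cm = numeric()))
  if (ncol(raw) < 9)
    stop("configuration error: expected 9 tab-delimited columns ",
         "(sample1 hap1 sample2 hap2 chrom start end LOD length_cM); ",
         "a genetic-length column is required")
  seg <- data.frame(
    sample1 = raw[[1]],
    hap1 = suppressWarnings(as.integer(raw[[2]])),
    sample2 = raw[[3]],
    hap2 = suppressWarnings(as.integer(raw[[4]])),
    chrom = raw[[5]],
    start = suppressWarnings(as.numeric(raw[[6]])),
    end = suppressWarnings(as.numeric(raw[[7]])),
    lod = suppressWarnings(as.numeric(raw[[8]])),
    length_cm = suppressWarnings(as.numeric(raw[[9]])))
  bad <- is.na(seg$start) | is.na(seg$end) | is.na(seg$length_cm) |
    seg$end < seg$start | seg$length_cm <= 0 | seg$sample1 == seg$sample2
  if (any(bad)) {
    warning("rejected ", sum(bad), " malformed IBD row(s) at line(s): ",
            paste(utils::head(which(bad), 10), collapse = ", "))
    seg <- seg[!bad, , drop = FALSE]
  }
  rownames(seg) <- NULL
  seg
}

#' Read a two-column sample-to-group table
#'
#' @param path tab-delimited file with columns sample, label (no header).
#' @return named character vector: group label per sample.
#' @export
readGroupTable <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "")
  stats::setNames(tb[[2]], tb[[1]])
}

#' Group-level IBD sharing matrix
#'
#' Aggregates pairwise IBD segments into mean total sharing between target
#' groups (e.g. recruitment cities) and reference clusters.  For each
#' target individual and cluster, the total is the sum of \code{length_cm}
#' over all segments linking that individual to any member of the cluster
#' — each segment counted once, overlapping segments summed (total
#' sharing, not coverage).  The matrix cell is the mean of these totals
#' over the individuals of the target group, where individuals with no
#' segments contribute zeros (otherwise group means are inflated).
#' Segments are split into a long class (\code{length_cm > threshold}) and
#' a short class (\code{<=}), so that all = long + short holds cell-wise
#' exactly.  Segments not linking a target-labelled to a
#' reference-labelled sample are ignored and counted.
#'
#' @param segments data.frame from [readIbdSegments()] or
#'   [simulateIbdSegments()].
#' @param targets named character vector: target group label per sample.
#' @param refs named character vector: reference cluster label per sample.
#' @param threshold length-class boundary in cM (default 3).
#' @return A \code{SharingMatrix} (see [sharingCells()]); the number of
#'   ignored segments is in \code{attr(, "n_ignored")} of the \code{all}
#'   matrix.
#' @export
groupSharingMatrix <- function(segments, targets, refs, threshold = 3.0) {
  tg <- sort(unique(unname(targets)))
  rg <- sort(unique(unname(refs)))
  tSamples <- names(targets)

  # orient each segment as (target sample, ref cluster); a segment whose
  # two members are both target- and ref-labelled is counted for both
  # orientations of (individual, cluster) totals
  s1t <- segments$sample1 %in% tSamples & segments$sample2 %in% names(refs)
  s2t <- segments$sample2 %in% tSamples & segments$sample1 %in% names(refs)
  nIgnored <- sum(!(s1t | s2t))

  mk <- function() matrix(0, length(tSamples), length(rg),
                          dimnames = list(tSamples, rg))
  addTotals <- function(sel, tSide, rSide, long, short) {
    if (!any(sel)) return(list(long = long, short = short))
    ts <- segments[[tSide]][sel]
    cl <- refs[segments[[rSide]][sel]]
    len <- segments$length_cm[sel]
    isLong <- len > threshold
    for (cls in c(TRUE, FALSE)) {
      ss <- which(isLong == cls)
      if (!length(ss)) next
      agg <- stats::aggregate(len[ss],
                              by = list(t = ts[ss], c = cl[ss]), FUN = sum)
      idx <- cbind(match(agg$t, tSamples), match(agg$c, rg))
      if (cls) long[idx] <- long[idx] + agg$x
      else short[idx] <- short[idx] + agg$x
    }
    list(long = long, short = short)
  }
  long <- mk(); short <- mk()
  r <- addTotals(s1t, "sample1", "sample2", long, short)
  r <- addTotals(s2t, "sample2", "sample1", r$long, r$short)
  long <- r$long; short <- r$short

  groupMean <- function(perInd) {
    out <- matrix(NA_real_, length(tg), length(rg),
                  dimnames = list(tg, rg))
    for (grp in tg) {
      members <- tSamples[unname(targets) == grp]
      if (length(members))
        out[grp, ] <- colMeans(perInd[members, , drop = FALSE])
    }
    out
  }
  mAll <- groupMean(long + short)
  attr(mAll, "n_ignored") <- nIgnored
  new("SharingMatrix", all = mAll, long = groupMean(long),
      short = groupMean(short), threshold = threshold)
}

#' Merged IBD intervals of one individual with a reference group
#'
#' Returns the union of the physical spans of all segments linking the
#' individual to any member of the reference group with genetic length
#' above a threshold, merged where overlapping (coverage semantics — in
#' contrast to the summed totals of [groupSharingMatrix()]).  The result
#' is suitable as a genomic mask, e.g. for [hetDosageDistribution()].
#'
#' @param segments IBD segment data.frame.
#' @param individual sample ID.
#' @param refGroup character vector of reference sample IDs.
#' @param minCm minimum genetic length in cM (default 3; strict).
#' @return A reduced \code{GRanges} (possibly empty).
#' @export
ibdIntervals <- function(segments, individual, refGroup, minCm = 3.0) {
  sel <- ((segments$sample1 == individual & segments$sample2 %in% refGroup) |
          (segments$sample2 == individual & segments$sample1 %in% refGroup)) &
    segments$length_cm > minCm
  if (!any(sel))
    return(GRanges())
  GenomicRanges::reduce(GRanges(segments$chrom[sel],
                                IRanges(segments$start[sel],
                                        segments$end[sel])))
}

#' Genotype-level mask from IBD intervals
#'
#' Builds the variants x samples logical mask marking, for each sample,
#' the variants lying inside that sample's merged long-IBD intervals with
#' the reference group.  The mask feeds the inside/outside dosage
#' stratification of [hetDosageDistribution()] or the mask axis of
#' [iqsStratified()].
#'
#' @param x an [ImputedGenotypes] or [TruthGenotypes] object giving the
#'   variant grid and samples.
#' @param segments IBD segment data.frame.
#' @param refGroup character vector of reference sample IDs.
#' @param minCm minimum segment length in cM (default 3).
#' @return logical matrix, variants x samples.
#' @export
ibdMask <- function(x, segments, refGroup, minCm = 3.0) {
  gr <- rowRanges(x)
  mask <- matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(assay(x, 1)))
  for (s in colnames(x)) {
    iv <- ibdIntervals(segments, s, refGroup, minCm = minCm)
    if (length(iv))
      mask[, s] <- IRanges::overlapsAny(gr, iv)
  }
  mask
}

#' Write a sharing matrix as a tab-delimited table
#'
#' @param x a \code{SharingMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSharingMatrix <- function(x, path) {
  stopifnot(is(x, "SharingMatrix"))
  rows <- lapply(c("all", "long", "short"), function(cls) {
    m <- sharingCells(x, cls)
    data.frame(length_class = cls,
               target_group = rep(rownames(m), ncol(m)),
               ref_cluster = rep(colnames(m), each = nrow(m)),
               mean_total_cm = as.vector(m))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
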