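#' Configuration of the most-confident-vote merge
#'
#' The merge of two imputation runs retains, genotype by genotype, the trio
#' of posterior probabilities whose maximum is larger by more than a margin
#' \code{delta}; otherwise the run designated as the priority source wins.
#' With the defaults (\code{delta = 0.05}, priority to run B) run A's trio
#' is retained iff \eqn{p_{max}(A) > p_{max}(B) + 0.05} (strict), which
#' gives the non-priority run the burden of proof when the two maxima are
#' close.  Both knobs are configurable because the margin is an empirical
#' choice, not a derived quantity.
#'
#' @param delta priority margin in probability units, in [0, 1).
#' @param priority which run wins when neither exceeds the other by more
#'   than \code{delta}: \code{"b"} (default) or \code{"a"}.
#' @return A list of class \code{"HybridConfig"}.
#' @export
hybridConfig <- function(delta = 0.05, priority = c("b", "a")) {
  priority <- match.arg(priority)
  if (!is.numeric(delta) || length(delta) != 1 || is.na(delta) ||
      delta < 0 || delta >= 1)
    stop("delta must be a single number in [0, 1)")
  structure(list(delta = delta, priority = priority),
            class = "HybridConfig")
}

#' Select the more confident of two posterior trios
#'
#' Applies the most-confident-vote rule to a single genotype.  The retained
#' trio is emitted unchanged — the rule selects, it never blends.  A
#' missing trio on one side yields the other side with an \code{*_only}
#' label; both missing yields a missing result.
#'
#' @param a,b numeric length-3 probability trios (or \code{NULL}/all-NA for
#'   missing).
#' @param cfg a [hybridConfig()].
#' @return list with \code{trio} (numeric length-3 or \code{NA}s) and
#'   \code{source} (\code{"A_selected"}, \code{"B_selected"},
#'   \code{"A_only"}, \code{"B_only"} or \code{"missing"}).
#' @examples
#' selectTrio(c(0.95, 0.05, 0), c(0.85, 0.15, 0))  # retains A: 0.95 > 0.90
#' @export
selectTrio <- function(a, b, cfg = hybridConfig()) {
  stopifnot(inherits(cfg, "HybridConfig"))
  missA <- is.null(a) || all(is.na(a))
  missB <- is.null(b) || all(is.na(b))
  if (missA && missB)
    return(list(trio = rep(NA_real_, 3), source = "missing"))
  if (missA) return(list(trio = b, source = "B_only"))
  if (missB) return(list(trio = a, source = "A_only"))
  useA <- if (cfg$priority == "b")
    max(a) > max(b) + cfg$delta
  else
    !(max(b) > max(a) + cfg$delta)
  if (useA) list(trio = a, source = "A_selected")
  else list(trio = b, source = "B_selected")
}

#' Accord/Discord classification of two trios
#'
#' Two imputation runs are in Accord at a genotype when their most likely
#' genotypes coincide, and in Discord otherwise.  Within-trio argmax ties
#' are broken toward the smaller genotype code, deterministically.
#'
#' @param a,b numeric length-3 probability trios.
#' @return \code{"Accord"}, \code{"Discord"} or \code{"n/a"} (a missing
#'   trio).
#' @export
classifyConcordance <- function(a, b) {
  if (is.null(a) || all(is.na(a)) || is.null(b) || all(is.na(b)))
    return("n/a")
  if (.argmaxTrio(a[1], a[2], a[3]) == .argmaxTrio(b[1], b[2], b[3]))
    "Accord" else "Discord"
}

#' Merge two imputation runs by the most-confident-vote rule
#'
#' Produces a combined run over the union of the two variant sets.
#' Variants imputed by only one run are copied through (\code{A_only} /
#' \code{B_only}); at shared variants the rule of [selectTrio()] is applied
#' independently per genotype, so two individuals at the same variant may
#' draw from different sources.  Trios are never altered by merging.  The
#' provenance records, per genotype, the selected source and the
#' Accord/Discord concordance of the two runs (defined only where both
#' trios exist).
#'
#' @param a,b [ImputedGenotypes] runs with overlapping samples.
#' @param cfg a [hybridConfig()].
#' @param matchSwaps passed to [alignRuns()]: also match variants whose
#'   ref/alt are swapped between runs (B's trio is reversed).
#' @return list with \code{merged} (an [ImputedGenotypes] over the union,
#'   source label \code{"A+B"} style), \code{source} and \code{concordance}
#'   (character matrices, union variants x samples), and \code{alignment}
#'   (the [alignRuns()] result).
#' @export
mergeRuns <- function(a, b, cfg = hybridConfig(), matchSwaps = FALSE) {
  stopifnot(is(a, "ImputedGenotypes"), is(b, "ImputedGenotypes"),
            inherits(cfg, "HybridConfig"))
  al <- alignRuns(a, b, matchSwaps = matchSwaps)
  a <- al$a; b <- al$b
  keysU <- al$union
  smp <- colnames(a)
  nU <- length(keysU); nS <- length(smp)

  mk <- function() matrix(NA_real_, nU, nS, dimnames = list(keysU, smp))
  p0 <- mk(); p1 <- mk(); p2 <- mk()
  src <- matrix("missing", nU, nS, dimnames = list(keysU, smp))
  conc <- matrix("n/a", nU, nS, dimnames = list(keysU, smp))

  inA <- keysU %in% rownames(a)
  inB <- keysU %in% rownames(b)
  onlyA <- which(inA & !inB); onlyB <- which(inB & !inA)
  both <- which(inA & inB)

  if (length(onlyA)) {
    ka <- keysU[onlyA]
    p0[onlyA, ] <- assay(a, "p0")[ka, , drop = FALSE]
    p1[onlyA, ] <- assay(a, "p1")[ka, , drop = FALSE]
    p2[onlyA, ] <- assay(a, "p2")[ka, , drop = FALSE]
    src[onlyA, ] <- ifelse(is.na(p0[onlyA, , drop = FALSE]),
                           "missing", "A_only")
  }
  if (length(onlyB)) {
    kb <- keysU[onlyB]
    p0[onlyB, ] <- assay(b, "p0")[kb, , drop = FALSE]
    p1[onlyB, ] <- assay(b, "p1")[kb, , drop = FALSE]
    p2[onlyB, ] <- assay(b, "p2")[kb, , drop = FALSE]
    src[onlyB, ] <- ifelse(is.na(p0[onlyB, , drop = FALSE]),
                           "missing", "B_only")
  }
  if (length(both)) {
    kk <- keysU[both]
    a0 <- assay(a, "p0")[kk, , drop = FALSE]
    a1 <- assay(a, "p1")[kk, , drop = FALSE]
    a2 <- assay(a, "p2")[kk, , drop = FALSE]
    b0 <- assay(b, "p0")[kk, , drop = FALSE]
    b1 <- assay(b, "p1")[kk, , drop = FALSE]
    b2 <- assay(b, "p2")[kk, , drop = FALSE]
    pmA <- pmax(a0, a1, a2); pmB <- pmax(b0, b1, b2)
    missA <- is.na(a0); missB <- is.na(b0)
    useA <- if (cfg$priority == "b") pmA > pmB + cfg$delta
            else !(pmB > pmA + cfg$delta)
    useA[missA] <- FALSE
    useA[missB & !missA] <- TRUE
    pick <- function(xa, xb) ifelse(useA, xa, xb)
    p0[both, ] <- pick(a0, b0)
    p1[both, ] <- pick(a1, b1)
    p2[both, ] <- pick(a2, b2)
    lab <- ifelse(missA & missB, "missing",
           ifelse(missA, "B_only",
           ifelse(missB, "A_only",
           ifelse(useA, "A_selected", "B_selected"))))
    src[both, ] <- lab
    amA <- .argmaxTrio(a0, a1, a2)
    amB <- .argmaxTrio(b0, b1, b2)
    cc <- ifelse(is.na(amA) | is.na(amB), "n/a",
                 ifelse(amA == amB, "Accord", "Discord"))
    conc[both, ] <- cc
  }

  rr <- al$unionRanges
  merged <- ImputedGenotypes(p0, p1, p2, rr, samples = smp,
                             source = paste0(sourceLabel(a), "+",
                                             sourceLabel(b)))
  list(merged = merged, source = src, concordance = conc, alignment = al)
}

#' Long-format provenance table of a merge
#'
#' @param merge result of [mergeRuns()].
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{sample}, \code{source}, \code{concordance}, one row
#'   per genotype of the merged run.
#' @export
provenanceTable <- function(merge) {
  m <- merge$merged
  gr <- rowRanges(m)
  nV <- nrow(m); nS <- ncol(m)
  data.frame(
    chrom = rep(as.character(seqnames(gr)), nS),
    pos = rep(start(gr), nS),
    ref = rep(mcols(gr)$ref, nS),
    alt = rep(mcols(gr)$alt, nS),
    sample = rep(colnames(m), each = nV),
    source = as.vector(merge$source),
    concordance = as.vector(merge$concordance))
}

#' Per-individual IQS and correct-call fractions in Accord/Discord sets
#'
#' Splits the genotypes at variants imputed by both runs into the Accord
#' set (the two runs name the same most likely genotype) and the Discord
#' set, then reports, per individual: the Accord fraction; within Accord,
#' the fraction where the shared best guess equals the truth; within
#' Discord, the fraction where each source's best guess — and the merged
#' run's — equals the truth; and posterior-weighted IQS within each set.
#' Individuals with an empty Discord set get flagged undefined entries.
#'
#' @param a,b the two [ImputedGenotypes] runs.
#' @param merge the result of [mergeRuns()] on the same runs.
#' @param truth a [TruthGenotypes] object.
#' @return data.frame, one row per individual, with count, fraction and
#'   IQS columns for the Accord and Discord sets.
#' @export
accordSplitIqs <- function(a, b, merge, truth) {
  al <- merge$alignment
  a <- al$a; b <- al$b
  keys <- intersect(al$intersection, rownames(truth))
  smp <- intersect(colnames(a), colnames(truth))
  if (length(keys) == 0 || length(smp) == 0)
    stop("no overlap between the merged runs and the truth set")
  a <- a[keys, smp]; b <- b[keys, smp]
  m <- merge$merged[keys, smp]
  conc <- merge$concordance[keys, smp, drop = FALSE]
  g <- genotypeCalls(truth[keys, smp])
  amA <- gpArgmax(a); amB <- gpArgmax(b); amM <- gpArgmax(m)

  one <- function(j) {
    cj <- conc[, j]; gj <- g[, j]
    ok <- cj != "n/a" & !is.na(gj)
    acc <- ok & cj == "Accord"
    dis <- ok & cj == "Discord"
    frac <- function(x) if (length(x)) mean(x) else NA_real_
    iqsIn <- function(sel, run) {
      r <- iqsFromTable(buildContingency(
        assay(run, "p0")[sel, j], assay(run, "p1")[sel, j],
        assay(run, "p2")[sel, j], gj[sel]))
      r$iqs
    }
    data.frame(
      sample = colnames(g)[j],
      n_evaluable = sum(ok),
      n_accord = sum(acc),
      n_discord = sum(dis),
      accord_frac = if (sum(ok)) sum(acc) / sum(ok) else NA_real_,
      accord_correct = frac(amA[acc, j] == gj[acc]),
      discord_correct_a = frac(amA[dis, j] == gj[dis]),
      discord_correct_b = frac(amB[dis, j] == gj[dis]),
      discord_correct_merged = frac(amM[dis, j] == gj[dis]),
      iqs_accord = if (sum(acc)) iqsIn(acc, m) else NA_real_,
      iqs_discord_a = if (sum(dis)) iqsIn(dis, a) else NA_real_,
      iqs_discord_b = if (sum(dis)) iqsIn(dis, b) else NA_real_,
      iqs_discord_merged = if (sum(dis)) iqsIn(dis, m) else NA_real_,
      discord_defined = sum(dis) > 0)
  }
  out <- do.call(rbind, lapply(seq_along(smp), one))
  rownames(out) <- NULL
  out
}
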