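#' Read an imputed VCF with per-genotype posterior probabilities
#'
#' Reads a VCF (plain or gzipped) produced by imputation software and
#' returns the posterior genotype probability trios.  Only biallelic
#' SNV/indel records with ACGT alleles are kept; multiallelic and symbolic
#' records are excluded and counted.  A missing probability entry yields a
#' missing trio, never a fabricated one.  Trios whose probabilities sum to
#' 1 within 1e-2 are renormalized to sum exactly 1; trios deviating further
#' are set to missing and counted in the QC summary, which is stored in
#' \code{metadata(x)$qc}.  A per-variant quality score (INFO key \code{R2}
#' or \code{RSQ}, as emitted by the imputation run) is read as metadata
#' into \code{rowRanges()$quality} when present — it is never recomputed.
#'
#' @param path VCF file path.
#' @param gpField FORMAT field carrying the three genotype probabilities
#'   (default \code{"GP"}; pipelines differ in dialect).
#' @param region optional \code{"chrom"} or \code{"chrom:start-end"} filter
#'   (1-based inclusive).
#' @param source strategy label recorded on the returned object (defaults
#'   to the file name).
#' @return An [ImputedGenotypes] object.
#' @export
readImputedVcf <- function(path, gpField = "GP", region = NULL,
                           source = basename(path)) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  n0 <- nrow(fix)
  if (n0 == 0) stop("no records in ", path)
  keep <- .biallelicMask(fix)
  nMulti <- sum(!keep)
  if (!is.null(region)) {
    rg <- .parseRegion(region)
    keep <- keep & fix[, "CHROM"] == rg$chrom &
      as.numeric(fix[, "POS"]) >= rg$start &
      as.numeric(fix[, "POS"]) <= rg$end
  }
  if (!any(keep)) stop("no biallelic records retained from ", path)
  vcf <- vcf[keep, ]
  fix <- vcf@fix

  gp <- tryCatch(vcfR::extract.gt(vcf, element = gpField),
                 error = function(e) NULL)
  if (is.null(gp) || all(is.na(gp)))
    stop("configuration error: FORMAT field '", gpField,
         "' absent from all records of ", path)
  suppressWarnings({
    p0 <- vcfR::masplit(gp, delim = ",", record = 1, sort = 0)
    p1 <- vcfR::masplit(gp, delim = ",", record = 2, sort = 0)
    p2 <- vcfR::masplit(gp, delim = ",", record = 3, sort = 0)
  })
  partial <- (is.na(p0) + is.na(p1) + is.na(p2)) %in% c(1L, 2L)
  p0[partial] <- NA; p1[partial] <- NA; p2[partial] <- NA
  nMissing <- sum(is.na(p0))

  s <- p0 + p1 + p2
  bad <- !is.na(s) & abs(s - 1) > 1e-2
  if (any(bad)) {
    warning(sum(bad), " trio(s) with probability sum deviating from 1 by ",
            "> 1e-2 set to missing (counted in the QC summary)")
    p0[bad] <- NA; p1[bad] <- NA; p2[bad] <- NA
    s[bad] <- NA
  }
  renorm <- !is.na(s) & abs(s - 1) > 1e-12
  p0 <- p0 / s; p1 <- p1 / s; p2 <- p2 / s

  gr <- .rangesFromFix(fix)
  qual <- .variantQuality(vcf)
  if (!is.null(qual)) mcols(gr)$quality <- qual
  obj <- ImputedGenotypes(p0, p1, p2, gr, samples = colnames(gp),
                          source = source)
  metadata(obj)$qc <- list(
    n_records = n0,
    n_excluded_multiallelic = nMulti,
    n_retained = nrow(fix),
    n_missing_trios = nMissing,
    n_renormalized = sum(renorm),
    n_bad_sum_set_missing = sum(bad))
  obj
}

#' Read a truth VCF with hard genotype calls
#'
#' Diploid \code{GT} calls are mapped to alternate-allele counts 0/1/2;
#' fully or half missing genotypes map to missing and are excluded from the
#' per-variant MAF denominator.  Haploid or polyploid calls are a
#' record-level error.  Only biallelic ACGT records are kept.
#'
#' @param path VCF file path.
#' @param region optional \code{"chrom:start-end"} filter.
#' @return A [TruthGenotypes] object (per-variant MAF/MAC in
#'   \code{rowRanges()}).
#' @export
readTruthVcf <- function(path, region = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  keep <- .biallelicMask(fix)
  if (!is.null(region)) {
    rg <- .parseRegion(region)
    keep <- keep & fix[, "CHROM"] == rg$chrom &
      as.numeric(fix[, "POS"]) >= rg$start &
      as.numeric(fix[, "POS"]) <= rg$end
  }
  if (!any(keep)) stop("no biallelic records retained from ", path)
  vcf <- vcf[keep, ]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  u <- unique(as.vector(gt))
  u <- u[!is.na(u)]
  nAlleles <- lengths(strsplit(u, "[/|]"))
  if (any(nAlleles != 2))
    stop("non-diploid GT call(s) found: ",
         paste(utils::head(u[nAlleles != 2], 5), collapse = ", "))
  lut <- vapply(strsplit(u, "[/|]"), function(al) {
    if (any(al == ".")) NA_integer_ else sum(al == "1")
  }, integer(1))
  names(lut) <- u
  calls <- matrix(lut[gt], nrow = nrow(gt), dimnames = dimnames(gt))
  TruthGenotypes(calls, .rangesFromFix(vcf@fix), samples = colnames(gt))
}

.biallelicMask <- function(fix) {
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    grepl("^[ACGT]+$", ref) & grepl("^[ACGT]+$", alt) & ref != alt
}

.rangesFromFix <- function(fix) {
  GRanges(fix[, "CHROM"],
          IRanges(as.integer(fix[, "POS"]), width = 1L),
          ref = fix[, "REF"], alt = fix[, "ALT"])
}

.variantQuality <- function(vcf) {
  for (key in c("R2", "RSQ")) {
    q <- suppressWarnings(vcfR::extract.info(vcf, element = key,
                                             as.numeric = TRUE))
    if (!is.null(q) && !all(is.na(q))) return(q)
  }
  NULL
}

.parseRegion <- function(region) {
  m <- regmatches(region, regexec("^([^:]+)(?::([0-9]+)-([0-9]+))?$",
                                  region))[[1]]
  if (length(m) == 0) stop("cannot parse region '", region, "'")
  list(chrom = m[2],
       start = if (m[3] == "") 1 else as.numeric(m[3]),
       end = if (m[4] == "") Inf else as.numeric(m[4]))
}

#' Write an imputed run as a VCF
#'
#' Emits one record per variant with FORMAT fields \code{GT} (hard call =
#' most likely genotype), \code{GP} (the probability trio) and \code{DS}
#' (dosage \eqn{p_1 + 2 p_2}); a per-genotype provenance label (e.g. from
#' [mergeRuns()]) can be added as a string field \code{PV}.  Output is
#' gzip-compressed when the path ends in \code{.gz}.  A write/read round
#' trip through [readImputedVcf()] preserves keys and sample IDs exactly
#' and every probability within 1e-4.
#'
#' @param x an [ImputedGenotypes] object.
#' @param path output path (\code{.vcf} or \code{.vcf.gz}).
#' @param provenance optional character matrix (variants x samples) of
#'   per-genotype labels.
#' @return \code{path}, invisibly.
#' @export
writeImputedVcf <- function(x, path, provenance = NULL) {
  stopifnot(is(x, "ImputedGenotypes"))
  if (!is.null(provenance))
    stopifnot(identical(dim(provenance), dim(x)))
  gr <- rowRanges(x)
  p0 <- assay(x, "p0"); p1 <- assay(x, "p1"); p2 <- assay(x, "p2")
  am <- gpArgmax(x)
  ds <- dosage(x)

  fmtNum <- function(v) {
    out <- formatC(v, digits = 6, format = "g")
    out[is.na(v)] <- "."
    out
  }
  gtStr <- c("0/0", "0/1", "1/1")[am + 1L]
  gtStr[is.na(am)] <- "./."
  cell <- paste0(gtStr, ":",
                 fmtNum(p0), ",", fmtNum(p1), ",", fmtNum(p2), ":",
                 fmtNum(ds))
  fmt <- "GT:GP:DS"
  if (!is.null(provenance)) {
    cell <- paste0(cell, ":", as.vector(provenance))
    fmt <- paste0(fmt, ":PV")
  }
  cellM <- matrix(cell, nrow = nrow(x))

  qual <- mcols(gr)$quality
  info <- if (is.null(qual)) rep(".", nrow(x))
          else ifelse(is.na(qual), ".", paste0("R2=", fmtNum(qual)))
  meta <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=imputeval(", sourceLabel(x), ")"),
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality score from the source run\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Most likely genotype\">",
    "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Posterior genotype probabilities for 0/0, 0/1, 1/1\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Expected alternate allele dosage\">")
  if (!is.null(provenance))
    meta <- c(meta,
      "##FORMAT=<ID=PV,Number=1,Type=String,Description=\"Merge provenance label\">")
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", colnames(x)), collapse = "\t")
  body <- paste(as.character(seqnames(gr)), start(gr), ".",
                mcols(gr)$ref, mcols(gr)$alt, ".", ".", info, fmt,
                apply(cellM, 1, paste, collapse = "\t"), sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(meta, header, body), con)
  invisible(path)
}

#' Align two imputation runs (and optionally a truth set)
#'
#' Matches variants on the exact (chrom, pos, ref, alt) key and restricts
#' both runs to their shared samples in a canonical (sorted) order.  With
#' \code{matchSwaps = TRUE}, a variant of run B whose (ref, alt) equals run
#' A's (alt, ref) at the same position is additionally matched: B's trio is
#' reversed to \eqn{(p_2, p_1, p_0)} (an allele-count relabelling), its key
#' rewritten to A's, and the variant flagged.  Strand flips are never
#' attempted (ambiguous for A/T and C/G pairs).  Returns both the
#' intersection (the evaluation set) and the union (the merge set) of
#' variant keys.
#'
#' @param a,b [ImputedGenotypes] runs.
#' @param truth optional [TruthGenotypes]; when given, samples are also
#'   restricted to those present in the truth set.
#' @param matchSwaps also reconcile ref/alt-swapped keys (default
#'   \code{FALSE}, conservative).
#' @return list with elements \code{a}, \code{b} (sample-aligned runs, B
#'   possibly swap-corrected), \code{intersection}, \code{union} (character
#'   key vectors in canonical order), \code{unionRanges} (a \code{GRanges}
#'   for the union), and \code{swapped} (keys matched by allele swap).
#' @export
alignRuns <- function(a, b, truth = NULL, matchSwaps = FALSE) {
  stopifnot(is(a, "ImputedGenotypes"), is(b, "ImputedGenotypes"))
  smp <- sort(intersect(colnames(a), colnames(b)))
  if (!is.null(truth)) smp <- sort(intersect(smp, colnames(truth)))
  if (length(smp) == 0) stop("empty sample intersection")
  a <- a[, smp]; b <- b[, smp]
  if (anyDuplicated(rownames(a)) || anyDuplicated(rownames(b)))
    stop("duplicate variant keys")

  swapped <- character()
  if (matchSwaps) {
    grB <- rowRanges(b)
    swKeys <- paste0(as.character(seqnames(grB)), ":", start(grB), "_",
                     mcols(grB)$alt, "/", mcols(grB)$ref)
    toSwap <- which(!(rownames(b) %in% rownames(a)) &
                      swKeys %in% rownames(a))
    if (length(toSwap)) {
      p0 <- assay(b, "p0"); p1 <- assay(b, "p1"); p2 <- assay(b, "p2")
      tmp <- p0[toSwap, , drop = FALSE]
      p0[toSwap, ] <- p2[toSwap, , drop = FALSE]
      p2[toSwap, ] <- tmp
      ref <- mcols(grB)$ref; alt <- mcols(grB)$alt
      mcols(grB)$ref[toSwap] <- alt[toSwap]
      mcols(grB)$alt[toSwap] <- ref[toSwap]
      b <- ImputedGenotypes(p0, p1, p2, grB, samples = colnames(b),
                            source = sourceLabel(b))
      swapped <- rownames(b)[toSwap]
    }
  }

  inter <- intersect(rownames(a), rownames(b))
  grA <- rowRanges(a)
  grBonly <- rowRanges(b)[setdiff(rownames(b), rownames(a))]
  unionRanges <- suppressWarnings(c(grA, grBonly))
  ord <- order(as.character(seqnames(unionRanges)), start(unionRanges),
               mcols(unionRanges)$ref, mcols(unionRanges)$alt)
  unionRanges <- unionRanges[ord]
  keysU <- variantKeys(unionRanges)
  interOrd <- keysU[keysU %in% inter]
  list(a = a, b = b, intersection = interOrd, union = keysU,
       unionRanges = unionRanges, swapped = swapped)
}

#' Read a BED file of regions
#'
#' BED is 0-based half-open; coordinates are converted to the 1-based
#' inclusive convention used throughout the package.
#'
#' @param path BED file path.
#' @return A \code{GRanges}; the BED name column (when present) provides
#'   region names.
#' @export
readRegionsBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(mcols(gr)$name)) names(gr) <- mcols(gr)$name
  gr
}
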