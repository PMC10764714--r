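#' Evaluate one imputation run against a truth set
#'
#' The evaluation mode of the package: aligns a run to the truth set,
#' reports the variant overlap (imputed only / truth only / both — the
#' panel-overlap diagnostic), and computes IQS tables per individual, per
#' variant, per MAF bin and, when regions are supplied, per region.
#'
#' @param imputed an [ImputedGenotypes] object or a VCF path.
#' @param truth a [TruthGenotypes] object or a VCF path.
#' @param regions optional \code{GRanges} (or BED path) of regions for a
#'   per-region table.
#' @param mafThreshold rare/common boundary (default 0.01).
#' @param rsqFilter optional minimum per-variant quality
#'   (\code{rowRanges()$quality}) below which imputed variants are dropped
#'   before evaluation; \code{NULL} (default) keeps all.
#' @param mode contingency mode, see [buildContingency()].
#' @return list with \code{overlap} (named counts), \code{perIndividual},
#'   \code{perVariant}, \code{perMafBin}, optional \code{perRegion}
#'   data.frames, and \code{qc} (the run's QC summary, if any).
#' @export
evaluateImputation <- function(imputed, truth, regions = NULL,
                               mafThreshold = 0.01, rsqFilter = NULL,
                               mode = c("posterior", "hardcall")) {
  mode <- match.arg(mode)
  if (is.character(imputed)) imputed <- readImputedVcf(imputed)
  if (is.character(truth)) truth <- readTruthVcf(truth)
  if (is.character(regions)) regions <- readRegionsBed(regions)
  if (!is.null(rsqFilter)) {
    q <- mcols(rowRanges(imputed))$quality
    if (!is.null(q))
      imputed <- imputed[!is.na(q) & q > rsqFilter, ]
  }
  both <- intersect(rownames(imputed), rownames(truth))
  overlap <- c(imputed_only = length(setdiff(rownames(imputed), both)),
               truth_only = length(setdiff(rownames(truth), both)),
               both = length(both))
  if (length(both) == 0)
    stop("no aligned variants between run and truth set; overlap: ",
         paste(names(overlap), overlap, sep = "=", collapse = ", "))
  out <- list(
    overlap = overlap,
    perIndividual = iqsStratified(imputed, truth, "individual",
                                  mode = mode),
    perVariant = iqsStratified(imputed, truth, "variant", mode = mode),
    perMafBin = iqsStratified(imputed, truth, "maf_bin",
                              mafThreshold = mafThreshold, mode = mode),
    qc = metadata(imputed)$qc)
  if (!is.null(regions))
    out$perRegion <- iqsStratified(imputed, truth, "region",
                                   regions = regions, mode = mode)
  out
}

#' Mean of defined per-stratum IQS values
#'
#' Summarises a stratified IQS table.  Undefined strata (flagged by
#' \code{defined = FALSE}) are dropped and their count reported, rather
#' than being coerced to 0 or 1, which would bias the summary.
#'
#' @param tab a data.frame from [iqsStratified()].
#' @return list with \code{mean_iqs}, \code{n_defined},
#'   \code{n_undefined}.
#' @export
summariseIqs <- function(tab) {
  ok <- tab$defined & !is.na(tab$iqs)
  list(mean_iqs = if (any(ok)) mean(tab$iqs[ok]) else NA_real_,
       n_defined = sum(ok), n_undefined = sum(!ok))
}

#' Run the full synthetic benchmark
#'
#' One command reproduces the package's whole synthetic study: simulate a
#' two-strategy scenario ([simulateScenario()]), evaluate both runs and
#' their most-confident-vote merge, estimate the switch error rate from
#' seed-perturbed phasings, and aggregate group-structured IBD segments.
#' All tables are written to \code{outDir} as tab-delimited text together
#' with a JSON manifest recording the seed, configuration, per-stage
#' record counts and output checksums; rerunning with the same seed
#' reproduces every output bit-identically.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed driving every stage.
#' @param nVariants,nPerGroup scenario size.
#' @param delta,priority merge rule configuration ([hybridConfig()]).
#' @param serRate switch rate for the phasing-stability stage.
#' @param serIndividuals,serPairs,serK phasing-stability problem size.
#' @param ibdThreshold long/short segment boundary in cM.
#' @return (invisibly) list with the summary tables and the manifest.
#' @export
runBenchmark <- function(outDir, seed = 1, nVariants = 3000,
                         nPerGroup = 60, delta = 0.05, priority = "b",
                         serRate = 0.02, serIndividuals = 50,
                         serPairs = 500, serK = 21, ibdThreshold = 3.0) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfg <- hybridConfig(delta = delta, priority = priority)

  sc <- simulateScenario(nVariants = nVariants, nPerGroup = nPerGroup,
                         seed = seed)
  evA <- evaluateImputation(sc$runA, sc$truth)
  evB <- evaluateImputation(sc$runB, sc$truth)
  mg <- mergeRuns(sc$runA, sc$runB, cfg)
  evH <- evaluateImputation(mg$merged, sc$truth)
  acc <- accordSplitIqs(sc$runA, sc$runB, mg, sc$truth)

  ph <- simulateSeedPhasings(serIndividuals, serPairs, s = serRate,
                             K = serK, seed = seed + 1)
  ser <- estimateSer(ph$set)

  tg <- stats::setNames(rep(c("cityX", "cityY"), each = 10),
                        sprintf("T%02d", 1:20))
  rg <- stats::setNames(rep(c("clu1", "clu2", "clu3"), each = 15),
                        sprintf("R%02d", 1:45))
  rates <- matrix(c(2.0, 0.3, 0.3,
                    0.3, 1.2, 0.3), 2, 3, byrow = TRUE,
                  dimnames = list(c("cityX", "cityY"),
                                  c("clu1", "clu2", "clu3")))
  segs <- simulateIbdSegments(tg, rg, rates, seed = seed + 2)
  shr <- groupSharingMatrix(segs, tg, rg, threshold = ibdThreshold)

  wt <- function(x, f) {
    p <- file.path(outDir, f)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    wt(evA$perIndividual, "iqs_individual_runA.tsv"),
    wt(evB$perIndividual, "iqs_individual_runB.tsv"),
    wt(evH$perIndividual, "iqs_individual_merged.tsv"),
    wt(acc, "accord_discord.tsv"),
    wt(ser$perIndividual, "ser_individual.tsv"),
    writeSharingMatrix(shr, file.path(outDir, "ibd_sharing.tsv")))

  grp <- sc$groups[evH$perIndividual$stratum]
  summary <- list(
    mean_iqs = lapply(list(runA = evA, runB = evB, merged = evH),
      function(e) {
        v <- e$perIndividual
        stats::setNames(
          vapply(split(v$iqs, grp), mean, numeric(1)),
          names(split(v$iqs, grp)))
      }),
    accord_frac = mean(acc$accord_frac, na.rm = TRUE),
    accord_correct = mean(acc$accord_correct, na.rm = TRUE),
    discord_correct_merged = mean(acc$discord_correct_merged,
                                  na.rm = TRUE),
    mean_ser = mean(ser$perIndividual$mean_ser, na.rm = TRUE))

  manifest <- list(
    tool = paste0("imputeval ",
                  as.character(utils::packageVersion("imputeval"))),
    seed = seed,
    config = list(nVariants = nVariants, nPerGroup = nPerGroup,
                  delta = delta, priority = priority, serRate = serRate,
                  serIndividuals = serIndividuals, serPairs = serPairs,
                  serK = serK, ibdThreshold = ibdThreshold),
    counts = list(variants_runA = nrow(sc$runA),
                  variants_runB = nrow(sc$runB),
                  variants_merged = nrow(mg$merged),
                  ibd_segments = nrow(segs)),
    outputs = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                      basename(paths))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(summary = summary, manifest = manifest,
                 accordSplit = acc, ser = ser, sharing = shr))
}
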