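#' @include AllClasses.R io.R
NULL

#' Run the full simulate-and-analyze pipeline
#'
#' Orchestrates the stages end to end on a synthetic cohort: simulate
#' tumor samples, estimate per-sample purity and CNA clonality from probe
#' BAFs, call SNV clonality under the mutant-allele-fraction model,
#' summarize mutation signatures, and run the methylation association
#' stage on a simulated methylation cohort. Every stage writes its table
#' to the output directory atomically, and a JSON manifest records the
#' package version, seed and parameters. Reruns with the same
#' configuration reproduce identical outputs.
#'
#' @param config a configuration list, or the path to a YAML file holding
#'   one. Recognised fields (all optional): \code{seed}, \code{outDir},
#'   \code{simulation} (arguments to \code{\link{simulationConfig}}),
#'   \code{thresholds} (\code{minProbes}, \code{relTol},
#'   \code{alphaCutoff}, \code{alphaLevel}, \code{minPeakShare}),
#'   \code{methylation} (\code{nSamples}, \code{nProbes}, \code{nAssoc},
#'   \code{effectSize})
#' @return invisibly, a list with the output file paths, the per-sample
#'   results, and the manifest
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  outDir <- config$outDir %||% file.path(tempdir(), "clonescape-run")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  thr <- config$thresholds %||% list()
  minProbes <- as.integer(thr$minProbes %||% 50L)
  relTol <- thr$relTol %||% 0.1
  alphaCutoff <- thr$alphaCutoff %||% 0.05
  alphaLevel <- thr$alphaLevel %||% 0.05
  minPeakShare <- thr$minPeakShare %||% 0.05

  simArgs <- config$simulation %||% list()
  simArgs$seed <- seed
  simCfg <- do.call(simulationConfig, simArgs)

  # stage 1: simulate
  cohort <- simulateCohort(simCfg)
  samples <- cohort$samples

  # stage 2: purity + CNA clonality; stage 3: SNV clonality
  purityRows <- list()
  segTables <- list()
  snvTables <- list()
  sigSummaries <- list()
  for (i in seq_along(samples)) {
    s <- analyzeCna(samples[[i]], minProbes = minProbes, relTol = relTol,
                    minPeakShare = minPeakShare)
    if (is.null(s@purity))
      stop("purity estimation failed for sample ", s@sampleId,
           ": no usable CNAs")
    s <- analyzeSnvClonality(s, alphaCutoff = alphaCutoff)
    samples[[i]] <- s
    purityRows[[i]] <- data.frame(
      sample = s@sampleId, alpha = s@purity@alpha,
      n_cnas = length(s@purity@piValues),
      n_clones = length(s@purity@densityPeaks),
      stringsAsFactors = FALSE)
    mcSeg <- as.data.frame(S4Vectors::mcols(s@segments))
    segTables[[i]] <- cbind(sample = s@sampleId,
      data.frame(chrom = as.character(GenomeInfoDb::seqnames(s@segments)),
                 start = GenomicRanges::start(s@segments),
                 end = GenomicRanges::end(s@segments)), mcSeg)
    mcSnv <- as.data.frame(S4Vectors::mcols(s@snvs))
    snvTables[[i]] <- cbind(sample = s@sampleId,
      data.frame(chrom = as.character(GenomeInfoDb::seqnames(s@snvs)),
                 pos = GenomicRanges::start(s@snvs)), mcSnv)
    sigSummaries[[i]] <- summarizeSample(s@snvs, targetMb = 36,
                                         sampleId = s@sampleId)
  }

  purityPath <- file.path(outDir, "purity.tsv")
  writeTsv(do.call(rbind, purityRows), purityPath,
           comments = "per-sample tumor purity (rightmost clone peak)")
  segPath <- file.path(outDir, "segments.tsv")
  writeTsv(do.call(rbind, segTables), segPath, comments = c(
    "CNA segments with fitted BAF peaks, cell fractions and clonality",
    "coordinates 1-based inclusive; missing values '.'"))
  snvPath <- file.path(outDir, "mutations.tsv")
  writeTsv(do.call(rbind, snvTables), snvPath, comments = c(
    "somatic SNVs with clonal-null expected MAF, p-value and clonality",
    "coordinates 1-based inclusive; missing values '.'"))

  # stage 4: signatures
  sigPath <- file.path(outDir, "signatures.tsv")
  writeTsv(signatureTable(sigSummaries), sigPath,
           comments = "per-sample mutation-signature summary")

  # stage 5: methylation association
  methArgs <- config$methylation %||% list()
  meth <- simulateMethylationDataset(
    nSamples = methArgs$nSamples %||% 200L,
    nProbes = methArgs$nProbes %||% 2000L,
    nAssoc = methArgs$nAssoc %||% 20L,
    effectSize = methArgs$effectSize %||% 0.5,
    seed = seed)
  assoc <- methylationAssociation(meth$methylation, meth$trait,
                                  meth$covariates, meth$annotation,
                                  alphaLevel = alphaLevel,
                                  trait.name = "TNSM")
  assocPath <- file.path(outDir, "methylation_associations.tsv")
  writeTsv(assoc, assocPath,
           comments = sprintf(
             "per-probe association; Bonferroni threshold %.4g",
             attr(assoc, "threshold")))
  enrichPath <- file.path(outDir, "methylation_enrichment.tsv")
  writeTsv(rbind(cbind(by = "cgi", categoryEnrichment(assoc, "cgi")),
                 cbind(by = "region", categoryEnrichment(assoc, "region"))),
           enrichPath,
           comments = "annotation-category enrichment of significant probes")

  manifest <- list(
    package = "clonescape",
    version = as.character(utils::packageVersion("clonescape")),
    seed = seed,
    parameters = list(
      simulation = simArgs,
      thresholds = list(minProbes = minProbes, relTol = relTol,
                        alphaCutoff = alphaCutoff, alphaLevel = alphaLevel,
                        minPeakShare = minPeakShare),
      methylation = methArgs))
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(
    files = c(purity = purityPath, segments = segPath, mutations = snvPath,
              signatures = sigPath, associations = assocPath,
              enrichment = enrichPath, manifest = manifestPath),
    samples = samples,
    signatureSummaries = sigSummaries,
    methylation = meth,
    associations = assoc,
    manifest = manifest))
}
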