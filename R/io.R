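#' @include AllClasses.R
NULL

# TSV dialect: tab-separated, '#'-prefixed comment lines above a plain
# header row, '.' for missing values. Writes are atomic (temp file then
# rename).
writeTsv <- function(df, path, comments = character()) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, open = "wt")
  closed <- FALSE
  on.exit({
    if (!closed) close(con)
    if (file.exists(tmp)) unlink(tmp)
  }, add = TRUE)
  for (cm in comments) writeLines(paste0("# ", cm), con)
  df2 <- df
  for (j in seq_along(df2)) {
    v <- df2[[j]]
    if (is.numeric(v)) v <- format(v, digits = 15, trim = TRUE,
                                   scientific = FALSE)
    v[is.na(df[[j]])] <- "."
    df2[[j]] <- v
  }
  utils::write.table(df2, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  close(con)
  closed <- TRUE
  file.rename(tmp, path)
  invisible(path)
}

readTsv <- function(path) {
  utils::read.delim(path, comment.char = "#", na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

requireColumns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Read a somatic mutation table
#'
#' Reads a MAF-like TSV (required columns \code{chrom}, \code{pos},
#' \code{ref}, \code{alt}, \code{t_ref_count}, \code{t_alt_count},
#' \code{gene}, \code{consequence}; optional \code{context},
#' \code{t_depth}) or a VCF whose tumor genotype carries an \code{AD}
#' allele-depth field. File coordinates are 1-based inclusive.
#'
#' @param path path to the mutation file
#' @param format \code{"auto"} (by extension), \code{"tsv"} or \code{"vcf"}
#' @return a \code{GRanges} with metadata columns \code{ref}, \code{alt},
#'   \code{depth}, \code{altCount}, \code{gene}, \code{consequence},
#'   \code{context}
#' @export
readMutations <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") return(readMutationsVcf(path))
  df <- readTsv(path)
  requireColumns(df, c("chrom", "pos", "ref", "alt", "t_ref_count",
                       "t_alt_count", "gene", "consequence"),
                 "mutation table")
  depth <- if ("t_depth" %in% names(df)) df$t_depth else
    df$t_ref_count + df$t_alt_count
  if (any(df$t_alt_count > depth))
    stop("mutation table has alt_count > depth in row(s): ",
         paste(which(df$t_alt_count > depth), collapse = ", "))
  gr <- GRanges(df$chrom, IRanges(df$pos, width = 1L))
  S4Vectors::mcols(gr) <- DataFrame(
    ref = df$ref, alt = df$alt,
    depth = as.integer(depth), altCount = as.integer(df$t_alt_count),
    gene = df$gene, consequence = df$consequence,
    context = if ("context" %in% names(df)) df$context else
      rep(NA_character_, nrow(df)))
  gr
}

readMutationsVcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop("VCF has no AD (allele depth) genotype field")
  adc <- ad[, 1]
  refC <- vapply(adc, function(x) as.integer(x[1]), integer(1))
  altC <- vapply(adc, function(x) as.integer(x[2]), integer(1))
  gr <- GRanges(GenomeInfoDb::seqnames(rr),
                IRanges(GenomicRanges::start(rr), width = 1L))
  S4Vectors::mcols(gr) <- DataFrame(
    ref = as.character(rr$REF),
    alt = vapply(rr$ALT, function(a) as.character(a)[1], character(1)),
    depth = refC + altC, altCount = altC,
    gene = rep(NA_character_, length(rr)),
    consequence = rep(NA_character_, length(rr)),
    context = rep(NA_character_, length(rr)))
  gr
}

#' Write a somatic mutation table
#'
#' @param snvs a \code{GRanges} of mutations (as from
#'   \code{\link{readMutations}}, optionally augmented with
#'   \code{expectedMaf}, \code{pClonal}, \code{clonality})
#' @param path output path
#' @return the path, invisibly
#' @export
writeMutations <- function(snvs, path) {
  mc <- as.data.frame(S4Vectors::mcols(snvs))
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(snvs)),
                   pos = GenomicRanges::start(snvs),
                   ref = mc$ref, alt = mc$alt,
                   t_ref_count = mc$depth - mc$altCount,
                   t_alt_count = mc$altCount,
                   gene = mc$gene, consequence = mc$consequence,
                   context = mc$context,
                   stringsAsFactors = FALSE)
  for (extra in c("segmentState", "beta", "expectedMaf", "pClonal",
                  "clonality"))
    if (!is.null(mc[[extra]])) df[[extra]] <- mc[[extra]]
  writeTsv(df, path, comments = c(
    "somatic point mutations; coordinates 1-based inclusive",
    "missing values encoded as '.'"))
}

#' Read a CNA segment table
#'
#' TSV with columns \code{chrom}, \code{start}, \code{end}, \code{state}
#' and optionally \code{read_ratio}, \code{mu1}, \code{mu2},
#' \code{cell_fraction}, \code{clonality}; coordinates 1-based inclusive.
#'
#' @param path path to the segment TSV
#' @return a \code{GRanges} with a \code{state} metadata column (plus the
#'   optional columns present)
#' @export
readSegments <- function(path) {
  df <- readTsv(path)
  requireColumns(df, c("chrom", "start", "end", "state"), "segment table")
  if (!all(df$state %in% CNA_STATES))
    stop("segment table has unknown copy state(s): ",
         paste(setdiff(df$state, CNA_STATES), collapse = ", "))
  gr <- GRanges(df$chrom, IRanges(df$start, df$end))
  mc <- DataFrame(segmentId = seq_len(nrow(df)), state = df$state)
  for (nm in c("read_ratio", "mu1", "mu2", "cell_fraction", "clonality")) {
    if (nm %in% names(df))
      mc[[c(read_ratio = "readRatio", mu1 = "mu1", mu2 = "mu2",
            cell_fraction = "cellFraction", clonality = "clonality")[nm]]] <-
        df[[nm]]
  }
  S4Vectors::mcols(gr) <- mc
  gr
}

#' Write a CNA segment table
#'
#' @param segments a \code{GRanges} of segments
#' @param path output path
#' @return the path, invisibly
#' @export
writeSegments <- function(segments, path) {
  mc <- as.data.frame(S4Vectors::mcols(segments))
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(segments)),
                   start = GenomicRanges::start(segments),
                   end = GenomicRanges::end(segments),
                   state = mc$state, stringsAsFactors = FALSE)
  map <- c(readRatio = "read_ratio", mu1 = "mu1", mu2 = "mu2",
           cellFraction = "cell_fraction", clonality = "clonality")
  for (nm in names(map))
    if (!is.null(mc[[nm]])) df[[map[[nm]]]] <- mc[[nm]]
  writeTsv(df, path, comments = c(
    "CNA segments; coordinates 1-based inclusive",
    "missing values encoded as '.'"))
}

#' Read a heterozygous SNP probe table
#'
#' TSV with columns \code{chrom}, \code{pos}, \code{baf} and optionally
#' \code{lrr}, \code{segment_id}; positions 1-based.
#'
#' @param path path to the probe TSV
#' @return a \code{GRanges} with \code{baf} (and optional) columns
#' @export
readProbes <- function(path) {
  df <- readTsv(path)
  requireColumns(df, c("chrom", "pos", "baf"), "probe table")
  if (any(df$baf < 0 | df$baf > 1, na.rm = TRUE))
    stop("probe BAF values must lie in [0, 1]")
  gr <- GRanges(df$chrom, IRanges(df$pos, width = 1L))
  mc <- DataFrame(baf = df$baf)
  if ("lrr" %in% names(df)) mc$lrr <- df$lrr
  if ("segment_id" %in% names(df)) mc$segmentId <- df$segment_id
  S4Vectors::mcols(gr) <- mc
  gr
}

#' Write a heterozygous SNP probe table
#'
#' @param probes a \code{GRanges} of probes with a \code{baf} column
#' @param path output path
#' @return the path, invisibly
#' @export
writeProbes <- function(probes, path) {
  mc <- as.data.frame(S4Vectors::mcols(probes))
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(probes)),
                   pos = GenomicRanges::start(probes),
                   baf = mc$baf, stringsAsFactors = FALSE)
  if (!is.null(mc$lrr)) df$lrr <- mc$lrr
  if (!is.null(mc$segmentId)) df$segment_id <- mc$segmentId
  writeTsv(df, path, comments = c(
    "heterozygous SNP-array probes; positions 1-based",
    "missing values encoded as '.'"))
}

#' Read a methylation beta-value matrix
#'
#' TSV with probes in rows (first column \code{probe}) and samples in
#' columns.
#'
#' @param path path to the methylation TSV
#' @return a numeric matrix, probes x samples, probe ids as row names
#' @export
readMethylationMatrix <- function(path) {
  df <- readTsv(path)
  requireColumns(df, "probe", "methylation matrix")
  m <- as.matrix(df[, setdiff(names(df), "probe"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$probe
  m
}

#' Write a methylation beta-value matrix
#'
#' @param methylation numeric probes x samples matrix
#' @param path output path
#' @return the path, invisibly
#' @export
writeMethylationMatrix <- function(methylation, path) {
  df <- data.frame(probe = rownames(methylation), methylation,
                   check.names = FALSE, stringsAsFactors = FALSE)
  writeTsv(df, path,
           comments = "CpG probe beta values, probes x samples")
}
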