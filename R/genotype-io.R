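#' Write a genotype panel as VCF v4.2
#'
#' Emits a minimal single-ALT, GT-only, unphased diploid VCF: contig "1",
#' sequential positions, genotypes "0/0", "0/1", "1/1" (counting ALT copies)
#' or "./." for missing. Sample order is preserved.
#'
#' @param panel a [GenotypeMatrix-class].
#' @param design optional [StudyDesign-class]; only used to check sample IDs.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso [readVcf()]
#' @export
writeVcf <- function(panel, design = NULL, path) {
  stopifnot(is(panel, "GenotypeMatrix"))
  if (!is.null(design) && !identical(sampleIds(panel), sampleIds(design)))
    stop("panel and design sample IDs differ", call. = FALSE)
  cts <- genotypeCounts(panel)
  gtmap <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(cts), ncol(cts))
  ok <- !is.na(cts)
  gt[ok] <- gtmap[as.character(cts[ok])]
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleIds(panel)), collapse = "\t"))
  fixed <- cbind("1", seq_len(nrow(cts)), snpIds(panel), refAlleles(panel),
                 altAlleles(panel), ".", ".", ".", "GT")
  body <- apply(cbind(fixed, gt), 1L, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genotype panel from VCF
#'
#' Parses a VCF (via the vcfR package) into ALT-allele counts. Only the
#' unphased single-ALT diploid GT dialect is supported: multi-allelic or
#' phased records raise an error naming the offending record.
#'
#' @param path VCF file path.
#' @return a [GenotypeMatrix-class].
#' @export
readVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    stop("multi-allelic record not supported: ",
         fix[which(multi)[1L], "ID"], call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  phased <- grepl("|", gt, fixed = TRUE)
  if (any(phased)) {
    bad <- arrayInd(which(phased)[1L], dim(gt))[1L, 1L]
    stop("phased genotype not supported in record: ",
         fix[bad, "ID"], call. = FALSE)
  }
  lut <- c(`0/0` = 0, `0/1` = 1, `1/0` = 1, `1/1` = 2, `./.` = NA_real_)
  known <- is.na(gt) | gt %in% names(lut)
  if (!all(known)) {
    bad <- which(!known, arr.ind = TRUE)[1L, ]
    stop("unsupported GT '", gt[bad[1L], bad[2L]], "' in record ",
         fix[bad[1L], "ID"], call. = FALSE)
  }
  cts <- matrix(lut[gt], nrow(gt), ncol(gt))
  cts[is.na(gt)] <- NA_real_
  GenotypeMatrix(cts, snpIds = fix[, "ID"], sampleIds = colnames(gt),
                 ref = fix[, "REF"], alt = alt)
}

.parseTsvMatrix <- function(path, what) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop(what, " TSV '", path, "' has no data rows", call. = FALSE)
  strsplit(lines, "\t", fixed = TRUE)
}

#' Read and write the plain genotype-matrix TSV dialect
#'
#' Header row: \code{snp_id} then sample IDs; one row per SNP holding the
#' SNP ID and N allele-count fields (\code{NA} for missing). Ragged rows or
#' tokens outside \{0, 1, 2, NA\} raise a parse error with the line number.
#'
#' @param panel a [GenotypeMatrix-class].
#' @param path file path.
#' @return \code{readGenotypeTsv} returns a [GenotypeMatrix-class].
#' @export
writeGenotypeTsv <- function(panel, path) {
  cts <- genotypeCounts(panel)
  txt <- matrix(as.character(cts), nrow(cts))
  txt[is.na(txt)] <- "NA"
  body <- paste(snpIds(panel), apply(txt, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(paste(c("snp_id", sampleIds(panel)), collapse = "\t"), body),
             path)
  invisible(path)
}

#' @rdname writeGenotypeTsv
#' @export
readGenotypeTsv <- function(path) {
  toks <- .parseTsvMatrix(path, "genotype")
  header <- toks[[1L]]
  ids <- header[-1L]
  n <- length(ids)
  m <- length(toks) - 1L
  cts <- matrix(NA_real_, m, n)
  snps <- character(m)
  for (i in seq_len(m)) {
    f <- toks[[i + 1L]]
    if (length(f) != n + 1L)
      stop("genotype TSV line ", i + 1L, ": expected ", n + 1L,
           " fields, got ", length(f), call. = FALSE)
    snps[i] <- f[[1L]]
    vals <- f[-1L]
    bad <- !vals %in% c("0", "1", "2", "NA")
    if (any(bad))
      stop("genotype TSV line ", i + 1L, ": invalid token '",
           vals[which(bad)[1L]], "'", call. = FALSE)
    cts[i, ] <- suppressWarnings(as.numeric(vals))
  }
  GenotypeMatrix(cts, snpIds = snps, sampleIds = ids)
}

#' Read and write phenotype TSV
#'
#' Columns \code{sample_id}, \code{status} (1 = case, 0 = control) and
#' \code{site} (free text, may be empty).
#'
#' @param design a [StudyDesign-class].
#' @param path file path.
#' @return \code{readPheno} returns a [StudyDesign-class].
#' @export
writePheno <- function(design, path) {
  site <- if (length(design@siteLabel)) design@siteLabel
          else rep("", nSamples(design))
  writeLines(c("sample_id\tstatus\tsite",
               paste(sampleIds(design), design@status, site, sep = "\t")),
             path)
  invisible(path)
}

#' @rdname writePheno
#' @export
readPheno <- function(path) {
  toks <- .parseTsvMatrix(path, "phenotype")
  if (!identical(toks[[1L]][1:2], c("sample_id", "status")))
    stop("phenotype TSV must start with columns sample_id, status",
         call. = FALSE)
  m <- length(toks) - 1L
  ids <- character(m); status <- integer(m); site <- character(m)
  for (i in seq_len(m)) {
    f <- toks[[i + 1L]]
    if (length(f) < 2L || length(f) > 3L)
      stop("phenotype TSV line ", i + 1L, ": expected 2-3 fields, got ",
           length(f), call. = FALSE)
    if (!f[[2L]] %in% c("0", "1"))
      stop("phenotype TSV line ", i + 1L, ": invalid status '", f[[2L]], "'",
           call. = FALSE)
    ids[i] <- f[[1L]]
    status[i] <- as.integer(f[[2L]])
    site[i] <- if (length(f) == 3L) f[[3L]] else ""
  }
  if (all(site == "")) site <- character()
  StudyDesign(status = status, sampleIds = ids, siteLabel = site)
}

#' Write a simulation truth table
#'
#' Two TSV files: \code{<prefix>.truth_snps.tsv} (snp_id, ancestral_freq,
#' pop1_freq, pop2_freq, is_causal) and \code{<prefix>.truth_samples.tsv}
#' (sample_id, status, ancestry_fraction).
#'
#' @param truth the \code{truth} element returned by [simulateNullSnps()].
#' @param prefix output path prefix.
#' @return the two paths, invisibly.
#' @export
writeTruth <- function(truth, prefix) {
  p1 <- paste0(prefix, ".truth_snps.tsv")
  p2 <- paste0(prefix, ".truth_samples.tsv")
  utils::write.table(truth$snps, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$samples, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}
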