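.autoIds <- function(n, nCases = NULL) {
  if (is.null(nCases)) sprintf("S%04d", seq_len(n))
  else c(sprintf("case_%04d", seq_len(nCases)),
         sprintf("ctrl_%04d", seq_len(n - nCases)))
}

#' @rdname PopulationModel-classes
#' @param nCases,nControls arm sizes.
#' @export
HomogeneousModel <- function(nCases, nControls) {
  new("HomogeneousModel", nCases = as.integer(nCases),
      nControls = as.integer(nControls))
}

#' @rdname PopulationModel-classes
#' @param fst fixation index (present-day vs ancestral) in [0, 1).
#' @param fstControls optional distinct fixation index for the control
#'   population; \code{NA} (default) shares \code{fst}.
#' @export
IsolatedPairModel <- function(fst, nCases, nControls, fstControls = NA_real_) {
  new("IsolatedPairModel", fst = as.numeric(fst),
      fstControls = as.numeric(fstControls),
      nCases = as.integer(nCases), nControls = as.integer(nControls))
}

#' @rdname PopulationModel-classes
#' @param nuCases,nuControls ancestry fractions from ancestral source 1.
#' @export
CompleteAdmixtureModel <- function(fst, nuCases, nuControls, nCases,
                                   nControls) {
  new("CompleteAdmixtureModel", fst = as.numeric(fst),
      nuCases = as.numeric(nuCases), nuControls = as.numeric(nuControls),
      nCases = as.integer(nCases), nControls = as.integer(nControls))
}

#' @rdname PopulationModel-classes
#' @param het heterogeneity of individual ancestry fractions, in (0, 1).
#' @export
BetaAdmixtureModel <- function(fst, nuCases, nuControls, het, nCases,
                               nControls) {
  new("BetaAdmixtureModel", fst = as.numeric(fst),
      nuCases = as.numeric(nuCases), nuControls = as.numeric(nuControls),
      het = as.numeric(het),
      nCases = as.integer(nCases), nControls = as.integer(nControls))
}

#' @rdname BaldingNicholsParams-class
#' @param fst fixation index in [0, 1).
#' @param p ancestral allele frequency in (0, 1).
#' @export
BaldingNicholsParams <- function(fst, p) {
  new("BaldingNicholsParams", fst = as.numeric(fst), p = as.numeric(p))
}

#' @rdname KinshipMatrix-class
#' @param values square numeric relatedness matrix.
#' @param sampleIds sample identifiers; defaults to existing dimnames or
#'   generated IDs.
#' @export
KinshipMatrix <- function(values, sampleIds = NULL) {
  values <- as.matrix(values)
  if (is.null(sampleIds)) sampleIds <- rownames(values)
  if (is.null(sampleIds)) sampleIds <- .autoIds(nrow(values))
  dimnames(values) <- list(sampleIds, sampleIds)
  new("KinshipMatrix", values = values)
}

#' @rdname GenotypeMatrix-class
#' @param counts SNP-by-sample matrix of ALT-allele counts (0/1/2, NA missing).
#' @param snpIds,sampleIds identifiers; default to dimnames or generated IDs.
#' @param ref,alt per-SNP allele labels (defaults "A"/"G").
#' @export
GenotypeMatrix <- function(counts, snpIds = NULL, sampleIds = NULL,
                           ref = NULL, alt = NULL) {
  counts <- as.matrix(counts)
  if (is.null(snpIds)) snpIds <- rownames(counts)
  if (is.null(snpIds)) snpIds <- sprintf("snp_%06d", seq_len(nrow(counts)))
  if (is.null(sampleIds)) sampleIds <- colnames(counts)
  if (is.null(sampleIds)) sampleIds <- .autoIds(ncol(counts))
  dimnames(counts) <- list(snpIds, sampleIds)
  if (is.null(ref)) ref <- rep("A", nrow(counts))
  if (is.null(alt)) alt <- rep("G", nrow(counts))
  new("GenotypeMatrix", counts = counts, ref = ref, alt = alt)
}

#' @rdname StudyDesign-class
#' @param status 0/1 case indicator (1 = case).
#' @param sampleIds sample identifiers; generated (cases first) when missing.
#' @param siteLabel optional per-sample stratum label.
#' @export
StudyDesign <- function(status, sampleIds = NULL, siteLabel = character()) {
  status <- as.integer(status)
  if (is.null(sampleIds)) {
    if (is.unsorted(rev(status)))
      sampleIds <- .autoIds(length(status))
    else  # cases-first convention: name the arms
      sampleIds <- .autoIds(length(status), nCases = sum(status))
  }
  new("StudyDesign", sampleIds = as.character(sampleIds), status = status,
      siteLabel = as.character(siteLabel))
}

#' Case/control arm sizes of a design or model
#' @param x a [StudyDesign-class] or population model.
#' @return named integer vector with elements \code{cases}, \code{controls}.
#' @export
armSizes <- function(x) {
  if (is(x, "StudyDesign"))
    c(cases = sum(x@status), controls = sum(1L - x@status))
  else c(cases = x@nCases, controls = x@nControls)
}

#' Default cases-first design implied by a population model
#' @param model a population model.
#' @return a [StudyDesign-class] with cases first, then controls.
#' @export
modelDesign <- function(model) {
  StudyDesign(status = rep(c(1L, 0L), c(model@nCases, model@nControls)))
}
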