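#' Accessors for strucpower objects
#'
#' Small accessor generics shared across the package's S4 classes.
#' \code{sampleIds} returns sample identifiers; \code{snpIds} SNP identifiers;
#' \code{genotypeCounts} the SNP-by-sample allele-count matrix;
#' \code{kinshipValues} the numeric kinship matrix; \code{caseStatus} the 0/1
#' case indicator; \code{designMatrix} the N x 2 matrix C with rows (1, c_i);
#' \code{nSamples} and \code{nSnps} the obvious dimensions.
#'
#' @param x a strucpower object.
#' @return the accessed component.
#' @name accessors
#' @aliases sampleIds snpIds genotypeCounts kinshipValues caseStatus
#'   designMatrix nSamples nSnps refAlleles altAlleles
#' @examples
#' d <- StudyDesign(status = c(1L, 1L, 0L, 0L))
#' designMatrix(d)
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))
#' @rdname accessors
#' @export
setGeneric("genotypeCounts", function(x) standardGeneric("genotypeCounts"))
#' @rdname accessors
#' @export
setGeneric("kinshipValues", function(x) standardGeneric("kinshipValues"))
#' @rdname accessors
#' @export
setGeneric("caseStatus", function(x) standardGeneric("caseStatus"))
#' @rdname accessors
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
#' @rdname accessors
#' @export
setGeneric("refAlleles", function(x) standardGeneric("refAlleles"))
#' @rdname accessors
#' @export
setGeneric("altAlleles", function(x) standardGeneric("altAlleles"))

#' Theoretical kinship matrix of a structure model
#'
#' Constructs the model-implied relatedness matrix K (cases first, then
#' controls) for a population-structure model. For a
#' \linkS4class{BetaAdmixtureModel} the matrix depends on the realized
#' per-individual ancestry fractions, which must be supplied.
#'
#' @param model a [PopulationModel-classes] object.
#' @param ... passed to methods; for \code{BetaAdmixtureModel}, a numeric
#'   \code{fractions} vector of per-individual ancestry values.
#' @return a [KinshipMatrix-class].
#' @seealso [kinshipIsolatedPair()], [kinshipAdmixed()]
#' @export
setGeneric("theoreticalKinship",
           function(model, ...) standardGeneric("theoreticalKinship"))

setMethod("sampleIds", "KinshipMatrix", function(x) rownames(x@values))
setMethod("sampleIds", "GenotypeMatrix", function(x) colnames(x@counts))
setMethod("sampleIds", "StudyDesign", function(x) x@sampleIds)
setMethod("sampleIds", "EigenDecomposition", function(x) rownames(x@vectors))

setMethod("snpIds", "GenotypeMatrix", function(x) rownames(x@counts))
setMethod("genotypeCounts", "GenotypeMatrix", function(x) x@counts)
setMethod("refAlleles", "GenotypeMatrix", function(x) x@ref)
setMethod("altAlleles", "GenotypeMatrix", function(x) x@alt)
setMethod("nSamples", "GenotypeMatrix", function(x) ncol(x@counts))
setMethod("nSamples", "KinshipMatrix", function(x) nrow(x@values))
setMethod("nSamples", "StudyDesign", function(x) length(x@sampleIds))
setMethod("nSnps", "GenotypeMatrix", function(x) nrow(x@counts))

setMethod("kinshipValues", "KinshipMatrix", function(x) x@values)

setMethod("caseStatus", "StudyDesign", function(x) {
  stats::setNames(x@status, x@sampleIds)
})

setMethod("designMatrix", "StudyDesign", function(x) {
  C <- cbind(intercept = 1, case = as.numeric(x@status))
  rownames(C) <- x@sampleIds
  C
})

setMethod("show", "KinshipMatrix", function(object) {
  cat(class(object), "of", nrow(object@values), "samples;",
      "trace", format(sum(diag(object@values)), digits = 6), "\n")
  if (is(object, "SmoothedKinship"))
    cat("  retained eigenpairs L =", object@L,
        "; ridge gamma =", format(object@gamma, digits = 6), "\n")
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@counts), "SNPs x",
      ncol(object@counts), "samples;",
      sum(is.na(object@counts)), "missing calls\n")
})

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", sum(object@status), "cases /",
      sum(1L - object@status), "controls\n")
})

setMethod("show", "EigenDecomposition", function(object) {
  cat("EigenDecomposition:", length(object@values), "eigenvalues;",
      object@nSignificant, "Tracy-Widom significant at alpha =",
      object@alpha, "\n")
})

setMethod("show", "PopulationModel", function(object) {
  cat(class(object), "-", object@nCases, "cases /",
      object@nControls, "controls\n")
  for (s in setdiff(slotNames(object), c("nCases", "nControls")))
    cat(" ", s, "=", format(slot(object, s)), "\n")
})
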