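#' @import methods
NULL

.checkProb <- function(x, name, open = TRUE) {
  if (length(x) != 1L || !is.finite(x))
    return(sprintf("'%s' must be a single finite number", name))
  if (open && (x <= 0 || x >= 1))
    return(sprintf("'%s' must lie in (0, 1), got %g", name, x))
  if (!open && (x < 0 || x > 1))
    return(sprintf("'%s' must lie in [0, 1], got %g", name, x))
  NULL
}

.checkFst <- function(F, name = "fst") {
  if (length(F) != 1L || !is.finite(F) || F < 0 || F >= 1)
    return(sprintf("'%s' must lie in [0, 1), got %g", name, F))
  NULL
}

#' Population-structure models
#'
#' A small family of S4 parameter classes describing how cases and controls
#' relate to one or two ancestral populations under the Balding-Nichols drift
#' model. Each modern population's allele frequency at a SNP with ancestral
#' frequency p is Beta-distributed with mean p and variance F*p*(1-p), where F
#' is the fixation index between the modern and the ancestral population
#' (half of a pairwise between-population index).
#'
#' \describe{
#'   \item{HomogeneousModel}{cases and controls drawn from one unstructured
#'     population (F = 0).}
#'   \item{IsolatedPairModel}{all cases from one isolated population, all
#'     controls from another, each drifted from a shared ancestor with
#'     fixation index \code{fst} (optionally a different \code{fstControls}).}
#'   \item{CompleteAdmixtureModel}{cases and controls each a homogeneous mix
#'     of two ancestral sources, with case ancestry fraction \code{nuCases}
#'     and control fraction \code{nuControls} from source 1.}
#'   \item{BetaAdmixtureModel}{as above, but each individual's ancestry
#'     fraction is Beta-distributed with arm-specific mean and a shared
#'     heterogeneity parameter \code{het} = 1/(a+b+1), so the
#'     individual-ancestry variance is het*nu*(1-nu).}
#' }
#'
#' @slot nCases,nControls arm sizes (at least 1 each).
#' @slot fst fixation index in [0, 1).
#' @slot fstControls optional control-population fixation index
#'   (\code{NA} means shared with \code{fst}).
#' @slot nuCases,nuControls ancestry fractions from ancestral source 1.
#' @slot het heterogeneity of individual ancestry, in (0, 1).
#'
#' @name PopulationModel-classes
#' @aliases PopulationModel HomogeneousModel-class IsolatedPairModel-class
#'   CompleteAdmixtureModel-class BetaAdmixtureModel-class
#' @examples
#' IsolatedPairModel(fst = 0.0005, nCases = 500, nControls = 500)
NULL

setClass("PopulationModel", representation("VIRTUAL",
  nCases = "integer", nControls = "integer"))

setValidity("PopulationModel", function(object) {
  if (length(object@nCases) != 1L || is.na(object@nCases) || object@nCases < 1L)
    return("'nCases' must be a single count >= 1")
  if (length(object@nControls) != 1L || is.na(object@nControls) ||
      object@nControls < 1L)
    return("'nControls' must be a single count >= 1")
  TRUE
})

setClass("HomogeneousModel", contains = "PopulationModel")

setClass("IsolatedPairModel", contains = "PopulationModel",
  representation(fst = "numeric", fstControls = "numeric"))

setValidity("IsolatedPairModel", function(object) {
  msg <- .checkFst(object@fst)
  if (!is.null(msg)) return(msg)
  if (!is.na(object@fstControls)) {
    msg <- .checkFst(object@fstControls, "fstControls")
    if (!is.null(msg)) return(msg)
  }
  TRUE
})

setClass("CompleteAdmixtureModel", contains = "PopulationModel",
  representation(fst = "numeric", nuCases = "numeric", nuControls = "numeric"))

setValidity("CompleteAdmixtureModel", function(object) {
  for (msg in list(.checkFst(object@fst),
                   .checkProb(object@nuCases, "nuCases", open = FALSE),
                   .checkProb(object@nuControls, "nuControls", open = FALSE)))
    if (!is.null(msg)) return(msg)
  TRUE
})

setClass("BetaAdmixtureModel", contains = "PopulationModel",
  representation(fst = "numeric", nuCases = "numeric", nuControls = "numeric",
                 het = "numeric"))

setValidity("BetaAdmixtureModel", function(object) {
  for (msg in list(.checkFst(object@fst),
                   .checkProb(object@nuCases, "nuCases"),
                   .checkProb(object@nuControls, "nuControls"),
                   .checkProb(object@het, "het")))
    if (!is.null(msg)) return(msg)
  TRUE
})

#' Balding-Nichols drift parameters
#'
#' Fixation index F and ancestral allele frequency p of a single drifting
#' population: the modern-day frequency is Beta-distributed with mean p and
#' variance F*p*(1-p).
#'
#' @slot fst fixation index in [0, 1).
#' @slot p ancestral allele frequency in (0, 1).
#' @exportClass BaldingNicholsParams
#' @examples
#' BaldingNicholsParams(fst = 0.0005, p = 0.4)
setClass("BaldingNicholsParams",
  representation(fst = "numeric", p = "numeric"))

setValidity("BaldingNicholsParams", function(object) {
  for (msg in list(.checkFst(object@fst), .checkProb(object@p, "p")))
    if (!is.null(msg)) return(msg)
  TRUE
})

#' Kinship matrix
#'
#' A symmetric N x N relatedness matrix K: diagonal entries are 1 + f_i
#' (f_i the inbreeding coefficient) and off-diagonal entries twice the kinship
#' coefficient of the pair. Under the drift models here the theoretical
#' constructions have diagonal >= 1 and are positive semidefinite; the
#' genotype covariance at a SNP with frequency p_j is 2*p_j*(1-p_j) * K.
#'
#' @slot values numeric matrix with sample IDs as dimnames.
#' @seealso [kinshipIsolatedPair()], [kinshipAdmixed()], [estimateKinshipMom()]
#' @exportClass KinshipMatrix
setClass("KinshipMatrix",
  representation(values = "matrix"))

setValidity("KinshipMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v) || nrow(v) != ncol(v))
    return("'values' must be a square numeric matrix")
  if (anyNA(v) || !all(is.finite(v)))
    return("'values' must be finite")
  ids <- rownames(v)
  if (is.null(ids) || is.null(colnames(v)) || !identical(ids, colnames(v)))
    return("'values' must carry identical row and column sample IDs")
  if (anyDuplicated(ids))
    return("sample IDs must be unique")
  tol <- 1e-8 * max(1, max(abs(v)))
  if (max(abs(v - t(v))) > tol)
    return("'values' must be symmetric")
  TRUE
})

#' Smoothed kinship matrix
#'
#' Full-rank reconstruction of an estimated kinship matrix from its top-L
#' eigenpairs plus a trace-preserving ridge gamma on the complementary
#' subspace. Extends [KinshipMatrix-class] and can be used anywhere a kinship
#' matrix is accepted.
#'
#' @slot L number of eigenpairs retained.
#' @slot gamma ridge constant on the unretained subspace
#'   (\code{NA} when L = N and nothing was flattened).
#' @seealso [smoothKinship()]
#' @exportClass SmoothedKinship
setClass("SmoothedKinship", contains = "KinshipMatrix",
  representation(L = "integer", gamma = "numeric"))

#' Genotype panel
#'
#' Allele counts (0, 1, 2; NA for missing) for M SNPs (rows) by N samples
#' (columns), with per-SNP REF/ALT allele labels. Counts refer to copies of
#' the ALT allele.
#'
#' @slot counts numeric matrix, SNP IDs as rownames, sample IDs as colnames.
#' @slot ref,alt single-character allele labels, one per SNP.
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(counts = "matrix", ref = "character", alt = "character"))

setValidity("GenotypeMatrix", function(object) {
  cts <- object@counts
  if (!is.numeric(cts))
    return("'counts' must be numeric")
  if (is.null(rownames(cts)) || is.null(colnames(cts)))
    return("'counts' must have SNP IDs as rownames and sample IDs as colnames")
  if (anyDuplicated(rownames(cts))) return("SNP IDs must be unique")
  if (anyDuplicated(colnames(cts))) return("sample IDs must be unique")
  ok <- is.na(cts) | cts == 0 | cts == 1 | cts == 2
  if (!all(ok))
    return("non-missing genotype counts must be 0, 1 or 2")
  if (length(object@ref) != nrow(cts) || length(object@alt) != nrow(cts))
    return("'ref' and 'alt' must have one entry per SNP")
  TRUE
})

#' Case-control study design
#'
#' Per-sample case indicator (1 = case, 0 = control) and an optional free-text
#' site label. The implied design matrix C has rows (1, c_i). By package
#' convention cases precede controls in sample order.
#'
#' @slot sampleIds sample identifiers.
#' @slot status integer case indicator, one per sample.
#' @slot siteLabel optional stratum label (length 0 or N).
#' @exportClass StudyDesign
setClass("StudyDesign",
  representation(sampleIds = "character", status = "integer",
                 siteLabel = "character"))

setValidity("StudyDesign", function(object) {
  n <- length(object@sampleIds)
  if (anyDuplicated(object@sampleIds)) return("sample IDs must be unique")
  if (length(object@status) != n)
    return("'status' must have one entry per sample")
  if (anyNA(object@status) || !all(object@status %in% c(0L, 1L)))
    return("'status' must be 0 (control) or 1 (case)")
  if (sum(object@status) < 1L || sum(1L - object@status) < 1L)
    return("need at least one case and one control")
  if (length(object@siteLabel) != 0L && length(object@siteLabel) != n)
    return("'siteLabel' must be empty or one entry per sample")
  TRUE
})

#' Eigendecomposition of a kinship matrix
#'
#' Full spectrum (descending) and orthonormal eigenvectors of an estimated
#' kinship matrix, with the number of leading eigenvalues judged significant
#' by the sequential Tracy-Widom test at level \code{alpha}.
#'
#' @slot values eigenvalues, descending.
#' @slot vectors orthonormal eigenvectors (columns), sample IDs as rownames.
#' @slot nSignificant count of Tracy-Widom-significant leading eigenvalues.
#' @slot alpha per-eigenvalue significance level used.
#' @slot twPvalues sequential Tracy-Widom p-values (length nSignificant + 1
#'   or shorter when the residual spectrum degenerates).
#' @seealso [eigendecomposeKinship()]
#' @exportClass EigenDecomposition
setClass("EigenDecomposition",
  representation(values = "numeric", vectors = "matrix",
                 nSignificant = "integer", alpha = "numeric",
                 twPvalues = "numeric"))

setValidity("EigenDecomposition", function(object) {
  if (is.unsorted(rev(object@values)))
    return("eigenvalues must be sorted descending")
  if (ncol(object@vectors) != length(object@values))
    return("one eigenvector per eigenvalue required")
  if (object@nSignificant < 0L || object@nSignificant > length(object@values))
    return("'nSignificant' out of range")
  TRUE
})
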