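#' Beta shape parameters from mean and heterogeneity
#'
#' Re-parameterizes a Beta distribution of individual ancestry fractions by
#' its mean nu and a heterogeneity parameter h = 1/(a+b+1), so that the
#' variance is h*nu*(1-nu). Returns the usual shape parameters
#' a = nu*(1/h - 1) and b = (1-nu)*(1/h - 1).
#'
#' @param nu mean ancestry fraction, in (0, 1).
#' @param h heterogeneity parameter, in (0, 1); h -> 0 is a population whose
#'   members all share ancestry fraction nu, h = 1/3 with nu = 1/2 is the
#'   uniform distribution.
#' @return named numeric vector \code{c(a = , b = )}.
#' @examples
#' betaShapeFromMeanHet(0.5, 1/3)   # Beta(1, 1), the uniform
#' betaShapeFromMeanHet(0.2, 1/7)   # Beta(1.2, 4.8)
#' @export
betaShapeFromMeanHet <- function(nu, h) {
  msg <- .checkProb(nu, "nu")
  if (!is.null(msg)) stop(msg, call. = FALSE)
  msg <- .checkProb(h, "h")
  if (!is.null(msg)) stop(msg, call. = FALSE)
  s <- 1 / h - 1
  c(a = nu * s, b = (1 - nu) * s)
}

#' Theoretical kinship of a pair of isolated populations
#'
#' Under Balding-Nichols drift with fixation index F per population, the
#' relatedness matrix for samples drawn from two isolated populations (cases
#' from one, controls from the other, cases first) has diagonal 1 + F,
#' off-diagonal 2F within a population and 0 across populations.
#'
#' @param model an [IsolatedPairModel-class] (see
#'   [PopulationModel-classes]).
#' @return a [KinshipMatrix-class], cases first then controls.
#' @examples
#' kinshipIsolatedPair(IsolatedPairModel(0.0005, nCases = 2, nControls = 2))
#' @export
kinshipIsolatedPair <- function(model) {
  stopifnot(is(model, "IsolatedPairModel"))
  F1 <- model@fst
  F2 <- if (is.na(model@fstControls)) F1 else model@fstControls
  n1 <- model@nCases
  n2 <- model@nControls
  block <- function(n, F) {
    b <- matrix(2 * F, n, n)
    diag(b) <- 1 + F
    b
  }
  K <- matrix(0, n1 + n2, n1 + n2)
  K[seq_len(n1), seq_len(n1)] <- block(n1, F1)
  K[n1 + seq_len(n2), n1 + seq_len(n2)] <- block(n2, F2)
  KinshipMatrix(K, sampleIds = .autoIds(n1 + n2, nCases = n1))
}

#' Theoretical kinship of admixed individuals
#'
#' For individuals whose ancestry fractions from ancestral source 1 are
#' \code{fractions[i]}, both sources having drifted independently from a
#' common ancestor with fixation index F, the relatedness matrix has
#' diagonal 1 + F*(a_i^2 + (1-a_i)^2) and off-diagonal
#' 2F*(a_i*a_j + (1-a_i)*(1-a_j)). With all fractions 0 or 1 this reduces to
#' a single Balding-Nichols population (diagonal 1+F, off-diagonal 2F).
#'
#' @param fractions per-individual ancestry fractions in [0, 1].
#' @param fst fixation index of each ancestral source vs the common ancestor.
#' @param sampleIds optional identifiers.
#' @return a [KinshipMatrix-class].
#' @examples
#' kinshipAdmixed(c(0.25, 0.25, 0.20, 0.20), fst = 0.0765)
#' @export
kinshipAdmixed <- function(fractions, fst, sampleIds = NULL) {
  msg <- .checkFst(fst)
  if (!is.null(msg)) stop(msg, call. = FALSE)
  if (anyNA(fractions) || any(fractions < 0 | fractions > 1))
    stop("'fractions' must lie in [0, 1]", call. = FALSE)
  a <- as.numeric(fractions)
  # off-diagonal 2F(a_i a_j + (1-a_i)(1-a_j)) as a rank-2 outer product
  U <- cbind(a, 1 - a)
  K <- 2 * fst * tcrossprod(U)
  diag(K) <- 1 + fst * (a^2 + (1 - a)^2)
  if (is.null(sampleIds)) sampleIds <- .autoIds(length(a))
  KinshipMatrix(K, sampleIds = sampleIds)
}

#' @describeIn theoreticalKinship identity matrix (unrelated samples).
#' @export
setMethod("theoreticalKinship", "HomogeneousModel", function(model, ...) {
  n <- model@nCases + model@nControls
  KinshipMatrix(diag(n), sampleIds = .autoIds(n, nCases = model@nCases))
})

#' @describeIn theoreticalKinship two-block isolated-pair matrix.
#' @export
setMethod("theoreticalKinship", "IsolatedPairModel", function(model, ...) {
  kinshipIsolatedPair(model)
})

#' @describeIn theoreticalKinship completely-admixed matrix with constant
#'   ancestry nuCases / nuControls per arm.
#' @export
setMethod("theoreticalKinship", "CompleteAdmixtureModel", function(model, ...) {
  a <- rep(c(model@nuCases, model@nuControls),
           c(model@nCases, model@nControls))
  kinshipAdmixed(a, model@fst,
                 sampleIds = .autoIds(length(a), nCases = model@nCases))
})

#' @describeIn theoreticalKinship admixed matrix at supplied realized
#'   per-individual \code{fractions} (cases first).
#' @export
setMethod("theoreticalKinship", "BetaAdmixtureModel",
          function(model, fractions, ...) {
  n <- model@nCases + model@nControls
  if (missing(fractions) || length(fractions) != n)
    stop("BetaAdmixtureModel kinship needs realized per-individual ",
         "'fractions' (length nCases + nControls)", call. = FALSE)
  kinshipAdmixed(fractions, model@fst,
                 sampleIds = .autoIds(n, nCases = model@nCases))
})

#' Read and write kinship matrices as TSV
#'
#' The dialect is a header row of sample IDs, then one row per sample holding
#' the ID and the full row of N numeric values, written at 10 significant
#' digits.
#'
#' @param kinship a [KinshipMatrix-class].
#' @param path file path.
#' @return \code{readKinshipTsv} returns a [KinshipMatrix-class];
#'   \code{writeKinshipTsv} returns \code{path} invisibly.
#' @export
writeKinshipTsv <- function(kinship, path) {
  v <- kinshipValues(kinship)
  ids <- sampleIds(kinship)
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(ids[i], sprintf("%.10g", v[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("sample_id", ids), collapse = "\t"), body), path)
  invisible(path)
}

#' @rdname writeKinshipTsv
#' @export
readKinshipTsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("kinship TSV '", path, "' has no data rows", call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  ids <- header[-1L]
  n <- length(ids)
  v <- matrix(NA_real_, n, n)
  rowIds <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != n + 1L)
      stop("kinship TSV line ", i + 1L, ": expected ", n + 1L,
           " fields, got ", length(f), call. = FALSE)
    rowIds[i] <- f[[1L]]
    v[i, ] <- as.numeric(f[-1L])
  }
  if (!identical(rowIds, ids))
    stop("kinship TSV row IDs do not match header order", call. = FALSE)
  KinshipMatrix(v, sampleIds = ids)
}
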