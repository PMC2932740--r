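#' Non-centrality parameters for the Bourgain/Wald association test
#'
#' Closed-form non-centrality parameters (NCPs) of the 1-df chi-square Wald
#' statistic for an equal-arm case-control study testing a count-scale
#' case-minus-control difference \code{delta} at a SNP with ancestral
#' frequency \code{p}, under progressively richer population-structure
#' models. \code{delta = 0.2} corresponds to a 10-percentage-point
#' allele-frequency difference (odds ratio about 1.5 per copy at p = 0.4).
#'
#' \describe{
#'   \item{ncpHomogeneous}{no structure: lambda = n delta^2 / (4 p (1-p)),
#'     linear in n.}
#'   \item{ncpIsolated}{all cases from one isolated population and all
#'     controls from another, each drifted with fixation index F:
#'     lambda = delta^2 / ((2/n)(2p(1-p)(1+F) + (n-1) 4F p(1-p))), which is
#'     bounded above by delta^2 / (8 F p (1-p)) however large n grows.}
#'   \item{ncpCompleteAdmixture}{cases and controls each homogeneous mixes
#'     (fractions nu1, nu2 from ancestral source 1) of two sources with
#'     fixation index F from a common ancestor; the bound is
#'     delta^2 / (8 F p (1-p) (nu1 - nu2)^2), infinite when nu1 = nu2.}
#' }
#'
#' @param nPerArm cases per arm (equal numbers of cases and controls).
#' @param p ancestral allele frequency in (0, 1).
#' @param delta count-scale case-minus-control difference.
#' @param fst fixation index (present-day vs ancestral; half a pairwise
#'   between-population index).
#' @param nu1,nu2 ancestry fractions of cases / controls from source 1.
#' @return \code{ncpHomogeneous}: the NCP (numeric). The structured forms:
#'   list with \code{ncp} and \code{bound} (the large-n NCP bound, possibly
#'   \code{Inf}).
#' @examples
#' ncpHomogeneous(5000, 0.4, 0.2)               # 208.33
#' ncpIsolated(5000, 0.4, 0.2, 0.0005)$ncp      # 34.73
#' ncpCompleteAdmixture(5000, 0.4, 0.2, 0.153 / 2, 0.25, 0.20)$ncp  # 72.78
#' @name ncp-closed-forms
NULL

.checkNcpArgs <- function(nPerArm, p, delta) {
  stopifnot(length(nPerArm) == 1L, nPerArm >= 1)
  msg <- .checkProb(p, "p")
  if (!is.null(msg)) stop(msg, call. = FALSE)
  stopifnot(is.finite(delta))
}

#' @rdname ncp-closed-forms
#' @export
ncpHomogeneous <- function(nPerArm, p, delta) {
  .checkNcpArgs(nPerArm, p, delta)
  nPerArm * delta^2 / (4 * p * (1 - p))
}

#' @rdname ncp-closed-forms
#' @export
ncpIsolated <- function(nPerArm, p, delta, fst) {
  .checkNcpArgs(nPerArm, p, delta)
  msg <- .checkFst(fst)
  if (!is.null(msg)) stop(msg, call. = FALSE)
  n <- nPerArm
  v <- (2 / n) * (2 * p * (1 - p) * (1 + fst) +
                  (n - 1) * 4 * fst * p * (1 - p))
  bound <- if (fst > 0) delta^2 / (8 * fst * p * (1 - p)) else Inf
  list(ncp = delta^2 / v, bound = bound)
}

#' @rdname ncp-closed-forms
#' @export
ncpCompleteAdmixture <- function(nPerArm, p, delta, fst, nu1, nu2) {
  .checkNcpArgs(nPerArm, p, delta)
  msg <- .checkFst(fst)
  if (!is.null(msg)) stop(msg, call. = FALSE)
  stopifnot(nu1 >= 0, nu1 <= 1, nu2 >= 0, nu2 <= 1)
  n <- nPerArm
  pq <- p * (1 - p)
  V1 <- fst * pq * (nu1^2 + (1 - nu1)^2)
  V2 <- fst * pq * (nu2^2 + (1 - nu2)^2)
  cov12 <- 4 * fst * pq * (nu1 * nu2 + (1 - nu1) * (1 - nu2))
  varm <- function(V) (2 * pq + 2 * V + (n - 1) * 4 * V) / n
  v <- varm(V1) + varm(V2) - 2 * cov12
  bound <- if (fst > 0 && nu1 != nu2)
    delta^2 / (8 * fst * pq * (nu1 - nu2)^2) else Inf
  list(ncp = delta^2 / v, bound = bound)
}

# Var(beta1-hat) factor [(C'K^-1 C)^-1]_22 for an admixed kinship given
# per-individual ancestry fractions, via the Woodbury identity on
# K = D + U U', D_ii = 1 - F(a_i^2 + (1-a_i)^2), U = sqrt(2F) [a, 1-a].
.glsVar22Admixed <- function(a, status, fst) {
  d <- 1 - fst * (a^2 + (1 - a)^2)
  if (any(d <= 0)) return(NA_real_)
  U <- sqrt(2 * fst) * cbind(a, 1 - a)
  C <- cbind(1, status)
  DiC <- C / d
  DiU <- U / d
  M <- diag(2) + crossprod(U, DiU)
  KiC <- DiC - DiU %*% solve(M, crossprod(DiU, C))
  A <- crossprod(C, KiC)
  unname(solve(A)[2L, 2L])
}

#' NCP from an explicit kinship matrix and design
#'
#' Evaluates the Wald-test non-centrality parameter directly from the GLS
#' variance of the case-control contrast:
#' lambda = delta^2 / (2 p (1-p) [(C' K^-1 C)^-1]_22). On the theoretical
#' compound-symmetric kinship constructions this agrees with the closed-form
#' calculators.
#'
#' @param kinship a [KinshipMatrix-class] (or bare matrix).
#' @param design a [StudyDesign-class] of matching size.
#' @param p allele frequency of the tested SNP.
#' @param delta count-scale case-minus-control difference.
#' @return the NCP (numeric).
#' @examples
#' d <- StudyDesign(status = rep(c(1, 0), each = 100))
#' ncpFromStructure(diag(200), d, 0.4, 0.2)  # = ncpHomogeneous(100, 0.4, 0.2)
#' @export
ncpFromStructure <- function(kinship, design, p, delta) {
  K <- .asKinshipMatrixValues(kinship)
  n <- nSamples(design)
  if (nrow(K) != n) stop("kinship/design size mismatch", call. = FALSE)
  msg <- .checkProb(p, "p")
  if (!is.null(msg)) stop(msg, call. = FALSE)
  status <- as.numeric(caseStatus(design))
  C <- cbind(1, status)
  R <- .kinshipChol(K)
  KiC <- .cholSolve(R, C)
  A <- crossprod(C, KiC)
  var22 <- solve(A)[2L, 2L]
  unname(delta^2 / (2 * p * (1 - p) * var22))
}

#' Monte-Carlo NCP under beta-distributed individual admixture
#'
#' For incompletely admixed case and control populations (individual ancestry
#' fractions Beta-distributed with means nu1 / nu2 and common heterogeneity
#' h), the NCP depends on the realized ancestry draw. Each replicate draws
#' the fractions, builds the admixed kinship matrix, and evaluates the exact
#' matrix-form NCP (through a Woodbury inverse exploiting the
#' rank-2-plus-diagonal structure of K, so large arms stay cheap); results
#' are averaged over replicates. \code{nReplicates = 1} gives the
#' fixed-single-draw mode.
#'
#' @param nPerArm cases per arm (controls equal).
#' @param p allele frequency; \code{delta} count-scale difference.
#' @param delta count-scale case-minus-control difference.
#' @param fst fixation index of the ancestral sources vs their common
#'   ancestor.
#' @param nu1,nu2 mean ancestry fractions of cases / controls.
#' @param h heterogeneity parameter of individual ancestry, in (0, 1).
#' @param nReplicates Monte-Carlo replicates (default 50).
#' @param seed integer seed (required).
#' @return list with \code{ncp} (Monte-Carlo mean), \code{se} (standard
#'   error; 0 when nReplicates = 1), and \code{replicates} (per-replicate
#'   NCPs). Replicates yielding a numerically non-PSD kinship are rejected
#'   and recorded in \code{nRejected}.
#' @export
ncpBetaAdmixture <- function(nPerArm, p, delta, fst, nu1, nu2, h,
                             nReplicates = 50L, seed) {
  .checkNcpArgs(nPerArm, p, delta)
  msg <- .checkFst(fst)
  if (!is.null(msg)) stop(msg, call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  s1 <- betaShapeFromMeanHet(nu1, h)
  s2 <- betaShapeFromMeanHet(nu2, h)
  status <- rep(c(1, 0), each = nPerArm)
  withr::with_seed(seed, {
    vals <- numeric(0)
    nRejected <- 0L
    for (r in seq_len(nReplicates)) {
      a <- c(stats::rbeta(nPerArm, s1[["a"]], s1[["b"]]),
             stats::rbeta(nPerArm, s2[["a"]], s2[["b"]]))
      v22 <- .glsVar22Admixed(a, status, fst)
      if (is.na(v22) || v22 <= 0) {
        nRejected <- nRejected + 1L
        next
      }
      vals <- c(vals, delta^2 / (2 * p * (1 - p) * v22))
    }
    if (nRejected > 0L)
      message("ncpBetaAdmixture: rejected ", nRejected,
              " non-PSD replicates")
    list(ncp = mean(vals),
         se = if (length(vals) > 1L) stats::sd(vals) / sqrt(length(vals))
              else 0,
         replicates = vals, nRejected = nRejected)
  })
}

#' Power of the Wald test from its non-centrality parameter
#'
#' Upper-tail probability that a noncentral 1-df chi-square with
#' non-centrality \code{ncp} exceeds the central 1-df chi-square
#' (1 - alpha) quantile.
#'
#' @param ncp non-centrality parameter(s), >= 0.
#' @param alpha significance level in (0, 1).
#' @return power in [0, 1]; equals alpha at ncp = 0.
#' @examples
#' powerFromNcp(34.73, 1e-8)    # ~0.56
#' powerFromNcp(208.33, 1e-8)   # > 0.9999
#' @export
powerFromNcp <- function(ncp, alpha) {
  stopifnot(all(ncp >= 0), alpha > 0, alpha < 1)
  crit <- stats::qchisq(alpha, df = 1, lower.tail = FALSE)
  stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Expected estimated variance of the case-control contrast under
#' eigenvector adjustment
#'
#' When the test replaces the true kinship K by the smoothed estimate
#' K-tilde built from L eigenvectors, the reported variance of beta1-hat is
#' sigma-hat^2 [(C' Kt^-1 C)^-1]_22 with sigma-hat^2 the GLS residual mean
#' square. Its expectation under the true covariance 2 p (1-p) K follows
#' from trace identities: E sigma-hat^2 = 2 p (1-p) tr(T K) / (N - 2) with
#' T = Kt^-1 - Kt^-1 C (C' Kt^-1 C)^-1 C' Kt^-1. The function evaluates this
#' for each requested L, together with the true sampling variance of
#' beta1-hat and the effective-sample-size ratio against a homogeneous design
#' of the same size (variance 2 p (1-p) [(C'C)^-1]_22).
#'
#' @param kinship the true [KinshipMatrix-class] (the covariance the
#'   expectation is taken under).
#' @param design a [StudyDesign-class] of matching size.
#' @param L integer vector of eigenvector counts to adjust for (0 <= L <= N).
#' @param p allele frequency of the hypothetical marker.
#' @param smoothFrom optional estimated kinship (or its
#'   [EigenDecomposition-class]) whose eigenpairs define the smoothed
#'   matrices; defaults to \code{kinship} itself. Marker-estimated kinship
#'   concentrates population contrasts in its leading eigenvectors (the
#'   SNP-wise centering removes the common-mean direction), which is what
#'   makes small L effective in practice.
#' @return data.frame with columns \code{L}, \code{varBeta1} (expected
#'   reported variance), \code{trueVarBeta1} (actual sampling variance of the
#'   adjusted estimator), and \code{effectiveNRatio} (homogeneous-design
#'   variance / varBeta1; at most 1 when structure only destroys
#'   information, marginally above 1 when shared-drift correlations let the
#'   GLS beat the independent design).
#' @export
expectedVarianceUnderAdjustment <- function(kinship, design, L, p,
                                            smoothFrom = kinship) {
  Ktrue <- .asKinshipMatrixValues(kinship)
  n <- nSamples(design)
  if (nrow(Ktrue) != n) stop("kinship/design size mismatch", call. = FALSE)
  msg <- .checkProb(p, "p")
  if (!is.null(msg)) stop(msg, call. = FALSE)
  L <- as.integer(L)
  if (any(L < 0L | L > n)) stop("'L' must lie in [0, N]", call. = FALSE)
  status <- as.numeric(caseStatus(design))
  C <- cbind(1, status)
  scale <- 2 * p * (1 - p)
  varHom <- scale * solve(crossprod(C))[2L, 2L]
  ed <- if (is(smoothFrom, "EigenDecomposition")) {
    list(values = smoothFrom@values, vectors = smoothFrom@vectors)
  } else {
    Ks <- .asKinshipMatrixValues(smoothFrom)
    if (nrow(Ks) != n) stop("'smoothFrom' size mismatch", call. = FALSE)
    eigen((Ks + t(Ks)) / 2, symmetric = TRUE)
  }
  tr <- sum(ed$values)
  out <- lapply(L, function(l) {
    if (l == n) {
      w <- ed$values
      if (any(w <= 0)) stop("kinship not positive definite at L = N",
                            call. = FALSE)
    } else {
      gamma <- (tr - sum(ed$values[seq_len(l)])) / (n - l)
      if (gamma <= 0)
        stop("retained eigenvalues exhaust the trace at L = ", l,
             call. = FALSE)
      w <- c(ed$values[seq_len(l)], rep(gamma, n - l))
    }
    Ktinv <- ed$vectors %*% (t(ed$vectors) / w)
    KiC <- Ktinv %*% C
    A <- crossprod(C, KiC)
    Ainv <- solve(A)
    TT <- Ktinv - KiC %*% tcrossprod(Ainv, KiC)
    eSigma2 <- scale * sum(TT * Ktrue) / (n - 2)
    varB1 <- eSigma2 * Ainv[2L, 2L]
    trueVar <- scale *
      (Ainv %*% crossprod(KiC, Ktrue %*% KiC) %*% Ainv)[2L, 2L]
    data.frame(L = l, varBeta1 = varB1, trueVarBeta1 = trueVar,
               effectiveNRatio = varHom / varB1)
  })
  do.call(rbind, out)
}

#' Effective sample size of 1:m matching
#'
#' A study with n cases and m controls per case has the estimator variance of
#' a 1:1-matched study with n * 2m / (m + 1) cases: the increment from extra
#' controls is governed by m / (m + 1), approaching twice the effective size
#' as m grows.
#'
#' @param nCases number of cases.
#' @param m controls per case (> 0).
#' @return equivalent number of 1:1-matched case-control pairs.
#' @examples
#' effectiveNOneToM(1000, 3)   # 1500
#' @export
effectiveNOneToM <- function(nCases, m) {
  stopifnot(nCases > 0, m > 0)
  nCases * 2 * m / (m + 1)
}
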