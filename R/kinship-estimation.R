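#' Method-of-moments kinship estimate from genotypes
#'
#' Estimates the relatedness matrix as the SNP-average of outer products of
#' centered, scaled allele counts: for SNP j with pooled frequency estimate
#' p_j, the contribution is (g_j - 2*p_j*1)(g_j - 2*p_j*1)' / (2*p_j*(1-p_j)).
#' Missing genotypes are handled pairwise-complete: each entry is averaged
#' over the SNPs at which both samples were called. Monomorphic SNPs and SNPs
#' with missingness above \code{maxMissing} are skipped (counts are reported
#' via a message and the \code{nSkipped} element).
#'
#' @param panel a [GenotypeMatrix-class] with at least two samples.
#' @param snpSubset optional character vector of SNP IDs to use.
#' @param maxMissing per-SNP missingness ceiling (default 0.05).
#' @return list with \code{kinship} ([KinshipMatrix-class]), \code{freq}
#'   (named per-SNP pooled frequency estimates for the SNPs used) and
#'   \code{nSkipped} (named counts: monomorphic, missing).
#' @examples
#' sim <- simulateNullSnps(HomogeneousModel(20, 20), nSnps = 500, seed = 1)
#' k <- estimateKinshipMom(sim$panel)
#' mean(diag(kinshipValues(k$kinship)))   # near 1 for unrelated samples
#' @export
estimateKinshipMom <- function(panel, snpSubset = NULL, maxMissing = 0.05) {
  stopifnot(is(panel, "GenotypeMatrix"))
  G <- genotypeCounts(panel)
  if (ncol(G) < 2L) stop("need at least two samples", call. = FALSE)
  if (!is.null(snpSubset)) {
    missing <- setdiff(snpSubset, rownames(G))
    if (length(missing))
      stop("unknown SNP IDs in 'snpSubset': ", missing[[1L]], call. = FALSE)
    G <- G[snpSubset, , drop = FALSE]
  }
  missFrac <- rowMeans(is.na(G))
  tooMissing <- missFrac > maxMissing
  p <- rowMeans(G, na.rm = TRUE) / 2
  mono <- !tooMissing & (is.na(p) | p <= 0 | p >= 1)
  keep <- !tooMissing & !mono
  nSkipped <- c(monomorphic = sum(mono), missing = sum(tooMissing))
  if (any(nSkipped > 0))
    message("estimateKinshipMom: skipped ", nSkipped[["monomorphic"]],
            " monomorphic and ", nSkipped[["missing"]],
            " high-missingness SNPs")
  if (!any(keep)) stop("no usable SNPs for kinship estimation", call. = FALSE)
  G <- G[keep, , drop = FALSE]
  p <- p[keep]
  Z <- (G - 2 * p) / sqrt(2 * p * (1 - p))
  if (anyNA(Z)) {
    obs <- !is.na(Z)
    Z[!obs] <- 0
    num <- crossprod(Z)
    cnt <- crossprod(obs * 1)
    if (any(cnt == 0))
      stop("some sample pairs share no called SNPs", call. = FALSE)
    K <- num / cnt
  } else {
    K <- crossprod(Z) / nrow(Z)
  }
  K <- (K + t(K)) / 2
  list(kinship = KinshipMatrix(K, sampleIds = sampleIds(panel)),
       freq = stats::setNames(p, rownames(G)), nSkipped = nSkipped)
}

# Tracy-Widom (beta = 1) distribution via the moment-matched shifted-gamma
# approximation (Chiani 2014): matches mean, variance and skewness of TW1;
# CDF error ~1e-3, ample for sequential eigenvalue testing at alpha ~ 0.05.
.tw1Mean <- -1.2065335745820
.tw1Var <- 1.607781034581
.tw1Skew <- 0.29346452408
.tw1Shape <- (2 / .tw1Skew)^2
.tw1Scale <- sqrt(.tw1Var / .tw1Shape)
.tw1Shift <- .tw1Mean - .tw1Shape * .tw1Scale

#' Tracy-Widom (beta = 1) distribution
#'
#' CDF and quantile function of the Tracy-Widom distribution for the largest
#' eigenvalue of a GOE matrix, evaluated through a three-moment-matched
#' shifted-gamma approximation (accurate to about 1e-3 in probability).
#'
#' @param q,p quantile / probability.
#' @return probability (\code{ptw1}) or quantile (\code{qtw1}).
#' @examples
#' qtw1(0.95)   # ~0.98, the usual 5% critical point
#' @export
ptw1 <- function(q) {
  stats::pgamma(q - .tw1Shift, shape = .tw1Shape, scale = .tw1Scale)
}

#' @rdname ptw1
#' @export
qtw1 <- function(p) {
  stats::qgamma(p, shape = .tw1Shape, scale = .tw1Scale) + .tw1Shift
}

# Patterson-style moment estimate of the effective number of markers behind
# a residual spectrum, and the TW normalization of its leading eigenvalue.
.twStat <- function(lambda) {
  m <- length(lambda)
  if (m < 2L) return(NA_real_)
  s1 <- sum(lambda)
  s2 <- sum(lambda^2)
  denom <- (m - 1) * s2 - s1^2
  if (denom <= 0 || s1 <= 0) return(NA_real_)  # no excess spread: null-like
  nEff <- (m + 1) * s1^2 / denom
  ell <- m * lambda[[1L]] / s1
  mu <- (sqrt(nEff - 1) + sqrt(m))^2 / nEff
  sig <- (sqrt(nEff - 1) + sqrt(m)) / nEff *
    (1 / sqrt(nEff - 1) + 1 / sqrt(m))^(1 / 3)
  (ell - mu) / sig
}

#' Eigendecomposition with Tracy-Widom eigenvalue significance
#'
#' Returns the full spectrum and orthonormal eigenvectors of an estimated
#' kinship matrix, and counts the leading eigenvalues that are significant by
#' the sequential Tracy-Widom procedure: each leading eigenvalue is
#' normalized against the residual spectrum (Patterson-style moment-matched
#' effective marker count) and compared to the TW(1) alpha quantile; testing
#' stops at the first non-significant eigenvalue. Tests are nominal, with no
#' multiplicity correction.
#'
#' @param kinship a [KinshipMatrix-class] (typically a method-of-moments
#'   estimate).
#' @param twAlpha per-eigenvalue significance level (default 0.05).
#' @return an [EigenDecomposition-class].
#' @export
eigendecomposeKinship <- function(kinship, twAlpha = 0.05) {
  stopifnot(is(kinship, "KinshipMatrix"))
  K <- kinshipValues(kinship)
  asym <- max(abs(K - t(K)))
  if (asym > 1e-10 * max(1, max(abs(K))))
    stop("kinship matrix asymmetric beyond tolerance", call. = FALSE)
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  rownames(e$vectors) <- sampleIds(kinship)
  nSig <- 0L
  pvals <- numeric(0)
  lam <- pmax(e$values, 0)
  for (i in seq_len(length(lam) - 1L)) {
    x <- .twStat(lam[i:length(lam)])
    if (is.na(x)) break
    pv <- 1 - ptw1(x)
    pvals <- c(pvals, pv)
    if (pv < twAlpha) nSig <- nSig + 1L else break
  }
  new("EigenDecomposition", values = e$values, vectors = e$vectors,
      nSignificant = nSig, alpha = twAlpha, twPvalues = pvals)
}

#' Trace-preserving smoothed kinship matrix
#'
#' Reconstructs a full-rank kinship matrix from the top L eigenpairs of an
#' estimate K-hat, flattening the unretained subspace to a constant ridge:
#' K-tilde = sum_{l<=L} lambda_l e_l e_l' + gamma (I - sum_{l<=L} e_l e_l'),
#' with gamma = (trace(K-hat) - sum_{l<=L} lambda_l) / (N - L). The top-L
#' eigenpairs and the total trace are preserved exactly; the result is full
#' rank whenever gamma > 0. L = 0 gives the pure ridge (trace/N) * I; L = N
#' returns K-hat itself.
#'
#' @param kinship a [KinshipMatrix-class], or an [EigenDecomposition-class]
#'   already computed from one.
#' @param L number of eigenpairs to retain, 0 <= L <= N.
#' @return a [SmoothedKinship-class].
#' @examples
#' K <- kinshipIsolatedPair(IsolatedPairModel(0.01, 10, 10))
#' smoothKinship(K, L = 1)
#' @export
smoothKinship <- function(kinship, L) {
  ed <- if (is(kinship, "EigenDecomposition")) kinship
        else eigendecomposeKinship(kinship, twAlpha = 0.05)
  N <- length(ed@values)
  L <- as.integer(L)
  if (L < 0L || L > N) stop("'L' must lie in [0, N]", call. = FALSE)
  tr <- sum(ed@values)
  ids <- sampleIds(ed)
  if (L == N) {
    Kt <- ed@vectors %*% (ed@values * t(ed@vectors))
    gamma <- NA_real_
  } else {
    gamma <- (tr - sum(ed@values[seq_len(L)])) / (N - L)
    if (gamma <= 1e-10 * max(tr / N, 1))
      stop("retained eigenvalues exhaust the trace (gamma <= 0); ",
           "use a smaller L", call. = FALSE)
    w <- c(ed@values[seq_len(L)], rep(gamma, N - L))
    Kt <- ed@vectors %*% (w * t(ed@vectors))
  }
  Kt <- (Kt + t(Kt)) / 2
  dimnames(Kt) <- list(ids, ids)
  new("SmoothedKinship", values = Kt, L = L, gamma = gamma)
}
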