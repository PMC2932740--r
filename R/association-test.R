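.asKinshipMatrixValues <- function(kinship) {
  if (is(kinship, "KinshipMatrix")) kinshipValues(kinship)
  else as.matrix(kinship)
}

# Cholesky of K shared across SNPs; failure suggests smoothing.
.kinshipChol <- function(K) {
  R <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(R))
    stop("kinship matrix is singular or not positive definite; ",
         "consider smoothKinship() before testing", call. = FALSE)
  R
}

.cholSolve <- function(R, B) backsolve(R, backsolve(R, B, transpose = TRUE))

#' Generalized Bourgain retrospective association test for one SNP
#'
#' Fits the retrospective mean model E[Y_j] = C beta, C = (1, case-indicator),
#' by generalized least squares with covariance sigma_j^2 K:
#' beta-hat = (C'K^-1 C)^-1 C'K^-1 Y, residual scale
#' sigma-hat_j^2 = (Y - C beta-hat)' K^-1 (Y - C beta-hat) / (N - 2), and the
#' Wald statistic W = beta1^2 / (sigma-hat^2 [(C'K^-1 C)^-1]_22), referred to
#' a 1-df chi-square. With K = I this reduces to the ordinary
#' least-squares (Armitage-type) test; W and p are invariant to rescaling K.
#' Samples with a missing genotype are dropped along with the matching rows
#' and columns of K. A SNP monomorphic among the used samples is flagged and
#' assigned W = 0, p = 1.
#'
#' @param g numeric vector of allele counts (0/1/2, NA missing), one per
#'   sample, in the design's sample order.
#' @param design a [StudyDesign-class].
#' @param kinship a [KinshipMatrix-class] / [SmoothedKinship-class] (or bare
#'   matrix) matching the design.
#' @param snpId identifier recorded in the result.
#' @return one-row data.frame: snp_id, n_used, beta1, var_beta1, sigma2_hat,
#'   wald, p_value, monomorphic.
#' @examples
#' d <- StudyDesign(status = c(1, 1, 1, 1, 0, 0, 0, 0))
#' K <- diag(8)
#' bourgainWaldTest(c(2, 2, 1, 1, 0, 0, 1, 1), d, K)   # W = 6
#' @export
bourgainWaldTest <- function(g, design, kinship, snpId = "snp") {
  K <- .asKinshipMatrixValues(kinship)
  n <- nSamples(design)
  if (length(g) != n || nrow(K) != n)
    stop("genotype / design / kinship dimensions differ", call. = FALSE)
  use <- !is.na(g)
  if (!any(use)) stop("genotype vector is entirely missing", call. = FALSE)
  status <- as.numeric(caseStatus(design))[use]
  if (sum(status) < 1 || sum(1 - status) < 1)
    stop("need at least one case and one control with called genotypes",
         call. = FALSE)
  y <- g[use]
  if (stats::var(y) == 0) {
    return(data.frame(snp_id = snpId, n_used = sum(use), beta1 = 0,
                      var_beta1 = NA_real_, sigma2_hat = 0, wald = 0,
                      p_value = 1, monomorphic = TRUE))
  }
  Ku <- K[use, use, drop = FALSE]
  R <- .kinshipChol(Ku)
  C <- cbind(1, status)
  KiC <- .cholSolve(R, C)
  A <- crossprod(C, KiC)
  Ainv <- solve(A)
  Kiy <- .cholSolve(R, y)
  beta <- unname(drop(Ainv %*% crossprod(KiC, y)))
  rss <- drop(crossprod(y, Kiy)) - drop(crossprod(beta, A %*% beta))
  sigma2 <- rss / (sum(use) - 2)
  varB1 <- sigma2 * Ainv[2L, 2L]
  wald <- beta[[2L]]^2 / varB1
  data.frame(snp_id = snpId, n_used = sum(use), beta1 = beta[[2L]],
             var_beta1 = varB1, sigma2_hat = sigma2, wald = wald,
             p_value = stats::pchisq(wald, df = 1, lower.tail = FALSE),
             monomorphic = FALSE)
}

#' Genome scan with the generalized Bourgain test
#'
#' Applies [bourgainWaldTest()] to every SNP of a panel that passes the
#' standard filters (pooled MAF >= \code{mafMin}, call rate >=
#' \code{callRateMin}). A single Cholesky factorization of K is shared across
#' all completely-called SNPs; SNPs with missing calls fall back to the exact
#' drop-samples path. Filter counts are reported via a message and attached
#' as \code{attr(, "filters")}.
#'
#' @param panel a [GenotypeMatrix-class].
#' @param design a [StudyDesign-class] with the same samples, same order.
#' @param kinship kinship matrix matching the samples.
#' @param mafMin pooled minor-allele-frequency floor (default 0.01).
#' @param callRateMin per-SNP call-rate floor (default 0.95).
#' @return data.frame with one row per tested SNP (columns as in
#'   [bourgainWaldTest()]); attribute \code{filters} holds the exclusion
#'   counts.
#' @export
runScan <- function(panel, design, kinship, mafMin = 0.01,
                    callRateMin = 0.95) {
  stopifnot(is(panel, "GenotypeMatrix"), is(design, "StudyDesign"))
  if (!identical(sampleIds(panel), sampleIds(design)))
    stop("panel and design sample IDs differ (first mismatch: ",
         sampleIds(panel)[which(sampleIds(panel) != sampleIds(design))[1L]],
         ")", call. = FALSE)
  K <- .asKinshipMatrixValues(kinship)
  if (nrow(K) != nSamples(design))
    stop("kinship dimension does not match the design", call. = FALSE)
  G <- genotypeCounts(panel)
  callRate <- rowMeans(!is.na(G))
  f <- rowMeans(G, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  lowCall <- callRate < callRateMin
  lowMaf <- !lowCall & maf < mafMin
  keep <- !lowCall & !lowMaf
  filters <- c(low_call_rate = sum(lowCall), low_maf = sum(lowMaf),
               tested = sum(keep))
  message(sprintf("runScan: testing %d SNPs (%d excluded: %d call rate, %d MAF)",
                  filters[["tested"]], sum(lowCall) + sum(lowMaf),
                  filters[["low_call_rate"]], filters[["low_maf"]]))
  if (!any(keep)) {
    out <- data.frame(snp_id = character(), n_used = integer(),
                      beta1 = numeric(), var_beta1 = numeric(),
                      sigma2_hat = numeric(), wald = numeric(),
                      p_value = numeric(), monomorphic = logical())
    attr(out, "filters") <- filters
    return(out)
  }
  G <- G[keep, , drop = FALSE]
  complete <- rowSums(is.na(G)) == 0L
  n <- ncol(G)
  status <- as.numeric(caseStatus(design))
  pieces <- list()
  if (any(complete)) {
    R <- .kinshipChol(K)
    C <- cbind(1, status)
    KiC <- .cholSolve(R, C)
    A <- crossprod(C, KiC)
    Ainv <- solve(A)
    Y <- t(G[complete, , drop = FALSE])          # N x M
    KiY <- .cholSolve(R, Y)
    beta <- Ainv %*% crossprod(KiC, Y)           # 2 x M
    rss <- colSums(Y * KiY) - colSums(beta * (A %*% beta))
    sigma2 <- rss / (n - 2)
    varB1 <- sigma2 * Ainv[2L, 2L]
    wald <- beta[2L, ]^2 / varB1
    pieces$complete <- data.frame(
      snp_id = rownames(G)[complete], n_used = n, beta1 = beta[2L, ],
      var_beta1 = varB1, sigma2_hat = sigma2, wald = wald,
      p_value = stats::pchisq(wald, df = 1, lower.tail = FALSE),
      monomorphic = FALSE)
  }
  if (any(!complete)) {
    rows <- lapply(which(!complete), function(i)
      bourgainWaldTest(G[i, ], design, K, snpId = rownames(G)[i]))
    pieces$missing <- do.call(rbind, rows)
  }
  out <- do.call(rbind, pieces)
  out <- out[match(rownames(G), out$snp_id), ]
  rownames(out) <- NULL
  attr(out, "filters") <- filters
  out
}

#' Genomic-control inflation factor and QQ coordinates
#'
#' Computes lambda_GC, the median of the 1-df chi-square quantiles implied by
#' the p-values divided by the null median 0.4549, together with the
#' coordinates of a -log10 quantile-quantile plot (expected vs observed,
#' sorted ascending).
#'
#' @param pValues numeric vector of p-values in (0, 1].
#' @return list with \code{lambdaGC} and \code{qq}, a data.frame with
#'   columns \code{expected} and \code{observed} (-log10 scale, ascending).
#' @export
inflationDiagnostics <- function(pValues) {
  p <- pValues[!is.na(pValues)]
  if (!length(p)) stop("no p-values supplied", call. = FALSE)
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambdaGC <- stats::median(chi) / stats::qchisq(0.5, df = 1)
  n <- length(p)
  qq <- data.frame(expected = -log10(seq(n, 1) / (n + 1)),
                   observed = sort(-log10(p)))
  list(lambdaGC = lambdaGC, qq = qq)
}
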