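# Balding-Nichols draw of a modern-day frequency: Beta with mean p and
# variance F*p*(1-p), i.e. shapes (p(1-F)/F, (1-p)(1-F)/F). F = 0 is no drift.
.rBaldingNichols <- function(n, p, F) {
  if (F == 0) return(rep(p, length.out = max(n, length(p))))
  stats::rbeta(n, p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

# Per-individual ancestry fractions (cases first) implied by a model; these
# are a property of the sample, drawn once per panel, not per SNP.
.drawAncestry <- function(model) {
  n1 <- model@nCases
  n2 <- model@nControls
  if (is(model, "HomogeneousModel")) rep(1, n1 + n2)
  else if (is(model, "IsolatedPairModel")) rep(c(1, 0), c(n1, n2))
  else if (is(model, "CompleteAdmixtureModel"))
    rep(c(model@nuCases, model@nuControls), c(n1, n2))
  else if (is(model, "BetaAdmixtureModel")) {
    s1 <- betaShapeFromMeanHet(model@nuCases, model@het)
    s2 <- betaShapeFromMeanHet(model@nuControls, model@het)
    c(stats::rbeta(n1, s1[["a"]], s1[["b"]]),
      stats::rbeta(n2, s2[["a"]], s2[["b"]]))
  } else stop("unsupported model class: ", class(model), call. = FALSE)
}

# Draw per-SNP modern frequencies of the two ancestral/isolated sources.
# Returns list(p1, p2), each length nSnps. For the homogeneous model both
# equal the ancestral frequency.
.drawSourceFreqs <- function(model, p) {
  if (is(model, "HomogeneousModel")) return(list(p1 = p, p2 = p))
  F1 <- model@fst
  F2 <- if (is(model, "IsolatedPairModel") && !is.na(model@fstControls))
    model@fstControls else F1
  list(p1 = .rBaldingNichols(length(p), p, F1),
       p2 = .rBaldingNichols(length(p), p, F2))
}

#' Simulate null SNPs under a population-structure model
#'
#' Generates a case-control genotype panel with no SNP-phenotype association.
#' For each SNP an ancestral frequency p is drawn from \code{freqSampler};
#' each population source's modern frequency is Balding-Nichols
#' Beta-distributed with mean p and variance F*p*(1-p); individual i with
#' ancestry fraction a_i (1 or 0 for isolated populations) carries the
#' structured frequency q_i = a_i*p1 + (1-a_i)*p2 and a genotype drawn
#' binomial(2, q_i) (Hardy-Weinberg given ancestry). SNPs whose pooled minor
#' allele frequency falls below \code{minMaf} are regenerated, mirroring the
#' usual MAF < 1\% exclusion.
#'
#' @param model a population model ([PopulationModel-classes]).
#' @param nSnps number of SNPs.
#' @param freqSampler function(n) returning n ancestral frequencies in (0, 1);
#'   default Uniform(0.1, 0.9).
#' @param seed integer seed; all randomness flows from it and the caller's
#'   RNG state is left untouched.
#' @param minMaf pooled minor-allele-frequency floor (0 disables
#'   regeneration).
#' @param missingRate fraction of calls set missing at random (default 0;
#'   intended for I/O and estimator-robustness testing).
#' @return a list with elements \code{panel} ([GenotypeMatrix-class]),
#'   \code{design} ([StudyDesign-class], cases first), and \code{truth}, a
#'   list of two data frames: \code{snps} (snp_id, ancestral_freq, pop1_freq,
#'   pop2_freq, is_causal) and \code{samples} (sample_id, status,
#'   ancestry_fraction).
#' @examples
#' sim <- simulateNullSnps(IsolatedPairModel(0.01, 50, 50), nSnps = 20,
#'                         seed = 1)
#' sim$panel
#' @export
simulateNullSnps <- function(model, nSnps,
                             freqSampler = function(n) stats::runif(n, 0.1, 0.9),
                             seed, minMaf = 0.01, missingRate = 0) {
  stopifnot(is(model, "PopulationModel"), nSnps >= 1)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  withr::with_seed(seed, {
    a <- .drawAncestry(model)
    n <- length(a)
    p <- freqSampler(nSnps)
    if (anyNA(p) || any(p <= 0 | p >= 1))
      stop("'freqSampler' produced frequencies outside (0, 1)", call. = FALSE)
    src <- .drawSourceFreqs(model, p)
    draw <- function(p1, p2) {
      # Q: nSnps x N structured frequencies, then binomial genotypes
      Q <- outer(p1, a) + outer(p2, 1 - a)
      matrix(stats::rbinom(length(Q), 2L, Q), nrow = length(p1))
    }
    G <- draw(src$p1, src$p2)
    if (minMaf > 0) {
      for (iter in seq_len(100L)) {
        f <- rowMeans(G) / 2
        bad <- which(pmin(f, 1 - f) < minMaf)
        if (!length(bad)) break
        p[bad] <- freqSampler(length(bad))
        rep1 <- .drawSourceFreqs(model, p[bad])
        src$p1[bad] <- rep1$p1
        src$p2[bad] <- rep1$p2
        G[bad, ] <- draw(src$p1[bad], src$p2[bad])
      }
      f <- rowMeans(G) / 2
      if (any(pmin(f, 1 - f) < minMaf))
        warning("some SNPs remain below minMaf after regeneration")
    }
    if (missingRate > 0) {
      drop <- stats::runif(length(G)) < missingRate
      G[drop] <- NA_real_
    }
    design <- modelDesign(model)
    panel <- GenotypeMatrix(G, sampleIds = sampleIds(design))
    truth <- list(
      snps = data.frame(snp_id = snpIds(panel), ancestral_freq = p,
                        pop1_freq = src$p1, pop2_freq = src$p2,
                        is_causal = FALSE),
      samples = data.frame(sample_id = sampleIds(design),
                           status = as.integer(caseStatus(design)),
                           ancestry_fraction = a))
    list(panel = panel, design = design, truth = truth)
  })
}

#' Append causal SNPs to a panel
#'
#' Simulates SNPs carrying a true case-control difference: each individual's
#' structured frequency is shifted by +delta/4 for cases and -delta/4 for
#' controls (frequency scale), so the expected case-minus-control difference
#' in mean allele count is \code{delta} and the allele-frequency difference
#' is delta/2. Shifted frequencies are clipped to [0.01, 0.99]; a warning is
#' issued when more than 1\% of individuals are clipped.
#'
#' @param panel a [GenotypeMatrix-class] to append to.
#' @param design the matching [StudyDesign-class].
#' @param ancestralFreq ancestral frequency p of the causal allele.
#' @param delta case-minus-control difference in mean allele count
#'   (count scale; 0.2 corresponds to a 10-percentage-point allele-frequency
#'   difference).
#' @param seed integer seed.
#' @param model optional population model supplying drift for the causal
#'   SNP's source frequencies; default homogeneous (no drift).
#' @param ancestry optional realized per-individual ancestry fractions (in
#'   the panel's sample order); defaults to the model-implied constants.
#' @param n number of causal SNPs to append.
#' @return a list with \code{panel} (the extended [GenotypeMatrix-class]) and
#'   \code{truth}, a data frame of the appended SNPs in the same layout as
#'   the simulator's truth table (\code{is_causal = TRUE}).
#' @export
addCausalSnp <- function(panel, design, ancestralFreq, delta, seed,
                         model = NULL, ancestry = NULL, n = 1L) {
  stopifnot(is(panel, "GenotypeMatrix"), is(design, "StudyDesign"))
  if (!identical(sampleIds(panel), sampleIds(design)))
    stop("panel and design sample IDs differ", call. = FALSE)
  p <- ancestralFreq
  msg <- .checkProb(p, "ancestralFreq")
  if (!is.null(msg)) stop(msg, call. = FALSE)
  if (p + abs(delta) / 4 >= 1 || p - abs(delta) / 4 <= 0)
    stop("implied case/control frequencies leave (0, 1) for ",
         "ancestralFreq = ", p, ", delta = ", delta, call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (is.null(model))
    model <- HomogeneousModel(sum(caseStatus(design)),
                              sum(1L - caseStatus(design)))
  status <- as.numeric(caseStatus(design))
  if (is.null(ancestry)) {
    if (is(model, "BetaAdmixtureModel"))
      stop("supply realized 'ancestry' fractions for a BetaAdmixtureModel",
           call. = FALSE)
    aArm <- if (is(model, "HomogeneousModel")) c(1, 1)
      else if (is(model, "IsolatedPairModel")) c(1, 0)
      else c(model@nuCases, model@nuControls)
    ancestry <- ifelse(status == 1, aArm[1L], aArm[2L])
  }
  if (length(ancestry) != nSamples(panel))
    stop("'ancestry' must have one fraction per sample", call. = FALSE)
  withr::with_seed(seed, {
    pv <- rep(p, n)
    src <- .drawSourceFreqs(model, pv)
    shift <- ifelse(status == 1, delta / 4, -delta / 4)
    Q <- outer(src$p1, ancestry) + outer(src$p2, 1 - ancestry) +
      matrix(shift, n, length(shift), byrow = TRUE)
    nClip <- sum(Q < 0.01 | Q > 0.99)
    if (nClip > 0.01 * length(Q))
      warning(sprintf("clipping activated for %.1f%% of individual frequencies",
                      100 * nClip / length(Q)))
    Q <- pmin(pmax(Q, 0.01), 0.99)
    G <- matrix(stats::rbinom(length(Q), 2L, Q), nrow = n)
    nPrev <- sum(grepl("^causal_", snpIds(panel)))
    ids <- sprintf("causal_%06d", nPrev + seq_len(n))
    rownames(G) <- ids
    colnames(G) <- sampleIds(panel)
    newPanel <- GenotypeMatrix(rbind(genotypeCounts(panel), G),
                               ref = c(refAlleles(panel), rep("A", n)),
                               alt = c(altAlleles(panel), rep("G", n)))
    truth <- data.frame(snp_id = ids, ancestral_freq = pv,
                        pop1_freq = src$p1, pop2_freq = src$p2,
                        is_causal = TRUE)
    list(panel = newPanel, truth = truth)
  })
}
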