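---
title: "Methods: the generalized Bourgain test and power under population structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the generalized Bourgain test and power under population structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strucpower)
```

## The problem

Reusing existing controls — convenience controls from other studies, shared
control panels, public genotype resources — is attractive whenever cases are
expensive and controls are nearly free. The price is confounding by ancestry:
if cases and controls are drawn from populations that differ in genetic
background, allele-frequency differences arise at every marker, not only at
disease loci. This package quantifies that price at the design stage
(non-centrality parameters and power under explicit structure models) and
corrects for it at the analysis stage (a kinship-adjusted retrospective
association test), with a simulator that makes every claim checkable without
any external data.

## The retrospective GLS model

For SNP $j$, let $Y_j$ be the $N$-vector of allele counts (0/1/2 copies of
the ALT allele) and $C$ the $N \times 2$ design matrix with rows
$(1, c_i)$, $c_i \in \{0, 1\}$ the case indicator. The retrospective model
treats the genotype as the outcome:

$$E[Y_j] = C\beta, \qquad \mathrm{Var}[Y_j] = \sigma_j^2 K,$$

where $K$ is a relatedness (kinship) matrix shared by all SNPs and
$\sigma_j^2$ is a per-SNP scale, equal to $2p_j(1-p_j)$ for a SNP of
frequency $p_j$ in an outbred population. $\beta_1$ is the case-minus-control
difference in mean allele count; $\beta_1 = 0.2$ corresponds to a
10-percentage-point allele-frequency difference, roughly an odds ratio of
1.5 per copy at $p = 0.4$. The best linear unbiased estimate is generalized
least squares,
$\hat\beta = (C'K^{-1}C)^{-1}C'K^{-1}Y_j$, with
$\hat\sigma_j^2$ the GLS residual mean square (denominator $N - 2$, two mean
parameters), and the Wald statistic

$$W = \frac{\hat\beta_1^2}{\hat\sigma_j^2\,[(C'K^{-1}C)^{-1}]_{22}}$$

referred to a 1-df chi-square (`bourgainWaldTest()`, `runScan()`). Two
consequences shape the implementation: with $K = I$ the test collapses to
the ordinary Armitage-type regression test, and multiplying $K$ by any
positive constant leaves $W$ unchanged because $\hat\sigma^2$ absorbs the
scale. Both are asserted in the test suite, which pins the statistic even
where conventions (e.g. the residual denominator) could legitimately vary.

## Structure models and their kinship matrices

All Greek parameters live in a small family of model classes.

* **Balding–Nichols drift.** A modern population separated from its
  ancestral population by fixation index $F$ has allele frequency
  $\mathrm{Beta}$-distributed with mean $p$ and variance $Fp(1-p)$. $F$ here
  is *present-day versus ancestral*; a published pairwise between-population
  index is about twice this and must be halved (the CLI's
  `--from-pairwise-fst` flag does this).
* **Isolated pair** (`IsolatedPairModel`): all cases from one isolated
  population, all controls from another, giving the block kinship
  $K_{ii} = 1 + F$, $K_{ik} = 2F$ within a population and $0$ across. An
  optional second $F$ covers unequal drift.
* **Complete admixture** (`CompleteAdmixtureModel`): each arm a homogeneous
  mix of two ancestral sources (fractions $\nu_1$, $\nu_2$), the sources
  having drifted independently from a common ancestor with equal $F$ —
  independence is the natural reading of a shared earlier ancestor, and it
  is the assumption under which the worked admixture example reproduces
  exactly. Kinship entries follow from the mixture:
  $K_{ii} = 1 + F(a_i^2 + (1-a_i)^2)$,
  $K_{ik} = 2F(a_ia_k + (1-a_i)(1-a_k))$ (`kinshipAdmixed()`).
* **Incomplete admixture** (`BetaAdmixtureModel`): individual ancestry
  fractions are Beta-distributed, re-parameterized by mean $\nu$ and
  heterogeneity $h = 1/(a+b+1)$ so the individual-ancestry variance is
  $h\nu(1-\nu)$. $h \to 0$ recovers complete admixture; $h = 1/7$ is the
  value typical of African-American study sites, and $\nu \approx$ 0.20–0.25
  spans the East-coast-to-West-coast range of mean European ancestry in
  multi-site breast-cancer panels.

## Design-stage power

The non-centrality parameter of $W$ under a true difference $\delta$ is
$\lambda = \delta^2 / (2p(1-p)[(C'K^{-1}C)^{-1}]_{22})$
(`ncpFromStructure()`). For the structured models the compound-symmetric
algebra gives closed forms (`ncpIsolated()`, `ncpCompleteAdmixture()`), and
these expose the central design warning: $\lambda$ does **not** grow
linearly in $N$ but saturates at

$$\lambda \le \frac{\delta^2}{8Fp(1-p)} \quad\text{(isolated)},\qquad
\lambda \le \frac{\delta^2}{8Fp(1-p)(\nu_1-\nu_2)^2} \quad\text{(admixed)}.$$

At $F = 5\times10^{-4}$, $p = 0.4$, $\delta = 0.2$ and 5000 cases per arm,
$\lambda$ drops from 208.33 (homogeneous) to 34.73, i.e. from power
$>0.9999$ to about 0.56 at $\alpha = 10^{-8}$. (The genome-wide threshold
behind that 56% figure back-computes to $10^{-8}$; the package takes no
position elsewhere and `powerFromNcp()` accepts any $\alpha$.) Heterogeneous
admixture rescues power: overlapping ancestry distributions let the GLS
separate the phenotype contrast from the ancestry contrast, so $\lambda$
rises with $h$ (`ncpBetaAdmixture()`, a Monte-Carlo mean over ancestry
draws; 50 replicates by default with a standard error, one replicate giving
the fixed-draw mode — both are offered because either convention is
defensible for power curves). Its kinship is rank-2-plus-diagonal, so a
Woodbury inverse keeps large arms cheap; agreement with dense inversion is
asserted at $10^{-8}$.

The 1:m matching identity `effectiveNOneToM()` ($n \cdot 2m/(m+1)$
equivalent 1:1 pairs) quantifies the diminishing returns of piling on free
controls.

## Estimated and smoothed kinship

In practice $K$ is estimated from markers by the method of moments
(`estimateKinshipMom()`): the SNP-average of
$(g_j - 2\hat p_j\mathbf 1)(g_j - 2\hat p_j\mathbf 1)' / (2\hat p_j(1-\hat p_j))$,
with $\hat p_j$ the pooled frequency. Pooling is appropriate under the null
and is documented as a limitation for strongly associated SNPs. Missing
genotypes are handled pairwise-complete with per-pair renormalization
rather than imputation; SNPs above 5% missingness are dropped by default.
Because the centering uses the sample mean, unrelated pairs average
$-1/(N-1)$ rather than 0 — the tests account for this known finite-sample
offset.

The raw estimate is noisy, so the test uses a smoothed version: with
eigenpairs $(\lambda_l, e_l)$ of $\hat K$,

$$\tilde K = \sum_{l \le L}\lambda_l e_le_l' +
\gamma\Big(I - \sum_{l \le L}e_le_l'\Big),\qquad
\gamma = \frac{\mathrm{tr}(\hat K) - \sum_{l\le L}\lambda_l}{N - L},$$

which preserves the top-$L$ eigenpairs and the total trace exactly and is
full-rank whenever $\gamma > 0$ (`smoothKinship()`; requesting an $L$ whose
eigenvalues exhaust the trace is an error). Choosing $L$ is analogous to
choosing the number of principal components to adjust for; the Tracy–Widom
procedure (`eigendecomposeKinship()`) tests leading eigenvalues
sequentially against the residual spectrum at a nominal per-eigenvalue
$\alpha = 0.05$, with no multiplicity correction — deliberately so, since
over-adjusting is cheap (see below). The TW(1) distribution is evaluated
through a three-moment-matched shifted-gamma approximation (mean
$-1.2065$, variance $1.6078$, skewness $0.2935$), accurate to about
$10^{-3}$ in probability — far below what an $\alpha = 0.05$ sequential
test can resolve.

Marker-estimated kinship has a property the theoretical block matrices do
not: SNP-wise centering removes the common-mean direction, so $k$
populations surface as $k-1$ large eigenvalues and the leading eigenvector
*is* the population contrast. This is why adjusting for a single
eigenvector already restores calibration in a two-population sample, and
why `expectedVarianceUnderAdjustment()` accepts a separate `smoothFrom`
matrix: smoothing an eigendecomposition of the *theoretical* two-block
matrix instead would split the structure across a degenerate eigenpair.

## The cost of adjustment

`expectedVarianceUnderAdjustment()` evaluates, by trace identities, the
expectation of the reported variance
$\hat\sigma^2[(C'\tilde K^{-1}C)^{-1}]_{22}$ under a true covariance
$2p(1-p)K$, alongside the actual sampling variance of the adjusted
estimator. On a synthetic two-site admixture panel (635 vs 990 samples,
$\nu$ 0.20/0.25, $h = 1/7$, $F = 0.0765$) the curve rises from $L = 0$ to
$L = 1$ and is then essentially flat through $L = 200$: adjustment beyond
the structured rank costs almost nothing. Two honest caveats, both visible
in the tests: beyond the structured rank the curve is flat only to about
one part in $10^4$ (the smoothing reweights near-equal residual
eigenvalues), so monotonicity is asserted with a 0.1% relative numerical
tolerance; and the effective-sample-size ratio against a homogeneous design
can marginally exceed 1, because shared-drift correlations give the GLS a
little extra information — "adjustment can only cost" is a good rule of
thumb, not an exact inequality, under this covariance model.

## What the simulator does and does not emulate

`simulateNullSnps()` draws, per SNP, an ancestral frequency (default
Uniform(0.1, 0.9)), per-source modern frequencies from the Balding–Nichols
Beta, and genotypes binomial$(2, q_i)$ at the individual's ancestry-weighted
frequency $q_i = a_ip_1 + (1-a_i)p_2$ — Hardy–Weinberg given ancestry,
which is exactly the sampling scheme whose covariance is $2p(1-p)K$ with
the kinship forms above (verified entry-wise against a $10^5$-replicate
Monte-Carlo covariance). SNPs below 1% pooled MAF are regenerated,
mirroring standard QC. Causal SNPs (`addCausalSnp()`) shift individual
frequencies additively by $\pm\delta/4$ — the effect size is a frequency
difference by construction, not an odds-ratio model — with clipping to
$[0.01, 0.99]$ and a warning when clipping touches more than 1% of
individuals.

Not emulated: linkage disequilibrium (all SNPs independent given
structure), genotyping error and platform artifacts, sex chromosomes,
liability-scale ascertainment, and more than two ancestral sources. Passing
tests therefore demonstrate correctness of the statistical machinery under
the stated drift model, not robustness to LD pruning choices or batch
effects in real panels.

## Numerical choices

* One Cholesky of $K$ is shared across all completely-called SNPs in a
  scan; SNPs with missing calls drop those samples and the matching
  rows/columns of $K$ exactly (no imputation). Identity with the per-SNP
  path is asserted at $10^{-10}$.
* Symmetry is enforced defensively (max asymmetry $10^{-10}$) before any
  eigendecomposition; reduction identities are asserted at $10^{-10}$
  absolute.
* Kinship matrices serialize at 10 significant digits; all file formats are
  plain text (VCF v4.2 GT-only dialect, TSV).
* Every stochastic function takes an explicit seed and restores the
  caller's RNG state; equal seeds give byte-identical outputs.
* Monomorphic SNPs are flagged with $W = 0$, $p = 1$ rather than dropped
  silently in single-SNP calls; scans filter at pooled MAF $\ge$ 1% and
  call rate $\ge$ 95% and log the counts.

## Problem sizes used in the checks

The package's own validation uses desk-scale versions of the study
conditions: two-population null calibration at $F = 0.01$ with 500 + 500
samples and $2\times10^4$ SNPs (uncorrected $\lambda_{GC}$ around 11,
corrected within [0.95, 1.05]); power calibration with 2000 causal SNPs at
$F = 5\times10^{-4}$, 500 + 500 samples, against the closed-form NCP; drift
magnitude from $10^5$ simulated SNPs; and closed-form/matrix-form agreement
at $N \le 1000$ to $10^{-6}$ relative. These sizes were chosen to estimate
each quantity with Monte-Carlo error well inside the assertion tolerances.

## Worked example

```{r example}
# Design stage: what does reusing controls from a different isolated
# population cost at 5000 + 5000 samples?
ncpHomogeneous(5000, 0.4, 0.2)
ncpIsolated(5000, 0.4, 0.2, fst = 0.0005)
powerFromNcp(c(208.33, 34.73), alpha = 1e-8)

# Analysis stage on simulated data
model <- IsolatedPairModel(fst = 0.01, nCases = 150, nControls = 150)
sim <- simulateNullSnps(model, nSnps = 3000, seed = 1)
khat <- estimateKinshipMom(sim$panel)
ed <- eigendecomposeKinship(khat$kinship)
ed@nSignificant
scan <- runScan(sim$panel, sim$design, smoothKinship(ed, ed@nSignificant))
inflationDiagnostics(scan$p_value)$lambdaGC
```

## Known limitations

Only the intercept-plus-status design is supported (no covariates); the
theory is for autosomal additive coding; closed forms assume equal arms
(the matrix path handles any design); and the pooled-frequency kinship
estimator is slightly anticonservative at truly associated SNPs. The
Tracy–Widom count is a guide, not an oracle: with many nominally
significant eigenvalues the sensible analysis adjusts for a handful and
checks the QQ plot, which is exactly the workflow the CLI exposes
(`strucpower smooth`, `strucpower test`, `strucpower inflation`).
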