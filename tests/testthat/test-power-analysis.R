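test_that("closed-form NCPs have the right limits and bounds", {
  expect_equal(ncpHomogeneous(5000, 0.4, 0), 0)
  expect_equal(ncpHomogeneous(2000, 0.3, 0.2),
               2 * ncpHomogeneous(1000, 0.3, 0.2))
  # no-structure limit
  expect_equal(ncpIsolated(500, 0.4, 0.2, 0)$ncp,
               ncpHomogeneous(500, 0.4, 0.2))
  expect_identical(ncpIsolated(500, 0.4, 0.2, 0)$bound, Inf)
  # degenerate admixture = isolated pair
  expect_equal(ncpCompleteAdmixture(500, 0.4, 0.2, 0.01, 1, 0)$ncp,
               ncpIsolated(500, 0.4, 0.2, 0.01)$ncp, tolerance = 1e-12)
  # identical arms: no confounding, bound infinite
  expect_identical(ncpCompleteAdmixture(500, 0.4, 0.2, 0.01, 0.3, 0.3)$bound,
                   Inf)
  # NCP grows in n and approaches its bound within 1% at astronomical n
  ns <- c(1e2, 1e4, 1e6, 1e9)
  iso <- sapply(ns, function(n) ncpIsolated(n, 0.4, 0.2, 0.0005)$ncp)
  expect_false(is.unsorted(iso))
  bound <- ncpIsolated(1e9, 0.4, 0.2, 0.0005)$bound
  expect_equal(bound, 0.04 / (8 * 0.0005 * 0.24))   # 41.67
  expect_lt((bound - iso[4]) / bound, 0.01)
  adm <- sapply(ns, function(n)
    ncpCompleteAdmixture(n, 0.4, 0.2, 0.0765, 0.25, 0.20)$ncp)
  expect_false(is.unsorted(adm))
  admBound <- ncpCompleteAdmixture(1e9, 0.4, 0.2, 0.0765, 0.25, 0.20)$bound
  expect_equal(admBound, 0.04 / (8 * 0.0765 * 0.24 * 0.0025))   # 108.93
  expect_lt((admBound - adm[4]) / admBound, 0.01)
  expect_true(all(iso <= 0.04 / (8 * 0.0005 * 0.24) + 1e-6))
})

test_that("matrix-form NCP agrees with the closed forms on dense instances", {
  for (n in c(100, 250, 500)) {
    d <- StudyDesign(status = rep(c(1, 0), each = n))
    expect_equal(ncpFromStructure(diag(2 * n), d, 0.4, 0.2),
                 ncpHomogeneous(n, 0.4, 0.2), tolerance = 1e-6)
    Kiso <- theoreticalKinship(IsolatedPairModel(0.0005, n, n))
    expect_equal(ncpFromStructure(Kiso, d, 0.4, 0.2),
                 ncpIsolated(n, 0.4, 0.2, 0.0005)$ncp, tolerance = 1e-6)
    Kadm <- theoreticalKinship(CompleteAdmixtureModel(0.0765, 0.25, 0.20,
                                                      n, n))
    expect_equal(ncpFromStructure(Kadm, d, 0.4, 0.2),
                 ncpCompleteAdmixture(n, 0.4, 0.2, 0.0765, 0.25, 0.20)$ncp,
                 tolerance = 1e-6)
  }
})

test_that("beta-admixture NCP: Woodbury inverse equals dense inversion", {
  withr::with_seed(201, {
    n <- 150
    a <- c(rbeta(n, 1.2, 4.8), rbeta(n, 1.5, 4.5))
    status <- rep(c(1, 0), each = n)
    v22 <- strucpower:::.glsVar22Admixed(a, status, 0.0765)
    d <- StudyDesign(status = status)
    K <- kinshipAdmixed(a, 0.0765)
    dense <- 0.2^2 / (2 * 0.4 * 0.6 *
                        ncpFromStructure(K, d, 0.4, 0.2))
    expect_equal(v22, dense, tolerance = 1e-8)
  })
})

test_that("beta-admixture NCP recovers the zero-heterogeneity limit", {
  r <- ncpBetaAdmixture(200, 0.4, 0.2, 0.0765, 0.25, 0.20, h = 1e-8,
                        nReplicates = 3, seed = 5)
  expect_equal(r$ncp, ncpCompleteAdmixture(200, 0.4, 0.2, 0.0765,
                                           0.25, 0.20)$ncp,
               tolerance = 1e-3)
})

test_that("heterogeneity in ancestry restores power", {
  # at the two-site admixture parameters, NCP rises with h beyond MC error
  rs <- lapply(c(0.01, 0.05, 1 / 7, 0.3), function(h)
    ncpBetaAdmixture(150, 0.4, 0.2, 0.0765, 0.20, 0.25, h,
                     nReplicates = 30, seed = 42))
  ncp <- sapply(rs, `[[`, "ncp")
  se <- sapply(rs, `[[`, "se")
  expect_true(all(diff(ncp) > -3 * sqrt(se[-1]^2 + se[-4]^2)))
  expect_gt(ncp[4], ncp[1])
  # equal mean ancestry: at least the complete-admixture NCP
  same <- ncpBetaAdmixture(150, 0.4, 0.2, 0.0765, 0.25, 0.25, 1 / 7,
                           nReplicates = 20, seed = 43)
  expect_gt(same$ncp,
            ncpCompleteAdmixture(150, 0.4, 0.2, 0.0765, 0.25, 0.25)$ncp -
              3 * same$se)
})

test_that("power calculation has the chi-square null and monotonicity", {
  expect_equal(powerFromNcp(0, 0.05), 0.05, tolerance = 1e-12)
  lam <- c(0, 1, 5, 20, 100)
  expect_false(is.unsorted(powerFromNcp(lam, 1e-4)))
  expect_false(is.unsorted(sapply(c(1e-8, 1e-4, 0.05),
                                  function(a) powerFromNcp(10, a))))
})

test_that("identity kinship needs no adjustment at any L", {
  d <- StudyDesign(status = rep(c(1, 0), each = 30))
  ev <- expectedVarianceUnderAdjustment(diag(60), d, L = c(0, 1, 10, 60),
                                        p = 0.4)
  expect_equal(ev$effectiveNRatio, rep(1, 4), tolerance = 1e-10)
  expect_equal(ev$varBeta1, ev$trueVarBeta1, tolerance = 1e-10)
})

test_that("one eigenvector absorbs two-population stratification", {
  model <- IsolatedPairModel(0.01, 100, 100)
  sim <- simulateNullSnps(model, 5000, seed = 3)
  Khat <- quietKinship(sim$panel)$kinship
  Ktrue <- theoreticalKinship(model)
  ev <- expectedVarianceUnderAdjustment(Ktrue, sim$design, L = c(0, 1),
                                        p = 0.4, smoothFrom = Khat)
  # the OLS (L = 0) contrast has the closed-form isolated-pair variance
  expect_equal(ev$trueVarBeta1[1],
               0.2^2 / ncpIsolated(100, 0.4, 0.2, 0.01)$ncp,
               tolerance = 1e-6)
  # unadjusted analysis badly underestimates the true sampling variance
  expect_lt(ev$varBeta1[1], 0.5 * ev$trueVarBeta1[1])
  # one eigenvector recovers nearly all of it
  expect_gt(ev$varBeta1[2], 0.9 * ev$trueVarBeta1[2])
})

test_that("1:m matching effective sample size follows m/(m+1)", {
  expect_equal(effectiveNOneToM(1000, 1), 1000)
  expect_equal(effectiveNOneToM(1000, 3), 1500)
  expect_equal(effectiveNOneToM(1000, 1e9), 2000, tolerance = 1e-6)
})
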