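test_that("identity-kinship test reproduces the hand-computed OLS example", {
  d <- StudyDesign(status = c(1, 1, 1, 1, 0, 0, 0, 0))
  res <- bourgainWaldTest(c(2, 2, 1, 1, 0, 0, 1, 1), d, diag(8))
  expect_equal(res$beta1, 1)
  expect_equal(res$sigma2_hat, 2 / 6)
  expect_equal(res$var_beta1, 1 / 6)
  expect_equal(res$wald, 6)
  expect_equal(res$p_value, pchisq(6, 1, lower.tail = FALSE))
})

test_that("identical case and control genotypes give a null result", {
  d <- StudyDesign(status = c(1, 1, 1, 0, 0, 0))
  res <- bourgainWaldTest(c(0, 1, 2, 0, 1, 2), d, diag(6))
  expect_equal(res$beta1, 0)
  expect_equal(res$wald, 0)
})

test_that("with K = I the Wald statistic equals the squared OLS t-statistic", {
  withr::with_seed(101, {
    for (rep in 1:20) {
      n <- sample(10:40, 1)
      status <- rbinom(n, 1, 0.5)
      if (sum(status) < 1 || sum(1 - status) < 1) next
      g <- rbinom(n, 2, 0.4)
      if (var(g) == 0) next
      d <- StudyDesign(status = status)
      res <- bourgainWaldTest(g, d, diag(n))
      expect_equal(res$wald, olsWaldOracle(g, status), tolerance = 1e-10)
    }
  })
})

test_that("compound-symmetric kinship leaves the group-mean difference", {
  model <- IsolatedPairModel(0.01, 25, 25)
  K <- theoreticalKinship(model)
  d <- modelDesign(model)
  withr::with_seed(7, g <- rbinom(50, 2, 0.4))
  res <- bourgainWaldTest(g, d, K)
  st <- caseStatus(d)
  expect_equal(res$beta1, mean(g[st == 1]) - mean(g[st == 0]),
               tolerance = 1e-10)
})

test_that("the statistic is invariant to rescaling the kinship matrix", {
  model <- CompleteAdmixtureModel(0.05, 0.3, 0.2, 20, 20)
  K <- kinshipValues(theoreticalKinship(model))
  d <- modelDesign(model)
  withr::with_seed(11, g <- rbinom(40, 2, 0.5))
  r1 <- bourgainWaldTest(g, d, K)
  r5 <- bourgainWaldTest(g, d, 5 * K)
  expect_equal(r1$wald, r5$wald, tolerance = 1e-12)
  expect_equal(r1$p_value, r5$p_value, tolerance = 1e-12)
  expect_equal(r5$sigma2_hat, r1$sigma2_hat / 5, tolerance = 1e-12)
})

test_that("singular kinship suggests smoothing; monomorphic SNPs are flagged", {
  d <- StudyDesign(status = c(1, 1, 0, 0))
  expect_error(bourgainWaldTest(c(0, 1, 2, 1), d, matrix(1, 4, 4)),
               "smoothKinship")
  res <- bourgainWaldTest(c(2, 2, 2, 2), d, diag(4))
  expect_true(res$monomorphic)
  expect_equal(res$p_value, 1)
  expect_equal(res$wald, 0)
})

test_that("missing genotypes drop samples exactly", {
  model <- IsolatedPairModel(0.02, 15, 15)
  K <- kinshipValues(theoreticalKinship(model))
  d <- modelDesign(model)
  withr::with_seed(13, g <- rbinom(30, 2, 0.4))
  g[c(3, 28)] <- NA
  res <- bourgainWaldTest(g, d, K)
  # oracle: explicit subset of samples and kinship
  keep <- !is.na(g)
  dSub <- StudyDesign(status = caseStatus(d)[keep],
                      sampleIds = sampleIds(d)[keep])
  resSub <- bourgainWaldTest(g[keep], dSub, K[keep, keep])
  expect_equal(res$wald, resSub$wald, tolerance = 1e-12)
  expect_equal(res$n_used, 28L)
})

test_that("scan filters follow the MAF and call-rate rules", {
  cts <- rbind(
    common = c(0, 1, 2, 1, 0, 1),
    rare   = c(0, 0, 0, 0, 0, 1),        # MAF 1/12, below the 10% floor used
    holey  = c(NA, NA, 2, 1, 0, 1))      # call rate 4/6
  panel <- GenotypeMatrix(cts)
  d <- StudyDesign(status = c(1, 1, 1, 0, 0, 0),
                   sampleIds = sampleIds(panel))
  res <- quietScan(panel, d, diag(6), mafMin = 0.10, callRateMin = 0.95)
  expect_identical(res$snp_id, "common")
  f <- attr(res, "filters")
  expect_equal(unname(f["low_call_rate"] + f["low_maf"]), 2)

  # with relaxed thresholds the missing-genotype path is exercised
  res2 <- quietScan(panel, d, diag(6), mafMin = 0.01, callRateMin = 0.5)
  expect_true("holey" %in% res2$snp_id)
  expect_equal(res2$n_used[res2$snp_id == "holey"], 4L)
})

test_that("scans are deterministic and validate their inputs", {
  sim <- simulateNullSnps(HomogeneousModel(20, 20), 50, seed = 61)
  K <- diag(40)
  r1 <- quietScan(sim$panel, sim$design, K)
  r2 <- quietScan(sim$panel, sim$design, K)
  expect_identical(r1, r2)
  badDesign <- StudyDesign(status = caseStatus(sim$design),
                           sampleIds = paste0("x_", sampleIds(sim$design)))
  expect_error(quietScan(sim$panel, badDesign, K), "case_0001")
})

test_that("null scans are calibrated and match single-SNP results", {
  model <- IsolatedPairModel(0.01, 50, 50)
  sim <- simulateNullSnps(model, 400, seed = 67)
  K <- theoreticalKinship(model)
  res <- quietScan(sim$panel, sim$design, K)
  expect_equal(nrow(res), 400)
  # rejection rate near alpha under the true kinship
  expect_lt(abs(mean(res$p_value < 0.05) - 0.05),
            4 * sqrt(0.05 * 0.95 / 400))
  # vectorized scan equals the per-SNP path
  i <- 17
  single <- bourgainWaldTest(genotypeCounts(sim$panel)[i, ], sim$design, K,
                             snpId = res$snp_id[i])
  expect_equal(res$wald[i], single$wald, tolerance = 1e-10)
  # wald = beta1^2 / var_beta1 identically
  expect_equal(res$wald, res$beta1^2 / res$var_beta1, tolerance = 1e-10)
})

test_that("inflation diagnostics recover lambda for uniform p-values", {
  p <- (1:10000) / 10001
  d <- inflationDiagnostics(p)
  expect_equal(d$lambdaGC, 1, tolerance = 0.01)
  expect_false(is.unsorted(d$qq$expected))
  expect_false(is.unsorted(d$qq$observed))
  expect_equal(nrow(d$qq), length(p))
  expect_error(inflationDiagnostics(numeric(0)), "no p-values")
})
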