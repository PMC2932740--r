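test_that("method-of-moments entries follow the outer-product formula", {
  # one SNP, genotypes (0, 2), pooled p-hat = 0.5:
  # off-diagonal (0-1)(2-1)/(2*0.25) = -2
  panel <- GenotypeMatrix(matrix(c(0, 2), 1), snpIds = "s",
                          sampleIds = c("a", "b"))
  K <- kinshipValues(quietKinship(panel)$kinship)
  expect_equal(K[1, 2], -2)
  expect_equal(K[1, 1], 2)
})

test_that("unrelated homogeneous samples give near-identity kinship", {
  sim <- simulateNullSnps(HomogeneousModel(50, 50), nSnps = 2e4, seed = 17)
  est <- quietKinship(sim$panel)
  K <- kinshipValues(est$kinship)
  off <- K[upper.tri(K)]
  # centering on the pooled p-hat forces row sums near zero, so unrelated
  # pairs average -1/(N-1) rather than exactly zero
  expect_lt(abs(mean(off) + 1 / (ncol(K) - 1)),
            3 * sd(off) / sqrt(length(off)))
  expect_lt(abs(mean(diag(K)) - 1), 0.02)
  expect_equal(est$freq, rowMeans(genotypeCounts(sim$panel)) / 2,
               tolerance = 1e-12)
})

test_that("the leading eigenvector separates two isolated populations", {
  sim <- simulateNullSnps(IsolatedPairModel(0.01, 100, 100), nSnps = 1e4,
                          seed = 19)
  ed <- eigendecomposeKinship(quietKinship(sim$panel)$kinship)
  lab <- as.numeric(caseStatus(sim$design))
  expect_gt(abs(cor(ed@vectors[, 1], lab)), 0.99)
  expect_gte(ed@nSignificant, 1L)
})

test_that("monomorphic and high-missingness SNPs are skipped with a count", {
  cts <- rbind(c(0, 1, 2, 1), c(0, 0, 0, 0), c(NA, NA, NA, 1), c(2, 1, 0, 1))
  panel <- GenotypeMatrix(cts)
  expect_message(est <- estimateKinshipMom(panel), "skipped 1 monomorphic")
  expect_identical(unname(est$nSkipped), c(1L, 1L))
  expect_equal(length(est$freq), 2L)

  mono <- GenotypeMatrix(matrix(c(2, 2, 2, 2), 1))
  expect_error(suppressMessages(estimateKinshipMom(mono)), "no usable SNPs")
})

test_that("pairwise-complete missing handling stays close to complete data", {
  sim <- simulateNullSnps(HomogeneousModel(30, 30), nSnps = 5000, seed = 23)
  Kfull <- kinshipValues(quietKinship(sim$panel)$kinship)
  G <- genotypeCounts(sim$panel)
  set.seed(24)
  G[sample(length(G), length(G) * 0.02)] <- NA
  holey <- GenotypeMatrix(G)
  Kmiss <- kinshipValues(quietKinship(holey, maxMissing = 0.2)$kinship)
  expect_lt(max(abs(Kmiss - Kfull)), 0.15)
  expect_lt(mean(abs(Kmiss - Kfull)), 0.01)
})

test_that("eigendecomposition satisfies the spectral identities", {
  sim <- simulateNullSnps(IsolatedPairModel(0.02, 30, 30), nSnps = 2000,
                          seed = 29)
  K <- quietKinship(sim$panel)$kinship
  ed <- eigendecomposeKinship(K)
  expect_equal(sum(ed@values), sum(diag(kinshipValues(K))),
               tolerance = 1e-8)
  expect_false(is.unsorted(rev(ed@values)))
  orth <- crossprod(ed@vectors)
  expect_lt(max(abs(orth - diag(nrow(orth)))), 1e-8)
})

test_that("an exact identity matrix has no significant eigenvalues", {
  K <- KinshipMatrix(diag(100))
  ed <- eigendecomposeKinship(K)
  expect_identical(ed@nSignificant, 0L)
})

test_that("Tracy-Widom distribution matches the published critical points", {
  expect_equal(qtw1(0.95), 0.9793, tolerance = 0.02)
  expect_equal(qtw1(0.99), 2.0234, tolerance = 0.02)
  expect_equal(ptw1(qtw1(0.5)), 0.5, tolerance = 1e-10)
})

test_that("smoothing preserves trace and top-L eigenpairs", {
  sim <- simulateNullSnps(IsolatedPairModel(0.01, 40, 40), nSnps = 4000,
                          seed = 37)
  Khat <- quietKinship(sim$panel)$kinship
  tr <- sum(diag(kinshipValues(Khat)))
  N <- nSamples(Khat)
  ed <- eigendecomposeKinship(Khat)
  for (L in c(0L, 1L, 10L, N)) {
    sm <- smoothKinship(ed, L)
    expect_equal(sum(diag(kinshipValues(sm))), tr, tolerance = 1e-8)
    if (L > 0) {
      ed2 <- eigen(kinshipValues(sm), symmetric = TRUE)
      expect_equal(ed2$values[seq_len(L)], ed@values[seq_len(L)],
                   tolerance = 1e-6)
      # eigenvector agreement up to sign
      for (l in seq_len(min(L, 3)))
        expect_equal(abs(sum(ed2$vectors[, l] * ed@vectors[, l])), 1,
                     tolerance = 1e-6)
    }
  }
  expect_equal(kinshipValues(smoothKinship(ed, 0L)),
               diag(N) * tr / N, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(kinshipValues(smoothKinship(ed, N)),
               kinshipValues(Khat), tolerance = 1e-8)
})

test_that("smoothing an already-smoothed matrix is idempotent", {
  sim <- simulateNullSnps(IsolatedPairModel(0.01, 25, 25), nSnps = 2000,
                          seed = 41)
  Khat <- quietKinship(sim$panel)$kinship
  sm1 <- smoothKinship(Khat, 3L)
  sm2 <- smoothKinship(sm1, 3L)
  expect_equal(kinshipValues(sm2), kinshipValues(sm1), tolerance = 1e-8)
})

test_that("smoothing refuses an L that exhausts the trace", {
  K <- KinshipMatrix(matrix(1, 10, 10))   # rank one, eigenvalue 10 = trace
  expect_error(smoothKinship(K, 1L), "smaller L")
})

test_that("kinship estimates concentrate as the SNP count grows", {
  model <- IsolatedPairModel(0.02, 25, 25)
  limit <- kinshipValues(quietKinship(
    simulateNullSnps(model, 4e4, seed = 1000)$panel)$kinship)
  dist <- sapply(c(500, 2000, 8000), function(m) {
    mean(sapply(1:5, function(s) {
      K <- kinshipValues(quietKinship(
        simulateNullSnps(model, m, seed = 1000 + s)$panel)$kinship)
      sqrt(sum((K - limit)^2))
    }))
  })
  expect_false(is.unsorted(rev(dist)))   # strictly improving on average
})
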