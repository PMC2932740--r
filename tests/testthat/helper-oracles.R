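# Shared fixtures and independent oracles, built in code.

# Ordinary-least-squares Wald oracle: with K = I the Bourgain GLS test must
# reduce to the squared t-statistic of lm(genotype ~ status).
olsWaldOracle <- function(g, status) {
  fit <- stats::lm(g ~ status)
  unname(stats::coef(summary(fit))["status", "t value"]^2)
}

# Small deterministic panel used by the I/O round-trip tests.
tinyPanel <- function() {
  cts <- matrix(c(0, 1, 2,
                  2, NA, 0), nrow = 2, byrow = TRUE)
  GenotypeMatrix(cts, snpIds = c("rs1", "rs2"),
                 sampleIds = c("case_0001", "case_0002", "ctrl_0001"),
                 ref = c("A", "C"), alt = c("G", "T"))
}

tinyDesign <- function() {
  StudyDesign(status = c(1L, 1L, 0L),
              sampleIds = c("case_0001", "case_0002", "ctrl_0001"))
}

quietScan <- function(...) suppressMessages(runScan(...))
quietKinship <- function(...) suppressMessages(estimateKinshipMom(...))
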