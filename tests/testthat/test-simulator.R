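test_that("library construction is deterministic and structurally sound", {
  l1 <- buildParameterLibrary(nNull = 100, nCandidates = 200, seed = 5)
  l2 <- buildParameterLibrary(nNull = 100, nCandidates = 200, seed = 5)
  expect_identical(l1@nulls, l2@nulls)
  expect_identical(l1@informative, l2@informative)
  # group 1 (CIMP-like) has higher means and no more precision than group 2
  expect_gt(mean(l1@informative$mu1), mean(l1@informative$mu2))
  expect_true(all(l1@informative$phi1 <= l1@informative$phi2))
  # theta is the log odds ratio of group-2 over group-1 means; hypermethylation
  # of the CIMP-like group makes it negative, with magnitude equal to the shift
  expect_true(all(l1@informative$theta < 0))
  expect_equal(l1@informative$theta,
               effectSize(l1@informative$mu1, l1@informative$mu2), tolerance = 1e-12)
})

test_that("effect-size capping removes exactly the out-of-range pairs", {
  lib <- buildParameterLibrary(nNull = 50, nCandidates = 400, seed = 2)
  capped <- filterByEffectSize(lib, 1)
  expect_true(all(abs(capped@informative$theta) <= 1))
  expect_identical(capped@nulls, lib@nulls)
  expect_equal(nrow(capped@informative), sum(abs(lib@informative$theta) <= 1))
  expect_identical(filterByEffectSize(lib, Inf)@informative, lib@informative)
  expect_error(filterByEffectSize(lib, 0), "removes every")
  # direct count: pairs at 0.4 / 0.8 / 1.3, cap 1 -> 2 survive
  toy <- new("ParameterLibrary",
             informative = data.frame(mu1 = plogis(qlogis(0.1) + c(0.4, 0.8, 1.3)),
                                      phi1 = 50, mu2 = 0.1, phi2 = 100,
                                      theta = c(0.4, 0.8, 1.3)),
             nulls = data.frame(mu = 0.5, phi = 10))
  expect_equal(nrow(filterByEffectSize(toy, 1)@informative), 2L)
})

test_that("simulated data sets have the designed shape and truth structure", {
  design <- SimulationDesign(nFeatures = 400, nSamples = 60, groupRatio = c(1, 9),
                             seed = 7)
  lib <- small_library(360, seed = 7)
  sim <- simulateDataset(design, lib)
  expect_s4_class(sim, "MethylSimulation")
  expect_identical(dim(sim), c(400L, 60L))
  expect_identical(sum(informativeFeatures(sim)), 40L)
  expect_identical(as.integer(table(groupLabels(sim))), c(6L, 54L))
  b <- betaValues(sim)
  expect_true(all(b > 0 & b < 1))
  # determinism under the same seed and replicate
  sim2 <- simulateDataset(design, lib)
  expect_identical(betaValues(sim2), b)
  # default design at scale: 2000 x 200 with 200 informative
  d0 <- SimulationDesign(seed = 1)
  expect_identical(methylGOF:::.nInformative(d0), 200L)
  expect_identical(methylGOF:::.groupSizes(SimulationDesign(groupRatio = c(1, 9))),
                   c(20L, 180L))
})

test_that("replicates share null parameters and re-draw informative positions", {
  design <- SimulationDesign(nFeatures = 300, nSamples = 40, seed = 3)
  lib <- small_library(270, seed = 3)
  s1 <- simulateDataset(design, lib, replicate = 1)
  s2 <- simulateDataset(design, lib, replicate = 2)
  expect_false(identical(informativeFeatures(s1), informativeFeatures(s2)))
  rd1 <- SummarizedExperiment::rowData(s1); rd2 <- SummarizedExperiment::rowData(s2)
  # both replicates use exactly the library's null distribution set
  nullPairs <- function(rd) {
    o <- order(rd$mu2[!rd$informative])
    cbind(rd$mu2[!rd$informative][o], rd$phi2[!rd$informative][o])
  }
  libPairs <- as.matrix(lib@nulls[order(lib@nulls$mu), c("mu", "phi")])
  dimnames(libPairs) <- NULL
  expect_equal(nullPairs(rd1), libPairs, tolerance = 1e-12)
  expect_equal(nullPairs(rd2), libPairs, tolerance = 1e-12)
  # null features use identical parameters for both groups
  expect_identical(rd1$mu1[!rd1$informative], rd1$mu2[!rd1$informative])
})

test_that("per-feature sample moments converge to the design parameters", {
  design <- SimulationDesign(nFeatures = 20, fracInformative = 0.1,
                             nSamples = 10000, groupRatio = c(1, 1), seed = 9)
  lib <- small_library(18, seed = 9)
  sim <- simulateDataset(design, lib)
  b <- betaValues(sim)
  rd <- SummarizedExperiment::rowData(sim)
  g <- groupLabels(sim)
  okCount <- 0L
  for (i in seq_len(nrow(b))) for (grp in 1:2) {
    mu <- if (grp == 1) rd$mu1[i] else rd$mu2[i]
    phi <- if (grp == 1) rd$phi1[i] else rd$phi2[i]
    n <- sum(g == grp)
    bound <- 3 * sqrt(mu * (1 - mu) / ((phi + 1) * n))
    okCount <- okCount + (abs(mean(b[i, g == grp]) - mu) < bound + 2e-6)
  }
  expect_gte(okCount / 40, 0.95)
})

test_that("filter statistics are blind to sample order (null exchangeability)", {
  x <- make_beta_matrix(40, 24, 1.5, 6, seed = 13)
  perm <- sample(ncol(x))
  xp <- x[, perm]
  for (f in c("SD-b", "SD-m", "MAD", "DIP", "Precision", "BQ-GOF", "TM-GOF", "TQ-GOF"))
    expect_identical(statistic(computeFilter(x, f)), statistic(computeFilter(xp, f)))
})

test_that("library / design mismatches are rejected", {
  design <- SimulationDesign(nFeatures = 300, nSamples = 40, seed = 1)
  expect_error(simulateDataset(design, small_library(100, seed = 1)), "null parameter sets")
  tiny <- new("ParameterLibrary",
              informative = data.frame(mu1 = 0.3, phi1 = 10, mu2 = 0.1,
                                       phi2 = 20, theta = effectSize(0.1, 0.3)),
              nulls = buildParameterLibrary(nNull = 270, nCandidates = 10, seed = 1)@nulls)
  expect_error(simulateDataset(design, tiny), "candidate pairs")
})
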