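test_that("ROC points and AUC match a brute-force threshold count", {
  for (s in 1:20) {
    set.seed(s)
    p <- 30
    stat <- setNames(runif(p), sprintf("f%02d", 1:p))
    truth <- setNames(seq_len(p) %in% sample.int(p, 8), names(stat))
    rc <- rocPoints(rankFeatures(stat), truth)
    expect_equal(aucValue(rc), oracle_roc_auc(stat, truth), tolerance = 1e-10)
    pts <- curvePoints(rc)
    expect_equal(nrow(pts), p + 1)
    expect_equal(pts$fpf[1], 0); expect_equal(pts$tpf[p + 1], 1)
    expect_true(!is.unsorted(pts$fpf) && !is.unsorted(pts$tpf))
  }
})

test_that("oracle and anti-oracle rankings bound the AUC", {
  p <- 100
  truth <- setNames(seq_len(p) <= 20, sprintf("f%03d", 1:p))
  oracle <- rankFeatures(setNames(as.numeric(truth), names(truth)))
  expect_equal(aucValue(rocPoints(oracle, truth)), 1)
  anti <- rankFeatures(setNames(-as.numeric(truth), names(truth)))
  expect_equal(aucValue(rocPoints(anti, truth)), 0)
  # label-independent scores average to 1/2 over random permutations
  set.seed(2)
  aucs <- replicate(100, {
    sc <- rankFeatures(setNames(sample(p), names(truth)))
    aucValue(rocPoints(sc, truth))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("AUC antisymmetry under score reversal", {
  set.seed(3)
  p <- 50
  stat <- setNames(rnorm(p), sprintf("f%02d", 1:p))
  truth <- setNames(seq_len(p) %in% sample.int(p, 10), names(stat))
  a1 <- aucValue(rocPoints(rankFeatures(stat), truth))
  a2 <- aucValue(rocPoints(rankFeatures(-stat), truth))
  expect_equal(a1 + a2, 1, tolerance = 1e-10)
})

test_that("ROC curve averaging is pointwise and preserves constants", {
  p <- 20
  truth <- setNames(seq_len(p) <= 5, sprintf("f%02d", 1:p))
  rc <- rocPoints(rankFeatures(setNames(as.numeric(truth), names(truth))), truth)
  avg <- averageRoc(replicate(100, rc, simplify = FALSE))
  expect_equal(aucValue(avg), 1)
  set.seed(9)
  rc2 <- rocPoints(rankFeatures(setNames(runif(p), names(truth))), truth)
  mid <- averageRoc(list(rc, rc2))
  expect_equal(curvePoints(mid)$tpf, (curvePoints(rc)$tpf + curvePoints(rc2)$tpf) / 2)
  expect_error(averageRoc(list(rc, rocPoints(rankFeatures(
    setNames(1:3, c("a", "b", "c"))), setNames(c(TRUE, FALSE, FALSE), c("a", "b", "c"))))),
    "mismatched")
})

test_that("replicate AUC confidence intervals behave", {
  expect_equal(unname(aucCI(rep(0.7, 10))), c(0.7, 0.7, 0.7))
  set.seed(4)
  p <- 60
  truth <- setNames(seq_len(p) <= 10, sprintf("f%02d", 1:p))
  aucs <- replicate(50, aucValue(rocPoints(rankFeatures(
    setNames(sample(p), names(truth))), truth)))
  ci <- aucCI(aucs)
  expect_true(ci[["low"]] <= 0.5 && 0.5 <= ci[["high"]])
  expect_error(aucCI(0.5), "at least 2")
  expect_gte(aucCI(c(0.001, 0.002))[["low"]], 0)
})

test_that("fixed-list sensitivity and specificity follow the list-length arithmetic", {
  p <- 2000
  truth <- setNames(seq_len(p) <= 200, sprintf("f%04d", 1:p))
  oracle <- rankFeatures(setNames(as.numeric(truth) * 2 + runif(p), names(truth)))
  ss <- sensSpecAtK(oracle, truth, 100)
  expect_equal(unname(ss), c(0.5, 1.0))
  anti <- rankFeatures(setNames(-(as.numeric(truth) * 2 + runif(p)), names(truth)))
  ssa <- sensSpecAtK(anti, truth, 100)
  expect_equal(unname(ssa), c(0, 1 - 100 / 1800))
  sc <- rankFeatures(setNames(runif(p), names(truth)))
  expect_equal(unname(sensSpecAtK(sc, truth, p)), c(1, 0))
})

test_that("misclassification uses the best cluster-to-group assignment", {
  truth19 <- rep(c(1, 2), c(20, 180))
  expect_equal(misclassificationRate(rep(1, 200), truth19), 0.10)
  truth11 <- rep(c(1, 2), c(100, 100))
  expect_equal(misclassificationRate(rep(1, 200), truth11), 0.50)
  expect_equal(misclassificationRate(rep(c(5, 9), c(100, 100)), truth11), 0)
  expect_equal(misclassificationRate(rep(c(9, 5), c(100, 100)), truth11), 0)
  expect_error(misclassificationRate(c(1, 2, 3, 1), c(1, 1, 2, 2)), "at most 2")
  expect_error(misclassificationRate(c(1, 2, 1, 2), c(1, 1, 1, 1)), "exactly 2")
  # never exceeds 1/2
  set.seed(11)
  for (i in 1:25) {
    lab <- sample(1:2, 30, TRUE); tr <- sample(1:2, 30, TRUE)
    if (length(unique(tr)) < 2) next
    expect_lte(misclassificationRate(lab, tr), 0.5)
  }
})

test_that("adjusted Rand index matches its identities and an independent oracle", {
  expect_equal(adjustedRand(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjustedRand(1:4, rep(1, 4)), 0)
  set.seed(21)
  for (i in 1:20) {
    a <- sample(1:3, 40, TRUE); b <- sample(1:4, 40, TRUE)
    expect_equal(adjustedRand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
    relab <- c(7, 5, 9)[a]
    expect_equal(adjustedRand(relab, b), adjustedRand(a, b), tolerance = 1e-12)
  }
  expect_error(adjustedRand(1:3, 1:4), "length")
})
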