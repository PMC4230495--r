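test_that("worked single-filter examples", {
  x <- rbind(f1 = c(0.2, 0.4), f2 = c(0.3, 0.3), f3 = c(0.5, 0.5))
  colnames(x) <- c("s1", "s2")
  sdb <- sdStatistic(x, "beta")
  expect_equal(unname(statistic(sdb)["f1"]), 0.1, tolerance = 1e-12)
  expect_equal(unname(statistic(sdb)["f2"]), 0, tolerance = 1e-12)
  sdm <- sdStatistic(x, "mvalue")
  expect_equal(unname(statistic(sdm)["f3"]), 0, tolerance = 1e-12)
  expect_error(sdStatistic(x[, 1, drop = FALSE]), "2 samples")

  m <- rbind(f1 = c(0.1, 0.2, 0.4), f2 = c(0.3, 0.3, 0.3))
  colnames(m) <- paste0("s", 1:3)
  expect_equal(unname(statistic(madStatistic(m))["f1"]), 0.1, tolerance = 1e-12)
  expect_equal(unname(statistic(madStatistic(m))["f2"]), 0, tolerance = 1e-12)
  m2 <- rbind(f1 = c(0, 1)); colnames(m2) <- c("s1", "s2")
  expect_equal(unname(statistic(madStatistic(m2))["f1"]), 0.5, tolerance = 1e-3)

  # precision: uniform feature has phi = 2, so 1/phi = 0.5
  n <- 6
  xu <- rbind(u = qunif((1:n) / (n + 1)))  # mean .5, 1/N var exactly that of its values
  colnames(xu) <- paste0("s", 1:n)
  v <- mean((xu - mean(xu))^2)
  expect_equal(unname(statistic(inversePrecision(xu))["u"]),
               1 / (0.25 / v - 1), tolerance = 1e-10)
})

test_that("every filter reproduces its brute-force oracle on random matrices", {
  for (s in 1:20) {
    x <- make_beta_matrix(50, 30, 2, 5, seed = s)
    expect_equal(unname(statistic(sdStatistic(x, "beta"))),
                 unname(apply(x, 1, oracle_sd)), tolerance = 1e-10)
    expect_equal(unname(statistic(sdStatistic(x, "mvalue"))),
                 unname(apply(log2(x / (1 - x)), 1, oracle_sd)), tolerance = 1e-10)
    expect_equal(unname(statistic(madStatistic(x))),
                 unname(apply(x, 1, oracle_mad)), tolerance = 1e-10)
    expect_equal(unname(statistic(inversePrecision(x))),
                 unname(apply(x, 1, oracle_invprec)), tolerance = 1e-10)
    expect_equal(unname(statistic(bqGof(x))),
                 unname(apply(x, 1, oracle_bq)), tolerance = 1e-10)
    expect_equal(unname(statistic(tqGof(x))),
                 unname(apply(x, 1, oracle_tq)), tolerance = 1e-10)
    expect_equal(unname(statistic(tmGof(x))),
                 unname(oracle_tm(x)), tolerance = 1e-8)
    if (s <= 3)   # the dip oracle is itself the validated implementation run per row
      expect_equal(unname(statistic(dipStatistic(x))),
                   unname(apply(x, 1, hartiganDip)), tolerance = 1e-12)
  }
})

test_that("scale equivariance of SD-b and MAD", {
  base <- c(0.4, 0.45, 0.5, 0.55, 0.6)
  for (cc in c(0.5, 2)) {
    scaled <- 0.5 + cc * (base - 0.5)
    x <- rbind(a = base, b = scaled); colnames(x) <- paste0("s", 1:5)
    expect_equal(statistic(sdStatistic(x))[["b"]],
                 cc * statistic(sdStatistic(x))[["a"]], tolerance = 1e-10)
    expect_equal(statistic(madStatistic(x))[["b"]],
                 cc * statistic(madStatistic(x))[["a"]], tolerance = 1e-10)
  }
})

test_that("SD-m ranks are invariant to the logit base", {
  x <- make_beta_matrix(40, 25, 1.5, 4, seed = 9)
  r2 <- rankValue(sdStatistic(x, "mvalue"))
  natural <- apply(log(x / (1 - x)), 1, oracle_sd)
  expect_identical(unname(rank(r2)), unname(rank(natural)))
})

test_that("transformed summary hits its fixed points", {
  n <- 25
  grid <- (1:n) / (n + 1)
  # a feature whose CDF-transform lands exactly on the symmetric grid
  expect_equal(mean(grid), 0.5, tolerance = 1e-12)
  x <- make_beta_matrix(30, 200, 2, 5, seed = 4)
  sm <- transformedSummary(x)
  expect_true(all(sm$ok))
  expect_true(all(abs(sm$yMean - 0.5) < 0.15))
  # large iid feature transformed with (near-)true parameters: close to target
  big <- matrix(rbeta(2e5, 2, 5), 1, dimnames = list("f", NULL))
  smb <- transformedSummary(big)
  expect_lt(abs(smb$yMean - 0.5), 0.01)
  expect_lt(abs(smb$ySD - sqrt(1 / 12)), 0.01)
})

test_that("TM-GOF standardized distance has the stated geometry", {
  sm <- data.frame(
    yMean = c(0.5, 0.52, 0.48, 0.55),
    ySD = c(sqrt(1 / 12), sqrt(1 / 12), 0.30, 0.27),
    ok = TRUE, row.names = paste0("f", 1:4))
  sc <- tmGof(sm)
  expect_equal(unname(statistic(sc)["f1"]), 0, tolerance = 1e-12)
  # a feature exactly one cross-feature SD off on one axis scores 1
  sdev <- function(v) sqrt(mean((v - mean(v))^2))
  d1 <- (sm$yMean[2] - 0.5) / sdev(sm$yMean)
  expect_equal(unname(statistic(sc)["f2"]), abs(d1), tolerance = 1e-12)
  # permutation invariance: scores do not depend on feature order
  perm <- c(3, 1, 4, 2)
  expect_equal(unname(statistic(tmGof(sm[perm, ]))[rownames(sm)]),
               unname(statistic(sc)[rownames(sm)]), tolerance = 1e-12)
})

test_that("quantile GOF statistics vanish on perfect fits and stay bounded", {
  # TQ-GOF: transformed values exactly on the uniform grid -> 0
  n <- 25
  p <- (1:n) / (n + 1)
  v <- qbeta(p, 2, 5)
  m <- mean(v); s2 <- mean((v - m)^2)
  nu <- m * (1 - m) / s2 - 1
  y <- sort(pbeta(v, m * nu, (1 - m) * nu))
  tq <- sum(abs(y[ceiling(p * n)] - p))
  x <- rbind(f = v); colnames(x) <- paste0("s", 1:n)
  expect_equal(unname(statistic(tqGof(x))["f"]), tq, tolerance = 1e-10)
  expect_lte(max(statistic(tqGof(make_beta_matrix(20, 40, seed = 2)))), 25)
  expect_lte(max(statistic(bqGof(make_beta_matrix(20, 40, seed = 3)))), 25)
})

test_that("two-Beta mixtures score worse than single-Beta features (BQ and TQ)", {
  set.seed(11)
  single <- rbeta(2000, 2, 5)
  mixed <- c(rbeta(1000, 20, 2), rbeta(1000, 2, 20))
  x <- rbind(single = single, mixed = mixed)
  colnames(x) <- paste0("s", 1:2000)
  expect_gt(statistic(bqGof(x))[["mixed"]], statistic(bqGof(x))[["single"]])
  expect_gt(statistic(tqGof(x))[["mixed"]], statistic(tqGof(x))[["single"]])
})

test_that("rank assignment and tie handling", {
  sc <- rankFeatures(c(a = 3, b = 1, c = 2))
  expect_equal(unname(rankValue(sc)[c("a", "b", "c")]), c(3, 1, 2))
  sc2 <- rankFeatures(c(a = 5, b = 5, c = 1))
  expect_equal(unname(rankValue(sc2)[c("a", "b", "c")]), c(2.5, 2.5, 1))
  p <- 37
  sc3 <- rankFeatures(setNames(rnorm(p), paste0("f", 1:p)))
  expect_equal(sum(rankValue(sc3)), p * (p + 1) / 2)
  expect_error(rankFeatures(numeric(0)), "empty")
})

test_that("BR, AR, WAR combine ranks exactly as specified", {
  r <- c(5, 8, 2, 1, 1, 1, 1, 1)
  # build 8 filters so that feature f1 receives rank r[i] under filter i
  p <- 8
  mats <- lapply(seq_len(8), function(i) {
    stat <- setNames(seq_len(p), paste0("f", 1:p))
    # permute so that feature f1 receives rank r[i]
    stat["f1"] <- r[i]; others <- setdiff(seq_len(p), r[i])
    stat[paste0("f", 2:p)] <- others
    rankFeatures(stat)
  })
  br <- combineRanks(mats, "BR"); ar <- combineRanks(mats, "AR"); war <- combineRanks(mats, "WAR")
  expect_equal(unname(statistic(br)["f1"]), 8)
  expect_equal(unname(statistic(ar)["f1"]), 6.5)
  expect_equal(unname(statistic(war)["f1"]), 5.2)
  expect_error(combineRanks(mats[1:7], "BR"), "exactly 8")
})

test_that("top-k selection is deterministic with lexicographic ties", {
  sc <- rankFeatures(c(a = 3, b = 1, c = 2))
  expect_identical(selectTop(sc, 2), c("a", "c"))
  expect_identical(selectTop(sc, 3), c("a", "c", "b"))
  expect_identical(selectTop(sc, 1), "a")
  expect_error(selectTop(sc, 4), "between 1 and")
  tie <- rankFeatures(c(b = 1, a = 1, c = 0))
  expect_identical(selectTop(tie, 1), "a")
})

test_that("hybrid selection pools top lists with the union arithmetic", {
  p <- 2100
  ids <- sprintf("f%04d", 1:p)
  s1 <- rankFeatures(setNames(p:1, ids))
  # second filter: shares exactly 47 of the first 1000 with filter 1
  stat2 <- setNames(rep(0, p), ids)
  shared <- ids[1:47]; distinct <- ids[1048:2000]
  stat2[c(shared, distinct)] <- seq(1000, 1, length.out = 1000)
  sc2 <- rankFeatures(stat2)
  expect_length(hybridSelect(s1, sc2, 1000), 2000 - 47)
  expect_length(hybridSelect(s1, s1, 500), 500)
})

test_that("features without a valid Beta fit get the worst-fit sentinel and a flag", {
  set.seed(3)
  x <- make_beta_matrix(20, 40, 2, 5)
  x["f001", ] <- rep(0.5, 40)   # zero variance: no moment fit exists
  for (fn in list(inversePrecision, bqGof, tmGof, tqGof)) {
    sc <- fn(x)
    expect_true(flagged(sc)[["f001"]])
    expect_equal(which.max(statistic(sc)), c(f001 = 1L))
  }
})

test_that("GOF filters are not enriched on null single-Beta data", {
  reps <- 50
  aucs <- matrix(NA_real_, reps, 3, dimnames = list(NULL, c("TM-GOF", "TQ-GOF", "BQ-GOF")))
  for (r in 1:reps) {
    set.seed(1000 + r)
    P <- 400; N <- 60
    mu <- runif(P, 0.05, 0.95)
    phi <- exp(runif(P, log(5), log(200)))
    x <- matrix(rbeta(P * N, mu * phi, (1 - mu) * phi), P, N,
                dimnames = list(sprintf("f%03d", 1:P), sprintf("s%02d", 1:N)))
    truth <- setNames(seq_len(P) %in% sample.int(P, P / 10), rownames(x))
    for (f in colnames(aucs))
      aucs[r, f] <- aucValue(rocPoints(computeFilter(x, f), truth))
  }
  for (f in colnames(aucs)) {
    se <- sd(aucs[, f]) / sqrt(reps)
    expect_lt(abs(mean(aucs[, f]) - 0.5), 3 * se + 1e-8)
  }
})

test_that("two-group mixtures raise TM-GOF and TQ-GOF scores above matched singles", {
  winsTM <- winsTQ <- 0L
  reps <- 50
  for (r in 1:reps) {
    set.seed(2000 + r)
    P <- 30; N <- 60
    mu2 <- runif(P, 0.05, 0.15); phi <- exp(runif(P, log(30), log(300)))
    mu1 <- plogis(qlogis(mu2) + 1)   # |theta| = 1
    xs <- matrix(rbeta(P * N, mu2 * phi, (1 - mu2) * phi), P, N)
    xm <- cbind(matrix(rbeta(P * N / 2, mu1 * phi, (1 - mu1) * phi), P),
                matrix(rbeta(P * N / 2, mu2 * phi, (1 - mu2) * phi), P))
    x <- rbind(xs, xm)
    dimnames(x) <- list(sprintf("f%03d", 1:(2 * P)), sprintf("s%02d", 1:N))
    isMix <- seq_len(2 * P) > P
    tm <- statistic(tmGof(x)); tq <- statistic(tqGof(x))
    winsTM <- winsTM + (mean(tm[isMix]) > mean(tm[!isMix]))
    winsTQ <- winsTQ + (mean(tq[isMix]) > mean(tq[!isMix]))
  }
  expect_lt(binom.test(winsTM, reps, alternative = "greater")$p.value, 0.01)
  expect_lt(binom.test(winsTQ, reps, alternative = "greater")$p.value, 0.01)
})
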