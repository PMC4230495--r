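# Independent brute-force re-implementations of the filter statistics and
# evaluation quantities, used as oracles against the package's code paths.

oracle_sd <- function(v) sqrt(mean((v - mean(v))^2))
oracle_mad <- function(v) median(abs(v - median(v)))
oracle_mom <- function(v) {
  m <- mean(v); s2 <- mean((v - m)^2)
  nu <- m * (1 - m) / s2 - 1
  c(alpha = m * nu, beta = (1 - m) * nu)
}
oracle_invprec <- function(v) { p <- oracle_mom(v); 1 / (p[1] + p[2]) }
oracle_bq <- function(v, K = 25) {
  p <- seq_len(K) / (K + 1)
  ab <- oracle_mom(v)
  q <- qbeta(p, ab[1], ab[2])
  sum(abs(vapply(q, function(qq) mean(v <= qq), 0) - p))
}
oracle_tq <- function(v, K = 25) {
  p <- seq_len(K) / (K + 1)
  ab <- oracle_mom(v)
  y <- sort(pbeta(v, ab[1], ab[2]))
  sum(abs(y[ceiling(p * length(v))] - p))
}
oracle_tm <- function(x) {
  n <- ncol(x)
  ms <- t(apply(x, 1, function(v) {
    ab <- oracle_mom(v)
    y <- pbeta(v, ab[1], ab[2])
    c(mean(y), oracle_sd(y))
  }))
  sy <- oracle_sd(ms[, 1]); ss <- oracle_sd(ms[, 2])
  sqrt(((ms[, 1] - 0.5) / sy)^2 + ((ms[, 2] - sqrt(1 / 12)) / ss)^2)
}
oracle_roc_auc <- function(stat, truth) {
  # probability that a random informative feature outranks a random null,
  # counting ties as half -- equals the trapezoid AUC of the ROC curve
  pos <- stat[truth]; neg <- stat[!truth]
  cmp <- outer(pos, neg, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Exact dip by linear programming over piecewise-linear unimodal CDFs:
# for each candidate mode placement, minimize the band half-width t subject to
# convexity before / concavity after the mode, monotonicity, the ECDF value
# and left-limit bands, and the junction-slope condition across a gap mode.
oracle_dip_lp <- function(x) {
  x <- sort(x); n <- length(x)
  u <- rle(x); z <- u$values; w <- u$lengths; m <- length(z)
  if (m == 1) return(0)
  cu <- cumsum(w) / n; cl <- cu - w / n
  solveLP <- function(A, b, nv) {
    A <- rbind(A, cbind(diag(nv - 1), 0))   # g_i <= 1
    b <- c(b, rep(1, nv - 1))
    r <- tryCatch(pracma::linprog(c(rep(0, nv - 1), 1), A = A, b = b, maxiter = 400),
                  error = function(e) NULL, warning = function(w) NULL)
    if (is.null(r) || is.null(r$fval) || r$errno != 1) return(Inf)
    if (any(A %*% r$x > b + 1e-8)) return(Inf)   # claimed solution not feasible
    r$fval
  }
  band <- function(i, target, nv) {
    r1 <- rep(0, nv); r1[i] <- 1; r1[nv] <- -1
    r2 <- rep(0, nv); r2[i] <- -1; r2[nv] <- -1
    rbind(r1, r2)
  }
  mono <- function(i, j, nv) { r <- rep(0, nv); r[i] <- 1; r[j] <- -1; rbind(r) }
  curv <- function(i0, i1, i2, zz, nv, sign) {
    d1 <- zz[2] - zz[1]; d2 <- zz[3] - zz[2]
    r <- rep(0, nv); r[i0] <- d2; r[i1] <- -(d1 + d2); r[i2] <- d1
    rbind(sign * r)
  }
  best <- Inf
  for (g in 0:m) {
    nv <- m + 1
    A <- NULL; b <- NULL
    add <- function(Ap, bp) { A <<- rbind(A, Ap); b <<- c(b, bp) }
    for (i in 1:m) { add(band(i, cu[i], nv), c(cu[i], -cu[i])); add(band(i, cl[i], nv), c(cl[i], -cl[i])) }
    if (m > 1) for (i in 1:(m - 1)) add(mono(i, i + 1, nv), 0)
    if (g >= 3) for (i in 2:(g - 1)) add(curv(i - 1, i, i + 1, z[(i-1):(i+1)], nv, -1), 0)
    if (g <= m - 3) for (i in (g + 2):(m - 1)) add(curv(i - 1, i, i + 1, z[(i-1):(i+1)], nv, 1), 0)
    if (g <= 1 || g >= m - 1) {
      best <- min(best, solveLP(A, b, nv))
    } else {
      best <- min(best,
        solveLP(rbind(A, curv(g - 1, g, g + 1, z[(g-1):(g+1)], nv, -1)), c(b, 0), nv),
        solveLP(rbind(A, curv(g, g + 1, g + 2, z[g:(g+2)], nv, 1)), c(b, 0), nv))
    }
  }
  for (k in 1:m) {
    nv <- m + 2; h <- m + 1
    A <- NULL; b <- NULL
    add <- function(Ap, bp) { A <<- rbind(A, Ap); b <<- c(b, bp) }
    for (i in 1:m) {
      add(band(i, cu[i], nv), c(cu[i], -cu[i]))
      if (i != k) add(band(i, cl[i], nv), c(cl[i], -cl[i]))
    }
    add(band(h, cl[k], nv), c(cl[k], -cl[k]))
    if (m > 1) for (i in 1:(m - 1)) {
      if (i == k - 1) { add(mono(i, h, nv), 0); add(mono(h, i + 1, nv), 0) }
      else add(mono(i, i + 1, nv), 0)
    }
    if (k == 1) add(mono(h, 1, nv), 0)
    left <- c(seq_len(k - 1), h); zl <- z[1:k]
    if (length(left) >= 3) for (i in 2:(length(left) - 1))
      add(curv(left[i - 1], left[i], left[i + 1], zl[(i-1):(i+1)], nv, -1), 0)
    right <- k:m; zr <- z[k:m]
    if (length(right) >= 3) for (i in 2:(length(right) - 1))
      add(curv(right[i - 1], right[i], right[i + 1], zr[(i-1):(i+1)], nv, 1), 0)
    best <- min(best, solveLP(A, b, nv))
  }
  best
}

make_beta_matrix <- function(P, N, shape1 = 2, shape2 = 5, seed = 1) {
  set.seed(seed)
  matrix(rbeta(P * N, shape1, shape2), P, N,
         dimnames = list(sprintf("f%03d", seq_len(P)), sprintf("s%03d", seq_len(N))))
}

small_library <- function(nNull, seed = 1, ...)
  buildParameterLibrary(nNull = nNull, nCandidates = max(200L, nNull), seed = seed, ...)
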