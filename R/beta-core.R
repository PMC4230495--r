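# Beta-distribution machinery shared by the filters, the simulator and the
# clustering stage: moment estimation, the CDF variance-stabilizing transform,
# the M-value transform and the two-group effect size.

#' Construct BetaParams from shape parameters
#'
#' @param alpha,beta positive numeric vectors of equal length.
#' @return A \linkS4class{BetaParams} object with derived mean and precision.
#' @examples
#' BetaParams(2, 5)
#' @export
BetaParams <- function(alpha, beta) {
  alpha <- as.numeric(alpha); beta <- as.numeric(beta)
  new("BetaParams", alpha = alpha, beta = beta,
      mu = alpha / (alpha + beta), phi = alpha + beta)
}

#' @rdname BetaParams-class
#' @export
setMethod("shape1", "BetaParams", function(x) x@alpha)
#' @rdname BetaParams-class
#' @export
setMethod("shape2", "BetaParams", function(x) x@beta)
#' @rdname BetaParams-class
#' @export
setMethod("betaMean", "BetaParams", function(x) x@mu)
#' @rdname BetaParams-class
#' @export
setMethod("betaPrecision", "BetaParams", function(x) x@phi)

setMethod("show", "BetaParams", function(object) {
  n <- length(object@alpha)
  cat("BetaParams with", n, if (n == 1) "distribution\n" else "distributions\n")
  k <- min(n, 5L)
  for (i in seq_len(k))
    cat(sprintf("  Beta(%.4g, %.4g): mu = %.4g, phi = %.4g\n",
                object@alpha[i], object@beta[i], object@mu[i], object@phi[i]))
  if (n > k) cat("  ...\n")
})

#' Clip proportions away from the boundaries 0 and 1
#'
#' Methylation proportions of exactly 0 or 1 break the logit transform and the
#' Beta likelihood; this clamps them to `[epsilon, 1 - epsilon]` and leaves
#' interior values untouched.
#'
#' @param values numeric vector (or matrix) of proportions in `[0, 1]`.
#' @param epsilon small positive clamp, `0 < epsilon < 0.5`.
#' @return The clipped values, same shape and order as the input.
#' @examples
#' clipBoundary(c(0, 0.5, 1))
#' @export
clipBoundary <- function(values, epsilon = 1e-6) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0, epsilon < 0.5)
  bad <- which(!is.finite(values) | values < 0 | values > 1)
  if (length(bad))
    stop("values outside [0, 1] or non-finite at index ", bad[1L],
         " (value = ", values[bad[1L]], ")")
  pmin(pmax(values, epsilon), 1 - epsilon)
}

#' Method-of-moments Beta fit from a feature's mean and variance
#'
#' Given the sample mean \eqn{\bar x} and variance \eqn{s^2} of a feature, the
#' moment estimators are
#' \eqn{\hat\alpha = \bar x (\bar x(1-\bar x)/s^2 - 1)} and
#' \eqn{\hat\beta = (1-\bar x)(\bar x(1-\bar x)/s^2 - 1)}.
#' The fit only exists when \eqn{0 < s^2 < \bar x(1-\bar x)}; features more
#' dispersed than any single Beta distribution raise an overdispersion error
#' (filters decide their own policy for such features, see e.g. [tmGof()]).
#'
#' @param mean numeric vector of means in (0, 1).
#' @param var numeric vector of variances (the caller chooses the divisor;
#'   the filters in this package use the 1/N convention).
#' @return A \linkS4class{BetaParams} object.
#' @examples
#' fitBetaMoM(0.5, 1/12)   # Beta(1, 1), the uniform
#' fitBetaMoM(0.2, 0.01)   # Beta(3, 12)
#' @export
fitBetaMoM <- function(mean, var) {
  if (length(var) == 1L && length(mean) > 1L) var <- rep(var, length(mean))
  stopifnot(length(mean) == length(var))
  bad <- which(!is.finite(mean) | mean <= 0 | mean >= 1)
  if (length(bad)) stop("mean outside (0, 1) at index ", bad[1L])
  bad <- which(!is.finite(var) | var <= 0)
  if (length(bad)) stop("degenerate feature (variance <= 0) at index ", bad[1L])
  bad <- which(var >= mean * (1 - mean))
  if (length(bad))
    stop("overdispersed feature at index ", bad[1L],
         ": variance ", var[bad[1L]], " >= mean(1-mean) = ",
         (mean * (1 - mean))[bad[1L]], "; no single Beta distribution fits")
  nu <- mean * (1 - mean) / var - 1
  BetaParams(mean * nu, (1 - mean) * nu)
}

#' Moments implied by Beta parameters
#'
#' Inverse of [fitBetaMoM()]: mean \eqn{\mu = \alpha/(\alpha+\beta)} and
#' variance \eqn{\mu(1-\mu)/(\phi+1)}.
#'
#' @param params a \linkS4class{BetaParams} object.
#' @return list with numeric components `mean` and `var`.
#' @export
paramsToMoments <- function(params) {
  stopifnot(is(params, "BetaParams"))
  list(mean = params@mu, var = params@mu * (1 - params@mu) / (params@phi + 1))
}

#' Variance-stabilizing CDF transform for Beta data
#'
#' Maps each value through the regularized incomplete beta function
#' \eqn{I_x(\alpha, \beta)}.  If the inputs are iid Beta(\eqn{\alpha, \beta})
#' draws and the true parameters are used, the outputs are iid Uniform(0, 1)
#' with mean 1/2 and variance 1/12; departures of the transformed data from
#' that target indicate that a single Beta does not fit (e.g. a mixture).
#'
#' @param values numeric vector in (0, 1), boundary-clipped beforehand.
#' @param params a \linkS4class{BetaParams} with a single (alpha, beta) pair,
#'   or vectors matching `values`.
#' @return numeric vector in `[0, 1]`.
#' @examples
#' betaCdfTransform(0.5, BetaParams(2, 1))   # CDF of Beta(2,1) is x^2 -> 0.25
#' @export
betaCdfTransform <- function(values, params) {
  stopifnot(is(params, "BetaParams"))
  if (any(!is.finite(values))) stop("non-finite values in input")
  pbeta(values, params@alpha, params@beta)
}

#' M-value (log2 logit) transform
#'
#' \eqn{M = \log_2(x / (1 - x))}; antisymmetric about \eqn{x = 0.5}.  Values of
#' exactly 0 or 1 are an error: clip with [clipBoundary()] first.
#'
#' @param values numeric vector strictly inside (0, 1).
#' @return numeric vector of M-values.
#' @export
mValues <- function(values) {
  if (any(!is.finite(values)) || any(values <= 0) || any(values >= 1))
    stop("mValues requires values strictly inside (0, 1); clip boundaries first")
  log2(values / (1 - values))
}

#' Effect size between two group means
#'
#' The log odds ratio
#' \eqn{\hat\theta = \ln\{\mu_2/(1-\mu_2)\} - \ln\{\mu_1/(1-\mu_1)\}}
#' of the two group means of a feature; zero exactly when the means are equal.
#'
#' @param mu1,mu2 group means in (0, 1) (group 1 = CIMP-like minority
#'   convention in this package).
#' @return numeric effect size(s).
#' @examples
#' effectSize(0.5, 0.8)  # log(4)
#' @export
effectSize <- function(mu1, mu2) {
  if (any(!is.finite(mu1) | mu1 <= 0 | mu1 >= 1) ||
      any(!is.finite(mu2) | mu2 <= 0 | mu2 >= 1))
    stop("group means must lie strictly inside (0, 1)")
  log(mu2 / (1 - mu2)) - log(mu1 / (1 - mu1))
}

# Internal: clamped, never-failing moment fit used where a policy (rather than
# an error) is wanted.  Returns alpha/beta plus an ok flag; !ok marks features
# with no valid single-Beta fit (variance zero or overdispersed).
.momFit <- function(m, v) {
  ok <- is.finite(m) & is.finite(v) & m > 0 & m < 1 & v > 0 & v < m * (1 - m)
  nu <- ifelse(ok, m * (1 - m) / v - 1, NA_real_)
  list(alpha = m * nu, beta = (1 - m) * nu, ok = ok)
}

# Internal: row means/variances with the 1/N convention.
.rowMoments <- function(x) {
  m <- rowMeans(x)
  v <- rowMeans(x * x) - m * m
  v[v < 0] <- 0     # guard against catastrophic cancellation on constants
  list(mean = m, var = v)
}
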