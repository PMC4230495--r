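#' Hartigan-Hartigan dip statistic of a sample
#'
#' The dip is the smallest sup-norm distance between the empirical distribution
#' function of the sample and any unimodal distribution function (convex up to
#' a mode, concave after it, with an atom allowed at the mode).  Large values
#' indicate multimodality.  Computed by the classical modal-interval algorithm:
#' the greatest convex minorant (GCM) and least concave majorant (LCM) of the
#' ECDF are intersected over a shrinking modal interval, and the deviations of
#' the ECDF from the hulls outside that interval accumulate into the dip.
#'
#' For any sample of n distinct values the dip is at least 1/(2n); that floor
#' is also returned for degenerate (all-equal) samples so that constant
#' features remain comparable in filter rankings.
#'
#' @param x numeric vector (need not be sorted; exact ties allowed).
#' @return The dip statistic, a number in `[1/(2n), 1/4]`.
#' @examples
#' hartiganDip(c(rep(0.01, 10), rep(0.99, 10)))  # maximally bimodal: 0.25
#' @export
hartiganDip <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 1L) stop("empty sample")
  if (n == 1L) return(0.5)             # 1/(2n) floor
  if (x[n] == x[1L]) return(1 / (2 * n))
  low <- 1L; high <- n
  dip <- 1                              # count units; reported dip = dip/(2n)

  # GCM predecessor pointers (lower hull of the ECDF corner points) and LCM
  # successor pointers (upper hull), computed once over the whole sample.
  mn <- integer(n); mn[1L] <- 1L
  for (j in 2:n) {
    mn[j] <- j - 1L
    repeat {
      mnj <- mn[j]
      if (mnj == 1L) break
      mnmnj <- mn[mnj]
      if ((x[j] - x[mnj]) * (mnj - mnmnj) < (x[mnj] - x[mnmnj]) * (j - mnj)) break
      mn[j] <- mnmnj
    }
  }
  mj <- integer(n); mj[n] <- n
  for (k in (n - 1L):1L) {
    mj[k] <- k + 1L
    repeat {
      mjk <- mj[k]
      if (mjk == n) break
      mjmjk <- mj[mjk]
      if ((x[k] - x[mjk]) * (mjk - mjmjk) < (x[mjk] - x[mjmjk]) * (k - mjk)) break
      mj[k] <- mjmjk
    }
  }

  repeat {
    gcm <- integer(0); i <- high
    repeat { gcm <- c(gcm, i); if (i <= low) break; i <- mn[i] }
    l_gcm <- length(gcm); ig <- l_gcm; ix <- l_gcm - 1L
    lcm <- integer(0); i <- low
    repeat { lcm <- c(lcm, i); if (i >= high) break; i <- mj[i] }
    l_lcm <- length(lcm); ih <- l_lcm; iv <- 2L

    # largest gap between the LCM and GCM curves over [low, high]
    d <- 0
    if (l_gcm != 2L || l_lcm != 2L) {
      repeat {
        gcmix <- gcm[ix]; lcmiv <- lcm[iv]
        if (gcmix > lcmiv) {            # gap at an LCM vertex vs a GCM segment
          gcmi1 <- gcm[ix + 1L]
          dx <- (lcmiv - gcmi1 + 1) -
            (x[lcmiv] - x[gcmi1]) * (gcmix - gcmi1) / (x[gcmix] - x[gcmi1])
          iv <- iv + 1L
          if (dx >= d) { d <- dx; ig <- ix + 1L; ih <- iv - 1L }
        } else {                        # gap at a GCM vertex vs an LCM segment
          lcmiv1 <- lcm[iv - 1L]
          dx <- (x[gcmix] - x[lcmiv1]) * (lcmiv - lcmiv1) /
            (x[lcmiv] - x[lcmiv1]) - (gcmix - lcmiv1 - 1)
          ix <- ix - 1L
          if (dx > d) { d <- dx; ig <- ix + 1L; ih <- iv }
        }
        if (ix < 1L) ix <- 1L
        if (iv > l_lcm) iv <- l_lcm
        if (gcm[ix] == lcm[iv]) break
      }
    } else d <- 1

    if (d <= dip) break

    # ECDF deviations outside the shrunken modal interval are locked in: full
    # jump gap of the ECDF above the minorant chords on the left, and of the
    # majorant chords above the ECDF left limits on the right.
    dip_l <- 0
    if (ig < l_gcm) for (j in ig:(l_gcm - 1L)) {
      max_t <- 1
      jb <- gcm[j + 1L]; je <- gcm[j]
      if (je - jb > 1L && x[je] != x[jb]) {
        C <- (je - jb) / (x[je] - x[jb])
        jj <- (jb + 1L):je
        max_t <- max(max_t, (jj - jb + 1) - (x[jj] - x[jb]) * C)
      }
      dip_l <- max(dip_l, max_t)
    }
    dip_u <- 0
    if (ih < l_lcm) for (j in ih:(l_lcm - 1L)) {
      max_t <- 1
      jb <- lcm[j]; je <- lcm[j + 1L]
      if (je - jb > 1L && x[je] != x[jb]) {
        C <- (je - jb) / (x[je] - x[jb])
        jj <- (jb + 1L):je
        max_t <- max(max_t, (x[jj] - x[jb]) * C - (jj - jb - 1))
      }
      dip_u <- max(dip_u, max_t)
    }
    dip <- max(dip, dip_l, dip_u)
    if (gcm[ig] == low && lcm[ih] == high) break
    low <- gcm[ig]; high <- lcm[ih]
  }
  dip / (2 * n)
}
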