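#' Hartigan's dip statistic
#'
#' The dip of a sample is the maximum distance between its empirical CDF and
#' the closest unimodal CDF, computed by the greatest-convex-minorant /
#' least-concave-majorant cycling algorithm over candidate modal intervals.
#' Internally distances are kept in count units and divided by 2n at the
#' end; the minimum attainable dip is 1/(2n) (attained by, e.g., equispaced
#' samples) and a sample of two points has dip exactly 1/4. A constant
#' sample has dip 0 by convention.
#'
#' @param x numeric vector.
#' @return the dip statistic (scalar in [0, 1/4]).
#' @export
dip_statistic <- function(x) {
  x <- sort(as.numeric(x[!is.na(x)]))
  n <- length(x)
  if (n < 2 || x[n] == x[1]) return(0)

  # pointer arrays for the greatest convex minorant (mn) and least concave
  # majorant (mj) over the whole sample, by cross-multiplied slope checks
  mn <- integer(n); mj <- integer(n)
  mn[1] <- 1L
  for (j in 2:n) {
    mn[j] <- j - 1L
    repeat {
      mnj <- mn[j]
      if (mnj == 1L) break
      mnmnj <- mn[mnj]
      if ((x[j] - x[mnj]) * (mnj - mnmnj) <
          (x[mnj] - x[mnmnj]) * (j - mnj)) break
      mn[j] <- mnmnj
    }
  }
  mj[n] <- n
  for (k in (n - 1):1) {
    mj[k] <- k + 1L
    repeat {
      mjk <- mj[k]
      if (mjk == n) break
      mjmjk <- mj[mjk]
      if ((x[k] - x[mjk]) * (mjk - mjmjk) <
          (x[mjk] - x[mjmjk]) * (k - mjk)) break
      mj[k] <- mjmjk
    }
  }

  low <- 1L; high <- n
  dip <- 1  # count units; final value is dip / (2n)
  repeat {
    # GCM change points from high down to low; LCM from low up to high
    gcm <- high
    while (gcm[length(gcm)] > low) gcm <- c(gcm, mn[gcm[length(gcm)]])
    l_gcm <- length(gcm)
    lcm <- low
    while (lcm[length(lcm)] < high) lcm <- c(lcm, mj[lcm[length(lcm)]])
    l_lcm <- length(lcm)

    if (l_gcm == 2L && l_lcm == 2L) break
    d <- 0; ig <- l_gcm; ih <- l_lcm
    ix <- l_gcm - 1L; iv <- 2L
    repeat {
      gcmix <- gcm[ix]; lcmiv <- lcm[iv]
      if (gcmix > lcmiv) {
        # next change point is on the LCM: distance at lcm[iv] to gcm chord
        gcmi1 <- gcm[ix + 1L]
        dx <- (lcmiv - gcmi1 + 1) -
          (x[lcmiv] - x[gcmi1]) * (gcmix - gcmi1) / (x[gcmix] - x[gcmi1])
        iv <- iv + 1L
        if (dx >= d) { d <- dx; ig <- ix + 1L; ih <- iv - 1L }
      } else {
        # next change point is on the GCM: distance at gcm[ix] to lcm chord
        lcmiv1 <- lcm[iv - 1L]
        dx <- (x[gcmix] - x[lcmiv1]) * (lcmiv - lcmiv1) /
          (x[lcmiv] - x[lcmiv1]) - (gcmix - lcmiv1 - 1)
        ix <- ix - 1L
        if (dx >= d) { d <- dx; ig <- ix + 1L; ih <- iv }
      }
      if (ix < 1L) ix <- 1L
      if (iv > l_lcm) iv <- l_lcm
      if (gcm[ix] == lcm[iv]) break
    }
    if (d < dip) break

    # dips of the left region (follows the GCM) and right region (LCM)
    dl <- 0
    if (ig < l_gcm) {
      for (j in ig:(l_gcm - 1L)) {
        jb <- gcm[j + 1L]; je <- gcm[j]
        if (je - jb > 1L && x[je] != x[jb]) {
          C <- (je - jb) / (x[je] - x[jb])
          for (jj in jb:je) {
            t <- (jj - jb + 1) - (x[jj] - x[jb]) * C
            if (t > dl) dl <- t
          }
        }
      }
    }
    du <- 0
    if (ih < l_lcm) {
      for (k in ih:(l_lcm - 1L)) {
        kb <- lcm[k]; ke <- lcm[k + 1L]
        if (ke - kb > 1L && x[ke] != x[kb]) {
          C <- (ke - kb) / (x[ke] - x[kb])
          for (kk in kb:ke) {
            t <- (x[kk] - x[kb]) * C - (kk - kb - 1)
            if (t > du) du <- t
          }
        }
      }
    }
    dnew <- max(dl, du)
    if (dnew > dip) dip <- dnew
    if (low == gcm[ig] && high == lcm[ih]) break  # no progress: done
    low <- gcm[ig]; high <- lcm[ih]
  }
  dip / (2 * n)
}

#' Dip test of unimodality
#'
#' Tests the null of a unimodal distribution with the dip statistic; the
#' p-value is calibrated by parametric bootstrap under the uniform null (the
#' asymptotically least favorable unimodal distribution) at the same sample
#' size.
#'
#' @param values numeric vector (>= 8 observations).
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed for the bootstrap.
#' @return list with `statistic` (dip), `p_value`, `n`, `n_boot`.
#' @export
dip_test <- function(values, n_boot = 2000L, seed = 1L) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 8) stop("dip test needs at least 8 observations")
  d <- dip_statistic(values)
  if (d == 0) return(list(statistic = 0, p_value = 1, n = n, n_boot = 0L))
  set.seed(seed)
  null <- vapply(seq_len(n_boot),
                 function(i) dip_statistic(stats::runif(n)), numeric(1))
  list(statistic = d,
       p_value = (1 + sum(null >= d)) / (n_boot + 1),
       n = n, n_boot = n_boot)
}
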