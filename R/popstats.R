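#' Population-genetic summaries and resampling statistics
#'
#' Folded projected site frequency spectra, Watterson's theta, nucleotide
#' diversity, Tajima's D, locus-dosage LD decay with bootstrap intervals,
#' Cohen's D, binomial carrier-sampling probabilities and the induced-pair
#' permutation test on relatedness graphs.
#'
#' @name popstats
NULL

#' Folded, projected site frequency spectrum
#'
#' Each segregating site with derived-allele count k out of N chromosomes
#' contributes its hypergeometric expectation
#' \eqn{C(k, j) C(N-k, n-j) / C(N, n)} to projected class j of a sample of
#' size `n_proj`; classes 0 and `n_proj` (monomorphic after projection) are
#' discarded, and the spectrum is folded onto minor-allele classes
#' 1..floor(n_proj/2).
#'
#' @param derived_allele_counts integer vector, one count in [0, N] per site.
#' @param n_chromosomes N, the number of sampled chromosomes.
#' @param n_proj projection size (default 40; must be <= N).
#' @return an `sfs` list: `folded` (numeric, classes 1..floor(n_proj/2)),
#'   `n_proj`, `S` (total projected segregating mass),
#'   `n_input_segregating`.
#' @export
folded_projected_sfs <- function(derived_allele_counts, n_chromosomes,
                                 n_proj = 40L) {
  k <- as.numeric(derived_allele_counts)
  N <- n_chromosomes
  if (any(k < 0 | k > N)) stop("allele counts must lie in [0, n_chromosomes]")
  if (n_proj > N) stop("n_proj must not exceed n_chromosomes")
  if (n_proj < 2) stop("n_proj must be at least 2")
  seg <- k > 0 & k < N
  unfolded <- numeric(n_proj + 1)
  for (kk in unique(k[seg])) {
    nsite <- sum(k[seg] == kk)
    j <- 0:n_proj
    unfolded <- unfolded + nsite * stats::dhyper(j, kk, N - kk, n_proj)
  }
  poly <- unfolded[2:n_proj]  # classes 1..n_proj-1
  half <- floor(n_proj / 2)
  folded <- numeric(half)
  for (j in 1:(n_proj - 1)) {
    cls <- min(j, n_proj - j)
    folded[cls] <- folded[cls] + poly[j] * if (2 * j == n_proj) 0.5 else 1
  }
  # the central class of an even projection was added twice at half weight
  if (n_proj %% 2 == 0) folded[half] <- folded[half] * 2
  structure(list(folded = folded, n_proj = as.integer(n_proj),
                 S = sum(folded), n_input_segregating = sum(seg)),
            class = "sfs")
}

#' Watterson's theta, pi and Tajima's D from a folded spectrum
#'
#' @param sfs an `sfs` from [folded_projected_sfs()], or a bare folded count
#'   vector (classes 1..floor(n/2)).
#' @param n sample size in chromosomes (taken from the `sfs` if present).
#' @param L_sites number of sites surveyed (monomorphic included), for the
#'   per-site scaling.
#' @return list: `theta_w` and `pi` per site, `tajimas_d` (NA with a
#'   `reason` when S = 0), `S`, `n`, `L_sites`.
#' @export
theta_pi_tajima <- function(sfs, n = NULL, L_sites) {
  if (inherits(sfs, "sfs")) {
    eta <- sfs$folded; n <- sfs$n_proj
  } else {
    eta <- as.numeric(sfs)
    if (is.null(n)) stop("supply n when passing a bare folded spectrum")
  }
  stopifnot(n >= 2, L_sites > 0, length(eta) == floor(n / 2))
  S <- sum(eta)
  j <- seq_along(eta)
  # folded class j pools j and n-j; the pairwise-difference weight
  # 2 k (n-k) / (n (n-1)) is symmetric in k <-> n-k, so it applies directly
  pi_total <- sum(eta * 2 * j * (n - j) / (n * (n - 1)))
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  theta_w_total <- S / a1
  if (S <= 0) {
    return(list(theta_w = 0, pi = 0, tajimas_d = NA_real_,
                reason = "no segregating sites", S = S, n = n,
                L_sites = L_sites))
  }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (pi_total - theta_w_total) / sqrt(e1 * S + e2 * S * (S - 1))
  list(theta_w = theta_w_total / L_sites, pi = pi_total / L_sites,
       tajimas_d = D, reason = NULL, S = S, n = n, L_sites = L_sites)
}

#' LD decay across panel loci from locus dosages
#'
#' Pairwise r^2 (squared Pearson correlation) between locus dosage vectors,
#' same-chromosome pairs binned by the physical distance between locus
#' midpoints; a bootstrap over individuals gives percentile 95% intervals
#' per bin. Dosages may be coded as freshwater or marine allele counts --
#' r^2 is invariant to the 0/2 flip.
#'
#' @param dosage complete genotype matrix (individuals x loci, 0/1/2).
#' @param panel the `locus_panel` (columns of `dosage` must be panel loci).
#' @param breaks distance bin breaks in bp (default log-spaced from 10 kb to
#'   the panel extent).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return data.frame per bin: bin_lo, bin_hi, n_pairs, mean_r2, ci_lo,
#'   ci_hi, plus attribute `n_excluded` (zero-variance loci dropped).
#' @export
ld_decay <- function(dosage, panel, breaks = NULL, n_boot = 1000L, seed = 1L) {
  li <- match(colnames(dosage), panel$loci$locus_id)
  if (anyNA(li)) stop("dosage columns are not panel loci")
  v <- apply(dosage, 2, stats::var)
  n_excluded <- sum(v == 0)
  keep <- v > 0
  if (sum(keep) < 2) stop("need at least 2 polymorphic loci")
  d <- dosage[, keep, drop = FALSE]
  li <- li[keep]
  if (nrow(d) < 3) stop("need at least 3 individuals")
  chrom <- panel$loci$chrom[li]
  mid <- (panel$loci$start[li] + panel$loci$end[li]) / 2

  pair <- which(upper.tri(diag(length(li))), arr.ind = TRUE)
  same <- chrom[pair[, 1]] == chrom[pair[, 2]]
  pair <- pair[same, , drop = FALSE]
  if (nrow(pair) == 0) stop("no same-chromosome locus pairs")
  dist <- abs(mid[pair[, 1]] - mid[pair[, 2]])
  if (is.null(breaks))
    breaks <- c(0, 10^seq(4, ceiling(log10(max(dist) + 1)), length.out = 12))
  bin <- cut(dist, breaks, include.lowest = TRUE)

  r2_of <- function(rows) {
    cm <- suppressWarnings(stats::cor(d[rows, , drop = FALSE]))
    r2 <- cm[pair]^2
    tapply(r2, bin, mean, na.rm = TRUE)
  }
  point <- r2_of(seq_len(nrow(d)))
  set.seed(seed)
  boots <- replicate(n_boot, r2_of(sample.int(nrow(d), replace = TRUE)))
  boots <- matrix(boots, nrow = length(point))
  ci <- apply(boots, 1, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  lev <- levels(bin)
  lo <- breaks[-length(breaks)]; hi <- breaks[-1]
  out <- data.frame(bin = lev, bin_lo = lo, bin_hi = hi,
                    n_pairs = as.integer(table(bin)),
                    mean_r2 = as.numeric(point),
                    ci_lo = ci[1, ], ci_hi = ci[2, ], row.names = NULL)
  out <- out[out$n_pairs > 0, , drop = FALSE]
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Cohen's D with a percentile bootstrap interval
#'
#' D = (mean(x) - mean(y)) / s_pooled, with the pooled standard deviation
#' from the two sample variances; the CI resamples each group independently.
#'
#' @param x,y numeric vectors (length >= 2 each).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return list with `d` and `ci` (length 2).
#' @export
cohens_d <- function(x, y, n_boot = 1000L, seed = 1L, conf = 0.95) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  d_of <- function(a, b) {
    sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
      (length(a) + length(b) - 2)
    if (sp2 <= 0) stop("zero pooled variance: Cohen's D undefined")
    (mean(a) - mean(b)) / sqrt(sp2)
  }
  d <- d_of(x, y)
  set.seed(seed)
  bd <- vapply(seq_len(n_boot), function(i) {
    d_of(sample(x, replace = TRUE), sample(y, replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(d = d, ci = unname(stats::quantile(bd, c(alpha, 1 - alpha))))
}

#' Welch's unequal-variance t-test (thin wrapper)
#'
#' @param x,y numeric vectors.
#' @return list with `t`, `df`, `p_value`.
#' @export
welch_t <- function(x, y) {
  w <- stats::t.test(x, y)
  list(t = unname(w$statistic), df = unname(w$parameter), p_value = w$p.value)
}

#' Probability of sampling at least k_min jackpot carriers
#'
#' Exact binomial upper tail: with carrier frequency p in the source
#' population and a sample of n fish, returns P(X >= k_min) for
#' X ~ Binomial(n, p). With k_min = 1 this is 1 - (1-p)^n.
#'
#' @param n sample size (>= 1).
#' @param p carrier frequency in (0, 1).
#' @param k_min minimum number of carriers (>= 0).
#' @return probability.
#' @export
jackpot_sampling_prob <- function(n, p, k_min) {
  stopifnot(n >= 1, p > 0, p < 1, k_min >= 0)
  if (k_min == 0) return(1)
  stats::pbinom(k_min - 1, n, p, lower.tail = FALSE)
}

#' Permutation test of relatedness enrichment
#'
#' Repeatedly samples `n_sub` individuals without replacement from a
#' relatedness graph and counts the induced related pairs, giving the null
#' distribution of pair counts under random sampling; the closed-form
#' expectation is |E| * C(n-2, n_sub-2) / C(n, n_sub).
#'
#' @param graph data.frame i/j(/degree) of related pairs.
#' @param n_individuals number of nodes in the graph.
#' @param n_sub subsample size (default 20).
#' @param reps permutation replicates (default 1000).
#' @param seed integer seed.
#' @return list: `counts` (per rep), `mean`, `min`, `max`, `n_zero_reps`,
#'   `expected` (closed form).
#' @export
relatedness_permutation <- function(graph, n_individuals, n_sub = 20L,
                                    reps = 1000L, seed = 1L) {
  stopifnot(n_sub <= n_individuals)
  set.seed(seed)
  m <- nrow(graph)
  counts <- if (m == 0) integer(reps) else {
    vapply(seq_len(reps), function(r) {
      keep <- logical(n_individuals)
      keep[sample.int(n_individuals, n_sub)] <- TRUE
      sum(keep[graph$i] & keep[graph$j])
    }, integer(1))
  }
  expected <- m * choose(n_individuals - 2, n_sub - 2) /
    choose(n_individuals, n_sub)
  list(counts = counts, mean = mean(counts), min = min(counts),
       max = max(counts), n_zero_reps = sum(counts == 0),
       expected = expected)
}
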