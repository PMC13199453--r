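#' Variational Bayesian Gaussian mixture for jackpot classification
#'
#' Individuals are classified as jackpot carriers or non-jackpot from their
#' freshwater content with a univariate Bayesian Gaussian mixture: a
#' symmetric Dirichlet prior (concentration 1/K, the truncated stick-
#' breaking surrogate that lets superfluous components empty themselves)
#' over weights and Normal-Gamma priors over component means/precisions,
#' fitted by variational inference. Candidate component counts 1..K_max are
#' compared by BIC computed at the posterior-mean parameters with the
#' effective (non-empty) parameter count.
#'
#' @name bgmm
NULL

# one VB fit at fixed K; deterministic given init (quantile means)
vb_gmm_fit <- function(x, K, max_iter = 500L, tol = 1e-8) {
  n <- length(x)
  m0 <- mean(x); v0 <- stats::var(x)
  if (v0 == 0) v0 <- 1e-12
  alpha0 <- 1 / K; beta0 <- 1; a0 <- 1; b0 <- v0 / 2

  # responsibilities from quantile-spaced means (deterministic init)
  mk <- stats::quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE)
  d2 <- outer(x, mk, function(a, b) (a - b)^2)
  r <- exp(-d2 / (2 * v0 / K))
  r <- r / pmax(rowSums(r), .Machine$double.xmin)
  r[!is.finite(r)] <- 1 / K

  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    Nk <- colSums(r) + 1e-12
    xbar <- colSums(r * x) / Nk
    Sk <- colSums(r * (outer(x, xbar, "-")^2)) / Nk
    alpha <- alpha0 + Nk
    beta <- beta0 + Nk
    mk <- (beta0 * m0 + Nk * xbar) / beta
    ak <- a0 + Nk / 2
    bk <- b0 + 0.5 * (Nk * Sk + beta0 * Nk * (xbar - m0)^2 / beta)

    elog_pi <- digamma(alpha) - digamma(sum(alpha))
    elog_lam <- digamma(ak) - log(bk)
    eq <- outer(x, mk, "-")^2 * rep(ak / bk, each = n) + rep(1 / beta, each = n)
    log_rho <- rep(elog_pi + 0.5 * elog_lam, each = n) - 0.5 * log(2 * pi) -
      0.5 * eq
    mx <- apply(log_rho, 1, max)
    r <- exp(log_rho - mx)
    rs <- rowSums(r)
    r <- r / rs
    ll <- sum(mx + log(rs))  # variational surrogate, monitored for convergence
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  weights <- alpha / sum(alpha)
  vars <- bk / ak  # posterior-mean precision inverted
  list(K = K, weights = as.numeric(weights), means = as.numeric(mk),
       vars = as.numeric(vars), resp = r, converged = converged, iter = it)
}

# mixture log-likelihood at plug-in parameters
gmm_loglik <- function(x, weights, means, vars) {
  dens <- vapply(seq_along(weights), function(k) {
    weights[k] * stats::dnorm(x, means[k], sqrt(vars[k]))
  }, numeric(length(x)))
  sum(log(pmax(rowSums(matrix(dens, ncol = length(weights))),
               .Machine$double.xmin)))
}

#' Fit the Bayesian Gaussian mixture over candidate component counts
#'
#' @param values numeric vector of freshwater contents (length >=
#'   `max_components`).
#' @param max_components largest candidate component count (default 4).
#' @param weight_floor components with fitted weight below `weight_floor/n`
#'   count as empty when reporting effective components (default 1).
#' @param seed integer seed (kept for interface symmetry; the fit itself is
#'   deterministic through its quantile initialization).
#' @return a `bgmm_fit`: selected component count `K`, `n_effective`,
#'   weights/means/vars, per-observation responsibilities, `bic` per
#'   candidate K, convergence flags.
#' @export
fit_bgmm <- function(values, max_components = 4L, weight_floor = 1,
                     seed = 1L) {
  x <- as.numeric(values[!is.na(values)])
  n <- length(x)
  if (n < max_components)
    stop("need at least max_components observations")
  set.seed(seed)
  fits <- lapply(seq_len(max_components), function(K) vb_gmm_fit(x, K))
  bic <- vapply(fits, function(f) {
    eff <- f$weights >= weight_floor / n
    keff <- max(1L, sum(eff))
    p <- 3 * keff - 1
    -2 * gmm_loglik(x, f$weights, f$means, f$vars) + p * log(n)
  }, numeric(1))
  best <- which.min(bic)
  f <- fits[[best]]
  eff <- f$weights >= weight_floor / n
  if (!f$converged)
    warning("variational fit at K = ", f$K, " did not converge after ",
            f$iter, " iterations")
  structure(list(K = f$K, n_effective = sum(eff), effective = eff,
                 weights = f$weights, means = f$means, vars = f$vars,
                 resp = f$resp, bic = bic, converged = f$converged,
                 values = x, seed = seed),
            class = "bgmm_fit")
}

#' @export
print.bgmm_fit <- function(x, ...) {
  cat("bgmm_fit: K =", x$K, "selected by BIC;", x$n_effective,
      "effective component(s)\n")
  cat("  weights:", signif(x$weights, 3), "\n")
  cat("  means:  ", signif(x$means, 4), "\n")
  invisible(x)
}

#' Posterior responsibilities of new observations under a fitted mixture
#'
#' @param fit a `bgmm_fit`.
#' @param values numeric vector.
#' @return matrix n x K of posterior membership probabilities (rows sum
#'   to 1).
#' @export
bgmm_posterior <- function(fit, values) {
  dens <- vapply(seq_along(fit$weights), function(k) {
    fit$weights[k] * stats::dnorm(values, fit$means[k], sqrt(fit$vars[k]))
  }, numeric(length(values)))
  dens <- matrix(dens, ncol = length(fit$weights))
  dens / pmax(rowSums(dens), .Machine$double.xmin)
}

#' Classify individuals as jackpot carriers
#'
#' The jackpot component is the effective component with the largest mean;
#' an individual is labelled a jackpot carrier when its posterior membership
#' in that component exceeds 0.5. With fewer than two effective components
#' every individual is non-jackpot.
#'
#' @param fit a `bgmm_fit` (typically fitted on all timepoints pooled).
#' @param values contents to classify (defaults to the fitted values).
#' @param sample ids carried into the table.
#' @param timepoint optional labels carried into the table.
#' @return data.frame: sample, content, posterior_jackpot, label.
#' @export
classify_jackpot <- function(fit, values = fit$values,
                             sample = seq_along(values), timepoint = NULL) {
  if (fit$n_effective < 2) {
    post <- rep(0, length(values))
  } else {
    means <- ifelse(fit$effective, fit$means, -Inf)
    jk <- which.max(means)
    post <- bgmm_posterior(fit, values)[, jk]
  }
  data.frame(sample = sample, content = values, posterior_jackpot = post,
             label = ifelse(post > 0.5, "jackpot", "non-jackpot"),
             timepoint = if (is.null(timepoint)) NA_character_
                         else rep_len(timepoint, length(values)),
             stringsAsFactors = FALSE)
}
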