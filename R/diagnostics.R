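#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance form: with `m` chains of `n` draws,
#' `B = n * var(chain means)`, `W = mean(chain variances)`,
#' `Rhat = sqrt(((n-1)/n * W + B/n) / W)`. Values below about 1.1 indicate
#' convergence.
#'
#' @param fit a `commoccu_fit` (or a draws matrix with a `chain` attribute
#'   supplied via `chain`).
#' @param pars parameter names (default: all hyper-parameter columns).
#' @param chain optional chain-id vector when `fit` is a plain matrix.
#' @return named numeric vector of Rhat values.
#' @export
gelman_rubin <- function(fit, pars = NULL, chain = NULL) {
  if (inherits(fit, "commoccu_fit")) {
    draws <- fit$draws; chain <- fit$chain
  } else draws <- as.matrix(fit)
  if (is.null(chain)) fail("chain ids required")
  m <- length(unique(chain))
  if (m < 2) fail("Gelman-Rubin requires at least 2 chains")
  n <- min(table(chain))
  if (n < 2) fail("need at least 2 draws per chain")
  if (is.null(pars))
    pars <- grep("^(mu_|sigma_|rho)", colnames(draws), value = TRUE)
  vapply(pars, function(pp) {
    x <- draws[, pp]
    means <- tapply(x, chain, mean)
    vars <- tapply(x, chain, stats::var)
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W < .Machine$double.eps) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

#' Effective sample size and Monte Carlo standard error
#'
#' ESS from the initial positive sequence of autocorrelations (computed per
#' chain and summed); MCSE = sd / sqrt(ESS).
#'
#' @param x numeric vector of draws.
#' @param chain optional chain ids (default: one chain).
#' @return list with `ess` and `mcse`.
#' @export
mcmc_ess <- function(x, chain = NULL) {
  if (is.null(chain)) chain <- rep(1L, length(x))
  ess <- 0
  for (ch in unique(chain)) {
    xc <- x[chain == ch]
    n <- length(xc)
    if (stats::var(xc) == 0) { ess <- ess + n; next }
    ac <- stats::acf(xc, lag.max = min(n - 1, 200), plot = FALSE)$acf[, 1, 1]
    # Geyer initial positive sequence: tau = 2 * sum of positive paired
    # autocorrelation sums (rho_0 + rho_1), (rho_2 + rho_3), ... minus 1
    tau <- -1; lag <- 1
    while (lag + 1 <= length(ac)) {
      pair <- ac[lag] + ac[lag + 1]
      if (pair <= 0) break
      tau <- tau + 2 * pair
      lag <- lag + 2
    }
    ess <- ess + n / max(tau, 1)
  }
  list(ess = ess, mcse = stats::sd(x) / sqrt(max(ess, 1)))
}
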