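#' MCMC configuration
#'
#' @param n_chains number of independent chains (>= 1; >= 2 needed for
#'   Gelman-Rubin diagnostics).
#' @param n_iter post-burn-in iterations per chain.
#' @param n_burnin burn-in iterations (adaptation happens here only).
#' @param thin thinning rate; `floor(n_iter / thin)` draws are retained per
#'   chain.
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @return an `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 50000, n_burnin = 50000,
                        thin = 50, seed = 1) {
  stopifnot(n_chains >= 1, n_iter >= 1, n_burnin >= 0, thin >= 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Fit the hierarchical multi-species occupancy model by MCMC
#'
#' Metropolis-within-Gibbs: latent occurrence states and (when `selection`)
#' community-level inclusion indicators are drawn from their full
#' conditionals, community means by conjugate Gibbs, and all remaining
#' continuous parameters by adaptive random-walk Metropolis (adaptation is
#' confined to burn-in). The spatial autocovariate, when enabled, is
#' refreshed from the current latent states at the top of every sweep.
#'
#' @param data a `detection_dataset`.
#' @param covariates data frame with one row per site (aligned with
#'   `data$sites` by a `station_id` column when present, else by order)
#'   containing every covariate named in `spec`. Continuous covariates must
#'   already be standardized (mean 0, unit variance); binary 0/1 covariates
#'   pass through. Anything else is rejected.
#' @param spec a [community_model_spec()].
#' @param cfg an [mcmc_config()].
#' @param selection run Kuo-Mallick indicator-variable model selection?
#' @param fixed_hyper optional named list fixing the community
#'   hyper-parameters (`mu_phi`, `mu_eta`, `sigma_phi`, `sigma_eta`, `rho`,
#'   and `mu_alpha`/`sigma_alpha`, `mu_beta`/`sigma_beta`, `mu_delta`/
#'   `sigma_delta` vectors); used mainly for validation against exact
#'   small-instance posteriors.
#' @return a `commoccu_fit`: list with `draws` (matrix, one row per retained
#'   draw), `chain` (chain id per row), `species`, `spec`, `cfg`,
#'   `selection`, `accept_rate`.
#' @export
run_mcmc <- function(data, covariates, spec, cfg = mcmc_config(),
                     selection = FALSE, fixed_hyper = NULL) {
  stopifnot(inherits(data, "detection_dataset"),
            inherits(spec, "community_model_spec"),
            inherits(cfg, "mcmc_config"))
  N <- length(data$species); J <- length(data$sites)
  if (N < 1) fail("no species in dataset")
  if (any(rowSums(data$y) == 0) && any(data$k > 0))
    fail("species never detected: %s (the model assumes every community member was detected at least once)",
         paste(data$species[rowSums(data$y) == 0], collapse = ", "))

  covariates <- align_covariates(covariates, data$sites)
  X <- covariate_matrix(covariates, spec$occ_covariates, J)
  V <- covariate_matrix(covariates, spec$det_covariates, J)
  check_standardized(X); check_standardized(V)

  if (spec$autocov) {
    graph <- neighborhood_graph(data$coords, spec$autocov_radius)
    nb_idx <- lapply(graph$idx, as.integer)
    nb_w <- graph$w
  } else {
    nb_idx <- rep(list(integer(0)), J)
    nb_w <- rep(list(numeric(0)), J)
  }

  init <- make_init(data, X, V, fixed_hyper)
  sel_occ <- spec$occ_covariates %in% spec$selectable_occ
  sel_det <- spec$det_covariates %in% spec$selectable_det

  n_keep <- cfg$n_iter %/% cfg$thin
  draws_list <- vector("list", cfg$n_chains)
  acc <- numeric(cfg$n_chains)
  for (ch in seq_len(cfg$n_chains)) {
    set.seed(cfg$seed + ch - 1L)
    init_ch <- jitter_init(init, fixed = !is.null(fixed_hyper))
    res <- run_chain_cpp(data$y, data$k, X, V,
                         spec$autocov, nb_idx, nb_w,
                         init_ch, spec$priors,
                         fix_hyper = !is.null(fixed_hyper),
                         selection = selection,
                         sel_occ = sel_occ, sel_det = sel_det,
                         sel_auto = spec$autocov,
                         n_iter = cfg$n_iter, n_burn = cfg$n_burnin,
                         thin = cfg$thin)
    draws_list[[ch]] <- res$draws[seq_len(n_keep), , drop = FALSE]
    acc[ch] <- res$accept_rate
  }
  draws <- do.call(rbind, draws_list)
  colnames(draws) <- draw_colnames(data$species, spec)

  structure(list(draws = draws,
                 chain = rep(seq_len(cfg$n_chains), each = n_keep),
                 species = data$species, spec = spec, cfg = cfg,
                 selection = selection,
                 fixed_hyper = !is.null(fixed_hyper),
                 accept_rate = acc),
            class = "commoccu_fit")
}

#' @export
print.commoccu_fit <- function(x, ...) {
  cat(sprintf("commoccu_fit: %d draws (%d chains), %d species, selection %s\n",
              nrow(x$draws), x$cfg$n_chains, length(x$species),
              if (x$selection) "on" else "off"))
  cat(sprintf("  mean RW acceptance rate: %.2f\n", mean(x$accept_rate)))
  invisible(x)
}

# Internal: align a covariate table with the dataset's site order
align_covariates <- function(covariates, sites) {
  if (!is.null(covariates$station_id)) {
    idx <- match(sites, as.character(covariates$station_id))
    if (anyNA(idx)) fail("covariate table is missing site(s): %s",
                         paste(sites[is.na(idx)], collapse = ", "))
    covariates <- covariates[idx, , drop = FALSE]
  } else if (nrow(covariates) != length(sites)) {
    fail("covariate table has %d rows but the dataset has %d sites",
         nrow(covariates), length(sites))
  }
  covariates
}

# Internal: extract named covariate columns into a J x C matrix
covariate_matrix <- function(covariates, names, J) {
  miss <- setdiff(names, colnames(covariates))
  if (length(miss)) fail("covariate(s) not in table: %s", paste(miss, collapse = ", "))
  m <- as.matrix(covariates[, names, drop = FALSE])
  if (anyNA(m)) fail("missing covariate values at modeled sites")
  storage.mode(m) <- "double"
  m
}

# Internal: initial values; hyper-parameters from data-driven guesses or the
# fixed_hyper list
make_init <- function(data, X, V, fixed_hyper) {
  Co <- ncol(X); Cd <- ncol(V)
  naive <- pmin(pmax(naive_occupancy(data), 0.03), 0.95)
  kpos <- pmax(data$k, 1)
  det_rate <- pmin(pmax(rowSums(data$y) / sum(kpos) * 3, 0.02), 0.9)
  init <- list(phi = logit(naive), eta = logit(det_rate),
               alpha = matrix(0, length(naive), max(Co, 1))[, seq_len(Co), drop = FALSE],
               beta = matrix(0, length(naive), max(Cd, 1))[, seq_len(Cd), drop = FALSE],
               delta = rep(0, length(naive)),
               mu_phi = mean(logit(naive)), mu_eta = mean(logit(det_rate)),
               sigma_phi = 0.75, sigma_eta = 0.75, rho = 0,
               mu_alpha = rep(0, Co), sigma_alpha = rep(0.75, Co),
               mu_beta = rep(0, Cd), sigma_beta = rep(0.75, Cd),
               mu_delta = 0, sigma_delta = 1)
  if (!is.null(fixed_hyper)) init <- utils::modifyList(init, fixed_hyper)
  init
}

# Internal: randomized starting points per chain (hyper jittered only when
# not fixed)
jitter_init <- function(init, fixed) {
  N <- length(init$phi)
  init$phi <- init$phi + stats::rnorm(N, 0, 0.5)
  init$eta <- init$eta + stats::rnorm(N, 0, 0.5)
  init$alpha <- init$alpha + stats::rnorm(length(init$alpha), 0, 0.25)
  init$beta <- init$beta + stats::rnorm(length(init$beta), 0, 0.25)
  init$delta <- init$delta + stats::rnorm(N, 0, 0.25)
  if (!fixed) {
    init$mu_phi <- init$mu_phi + stats::rnorm(1, 0, 0.5)
    init$mu_eta <- init$mu_eta + stats::rnorm(1, 0, 0.5)
  }
  init
}

# Internal: column names matching the sampler's storage layout
draw_colnames <- function(species, spec) {
  oc <- spec$occ_covariates; dc <- spec$det_covariates
  nm <- c("mu_phi", "mu_eta", "sigma_phi", "sigma_eta", "rho")
  for (c in oc) nm <- c(nm, paste0("mu_occ_", c), paste0("sigma_occ_", c))
  for (c in dc) nm <- c(nm, paste0("mu_det_", c), paste0("sigma_det_", c))
  nm <- c(nm, "mu_delta", "sigma_delta")
  nm <- c(nm, paste0("w_occ_", oc, recycle0 = TRUE),
          paste0("w_det_", dc, recycle0 = TRUE), "w_auto")
  for (sp in species) {
    nm <- c(nm, paste0("phi[", sp, "]"), paste0("eta[", sp, "]"),
            paste0("alpha_", oc, "[", sp, "]", recycle0 = TRUE),
            paste0("beta_", dc, "[", sp, "]", recycle0 = TRUE),
            paste0("delta[", sp, "]"))
  }
  for (sp in species)
    nm <- c(nm, paste0("psi_mean[", sp, "]"), paste0("p_mean[", sp, "]"),
            paste0("zbar[", sp, "]"))
  nm
}
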