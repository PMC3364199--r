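# Shared fixture builders for the test suite. Everything is generated in
# code; nothing is read from disk.

# Deployment table builder: n stations with given window lengths (days)
make_deployments <- function(lengths, start = as.Date("2007-01-01"),
                             on_road = 0, team = 0) {
  n <- length(lengths)
  data.frame(station_id = sprintf("st%03d", seq_len(n)),
             x_km = seq_len(n), y_km = rep(0, n),
             start_date = start,
             end_date = start + lengths - 1,
             on_road = rep_len(on_road, n), paired = 0,
             team = rep_len(team, n))
}

empty_detections <- function() {
  data.frame(station_id = character(0), species = character(0),
             timestamp = character(0))
}

# A small detection dataset with two species over four stations
tiny_dataset <- function() {
  dep <- make_deployments(c(5, 5, 5, 5))
  det <- data.frame(
    station_id = c("st001", "st001", "st002", "st003"),
    species = c("civet", "civet", "genet", "civet"),
    timestamp = c("2007-01-01 20:00:00", "2007-01-03 04:00:00",
                  "2007-01-02 22:10:00", "2007-01-05 01:00:00"))
  build_detection_dataset(det, dep)
}

# Minimal hand-built fit object for summary/table functions that only touch
# draws, spec and species
make_fake_fit <- function(draws, spec, species, selection = TRUE) {
  structure(list(draws = draws, chain = rep(1L, nrow(draws)),
                 species = species, spec = spec,
                 cfg = mcmc_config(n_chains = 1, n_iter = nrow(draws),
                                   n_burnin = 0, thin = 1),
                 selection = selection, fixed_hyper = FALSE,
                 accept_rate = 0.44),
            class = "commoccu_fit")
}

# Independent oracle: dense grid quadrature of the exact single-species
# posterior under fixed hyper-parameters (no covariates). Returns posterior
# means of psi = ilogit(phi) and p = ilogit(eta). Never calls the sampler.
quadrature_psi_p <- function(y, k, mu_phi, mu_eta, sig_phi, sig_eta, rho,
                             lim = 8, step = 0.04) {
  g <- seq(-lim, lim, by = step)
  phi <- matrix(g, length(g), length(g))
  eta <- matrix(g, length(g), length(g), byrow = TRUE)
  zx <- (phi - mu_phi) / sig_phi
  zy <- (eta - mu_eta) / sig_eta
  logprior <- -(zx^2 - 2 * rho * zx * zy + zy^2) / (2 * (1 - rho^2))
  psi <- plogis(phi); p <- plogis(eta)
  loglik <- 0
  for (j in seq_along(y)) {
    lik_j <- psi * dbinom(y[j], k[j], p) + (1 - psi) * (y[j] == 0)
    loglik <- loglik + log(lik_j)
  }
  wgt <- exp(logprior + loglik - max(logprior + loglik))
  wgt <- wgt / sum(wgt)
  list(psi = sum(wgt * psi), p = sum(wgt * p))
}

# One small selection fit shared across selection/report tests (computed at
# most once per test run)
.fit_cache <- new.env(parent = emptyenv())
small_selection_fit <- function() {
  if (!is.null(.fit_cache$fit)) return(.fit_cache$fit)
  cfg <- generator_config(
    seed = 11, n_species = 4, n_sites = 80,
    occ_covariates = list(strong = list(mu = 1.5, sigma = 0.3),
                          weak = list(mu = 0, sigma = 0.2)),
    det_covariates = list(road = list(mu = 0.8, sigma = 0.3,
                                      binary = TRUE, prob = 0.5)),
    mu_phi = 0, sigma_phi = 0.8, mu_eta = -0.5, sigma_eta = 0.5)
  sim <- simulate_community_data(cfg)
  spec <- community_model_spec(c("strong", "weak"), "road")
  fit <- run_mcmc(sim$data, sim$covariates, spec,
                  mcmc_config(n_chains = 2, n_iter = 1500, n_burnin = 500,
                              thin = 3, seed = 42),
                  selection = TRUE)
  .fit_cache$fit <- fit
  .fit_cache$sim <- sim
  fit
}
small_selection_sim <- function() {
  small_selection_fit()
  .fit_cache$sim
}
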