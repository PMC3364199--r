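test_that("occurrence and detection probabilities follow the logit-linear form", {
  eff <- list(phi = 0, alpha = numeric(0), eta = 0, beta = numeric(0))
  expect_equal(occurrence_prob(eff, numeric(0)), 0.5)
  expect_equal(detection_prob(eff, numeric(0)), 0.5)

  eff2 <- list(phi = 0, alpha = 1)
  expect_equal(occurrence_prob(eff2, 1), plogis(1))
  eff3 <- list(eta = -1, beta = 0.5)
  expect_equal(detection_prob(eff3, 2), 0.5)

  # strictly monotone in each coefficient x covariate product
  psis <- sapply(seq(-3, 3, 0.5), function(a)
    occurrence_prob(list(phi = 0.2, alpha = a), 1.5))
  expect_true(all(diff(psis) > 0))
  ps <- sapply(seq(-3, 3, 0.5), function(phi)
    occurrence_prob(list(phi = phi, alpha = numeric(0)), numeric(0)))
  expect_true(all(diff(ps) > 0))

  expect_error(occurrence_prob(eff2, c(1, 2)), "length")
  expect_error(detection_prob(eff3, numeric(0)), "length")
})

test_that("autocovariate is the normalized inverse-distance neighbour mean", {
  coords <- rbind(c(0, 0), c(1, 0), c(2, 0), c(30, 30))
  g <- neighborhood_graph(coords, radius = 5)
  # weights are normalized and never include self
  for (j in 1:3) {
    expect_false(j %in% g$idx[[j]])
    expect_equal(sum(g$w[[j]]), 1)
  }
  expect_length(g$idx[[4]], 0)

  # site 1: neighbours at 1 km (z=1) and 2 km (z=0) -> (1)/(1 + 1/2) = 2/3
  z <- c(0, 1, 0, 1)
  expect_equal(autocovariate(z, g, 1), 2 / 3)
  expect_equal(autocovariate(z, g, 4), 0)          # empty neighbourhood
  expect_equal(autocovariate(c(0, 1, 1, 0), g, 1), 1)  # all neighbours present

  # equidistant neighbours reduce to the plain mean
  sq <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  gs <- neighborhood_graph(sq, radius = 2)
  zs <- c(0, 1, 0, 1, 1)
  expect_equal(autocovariate(zs, gs, 1), mean(zs[2:5]))

  A <- autocovariate_matrix(rbind(z, 1 - z), g)
  expect_true(all(A >= 0 & A <= 1))
  expect_equal(A[1, 1], 2 / 3)
})

test_that("marginal likelihood and z conditional have their closed forms", {
  expect_equal(site_species_loglik(0, 2, 0.5, 0.5), log(0.625))
  expect_equal(site_species_loglik(1, 1, 1, 0.3), log(0.3))
  expect_equal(site_species_loglik(0, 3, 0, 0.4), 0)
  expect_error(site_species_loglik(4, 3, 0.5, 0.5), "y <= k")

  expect_equal(z_conditional(0, 1, 0.5, 0.5), 1 / 3)
  expect_equal(z_conditional(0, 10, 0.37, 0), 0.37)     # p = 0: prior
  expect_equal(z_conditional(2, 5, 0.2, 0.1), 1)        # detection -> present
  expect_lt(z_conditional(0, 500, 0.5, 0.2), 1e-20)     # k large: absent
})

test_that("likelihood normalizes and z conditional obeys Bayes by enumeration", {
  for (k in c(1, 3, 7, 10)) {
    for (psi in c(0.05, 0.5, 0.93)) {
      for (p in c(0.1, 0.45, 0.8)) {
        tot <- sum(exp(sapply(0:k, site_species_loglik, k = k,
                              psi = psi, p = p)))
        expect_equal(tot, 1, tolerance = 1e-12)
        # Bayes by direct enumeration of the two mixture components
        num <- psi * dbinom(0, k, p)
        expect_equal(z_conditional(0, k, psi, p), num / (num + (1 - psi)),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("community prior density couples intercepts through rho", {
  hyper <- list(mu_phi = 0.2, sigma_phi = 1.1, mu_eta = -0.4, sigma_eta = 0.7,
                rho = 0, mu_alpha = c(0, 1), sigma_alpha = c(1, 0.5))
  eff <- list(phi = 0.5, eta = -1, alpha = c(0.3, 0.8))
  # rho = 0 factorizes into independent normals
  expect_equal(
    species_effects_prior_logpdf(eff, hyper),
    dnorm(0.5, 0.2, 1.1, log = TRUE) + dnorm(-1, -0.4, 0.7, log = TRUE) +
      sum(dnorm(c(0.3, 0.8), c(0, 1), c(1, 0.5), log = TRUE)))
  # symmetry about the mean when rho = 0
  effp <- list(phi = 0.2 + 0.7, eta = -1)
  effm <- list(phi = 0.2 - 0.7, eta = -1)
  expect_equal(species_effects_prior_logpdf(effp, hyper),
               species_effects_prior_logpdf(effm, hyper))
  # bivariate mode with unit sds and rho = 0.5: -log(2 pi sqrt(0.75))
  h2 <- list(mu_phi = 0, sigma_phi = 1, mu_eta = 0, sigma_eta = 1, rho = 0.5)
  expect_equal(species_effects_prior_logpdf(list(phi = 0, eta = 0), h2),
               -log(2 * pi * sqrt(0.75)))
})

test_that("candidate set size is 2^C over the selectable covariates", {
  full <- community_model_spec(
    occ_covariates = c("patrol", "hunting", "ndvi_s", "ndvi_i", "edge",
                       "river", "prey", "small_prey", "prey_cam",
                       "small_prey_cam"),
    det_covariates = c("road", "paired", "team", "hunting", "edge", "season"),
    autocov = TRUE)
  expect_equal(candidate_set_size(full), 131072)  # 2^17

  expect_equal(candidate_set_size(
    community_model_spec(character(0), character(0))), 1)
  expect_equal(candidate_set_size(
    community_model_spec(c("a", "b"), "c")), 8)
  # dropping redundant covariates from the selectable set shrinks the space
  expect_equal(candidate_set_size(
    community_model_spec(c("a", "b", "c"), "d",
                         selectable_occ = c("a", "b"))), 8)
})

test_that("model specification survives YAML and JSON round-trips", {
  spec <- community_model_spec(c("edge", "river"), c("road", "team"),
                               autocov = TRUE, autocov_radius = 5,
                               priors = list(mu_sd = 1.5),
                               selectable_occ = "edge")
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_model_spec(spec, path)
    expect_equal(read_model_spec(path), spec)
  }
})

test_that("unstandardized continuous covariates are refused by the model", {
  sim <- small_selection_sim()
  bad <- sim$covariates
  bad$strong <- bad$strong * 3 + 1
  spec <- community_model_spec(c("strong", "weak"), "road")
  expect_error(run_mcmc(sim$data, bad, spec,
                        mcmc_config(1, 20, 10, 1, seed = 1)),
               "standardize")
})
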