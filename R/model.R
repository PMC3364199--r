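#' Specify a community occupancy model
#'
#' Names the occurrence and detection covariates (columns of the site
#' covariate table), configures the auto-logistic spatial autocovariate, and
#' fixes the prior settings. Species-level coefficients are drawn from
#' community-level normal distributions; occurrence and detection intercepts
#' `(phi_i, eta_i)` share a bivariate normal prior with correlation `rho`.
#'
#' Default hyperpriors are weakly informative on the probability scale:
#' community means `~ Normal(0, sd 2)` on the logit scale, community sds
#' `~ half-Normal(0, sd 1.5)` truncated above 0.01, and
#' `rho ~ Uniform(-1, 1)`.
#'
#' @param occ_covariates character vector of occurrence covariate names.
#' @param det_covariates character vector of detection covariate names.
#' @param autocov include the spatial autocovariate in occurrence?
#' @param autocov_radius neighbourhood radius in km (default 5).
#' @param priors list overriding any of `mu_sd` (sd of the normal hyperprior
#'   on community means), `sigma_sd` (scale of the half-normal hyperprior on
#'   community sds), `sigma_min` (truncation), `w_prior` (prior inclusion
#'   probability of each covariate).
#' @param selectable_occ,selectable_det covariates subject to indicator
#'   selection (defaults: all of them). The autocovariate is selectable
#'   whenever `autocov` is TRUE.
#' @return a `community_model_spec`.
#' @export
community_model_spec <- function(occ_covariates, det_covariates,
                                 autocov = FALSE, autocov_radius = 5,
                                 priors = list(),
                                 selectable_occ = occ_covariates,
                                 selectable_det = det_covariates) {
  defaults <- list(mu_sd = 2, sigma_sd = 1.5, sigma_min = 0.01, w_prior = 0.5)
  pr <- utils::modifyList(defaults, priors)
  stopifnot(pr$mu_sd > 0, pr$sigma_sd > 0, pr$sigma_min > 0,
            pr$w_prior > 0, pr$w_prior < 1)
  if (!all(selectable_occ %in% occ_covariates) ||
      !all(selectable_det %in% det_covariates))
    fail("selectable covariates must be a subset of the model covariates")
  structure(list(occ_covariates = as.character(occ_covariates),
                 det_covariates = as.character(det_covariates),
                 autocov = isTRUE(autocov),
                 autocov_radius = autocov_radius,
                 priors = pr,
                 selectable_occ = as.character(selectable_occ),
                 selectable_det = as.character(selectable_det)),
            class = "community_model_spec")
}

#' Size of the candidate model set under indicator selection
#'
#' `2^C` where `C` counts the selectable occurrence covariates (including the
#' autocovariate when present) plus the selectable detection covariates.
#'
#' @param spec a `community_model_spec`.
#' @return number of candidate models.
#' @export
candidate_set_size <- function(spec) {
  stopifnot(inherits(spec, "community_model_spec"))
  C <- length(spec$selectable_occ) + length(spec$selectable_det) +
    as.integer(spec$autocov)
  2^C
}

#' Write / read a model specification (YAML or JSON)
#'
#' @param spec a `community_model_spec`.
#' @param path output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @export
write_model_spec <- function(spec, path) {
  obj <- unclass(spec)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(spec)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  community_model_spec(obj$occ_covariates, obj$det_covariates,
                       autocov = obj$autocov,
                       autocov_radius = obj$autocov_radius,
                       priors = obj$priors,
                       selectable_occ = obj$selectable_occ,
                       selectable_det = obj$selectable_det)
}

#' Per-species occurrence probability at a site
#'
#' `psi_ij = logit^-1(phi_i + alpha_i . x_j + delta_i * autocov_j)`.
#'
#' @param effects list with `phi` (scalar), `alpha` (coefficient vector) and
#'   optionally `delta` (autocovariate coefficient).
#' @param x occurrence covariate vector for the site (same length as `alpha`).
#' @param autocov autocovariate value (default 0).
#' @return occurrence probability in (0, 1).
#' @export
occurrence_prob <- function(effects, x = numeric(0), autocov = 0) {
  alpha <- effects$alpha %||% numeric(0)
  if (length(alpha) != length(x))
    fail("covariate vector length %d does not match %d coefficients",
         length(x), length(alpha))
  delta <- effects$delta %||% 0
  ilogit(effects$phi + sum(alpha * x) + delta * autocov)
}

#' Per-species detection probability at a site
#'
#' `p_ij = logit^-1(eta_i + beta_i . v_j)`.
#'
#' @param effects list with `eta` (scalar) and `beta` (coefficient vector).
#' @param v detection covariate vector for the site.
#' @return detection probability in (0, 1).
#' @export
detection_prob <- function(effects, v = numeric(0)) {
  beta <- effects$beta %||% numeric(0)
  if (length(beta) != length(v))
    fail("covariate vector length %d does not match %d coefficients",
         length(v), length(beta))
  ilogit(effects$eta + sum(beta * v))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the inverse-distance neighbourhood graph
#'
#' For each site, the neighbours within `radius` km, weighted proportionally
#' to 1/distance and normalized to sum to one. A site is never its own
#' neighbour; empty neighbourhoods are allowed.
#'
#' @param coords two-column matrix of site coordinates (km).
#' @param radius neighbourhood radius in km (default 5).
#' @return a `neighborhood_graph`: list with `idx` and `w` (lists of integer
#'   indices and weights per site) and the radius.
#' @export
neighborhood_graph <- function(coords, radius = 5) {
  coords <- as.matrix(coords)
  J <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  idx <- vector("list", J)
  w <- vector("list", J)
  for (j in seq_len(J)) {
    nb <- which(d[j, ] <= radius & seq_len(J) != j)
    idx[[j]] <- nb
    if (length(nb)) {
      iw <- 1 / pmax(d[j, nb], 1e-6)
      w[[j]] <- iw / sum(iw)
    } else w[[j]] <- numeric(0)
  }
  structure(list(idx = idx, w = w, radius = radius, J = J),
            class = "neighborhood_graph")
}

#' Spatial autocovariate of one species at one site
#'
#' Normalized inverse-distance weighted average of the species' current
#' occurrence state at neighbouring sites; 0 when the neighbourhood is empty.
#'
#' @param z_i binary occurrence vector of the species over all sites.
#' @param graph a [neighborhood_graph()].
#' @param j focal site index.
#' @return value in `[0, 1]`.
#' @export
autocovariate <- function(z_i, graph, j) {
  stopifnot(inherits(graph, "neighborhood_graph"), length(z_i) == graph$J)
  nb <- graph$idx[[j]]
  if (!length(nb)) return(0)
  sum(graph$w[[j]] * z_i[nb])
}

#' Autocovariate matrix for all species and sites
#'
#' @param z N x J binary occurrence matrix.
#' @param graph a [neighborhood_graph()].
#' @return N x J matrix of autocovariate values.
#' @export
autocovariate_matrix <- function(z, graph) {
  J <- ncol(z)
  stopifnot(graph$J == J)
  A <- matrix(0, nrow(z), J)
  for (j in seq_len(J)) {
    nb <- graph$idx[[j]]
    if (length(nb))
      A[, j] <- as.numeric(z[, nb, drop = FALSE] %*% graph$w[[j]])
  }
  A
}

#' Marginal log-likelihood of one species-site detection count
#'
#' The latent occurrence state is summed out:
#' `log[ psi * C(k, y) p^y (1-p)^(k-y) + (1-psi) * 1{y = 0} ]`.
#'
#' @param y detection-day count (0 <= y <= k).
#' @param k trap-days.
#' @param psi occurrence probability.
#' @param p per-day detection probability.
#' @return log-likelihood contribution.
#' @export
site_species_loglik <- function(y, k, psi, p) {
  if (y < 0 || y > k) fail("need 0 <= y <= k")
  if (psi < 0 || psi > 1 || p < 0 || p > 1) fail("psi and p must be in [0, 1]")
  lik <- psi * stats::dbinom(y, k, p) + (1 - psi) * (y == 0)
  log(lik)
}

#' Full conditional of the latent occurrence state
#'
#' `Pr(z = 1 | y, psi, p)`. For `y >= 1` presence is certain; for `y = 0`,
#' `psi (1-p)^k / (psi (1-p)^k + 1 - psi)`.
#'
#' @inheritParams site_species_loglik
#' @return posterior probability of presence.
#' @export
z_conditional <- function(y, k, psi, p) {
  if (y > 0) return(1)
  a <- psi * (1 - p)^k
  a / (a + (1 - psi))
}

#' Log-density of one species' effects under the community prior
#'
#' Independent normal priors for each slope coefficient, and a bivariate
#' normal with correlation `rho` for the occurrence/detection intercept pair
#' `(phi_i, eta_i)`.
#'
#' @param effects list with `phi`, `eta`, optionally `alpha`, `delta`, `beta`.
#' @param hyper list with `mu_phi`, `sigma_phi`, `mu_eta`, `sigma_eta`,
#'   `rho`, and per-coefficient `mu_alpha`, `sigma_alpha`, `mu_beta`,
#'   `sigma_beta`, `mu_delta`, `sigma_delta` as needed.
#' @return log prior density.
#' @export
species_effects_prior_logpdf <- function(effects, hyper) {
  stopifnot(hyper$sigma_phi > 0, hyper$sigma_eta > 0,
            hyper$rho > -1, hyper$rho < 1)
  lp <- dbvnorm(effects$phi, effects$eta, hyper$mu_phi, hyper$mu_eta,
                hyper$sigma_phi, hyper$sigma_eta, hyper$rho)
  if (!is.null(effects$alpha) && length(effects$alpha))
    lp <- lp + sum(stats::dnorm(effects$alpha, hyper$mu_alpha,
                                hyper$sigma_alpha, log = TRUE))
  if (!is.null(effects$delta))
    lp <- lp + stats::dnorm(effects$delta, hyper$mu_delta %||% 0,
                            hyper$sigma_delta %||% 1, log = TRUE)
  if (!is.null(effects$beta) && length(effects$beta))
    lp <- lp + sum(stats::dnorm(effects$beta, hyper$mu_beta,
                                hyper$sigma_beta, log = TRUE))
  lp
}

# Internal: bivariate normal log-density
dbvnorm <- function(x, y, mx, my, sx, sy, rho) {
  zx <- (x - mx) / sx
  zy <- (y - my) / sy
  q <- (zx^2 - 2 * rho * zx * zy + zy^2) / (1 - rho^2)
  -log(2 * pi) - log(sx * sy) - 0.5 * log(1 - rho^2) - q / 2
}

# Internal: validate that a covariate matrix is modelling-ready — every
# column either binary 0/1 or standardized to mean 0, variance 1
check_standardized <- function(X, tol = 1e-6) {
  for (j in seq_len(ncol(X))) {
    col <- X[, j]
    if (is_binary01(col)) next
    if (abs(mean(col)) > tol || abs(stats::var(col) - 1) > 1e-3)
      fail("covariate '%s' is neither binary nor standardized (mean %.3g, var %.3g); standardize it first",
           colnames(X)[j], mean(col), stats::var(col))
  }
  invisible(TRUE)
}
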