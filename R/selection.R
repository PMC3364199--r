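#' Posterior inclusion probabilities of covariates
#'
#' Mean of each community-level inclusion indicator over the retained draws:
#' the posterior probability that the covariate belongs to the best model.
#'
#' @param fit a `commoccu_fit` produced with `selection = TRUE`.
#' @return named numeric vector over `w_occ_*`, `w_det_*` (and `w_auto` when
#'   the autocovariate is in the model).
#' @export
inclusion_probabilities <- function(fit) {
  stopifnot(inherits(fit, "commoccu_fit"))
  if (!fit$selection) fail("model selection was not enabled for this fit")
  cols <- w_columns(fit)
  colMeans(fit$draws[, cols, drop = FALSE])
}

# Internal: names of the active inclusion-indicator columns
w_columns <- function(fit) {
  spec <- fit$spec
  cols <- c(paste0("w_occ_", spec$selectable_occ, recycle0 = TRUE),
            paste0("w_det_", spec$selectable_det, recycle0 = TRUE))
  if (spec$autocov) cols <- c(cols, "w_auto")
  cols
}

#' Posterior model table
#'
#' Tabulates the distinct inclusion-indicator patterns in the posterior
#' sample; each pattern's probability is its relative frequency. Patterns
#' are rendered as `psi(cov + cov) p(cov + cov)` formula strings (a dot for
#' the empty set) and sorted by probability, ties broken lexicographically
#' on the pattern.
#'
#' @param fit a `commoccu_fit` with selection enabled.
#' @return data frame with columns `model`, `probability`, `pattern`.
#' @export
posterior_model_table <- function(fit) {
  stopifnot(inherits(fit, "commoccu_fit"))
  if (!fit$selection) fail("model selection was not enabled for this fit")
  spec <- fit$spec
  cols <- w_columns(fit)
  W <- fit$draws[, cols, drop = FALSE]
  pat <- apply(W, 1, paste0, collapse = "")
  tab <- table(pat)
  prob <- as.numeric(tab) / length(pat)
  pats <- names(tab)
  ord <- order(-prob, pats)
  pats <- pats[ord]; prob <- prob[ord]

  occ_names <- spec$selectable_occ
  if (spec$autocov) occ_all <- c(occ_names, "autocov") else occ_all <- occ_names
  n_occ <- length(occ_names)
  n_det <- length(spec$selectable_det)
  render <- vapply(pats, function(s) {
    bits <- as.integer(strsplit(s, "")[[1]])
    occ_bits <- bits[seq_len(n_occ)]
    det_bits <- bits[n_occ + seq_len(n_det)]
    occ_on <- occ_names[occ_bits == 1]
    if (spec$autocov && bits[n_occ + n_det + 1] == 1)
      occ_on <- c(occ_on, "autocov")
    det_on <- spec$selectable_det[det_bits == 1]
    fmt <- function(v) if (length(v)) paste(v, collapse = " + ") else "."
    sprintf("psi(%s) p(%s)", fmt(occ_on), fmt(det_on))
  }, character(1))
  data.frame(model = unname(render), probability = prob, pattern = pats,
             row.names = NULL)
}

#' Model-averaged posterior summaries
#'
#' Posterior mean, sd and equal-tailed credible intervals (sample quantiles
#' with linear interpolation, type 7) for every stored parameter. For
#' covariate coefficients of a selection run, the summary is conditional on
#' inclusion: only draws with the corresponding `w = 1` contribute
#' (Kuo-Mallick model averaging). Species-level coefficient rows carry effect
#' flags: `+`/`-` when the 95% interval excludes zero, `(+)`/`(-)` when only
#' the 80% interval does.
#'
#' @param fit a `commoccu_fit`.
#' @param pars parameter names (default: all columns).
#' @return data frame with columns `parameter`, `mean`, `sd`, `lo95`, `up95`,
#'   `lo80`, `up80`, `n_draws`, `effect`.
#' @export
model_averaged_summary <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "commoccu_fit"))
  draws <- fit$draws
  if (nrow(draws) == 0) fail("empty posterior sample")
  if (is.null(pars)) pars <- colnames(draws)
  rows <- lapply(pars, function(pp) {
    x <- draws[, pp]
    wcol <- coefficient_indicator(fit, pp)
    if (!is.null(wcol)) {
      keep <- draws[, wcol] == 1
      if (!any(keep))
        return(data.frame(parameter = pp, mean = NA_real_, sd = NA_real_,
                          lo95 = NA_real_, up95 = NA_real_, lo80 = NA_real_,
                          up80 = NA_real_, n_draws = 0L,
                          effect = "not included"))
      x <- x[keep]
    }
    q <- stats::quantile(x, c(0.025, 0.975, 0.1, 0.9), names = FALSE, type = 7)
    eff <- ""
    if (grepl("^(alpha_|beta_|delta\\[|mu_occ_|mu_det_|mu_delta)", pp)) {
      if (q[1] > 0) eff <- "+" else if (q[2] < 0) eff <- "-"
      else if (q[3] > 0) eff <- "(+)" else if (q[4] < 0) eff <- "(-)"
    }
    data.frame(parameter = pp, mean = mean(x), sd = stats::sd(x),
               lo95 = q[1], up95 = q[2], lo80 = q[3], up80 = q[4],
               n_draws = length(x), effect = eff)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Internal: the inclusion-indicator column governing a coefficient column,
# or NULL if the parameter is not subject to selection
coefficient_indicator <- function(fit, par) {
  if (!fit$selection) return(NULL)
  spec <- fit$spec
  for (c in spec$selectable_occ) {
    if (grepl(paste0("^(alpha_|mu_occ_|sigma_occ_)", c, "($|\\[)"), par))
      return(paste0("w_occ_", c))
  }
  for (c in spec$selectable_det) {
    if (grepl(paste0("^(beta_|mu_det_|sigma_det_)", c, "($|\\[)"), par))
      return(paste0("w_det_", c))
  }
  if (spec$autocov && grepl("^(delta\\[|mu_delta|sigma_delta)", par))
    return("w_auto")
  NULL
}

#' Marginal posterior-mean occurrence curve for one covariate
#'
#' For a species and an occurrence covariate, the posterior mean of
#' `logit^-1(phi_i + alpha_ic * x)` over a grid of standardized covariate
#' values, holding all other covariates at their standardized mean (0). For
#' selection runs only draws including the covariate are used.
#'
#' @param fit a `commoccu_fit`.
#' @param species species name.
#' @param covariate occurrence covariate name.
#' @param grid numeric vector of standardized covariate values.
#' @return data frame with columns `x` and `psi`.
#' @export
predict_marginal_occurrence <- function(fit, species, covariate,
                                        grid = seq(-2, 2, length.out = 41)) {
  stopifnot(inherits(fit, "commoccu_fit"))
  if (!covariate %in% fit$spec$occ_covariates)
    fail("unknown occurrence covariate: %s", covariate)
  if (!species %in% fit$species) fail("unknown species: %s", species)
  phi <- fit$draws[, paste0("phi[", species, "]")]
  a <- fit$draws[, paste0("alpha_", covariate, "[", species, "]")]
  if (fit$selection && covariate %in% fit$spec$selectable_occ) {
    keep <- fit$draws[, paste0("w_occ_", covariate)] == 1
    if (!any(keep)) fail("covariate '%s' was never included", covariate)
    phi <- phi[keep]; a <- a[keep]
  }
  psi <- vapply(grid, function(x) mean(ilogit(phi + a * x)), numeric(1))
  data.frame(x = grid, psi = psi)
}

#' Relative bias of naive occupancy against model estimates
#'
#' Per species, `100 * (psi_hat - naive) / naive`, where `psi_hat` is the
#' posterior mean of the species' average occurrence probability across
#' sites. Positive values measure how strongly the uncorrected naive measure
#' understates occurrence.
#'
#' @param data the `detection_dataset` the model was fitted to.
#' @param fit the corresponding `commoccu_fit`.
#' @return data frame with `species`, `naive`, `psi_hat`, `bias_pct`, plus
#'   attribute `mean_bias_pct` (cross-species mean over defined values).
#' @export
naive_bias_report <- function(data, fit) {
  stopifnot(inherits(data, "detection_dataset"), inherits(fit, "commoccu_fit"))
  if (!identical(data$species, fit$species))
    fail("species sets of data and fit disagree")
  naive <- naive_occupancy(data)
  psi_hat <- colMeans(fit$draws[, paste0("psi_mean[", data$species, "]"),
                                drop = FALSE])
  bias <- ifelse(naive > 0, 100 * (psi_hat - naive) / naive, NA_real_)
  out <- data.frame(species = data$species, naive = as.numeric(naive),
                    psi_hat = as.numeric(psi_hat), bias_pct = as.numeric(bias))
  attr(out, "mean_bias_pct") <- mean(bias, na.rm = TRUE)
  out
}
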