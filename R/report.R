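#' Species summary table (naive occupancy, psi, p, effect flags)
#'
#' One row per species: the naive proportion of sites with a detection, the
#' posterior mean (sd) of occurrence and detection probability, and the
#' occurrence covariates whose species-level coefficient shows an effect
#' (95% credible interval excluding zero, or 80% in parentheses), with sign.
#'
#' @param data the fitted `detection_dataset`.
#' @param fit the corresponding `commoccu_fit`.
#' @param file optional CSV output path.
#' @return data frame with columns `species`, `naive`, `psi`, `psi_sd`, `p`,
#'   `p_sd`, `effects`.
#' @export
render_species_table <- function(data, fit, file = NULL) {
  stopifnot(inherits(data, "detection_dataset"), inherits(fit, "commoccu_fit"))
  naive <- naive_occupancy(data)
  sp <- data$species
  psi_cols <- paste0("psi_mean[", sp, "]")
  p_cols <- paste0("p_mean[", sp, "]")
  psi <- colMeans(fit$draws[, psi_cols, drop = FALSE])
  psi_sd <- apply(fit$draws[, psi_cols, drop = FALSE], 2, stats::sd)
  p <- colMeans(fit$draws[, p_cols, drop = FALSE])
  p_sd <- apply(fit$draws[, p_cols, drop = FALSE], 2, stats::sd)

  oc <- fit$spec$occ_covariates
  effects <- vapply(sp, function(s) {
    pars <- paste0("alpha_", oc, "[", s, "]")
    summ <- model_averaged_summary(fit, pars)
    flagged <- summ$effect != "" & summ$effect != "not included"
    if (!any(flagged)) return("")
    lab <- vapply(which(flagged), function(r) {
      sign <- if (grepl("\\+", summ$effect[r])) "+" else "-"
      paste0(oc[r], "(", sign, ")")
    }, character(1))
    paste(lab, collapse = ", ")
  }, character(1))

  out <- data.frame(species = sp, naive = as.numeric(naive),
                    psi = as.numeric(psi), psi_sd = as.numeric(psi_sd),
                    p = as.numeric(p), p_sd = as.numeric(p_sd),
                    effects = unname(effects))
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Ranked posterior model table as CSV
#'
#' Renders the output of [posterior_model_table()] (formula strings like
#' `psi(edge + river + small_prey) p(road + team)`, probabilities sorted
#' descending) and optionally writes it to file.
#'
#' @param model_table output of [posterior_model_table()] or a `commoccu_fit`
#'   (from which the table is computed).
#' @param file optional CSV output path.
#' @param top keep only the first `top` rows (default all).
#' @return the (possibly truncated) model table data frame.
#' @export
render_model_table <- function(model_table, file = NULL, top = NULL) {
  if (inherits(model_table, "commoccu_fit"))
    model_table <- posterior_model_table(model_table)
  stopifnot(is.data.frame(model_table))
  out <- model_table
  if (!is.null(top)) out <- out[seq_len(min(top, nrow(out))), , drop = FALSE]
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
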