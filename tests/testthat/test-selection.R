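# Hand-built fits give deterministic oracles for the summary machinery;
# the shared small_selection_fit() exercises the real sampler output.

fake_spec <- community_model_spec(c("edge", "river"), "team")

make_draws <- function(n, cols) {
  m <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  m
}

test_that("model table probabilities are relative pattern frequencies", {
  cols <- c("w_occ_edge", "w_occ_river", "w_det_team")
  draws <- make_draws(4, cols)
  draws[1:3, ] <- rep(c(1, 1, 1), each = 3)   # three draws of the full model
  draws[4, ] <- c(0, 1, 0)
  fit <- make_fake_fit(draws, fake_spec, c("a", "b"))
  tab <- posterior_model_table(fit)
  expect_equal(tab$probability[1], 0.75)
  expect_equal(tab$model[1], "psi(edge + river) p(team)")
  expect_equal(tab$model[2], "psi(river) p(.)")
  expect_equal(sum(tab$probability), 1)

  # single pattern: one row with probability 1; empty model renders as dots
  null_draws <- make_draws(5, cols)
  fitn <- make_fake_fit(null_draws, fake_spec, c("a", "b"))
  tabn <- posterior_model_table(fitn)
  expect_equal(nrow(tabn), 1)
  expect_equal(tabn$probability, 1)
  expect_equal(tabn$model, "psi(.) p(.)")

  # ranking is invariant to permuting the draws
  perm <- make_fake_fit(draws[sample(4), , drop = FALSE], fake_spec, c("a", "b"))
  expect_equal(posterior_model_table(perm), tab)
})

test_that("inclusion probabilities are indicator means, guarded by selection", {
  cols <- c("w_occ_edge", "w_occ_river", "w_det_team")
  draws <- make_draws(10, cols)
  draws[, "w_occ_edge"] <- rep(c(1, 0), 5)
  draws[, "w_occ_river"] <- 1
  fit <- make_fake_fit(draws, fake_spec, c("a", "b"))
  pr <- inclusion_probabilities(fit)
  expect_equal(unname(pr["w_occ_edge"]), 0.5)
  expect_equal(unname(pr["w_occ_river"]), 1.0)
  expect_equal(unname(pr["w_det_team"]), 0)

  off <- make_fake_fit(draws, fake_spec, c("a", "b"), selection = FALSE)
  expect_error(inclusion_probabilities(off), "not enabled")
  expect_error(posterior_model_table(off), "not enabled")
})

test_that("posterior summaries use equal-tailed interpolated quantiles", {
  cols <- c("mu_phi", "w_occ_edge", "mu_occ_edge")
  draws <- make_draws(100, cols)
  draws[, "mu_phi"] <- 1:100
  draws[, "w_occ_edge"] <- 1
  fit <- make_fake_fit(draws, fake_spec, c("a", "b"))
  s <- model_averaged_summary(fit, "mu_phi")
  expect_equal(s$lo95, 3.475)     # type-7 quantiles of 1..100
  expect_equal(s$up95, 97.525)
  expect_equal(s$mean, 50.5)

  # constant draws: degenerate interval
  draws2 <- make_draws(20, cols)
  draws2[, "mu_phi"] <- 4.2
  fitc <- make_fake_fit(draws2, fake_spec, c("a", "b"))
  sc <- model_averaged_summary(fitc, "mu_phi")
  expect_equal(sc$sd, 0)
  expect_equal(c(sc$lo95, sc$up95), c(4.2, 4.2))

  # symmetric draws straddle zero: no effect flag
  draws3 <- make_draws(200, cols)
  draws3[, "mu_occ_edge"] <- rep(c(-1, 1), 100)
  draws3[, "w_occ_edge"] <- 1
  s3 <- model_averaged_summary(make_fake_fit(draws3, fake_spec, c("a", "b")),
                               "mu_occ_edge")
  expect_equal(s3$effect, "")
  expect_lte(s3$lo95, 0); expect_gte(s3$up95, 0)
})

test_that("coefficient summaries condition on inclusion (Kuo-Mallick)", {
  cols <- c("w_occ_edge", "mu_occ_edge")
  draws <- make_draws(100, cols)
  draws[, "w_occ_edge"] <- rep(c(1, 0), 50)
  draws[, "mu_occ_edge"] <- ifelse(draws[, "w_occ_edge"] == 1, 2, -50)
  fit <- make_fake_fit(draws, fake_spec, c("a", "b"))
  s <- model_averaged_summary(fit, "mu_occ_edge")
  expect_equal(s$mean, 2)          # prior draws with w = 0 are excluded
  expect_equal(s$n_draws, 50L)
  expect_equal(s$effect, "+")

  draws0 <- make_draws(10, cols)   # never included
  draws0[, "mu_occ_edge"] <- 1
  s0 <- model_averaged_summary(make_fake_fit(draws0, fake_spec, c("a", "b")),
                               "mu_occ_edge")
  expect_equal(s0$effect, "not included")
  expect_equal(s0$n_draws, 0L)
})

test_that("marginal occurrence curves are posterior means over the grid", {
  cols <- c("phi[a]", "alpha_edge[a]", "w_occ_edge")
  draws <- make_draws(50, cols)
  draws[, "phi[a]"] <- -0.5
  draws[, "alpha_edge[a]"] <- 1.2
  draws[, "w_occ_edge"] <- 1
  fit <- make_fake_fit(draws, fake_spec, c("a", "b"))
  curve <- predict_marginal_occurrence(fit, "a", "edge", seq(-2, 2, 1))
  # degenerate posterior: curve equals the deterministic inverse logit
  expect_equal(curve$psi, plogis(-0.5 + 1.2 * curve$x))
  expect_true(all(diff(curve$psi) > 0))          # positive coefficient
  expect_equal(curve$psi[curve$x == 0], plogis(-0.5))
  expect_error(predict_marginal_occurrence(fit, "a", "nope"), "unknown")
})

test_that("naive bias report measures the detectability correction", {
  sim <- small_selection_sim()
  d <- sim$data
  sp <- d$species
  cols <- c(paste0("psi_mean[", sp, "]"))
  draws <- make_draws(10, cols)
  naive <- naive_occupancy(d)
  # psi equal to naive: zero bias; psi = 3 x naive: +200%
  draws[, ] <- rep(naive, each = 10)
  spec0 <- community_model_spec(character(0), character(0))
  f0 <- make_fake_fit(draws, spec0, sp, selection = FALSE)
  r0 <- naive_bias_report(d, f0)
  expect_equal(r0$bias_pct, rep(0, length(sp)))
  draws[, ] <- rep(3 * naive, each = 10)
  r3 <- naive_bias_report(d, make_fake_fit(draws, spec0, sp, selection = FALSE))
  expect_equal(r3$bias_pct, rep(200, length(sp)))
  expect_equal(attr(r3, "mean_bias_pct"), 200)

  # the published genet-like arithmetic: naive 0.246 vs psi-hat 0.263 is ~7%
  expect_equal(100 * (0.263 - 0.246) / 0.246, 6.9, tolerance = 0.02)
})

test_that("a planted strong effect wins the inclusion race in a real fit", {
  fit <- small_selection_fit()
  pr <- inclusion_probabilities(fit)
  expect_gte(pr[["w_occ_strong"]], max(pr[c("w_occ_weak")]))
  expect_gt(pr[["w_occ_strong"]], 0.8)
  tab <- posterior_model_table(fit)
  expect_equal(sum(tab$probability), 1, tolerance = 1e-9)
  expect_true(all(diff(tab$probability) <= 0))
})
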