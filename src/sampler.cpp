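// Metropolis-within-Gibbs sampler for the hierarchical multi-species
// occupancy model with Kuo-Mallick indicator-variable selection.
//
// Latent occurrence states z and inclusion indicators w are drawn from their
// full conditionals; species-level effects and community hyper-parameter
// scales use random-walk Metropolis (community means are conjugate normal
// and drawn by Gibbs). The spatial autocovariate is refreshed from the
// current z at the top of every sweep (auto-logistic approximation).
// Proposal scales adapt during burn-in only and are frozen afterwards.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double l1pe(double x) {
  return x > 0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}
static inline double ilogit_c(double x) {
  return x >= 0 ? 1.0 / (1.0 + std::exp(-x)) : std::exp(x) / (1.0 + std::exp(x));
}

struct Adapt {
  std::vector<double> step, acc;
  std::vector<int> n;
  void init(int m, double s0) { step.assign(m, s0); acc.assign(m, 0.0); n.assign(m, 0); }
  void tally(int i, bool accepted) { n[i]++; if (accepted) acc[i] += 1.0; }
  void adapt(int i) {
    if (n[i] == 0) return;
    double rate = acc[i] / n[i];
    step[i] *= std::exp(0.6 * (rate - 0.44));
    if (step[i] < 1e-3) step[i] = 1e-3;
    if (step[i] > 10.0) step[i] = 10.0;
    acc[i] = 0.0; n[i] = 0;
  }
};

// [[Rcpp::export]]
List run_chain_cpp(IntegerMatrix y, IntegerVector k,
                   NumericMatrix X, NumericMatrix V,
                   bool use_auto, List nb_idx, List nb_w,
                   List init, List priors,
                   bool fix_hyper, bool selection,
                   LogicalVector sel_occ, LogicalVector sel_det, bool sel_auto,
                   int n_iter, int n_burn, int thin) {
  const int N = y.nrow(), J = y.ncol();
  const int Co = X.ncol(), Cd = V.ncol();

  // --- state -----------------------------------------------------------
  NumericVector phi = clone(as<NumericVector>(init["phi"]));
  NumericVector eta = clone(as<NumericVector>(init["eta"]));
  NumericMatrix alpha = clone(as<NumericMatrix>(init["alpha"]));
  NumericMatrix beta = clone(as<NumericMatrix>(init["beta"]));
  NumericVector delta = clone(as<NumericVector>(init["delta"]));
  double mu_phi = init["mu_phi"], mu_eta = init["mu_eta"];
  double sig_phi = init["sigma_phi"], sig_eta = init["sigma_eta"];
  double rho = init["rho"];
  NumericVector mu_a = clone(as<NumericVector>(init["mu_alpha"]));
  NumericVector sig_a = clone(as<NumericVector>(init["sigma_alpha"]));
  NumericVector mu_b = clone(as<NumericVector>(init["mu_beta"]));
  NumericVector sig_b = clone(as<NumericVector>(init["sigma_beta"]));
  double mu_d = init["mu_delta"], sig_d = init["sigma_delta"];

  const double mu_sd = priors["mu_sd"], sigma_sd = priors["sigma_sd"];
  const double sigma_min = priors["sigma_min"], w_prior = priors["w_prior"];
  const double lodds_w = std::log(w_prior / (1.0 - w_prior));

  std::vector<int> w_occ(Co, 1), w_det(Cd, 1);
  int w_auto = 1;

  IntegerMatrix z(N, J);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < J; ++j)
      z(i, j) = y(i, j) > 0 ? 1 : (unif_rand() < 0.5 ? 1 : 0);

  NumericMatrix A(N, J);    // autocovariate
  NumericMatrix lpo(N, J);  // occurrence linear predictor
  NumericMatrix lpd(N, J);  // detection linear predictor

  // --- helpers ---------------------------------------------------------
  auto refresh_auto = [&]() {
    if (!use_auto) return;
    for (int j = 0; j < J; ++j) {
      IntegerVector nb = nb_idx[j];
      NumericVector wj = nb_w[j];
      for (int i = 0; i < N; ++i) {
        double a = 0.0;
        for (int g = 0; g < nb.size(); ++g) a += wj[g] * z(i, nb[g] - 1);
        A(i, j) = a;
      }
    }
  };
  auto refresh_lp = [&]() {
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < J; ++j) {
        double lo = phi[i];
        for (int c = 0; c < Co; ++c)
          if (w_occ[c]) lo += alpha(i, c) * X(j, c);
        if (use_auto && w_auto) lo += delta[i] * A(i, j);
        lpo(i, j) = lo;
        double ld = eta[i];
        for (int c = 0; c < Cd; ++c)
          if (w_det[c]) ld += beta(i, c) * V(j, c);
        lpd(i, j) = ld;
      }
  };
  // Bernoulli(z) log-likelihood of species i's occurrence row under lpo
  auto ll_occ = [&](int i) {
    double s = 0.0;
    for (int j = 0; j < J; ++j)
      s += z(i, j) ? -l1pe(-lpo(i, j)) : -l1pe(lpo(i, j));
    return s;
  };
  // Binomial detection log-likelihood of species i (occupied sites only)
  auto ll_det = [&](int i) {
    double s = 0.0;
    for (int j = 0; j < J; ++j)
      if (z(i, j) == 1 && k[j] > 0)
        s += y(i, j) * (-l1pe(-lpd(i, j)))
           + (k[j] - y(i, j)) * (-l1pe(lpd(i, j)));
    return s;
  };
  // bivariate normal log prior of (phi_i, eta_i)
  auto lp_int = [&](double ph, double et) {
    double zx = (ph - mu_phi) / sig_phi, zy = (et - mu_eta) / sig_eta;
    double q = (zx * zx - 2.0 * rho * zx * zy + zy * zy) / (1.0 - rho * rho);
    return -std::log(sig_phi * sig_eta) - 0.5 * std::log(1.0 - rho * rho) - 0.5 * q;
  };
  auto lp_norm = [](double x, double m, double s) {
    double zz = (x - m) / s;
    return -std::log(s) - 0.5 * zz * zz;
  };
  auto lp_halfnorm = [&](double s) {
    return -0.5 * (s / sigma_sd) * (s / sigma_sd);
  };

  // --- adaptation ------------------------------------------------------
  Adapt ad_phi, ad_eta, ad_alpha, ad_beta, ad_delta, ad_hyper;
  ad_phi.init(N, 0.3); ad_eta.init(N, 0.3);
  ad_alpha.init(N * Co, 0.3); ad_beta.init(N * Cd, 0.3);
  ad_delta.init(N, 0.5);
  ad_hyper.init(3 + Co + Cd + 2, 0.3); // sig_phi, sig_eta, rho, sig_a[], sig_b[], sig_d, spare

  refresh_auto();
  refresh_lp();

  // initial log-posterior finiteness check
  {
    double lp0 = 0.0;
    for (int i = 0; i < N; ++i) lp0 += ll_occ(i) + ll_det(i) + lp_int(phi[i], eta[i]);
    if (!std::isfinite(lp0))
      stop("non-finite log-posterior at initialization (check inits: mu_phi=%f, mu_eta=%f, sigma_phi=%f, sigma_eta=%f, rho=%f)",
           mu_phi, mu_eta, sig_phi, sig_eta, rho);
  }

  // --- storage ---------------------------------------------------------
  const int n_keep = n_iter / thin;
  const int P_hyper = 5 + 2 * Co + 2 * Cd + 2;
  const int P_w = Co + Cd + 1;
  const int P_sp = N * (2 + Co + Cd + 1) + 3 * N;
  NumericMatrix out(n_keep, P_hyper + P_w + P_sp);
  int stored = 0;

  long long acc_cont = 0, try_cont = 0;

  // ======================================================================
  for (int iter = 0; iter < n_burn + n_iter; ++iter) {
    if (iter % 256 == 0) Rcpp::checkUserInterrupt();
    const bool burning = iter < n_burn;

    refresh_auto();
    refresh_lp();

    // ---- latent occurrence states ----
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < J; ++j) {
        if (y(i, j) > 0) { z(i, j) = 1; continue; }
        double psi = ilogit_c(lpo(i, j));
        double pz;
        if (k[j] == 0) pz = psi;
        else {
          double lcond = std::log(psi) - k[j] * l1pe(lpd(i, j));
          double l0 = std::log(1.0 - psi);
          pz = 1.0 / (1.0 + std::exp(l0 - lcond));
        }
        z(i, j) = unif_rand() < pz ? 1 : 0;
      }

    // ---- species-level effects ----
    for (int i = 0; i < N; ++i) {
      double llo = ll_occ(i), lld = ll_det(i);

      // phi_i
      {
        double prop = phi[i] + ad_phi.step[i] * norm_rand();
        double save = phi[i];
        for (int j = 0; j < J; ++j) lpo(i, j) += prop - save;
        double llo_new = ll_occ(i);
        double lr = llo_new - llo + lp_int(prop, eta[i]) - lp_int(save, eta[i]);
        bool ok = std::log(unif_rand()) < lr;
        if (ok) { phi[i] = prop; llo = llo_new; }
        else for (int j = 0; j < J; ++j) lpo(i, j) -= prop - save;
        if (burning) { ad_phi.tally(i, ok); if ((iter + 1) % 50 == 0) ad_phi.adapt(i); }
        else { try_cont++; if (ok) acc_cont++; }
      }
      // eta_i
      {
        double prop = eta[i] + ad_eta.step[i] * norm_rand();
        double save = eta[i];
        for (int j = 0; j < J; ++j) lpd(i, j) += prop - save;
        double lld_new = ll_det(i);
        double lr = lld_new - lld + lp_int(phi[i], prop) - lp_int(phi[i], save);
        bool ok = std::log(unif_rand()) < lr;
        if (ok) { eta[i] = prop; lld = lld_new; }
        else for (int j = 0; j < J; ++j) lpd(i, j) -= prop - save;
        if (burning) { ad_eta.tally(i, ok); if ((iter + 1) % 50 == 0) ad_eta.adapt(i); }
        else { try_cont++; if (ok) acc_cont++; }
      }
      // occurrence slopes
      for (int c = 0; c < Co; ++c) {
        if (!w_occ[c]) { // dropped covariate: coefficient refreshed from prior
          alpha(i, c) = mu_a[c] + sig_a[c] * norm_rand();
          continue;
        }
        int id = i * Co + c;
        double prop = alpha(i, c) + ad_alpha.step[id] * norm_rand();
        double save = alpha(i, c);
        for (int j = 0; j < J; ++j) lpo(i, j) += (prop - save) * X(j, c);
        double llo_new = ll_occ(i);
        double lr = llo_new - llo + lp_norm(prop, mu_a[c], sig_a[c])
                  - lp_norm(save, mu_a[c], sig_a[c]);
        bool ok = std::log(unif_rand()) < lr;
        if (ok) { alpha(i, c) = prop; llo = llo_new; }
        else for (int j = 0; j < J; ++j) lpo(i, j) -= (prop - save) * X(j, c);
        if (burning) { ad_alpha.tally(id, ok); if ((iter + 1) % 50 == 0) ad_alpha.adapt(id); }
        else { try_cont++; if (ok) acc_cont++; }
      }
      // autocovariate coefficient
      if (use_auto) {
        if (!w_auto) {
          delta[i] = mu_d + sig_d * norm_rand();
        } else {
          double prop = delta[i] + ad_delta.step[i] * norm_rand();
          double save = delta[i];
          for (int j = 0; j < J; ++j) lpo(i, j) += (prop - save) * A(i, j);
          double llo_new = ll_occ(i);
          double lr = llo_new - llo + lp_norm(prop, mu_d, sig_d)
                    - lp_norm(save, mu_d, sig_d);
          bool ok = std::log(unif_rand()) < lr;
          if (ok) { delta[i] = prop; llo = llo_new; }
          else for (int j = 0; j < J; ++j) lpo(i, j) -= (prop - save) * A(i, j);
          if (burning) { ad_delta.tally(i, ok); if ((iter + 1) % 50 == 0) ad_delta.adapt(i); }
          else { try_cont++; if (ok) acc_cont++; }
        }
      }
      // detection slopes
      for (int c = 0; c < Cd; ++c) {
        if (!w_det[c]) {
          beta(i, c) = mu_b[c] + sig_b[c] * norm_rand();
          continue;
        }
        int id = i * Cd + c;
        double prop = beta(i, c) + ad_beta.step[id] * norm_rand();
        double save = beta(i, c);
        for (int j = 0; j < J; ++j) lpd(i, j) += (prop - save) * V(j, c);
        double lld_new = ll_det(i);
        double lr = lld_new - lld + lp_norm(prop, mu_b[c], sig_b[c])
                  - lp_norm(save, mu_b[c], sig_b[c]);
        bool ok = std::log(unif_rand()) < lr;
        if (ok) { beta(i, c) = prop; lld = lld_new; }
        else for (int j = 0; j < J; ++j) lpd(i, j) -= (prop - save) * V(j, c);
        if (burning) { ad_beta.tally(id, ok); if ((iter + 1) % 50 == 0) ad_beta.adapt(id); }
        else { try_cont++; if (ok) acc_cont++; }
      }
    }

    // ---- inclusion indicators (community-level Gibbs) ----
    if (selection) {
      for (int c = 0; c < Co; ++c) {
        if (!sel_occ[c]) continue;
        double l1 = 0.0, l0 = 0.0;
        for (int i = 0; i < N; ++i)
          for (int j = 0; j < J; ++j) {
            double base = lpo(i, j) - (w_occ[c] ? alpha(i, c) * X(j, c) : 0.0);
            double with1 = base + alpha(i, c) * X(j, c);
            if (z(i, j)) { l1 += -l1pe(-with1); l0 += -l1pe(-base); }
            else { l1 += -l1pe(with1); l0 += -l1pe(base); }
          }
        double p1 = 1.0 / (1.0 + std::exp(-(l1 - l0 + lodds_w)));
        int w_new = unif_rand() < p1 ? 1 : 0;
        if (w_new != w_occ[c]) {
          double sgn = w_new ? 1.0 : -1.0;
          for (int i = 0; i < N; ++i)
            for (int j = 0; j < J; ++j) lpo(i, j) += sgn * alpha(i, c) * X(j, c);
          w_occ[c] = w_new;
        }
      }
      if (use_auto && sel_auto) {
        double l1 = 0.0, l0 = 0.0;
        for (int i = 0; i < N; ++i)
          for (int j = 0; j < J; ++j) {
            double base = lpo(i, j) - (w_auto ? delta[i] * A(i, j) : 0.0);
            double with1 = base + delta[i] * A(i, j);
            if (z(i, j)) { l1 += -l1pe(-with1); l0 += -l1pe(-base); }
            else { l1 += -l1pe(with1); l0 += -l1pe(base); }
          }
        double p1 = 1.0 / (1.0 + std::exp(-(l1 - l0 + lodds_w)));
        int w_new = unif_rand() < p1 ? 1 : 0;
        if (w_new != w_auto) {
          double sgn = w_new ? 1.0 : -1.0;
          for (int i = 0; i < N; ++i)
            for (int j = 0; j < J; ++j) lpo(i, j) += sgn * delta[i] * A(i, j);
          w_auto = w_new;
        }
      }
      for (int c = 0; c < Cd; ++c) {
        if (!sel_det[c]) continue;
        double l1 = 0.0, l0 = 0.0;
        for (int i = 0; i < N; ++i)
          for (int j = 0; j < J; ++j) {
            if (z(i, j) != 1 || k[j] == 0) continue;
            double base = lpd(i, j) - (w_det[c] ? beta(i, c) * V(j, c) : 0.0);
            double with1 = base + beta(i, c) * V(j, c);
            l1 += y(i, j) * (-l1pe(-with1)) + (k[j] - y(i, j)) * (-l1pe(with1));
            l0 += y(i, j) * (-l1pe(-base)) + (k[j] - y(i, j)) * (-l1pe(base));
          }
        double p1 = 1.0 / (1.0 + std::exp(-(l1 - l0 + lodds_w)));
        int w_new = unif_rand() < p1 ? 1 : 0;
        if (w_new != w_det[c]) {
          double sgn = w_new ? 1.0 : -1.0;
          for (int i = 0; i < N; ++i)
            for (int j = 0; j < J; ++j) lpd(i, j) += sgn * beta(i, c) * V(j, c);
          w_det[c] = w_new;
        }
      }
    }

    // ---- community hyper-parameters ----
    if (!fix_hyper) {
      // conjugate Gibbs for means
      {
        double s2 = sig_phi * sig_phi * (1.0 - rho * rho);
        double sum_r = 0.0;
        for (int i = 0; i < N; ++i)
          sum_r += phi[i] - rho * (sig_phi / sig_eta) * (eta[i] - mu_eta);
        double prec = N / s2 + 1.0 / (mu_sd * mu_sd);
        mu_phi = sum_r / s2 / prec + std::sqrt(1.0 / prec) * norm_rand();
      }
      {
        double s2 = sig_eta * sig_eta * (1.0 - rho * rho);
        double sum_r = 0.0;
        for (int i = 0; i < N; ++i)
          sum_r += eta[i] - rho * (sig_eta / sig_phi) * (phi[i] - mu_phi);
        double prec = N / s2 + 1.0 / (mu_sd * mu_sd);
        mu_eta = sum_r / s2 / prec + std::sqrt(1.0 / prec) * norm_rand();
      }
      for (int c = 0; c < Co; ++c) {
        double s2 = sig_a[c] * sig_a[c], sum = 0.0;
        for (int i = 0; i < N; ++i) sum += alpha(i, c);
        double prec = N / s2 + 1.0 / (mu_sd * mu_sd);
        mu_a[c] = sum / s2 / prec + std::sqrt(1.0 / prec) * norm_rand();
      }
      for (int c = 0; c < Cd; ++c) {
        double s2 = sig_b[c] * sig_b[c], sum = 0.0;
        for (int i = 0; i < N; ++i) sum += beta(i, c);
        double prec = N / s2 + 1.0 / (mu_sd * mu_sd);
        mu_b[c] = sum / s2 / prec + std::sqrt(1.0 / prec) * norm_rand();
      }
      if (use_auto) {
        double s2 = sig_d * sig_d, sum = 0.0;
        for (int i = 0; i < N; ++i) sum += delta[i];
        double prec = N / s2 + 1.0 / (mu_sd * mu_sd);
        mu_d = sum / s2 / prec + std::sqrt(1.0 / prec) * norm_rand();
      }

      // RW-MH for scales (log scale) and rho
      auto pair_lp = [&]() {
        double s = 0.0;
        for (int i = 0; i < N; ++i) s += lp_int(phi[i], eta[i]);
        return s;
      };
      int h = 0;
      { // sig_phi
        double save = sig_phi, lp_old = pair_lp() + lp_halfnorm(save);
        double prop = save * std::exp(ad_hyper.step[h] * norm_rand());
        if (prop > sigma_min) {
          sig_phi = prop;
          double lr = pair_lp() + lp_halfnorm(prop) - lp_old
                    + std::log(prop) - std::log(save); // Jacobian
          bool ok = std::log(unif_rand()) < lr;
          if (!ok) sig_phi = save;
          if (burning) { ad_hyper.tally(h, ok); if ((iter + 1) % 50 == 0) ad_hyper.adapt(h); }
        }
        h++;
      }
      { // sig_eta
        double save = sig_eta, lp_old = pair_lp() + lp_halfnorm(save);
        double prop = save * std::exp(ad_hyper.step[h] * norm_rand());
        if (prop > sigma_min) {
          sig_eta = prop;
          double lr = pair_lp() + lp_halfnorm(prop) - lp_old
                    + std::log(prop) - std::log(save);
          bool ok = std::log(unif_rand()) < lr;
          if (!ok) sig_eta = save;
          if (burning) { ad_hyper.tally(h, ok); if ((iter + 1) % 50 == 0) ad_hyper.adapt(h); }
        }
        h++;
      }
      { // rho (uniform prior)
        double save = rho, lp_old = pair_lp();
        double prop = save + ad_hyper.step[h] * norm_rand();
        if (prop > -0.995 && prop < 0.995) {
          rho = prop;
          double lr = pair_lp() - lp_old;
          bool ok = std::log(unif_rand()) < lr;
          if (!ok) rho = save;
          if (burning) { ad_hyper.tally(h, ok); if ((iter + 1) % 50 == 0) ad_hyper.adapt(h); }
        }
        h++;
      }
      for (int c = 0; c < Co; ++c) { // sig_alpha
        double save = sig_a[c];
        double lp_old = lp_halfnorm(save);
        for (int i = 0; i < N; ++i) lp_old += lp_norm(alpha(i, c), mu_a[c], save);
        double prop = save * std::exp(ad_hyper.step[h] * norm_rand());
        if (prop > sigma_min) {
          double lp_new = lp_halfnorm(prop);
          for (int i = 0; i < N; ++i) lp_new += lp_norm(alpha(i, c), mu_a[c], prop);
          double lr = lp_new - lp_old + std::log(prop) - std::log(save);
          bool ok = std::log(unif_rand()) < lr;
          if (ok) sig_a[c] = prop;
          if (burning) { ad_hyper.tally(h, ok); if ((iter + 1) % 50 == 0) ad_hyper.adapt(h); }
        }
        h++;
      }
      for (int c = 0; c < Cd; ++c) { // sig_beta
        double save = sig_b[c];
        double lp_old = lp_halfnorm(save);
        for (int i = 0; i < N; ++i) lp_old += lp_norm(beta(i, c), mu_b[c], save);
        double prop = save * std::exp(ad_hyper.step[h] * norm_rand());
        if (prop > sigma_min) {
          double lp_new = lp_halfnorm(prop);
          for (int i = 0; i < N; ++i) lp_new += lp_norm(beta(i, c), mu_b[c], prop);
          double lr = lp_new - lp_old + std::log(prop) - std::log(save);
          bool ok = std::log(unif_rand()) < lr;
          if (ok) sig_b[c] = prop;
          if (burning) { ad_hyper.tally(h, ok); if ((iter + 1) % 50 == 0) ad_hyper.adapt(h); }
        }
        h++;
      }
      if (use_auto) { // sig_delta
        double save = sig_d;
        double lp_old = lp_halfnorm(save);
        for (int i = 0; i < N; ++i) lp_old += lp_norm(delta[i], mu_d, save);
        double prop = save * std::exp(ad_hyper.step[h] * norm_rand());
        if (prop > sigma_min) {
          double lp_new = lp_halfnorm(prop);
          for (int i = 0; i < N; ++i) lp_new += lp_norm(delta[i], mu_d, prop);
          double lr = lp_new - lp_old + std::log(prop) - std::log(save);
          bool ok = std::log(unif_rand()) < lr;
          if (ok) sig_d = prop;
          if (burning) { ad_hyper.tally(h, ok); if ((iter + 1) % 50 == 0) ad_hyper.adapt(h); }
        }
        h++;
      }
    }

    // ---- record ----
    if (!burning && ((iter - n_burn + 1) % thin == 0) && stored < n_keep) {
      int c0 = 0;
      out(stored, c0++) = mu_phi; out(stored, c0++) = mu_eta;
      out(stored, c0++) = sig_phi; out(stored, c0++) = sig_eta;
      out(stored, c0++) = rho;
      for (int c = 0; c < Co; ++c) { out(stored, c0++) = mu_a[c]; out(stored, c0++) = sig_a[c]; }
      for (int c = 0; c < Cd; ++c) { out(stored, c0++) = mu_b[c]; out(stored, c0++) = sig_b[c]; }
      out(stored, c0++) = mu_d; out(stored, c0++) = sig_d;
      for (int c = 0; c < Co; ++c) out(stored, c0++) = w_occ[c];
      for (int c = 0; c < Cd; ++c) out(stored, c0++) = w_det[c];
      out(stored, c0++) = w_auto;
      for (int i = 0; i < N; ++i) {
        out(stored, c0++) = phi[i];
        out(stored, c0++) = eta[i];
        for (int c = 0; c < Co; ++c) out(stored, c0++) = alpha(i, c);
        for (int c = 0; c < Cd; ++c) out(stored, c0++) = beta(i, c);
        out(stored, c0++) = delta[i];
      }
      for (int i = 0; i < N; ++i) { // derived per-species summaries
        double ps = 0.0, pd = 0.0, zb = 0.0;
        for (int j = 0; j < J; ++j) {
          ps += ilogit_c(lpo(i, j));
          pd += ilogit_c(lpd(i, j));
          zb += z(i, j);
        }
        out(stored, c0++) = ps / J;
        out(stored, c0++) = pd / J;
        out(stored, c0++) = zb / J;
      }
      stored++;
    }
  }

  double acc_rate = try_cont > 0 ? (double)acc_cont / try_cont : NA_REAL;
  return List::create(_["draws"] = out, _["accept_rate"] = acc_rate,
                      _["n_kept"] = stored);
}
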