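#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Half-normal / Bernoulli encounter model on a discrete state space.
// With hazard h = lambda0 * e, e = exp(-d^2 / (2 sigma^2)) per occasion,
// p = 1 - exp(-h), so log(1-p) = -h exactly and log(p) = log(-expm1(-h)).
//
// The sampler caches, for the current sigma: e (G x J) and its row sums E,
// and log(p) on the columns that hold captures (lp_cap). A lambda0 proposal
// rescales hazards without any new exp grid; a sigma proposal evaluates the
// likelihood only at the currently occupied centers, and full grids are
// refreshed only on acceptance.

// [[Rcpp::export]]
NumericMatrix secr_loglik_cpp(IntegerMatrix nij, int K, NumericMatrix d2,
                              double sigma, double lam0) {
  // direct evaluation used by the wrapper and the likelihood-kernel tests
  const int G = d2.nrow(), J = d2.ncol(), n = nij.nrow();
  NumericMatrix out(n, G);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int g = 0; g < G; ++g) {
    for (int i = 0; i < n; ++i) {
      double ll = 0.0;
      for (int j = 0; j < J; ++j) {
        double h = lam0 * std::exp(-d2(g, j) * inv2s2);
        ll += -K * h;
        if (nij(i, j) > 0)
          ll += nij(i, j) * (std::log(-std::expm1(-h)) + h);
      }
      out(i, g) = ll;
    }
  }
  return out;
}

static int sample_cat(const std::vector<double>& cum) {
  double u = R::unif_rand() * cum.back();
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// [[Rcpp::export]]
List secr_mcmc_cpp(IntegerMatrix nij, int K, NumericMatrix d2, int M,
                   int n_iter, int n_burn, int thin,
                   double sigma_lo, double sigma_hi,
                   double lam0_lo, double lam0_hi,
                   double sigma_init, double lam0_init) {
  const int G = d2.nrow(), J = d2.ncol(), n = nij.nrow();
  if (M < n) stop("augmented size M must be >= number observed");

  // columns (traps) holding any capture, and sparse per-individual records
  std::vector<int> colmap(J, -1), capcols;
  for (int j = 0; j < J; ++j) {
    bool any = false;
    for (int i = 0; i < n; ++i) if (nij(i, j) > 0) { any = true; break; }
    if (any) { colmap[j] = (int)capcols.size(); capcols.push_back(j); }
  }
  const int Jc = (int)capcols.size();
  std::vector<int> trap_of, cnt_of, start(n + 1, 0);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < J; ++j)
      if (nij(i, j) > 0) { trap_of.push_back(j); cnt_of.push_back(nij(i, j)); }
    start[i + 1] = (int)trap_of.size();
  }

  double sigma = sigma_init, lam0 = lam0_init, psi = 0.5;

  std::vector<double> e((size_t)G * J), E(G), lp_cap((size_t)G * Jc);
  auto fill_e = [&](double sig) {
    const double inv2s2 = 1.0 / (2.0 * sig * sig);
    for (int g = 0; g < G; ++g) {
      double acc = 0.0;
      for (int j = 0; j < J; ++j) {
        double v = std::exp(-d2(g, j) * inv2s2);
        e[g + (size_t)G * j] = v;
        acc += v;
      }
      E[g] = acc;
    }
  };
  auto fill_lp = [&](double lam) {
    for (int c = 0; c < Jc; ++c) {
      const double* ec = &e[(size_t)G * capcols[c]];
      double* out = &lp_cap[(size_t)G * c];
      for (int g = 0; g < G; ++g)
        out[g] = std::log(-std::expm1(-lam * ec[g]));
    }
  };
  fill_e(sigma);
  fill_lp(lam0);

  // log-likelihood of captured individual i at cell g under current caches
  auto ind_ll = [&](int i, int g) {
    double ll = -K * lam0 * E[g];
    for (int r = start[i]; r < start[i + 1]; ++r) {
      int j = trap_of[r];
      ll += cnt_of[r] * (lp_cap[g + (size_t)G * colmap[j]] +
                         lam0 * e[g + (size_t)G * j]);
    }
    return ll;
  };
  std::vector<int> z(M, 0), s(M);
  for (int i = 0; i < n; ++i) z[i] = 1;
  for (int i = 0; i < M; ++i) s[i] = (int)std::floor(R::unif_rand() * G);
  for (int i = 0; i < n; ++i) {
    int best = 0; double bll = R_NegInf;
    for (int g = 0; g < G; ++g) {
      double ll = ind_ll(i, g);
      if (ll > bll) { bll = ll; best = g; }
    }
    s[i] = best;
  }

  // total data log-likelihood under a candidate (sig, lam), evaluated only at
  // the currently occupied centers of the z = 1 individuals
  auto total_ll_at = [&](double sig, double lam) {
    const double inv2s2 = 1.0 / (2.0 * sig * sig);
    double tot = 0.0;
    for (int i = 0; i < M; ++i) {
      if (!z[i]) continue;
      int g = s[i];
      double Eg = 0.0;
      for (int j = 0; j < J; ++j)
        Eg += std::exp(-d2(g, j) * inv2s2);
      double ll = -K * lam * Eg;
      if (i < n)
        for (int r = start[i]; r < start[i + 1]; ++r) {
          double h = lam * std::exp(-d2(g, trap_of[r]) * inv2s2);
          ll += cnt_of[r] * (std::log(-std::expm1(-h)) + h);
        }
      tot += ll;
    }
    return tot;
  };
  // current-state total, from the caches (cheap lookups)
  auto total_ll_cur = [&]() {
    double tot = 0.0;
    for (int i = 0; i < n; ++i) tot += ind_ll(i, s[i]);
    for (int i = n; i < M; ++i)
      if (z[i]) tot += -K * lam0 * E[s[i]];
    return tot;
  };

  double step_s = 0.1, step_l = 0.2;
  int acc_s = 0, try_s = 0, acc_l = 0, try_l = 0;
  long acc_s_tot = 0, try_s_tot = 0, acc_l_tot = 0, try_l_tot = 0;

  int n_keep = 0;
  for (int it = n_burn; it < n_iter; ++it)
    if ((it - n_burn) % thin == 0) ++n_keep;
  NumericMatrix draws(n_keep, 4);  // sigma, lambda0, psi, N
  int row = 0;

  std::vector<double> w(G), cum(G), cum0(G);

  for (int it = 0; it < n_iter; ++it) {
    // --- sigma (log-scale RW, uniform prior on [lo, hi]) ---
    ++try_s; ++try_s_tot;
    double sig_p = sigma * std::exp(R::norm_rand() * step_s);
    if (sig_p > sigma_lo && sig_p < sigma_hi) {
      double lr = total_ll_at(sig_p, lam0) - total_ll_cur() +
        std::log(sig_p / sigma);
      if (std::log(R::unif_rand()) < lr) {
        sigma = sig_p;
        fill_e(sigma);
        fill_lp(lam0);
        ++acc_s; ++acc_s_tot;
      }
    }
    // --- lambda0 (hazard rescaling; E grid unchanged) ---
    ++try_l; ++try_l_tot;
    double lam_p = lam0 * std::exp(R::norm_rand() * step_l);
    if (lam_p > lam0_lo && lam_p < lam0_hi) {
      double cur = 0.0, prop = 0.0;
      for (int i = 0; i < M; ++i) {
        if (!z[i]) continue;
        prop += -K * lam_p * E[s[i]];
        cur += -K * lam0 * E[s[i]];
      }
      for (int i = 0; i < n; ++i)
        for (int r = start[i]; r < start[i + 1]; ++r) {
          double eg = e[s[i] + (size_t)G * trap_of[r]];
          prop += cnt_of[r] *
            (std::log(-std::expm1(-lam_p * eg)) + lam_p * eg);
          cur += cnt_of[r] *
            (lp_cap[s[i] + (size_t)G * colmap[trap_of[r]]] + lam0 * eg);
        }
      double lr = prop - cur + std::log(lam_p / lam0);
      if (std::log(R::unif_rand()) < lr) {
        lam0 = lam_p;
        fill_lp(lam0);
        ++acc_l; ++acc_l_tot;
      }
    }
    // adapt proposal scales during burn-in only (target 20-40% acceptance)
    if (it < n_burn && (it + 1) % 50 == 0) {
      double rs = (double)acc_s / try_s, rl = (double)acc_l / try_l;
      if (rs > 0.4) step_s *= 1.25; else if (rs < 0.2) step_s /= 1.25;
      if (rl > 0.4) step_l *= 1.25; else if (rl < 0.2) step_l /= 1.25;
      acc_s = try_s = acc_l = try_l = 0;
    }

    // --- activity centers: exact Gibbs over the grid ---
    const double Klam = K * lam0;
    double m0 = -Klam * E[0];
    for (int g = 1; g < G; ++g) if (-Klam * E[g] > m0) m0 = -Klam * E[g];
    double c0 = 0.0;
    for (int g = 0; g < G; ++g) {
      c0 += std::exp(-Klam * E[g] - m0);
      cum0[g] = c0;
    }
    for (int i = 0; i < n; ++i) {
      double mi = R_NegInf;
      for (int g = 0; g < G; ++g) {
        w[g] = ind_ll(i, g);
        if (w[g] > mi) mi = w[g];
      }
      double c = 0.0;
      for (int g = 0; g < G; ++g) { c += std::exp(w[g] - mi); cum[g] = c; }
      s[i] = sample_cat(cum);
    }
    for (int i = n; i < M; ++i)
      s[i] = z[i] ? sample_cat(cum0)
                  : (int)std::floor(R::unif_rand() * G);

    // --- inclusion indicators for the augmented individuals ---
    int Nsup = n;
    for (int i = n; i < M; ++i) {
      double p1 = psi * std::exp(-Klam * E[s[i]]);
      z[i] = (R::unif_rand() < p1 / (p1 + (1.0 - psi))) ? 1 : 0;
      Nsup += z[i];
    }
    // --- psi ---
    psi = R::rbeta(1.0 + Nsup, 1.0 + M - Nsup);

    if (it >= n_burn && (it - n_burn) % thin == 0) {
      draws(row, 0) = sigma; draws(row, 1) = lam0;
      draws(row, 2) = psi; draws(row, 3) = Nsup;
      ++row;
    }
  }

  return List::create(
    _["draws"] = draws,
    _["accept"] = NumericVector::create(
      _["sigma"] = try_s_tot ? (double)acc_s_tot / try_s_tot : NA_REAL,
      _["lambda0"] = try_l_tot ? (double)acc_l_tot / try_l_tot : NA_REAL),
    _["steps"] = NumericVector::create(_["sigma"] = step_s,
                                       _["lambda0"] = step_l));
}
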