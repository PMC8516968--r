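// Adaptive Metropolis-within-Gibbs sampler for the zero-inflated Poisson
// spatio-temporal model. One call runs a single chain; R's RNG is used
// throughout so set.seed() on the R side fixes the chain.
//
// Model, per stratum r (area i(r), month j(r), age, sex):
//   y_r ~ ZIP(omega, mu_r),  mu_r = E_r * exp(theta_r)
//   theta_r = alpha + x_r' beta + u_i + s_i + delta_i * tcent_r
// with z_r the latent structural-zero indicator. Updates:
//   z  : Gibbs (Bernoulli) at observed zeros
//   omega : Gibbs, Beta(1 + sum z, 1 + n - sum z)
//   alpha, beta : adaptive random-walk Metropolis on strata with z = 0
//   u_i : RW Metropolis, exchangeable N(0, 1/tau_u) prior
//   s_i : RW Metropolis, ICAR pairwise-difference prior (islands proper)
//   delta_i : RW Metropolis, exchangeable or ICAR prior
//   tau_u, tau_s, tau_w : Gibbs (gamma conjugacy)
// s and delta are recentred each sweep, the means absorbed into alpha and
// the trend coefficient so theta is unchanged.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct Walker {
  double lsd;          // log proposal sd
  int acc = 0, tries = 0;
  int acc_post = 0, tries_post = 0;
  explicit Walker(double l = -1.0) : lsd(l) {}
  void record(bool accepted, bool adapting) {
    if (adapting) {
      tries++; if (accepted) acc++;
      if (tries == 50) {
        double rate = double(acc) / tries;
        lsd += (rate - 0.44);
        if (lsd > 4.0) lsd = 4.0;
        if (lsd < -12.0) lsd = -12.0;
        acc = 0; tries = 0;
      }
    } else {
      tries_post++; if (accepted) acc_post++;
    }
  }
  double rate() const {
    return tries_post ? double(acc_post) / tries_post : NA_REAL;
  }
};

// [[Rcpp::export]]
List zip_gibbs_cpp(IntegerVector y, NumericVector E, NumericMatrix X,
                   IntegerVector area, NumericVector tcent,
                   IntegerMatrix edges, IntegerVector nnb,
                   int n_area,
                   bool has_u, bool has_s, bool has_delta, bool delta_icar,
                   bool sample_omega, double omega_init,
                   int trend_col,
                   int burnin, int iters, int thin,
                   double alpha_prec, double beta_prec,
                   double tau_shape, double tau_rate,
                   double rank_s, double rank_w,
                   double alpha_init, NumericVector beta_init,
                   int alt_col, NumericVector alt_area) {
  const int n = y.size();
  const int p = X.ncol();
  const int n_keep = (iters - burnin) / thin;
  if (n_keep < 1) stop("no retained draws: iterations must exceed burn-in");

  // column pointers into X avoid per-element bounds logic in hot loops
  std::vector<const double*> Xc(p);
  for (int k = 0; k < p; k++) Xc[k] = &X(0, k);

  // rows per area and neighbour lists
  std::vector<std::vector<int>> rows(n_area), nb(n_area);
  for (int r = 0; r < n; r++) rows[area[r]].push_back(r);
  const int n_edge = edges.nrow();
  for (int e = 0; e < n_edge; e++) {
    nb[edges(e, 0)].push_back(edges(e, 1));
    nb[edges(e, 1)].push_back(edges(e, 0));
  }

  // state
  double alpha = alpha_init;
  std::vector<double> beta(p);
  for (int k = 0; k < p; k++) beta[k] = beta_init[k];
  double omega = omega_init;
  std::vector<double> u(n_area, 0.0), s(n_area, 0.0), del(n_area, 0.0);
  double tau_u = 1.0, tau_s = 1.0, tau_w = 1000.0;
  std::vector<int> z(n, 0);
  std::vector<double> theta(n), eth(n), scratch(n);

  for (int r = 0; r < n; r++) {
    double t = alpha;
    for (int k = 0; k < p; k++) t += beta[k] * X(r, k);
    theta[r] = t;
    eth[r] = std::exp(t);
  }

  std::vector<int> zero_rows;
  for (int r = 0; r < n; r++) if (y[r] == 0) zero_rows.push_back(r);

  Walker w_alpha(std::log(0.05));
  std::vector<Walker> w_beta(p, Walker(std::log(0.02)));
  Walker w_shift_a(std::log(0.2)), w_shift_alt(std::log(0.02));
  std::vector<Walker> w_u(n_area, Walker(std::log(0.2))),
                      w_s(n_area, Walker(std::log(0.2))),
                      w_d(n_area, Walker(std::log(0.01)));

  const int n_par = 1 + p + 1 + 3 + 3 * n_area + 1;
  NumericMatrix out(n_keep, n_par);
  NumericVector zbar(n);
  int kept = 0;

  for (int it = 0; it < iters; it++) {
    const bool adapting = it < burnin;

    // --- latent structural zeros ---
    if (sample_omega || omega > 0.0) {
      for (size_t q = 0; q < zero_rows.size(); q++) {
        const int r = zero_rows[q];
        const double mu = E[r] * eth[r];
        const double p1 = omega / (omega + (1.0 - omega) * std::exp(-mu));
        z[r] = (unif_rand() < p1) ? 1 : 0;
      }
    }

    // --- omega | z ---
    if (sample_omega) {
      int sz = 0;
      for (size_t q = 0; q < zero_rows.size(); q++) sz += z[zero_rows[q]];
      omega = R::rbeta(1.0 + sz, 1.0 + (n - sz));
    }

    // --- alpha ---
    {
      const double d = std::exp(w_alpha.lsd) * norm_rand();
      const double ed = std::exp(d);
      double dll = 0.0;
      for (int r = 0; r < n; r++) {
        if (z[r]) continue;
        dll += y[r] * d - E[r] * eth[r] * (ed - 1.0);
      }
      const double prop = alpha + d;
      dll += -0.5 * alpha_prec * (prop * prop - alpha * alpha);
      const bool ok = std::log(unif_rand()) < dll;
      if (ok) {
        alpha = prop;
        for (int r = 0; r < n; r++) { theta[r] += d; eth[r] *= ed; }
      }
      w_alpha.record(ok, adapting);
    }

    // --- beta ---
    for (int k = 0; k < p; k++) {
      const double d = std::exp(w_beta[k].lsd) * norm_rand();
      const double* xk = Xc[k];
      double dll = 0.0;
      for (int r = 0; r < n; r++) {
        const double x = xk[r];
        if (x == 0.0) { scratch[r] = 1.0; continue; }
        const double dt = d * x;
        const double edt = std::exp(dt);
        scratch[r] = edt;
        if (!z[r]) dll += y[r] * dt - E[r] * eth[r] * (edt - 1.0);
      }
      const double prop = beta[k] + d;
      dll += -0.5 * beta_prec * (prop * prop - beta[k] * beta[k]);
      const bool ok = std::log(unif_rand()) < dll;
      if (ok) {
        beta[k] = prop;
        for (int r = 0; r < n; r++) {
          theta[r] += d * xk[r];
          eth[r] *= scratch[r];
        }
      }
      w_beta[k].record(ok, adapting);
    }

    // --- area effects ---
    for (int i = 0; i < n_area; i++) {
      const std::vector<int>& R = rows[i];

      if (has_u) {
        const double d = std::exp(w_u[i].lsd) * norm_rand();
        const double ed = std::exp(d);
        double dll = 0.0;
        for (size_t q = 0; q < R.size(); q++) {
          const int r = R[q];
          if (!z[r]) dll += y[r] * d - E[r] * eth[r] * (ed - 1.0);
        }
        const double prop = u[i] + d;
        dll += -0.5 * tau_u * (prop * prop - u[i] * u[i]);
        const bool ok = std::log(unif_rand()) < dll;
        if (ok) {
          u[i] = prop;
          for (size_t q = 0; q < R.size(); q++) {
            theta[R[q]] += d; eth[R[q]] *= ed;
          }
        }
        w_u[i].record(ok, adapting);
      }

      if (has_s) {
        const double d = std::exp(w_s[i].lsd) * norm_rand();
        const double ed = std::exp(d);
        double dll = 0.0;
        for (size_t q = 0; q < R.size(); q++) {
          const int r = R[q];
          if (!z[r]) dll += y[r] * d - E[r] * eth[r] * (ed - 1.0);
        }
        const double prop = s[i] + d;
        if (nb[i].empty()) {                       // island: proper Gaussian
          dll += -0.5 * tau_s * (prop * prop - s[i] * s[i]);
        } else {
          double q2 = 0.0;
          for (size_t q = 0; q < nb[i].size(); q++) {
            const double sk = s[nb[i][q]];
            q2 += (prop - sk) * (prop - sk) - (s[i] - sk) * (s[i] - sk);
          }
          dll += -0.5 * tau_s * q2;
        }
        const bool ok = std::log(unif_rand()) < dll;
        if (ok) {
          s[i] = prop;
          for (size_t q = 0; q < R.size(); q++) {
            theta[R[q]] += d; eth[R[q]] *= ed;
          }
        }
        w_s[i].record(ok, adapting);
      }

      if (has_delta) {
        const double d = std::exp(w_d[i].lsd) * norm_rand();
        double dll = 0.0;
        for (size_t q = 0; q < R.size(); q++) {
          const int r = R[q];
          const double dt = d * tcent[r];
          scratch[r] = std::exp(dt);
          if (!z[r]) dll += y[r] * dt - E[r] * eth[r] * (scratch[r] - 1.0);
        }
        const double prop = del[i] + d;
        if (delta_icar && !nb[i].empty()) {
          double q2 = 0.0;
          for (size_t q = 0; q < nb[i].size(); q++) {
            const double dk = del[nb[i][q]];
            q2 += (prop - dk) * (prop - dk) - (del[i] - dk) * (del[i] - dk);
          }
          dll += -0.5 * tau_w * q2;
        } else {
          dll += -0.5 * tau_w * (prop * prop - del[i] * del[i]);
        }
        const bool ok = std::log(unif_rand()) < dll;
        if (ok) {
          del[i] = prop;
          for (size_t q = 0; q < R.size(); q++) {
            theta[R[q]] += d * tcent[R[q]];
            eth[R[q]] *= scratch[R[q]];
          }
        }
        w_d[i].record(ok, adapting);
      }
    }

    // --- translation moves along exact likelihood ridges ---
    // (alpha, u): alpha += c, u_i -= c leaves theta unchanged; accepted on
    // the prior ratio alone. Cures the slow random walk along the
    // intercept / mean(u) ridge.
    if (has_u) {
      const double c = std::exp(w_shift_a.lsd) * norm_rand();
      double su = 0.0;
      for (int i = 0; i < n_area; i++) su += u[i];
      double dlp = -0.5 * tau_u * (n_area * c * c - 2.0 * c * su);
      const double ap = alpha + c;
      dlp += -0.5 * alpha_prec * (ap * ap - alpha * alpha);
      const bool ok = std::log(unif_rand()) < dlp;
      if (ok) {
        alpha = ap;
        for (int i = 0; i < n_area; i++) u[i] -= c;
      }
      w_shift_a.record(ok, adapting);
    }
    // (beta_altitude, area effect): beta_alt += c, u_i -= c * alt_i (or
    // s_i when the model has no u) is theta-invariant because altitude is
    // constant within an area.
    if (alt_col >= 0 && (has_u || has_s)) {
      const double c = std::exp(w_shift_alt.lsd) * norm_rand();
      double dlp = 0.0;
      if (has_u) {
        for (int i = 0; i < n_area; i++) {
          const double un = u[i] - c * alt_area[i];
          dlp += -0.5 * tau_u * (un * un - u[i] * u[i]);
        }
      } else {
        for (int e = 0; e < n_edge; e++) {
          const int i = edges(e, 0), k = edges(e, 1);
          const double dn = (s[i] - c * alt_area[i]) - (s[k] - c * alt_area[k]);
          const double d0 = s[i] - s[k];
          dlp += -0.5 * tau_s * (dn * dn - d0 * d0);
        }
        for (int i = 0; i < n_area; i++) {
          if (nnb[i] == 0) {
            const double sn = s[i] - c * alt_area[i];
            dlp += -0.5 * tau_s * (sn * sn - s[i] * s[i]);
          }
        }
      }
      const double bp = beta[alt_col] + c;
      dlp += -0.5 * beta_prec * (bp * bp - beta[alt_col] * beta[alt_col]);
      const bool ok = std::log(unif_rand()) < dlp;
      if (ok) {
        beta[alt_col] = bp;
        if (has_u) {
          for (int i = 0; i < n_area; i++) u[i] -= c * alt_area[i];
        } else {
          for (int i = 0; i < n_area; i++) s[i] -= c * alt_area[i];
        }
      }
      w_shift_alt.record(ok, adapting);
    }

    // --- precisions (gamma conjugacy) ---
    if (has_u) {
      double ss = 0.0;
      for (int i = 0; i < n_area; i++) ss += u[i] * u[i];
      tau_u = R::rgamma(tau_shape + 0.5 * n_area, 1.0 / (tau_rate + 0.5 * ss));
    }
    if (has_s) {
      double qf = 0.0;
      for (int e = 0; e < n_edge; e++) {
        const double dd = s[edges(e, 0)] - s[edges(e, 1)];
        qf += dd * dd;
      }
      for (int i = 0; i < n_area; i++) if (nnb[i] == 0) qf += s[i] * s[i];
      tau_s = R::rgamma(tau_shape + 0.5 * rank_s, 1.0 / (tau_rate + 0.5 * qf));
    }
    if (has_delta) {
      double qf = 0.0;
      if (delta_icar) {
        for (int e = 0; e < n_edge; e++) {
          const double dd = del[edges(e, 0)] - del[edges(e, 1)];
          qf += dd * dd;
        }
        for (int i = 0; i < n_area; i++) if (nnb[i] == 0) qf += del[i] * del[i];
        tau_w = R::rgamma(tau_shape + 0.5 * rank_w,
                          1.0 / (tau_rate + 0.5 * qf));
      } else {
        // delta is recentred each sweep, so it lives on the sum-to-zero
        // subspace: n - 1 degrees of freedom in the conjugate update
        for (int i = 0; i < n_area; i++) qf += del[i] * del[i];
        tau_w = R::rgamma(tau_shape + 0.5 * rank_w,
                          1.0 / (tau_rate + 0.5 * qf));
      }
    }

    // --- recentre s and delta (theta-invariant reparameterization) ---
    if (has_s) {
      double ms = 0.0;
      for (int i = 0; i < n_area; i++) ms += s[i];
      ms /= n_area;
      for (int i = 0; i < n_area; i++) s[i] -= ms;
      alpha += ms;
    }
    if (has_delta && trend_col >= 0) {
      double md = 0.0;
      for (int i = 0; i < n_area; i++) md += del[i];
      md /= n_area;
      for (int i = 0; i < n_area; i++) del[i] -= md;
      beta[trend_col] += md;
    }

    // --- store ---
    if (it >= burnin && ((it - burnin) % thin == thin - 1)) {
      double dev = 0.0;
      for (int r = 0; r < n; r++) {
        const double mu = E[r] * eth[r];
        double lp;
        if (y[r] == 0) {
          lp = std::log(omega + (1.0 - omega) * std::exp(-mu));
        } else {
          lp = std::log1p(-omega) + y[r] * std::log(mu) - mu -
               R::lgammafn(y[r] + 1.0);
        }
        dev += lp;
        zbar[r] += z[r];
      }
      dev *= -2.0;
      if (!R_finite(dev)) {
        stop("non-finite deviance at iteration %d (divergent state)", it + 1);
      }
      int c = 0;
      out(kept, c++) = alpha;
      for (int k = 0; k < p; k++) out(kept, c++) = beta[k];
      out(kept, c++) = omega;
      out(kept, c++) = tau_u;
      out(kept, c++) = tau_s;
      out(kept, c++) = tau_w;
      for (int i = 0; i < n_area; i++) out(kept, c++) = u[i];
      for (int i = 0; i < n_area; i++) out(kept, c++) = s[i];
      for (int i = 0; i < n_area; i++) out(kept, c++) = del[i];
      out(kept, c++) = dev;
      kept++;
    }

    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  for (int r = 0; r < n; r++) zbar[r] /= n_keep;

  NumericVector acc_area_u(n_area), acc_area_s(n_area), acc_area_d(n_area);
  for (int i = 0; i < n_area; i++) {
    acc_area_u[i] = w_u[i].rate();
    acc_area_s[i] = w_s[i].rate();
    acc_area_d[i] = w_d[i].rate();
  }
  NumericVector acc_beta(p);
  for (int k = 0; k < p; k++) acc_beta[k] = w_beta[k].rate();

  return List::create(
    _["draws"] = out,
    _["zbar"] = zbar,
    _["accept"] = List::create(_["alpha"] = w_alpha.rate(),
                               _["beta"] = acc_beta,
                               _["u"] = acc_area_u,
                               _["s"] = acc_area_s,
                               _["delta"] = acc_area_d));
}
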