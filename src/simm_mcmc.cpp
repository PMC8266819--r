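// Adaptive random-walk Metropolis-within-Gibbs sampler for the
// concentration-weighted isotope mixing model on ILR coordinates.
//
// Linear predictor per observation: eta_i = sum_j X(i,j) * Z(j,) + b(bear_i,)
// Composition: p_i = softmax(V * eta_i)  (V = orthonormal ILR basis, K x K-1)
// Likelihood per isotope e with concentration weights q(,e):
//   w_k = p_k q_ke ; mean = sum w mu / sum w ;
//   procvar = sum w^2 var / (sum w)^2 ; y_ie ~ N(mean, procvar + s_e^2)
//
// Priors: intercept composition ~ Dirichlet(alpha) (with ILR Jacobian the
// log-prior reduces to sum alpha_k log p_k + const); other coefficient rows
// N(0, beta_sd); bear effects N(0, sigma_b); sigma_b ~ half-N(0, sb_scale);
// sigma_e ~ half-N(0, sres_scale); scale parameters sampled on the log scale
// (Jacobian included).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  int n, K, Km1, P, B;
  NumericMatrix y;      // n x 2 (NA allowed)
  NumericMatrix X;      // n x P
  IntegerVector bear;   // n, 0-based or -1
  NumericMatrix mu, vr, q; // K x 2
  NumericMatrix V;      // K x Km1
  NumericVector alpha;  // K
  double beta_sd, sb_scale, sres_scale;
  LogicalVector fix_sigma; // 2
  NumericVector sigma_fixed; // 2
  bool has_ranef;
  std::vector<std::vector<int>> obs_of_col;  // per fixed column: nonzero rows
  std::vector<std::vector<int>> obs_of_bear; // per bear: its rows
};

// composition from eta (length Km1) into p (length K)
inline void softmax_comp(const Model& M, const double* eta, double* p) {
  double mx = -1e300;
  for (int k = 0; k < M.K; ++k) {
    double u = 0.0;
    for (int c = 0; c < M.Km1; ++c) u += M.V(k, c) * eta[c];
    p[k] = u;
    if (u > mx) mx = u;
  }
  double s = 0.0;
  for (int k = 0; k < M.K; ++k) { p[k] = std::exp(p[k] - mx); s += p[k]; }
  for (int k = 0; k < M.K; ++k) p[k] /= s;
}

inline double obs_loglik(const Model& M, int i, const double* eta,
                         const double* sigma) {
  std::vector<double> p(M.K);
  softmax_comp(M, eta, p.data());
  double ll = 0.0;
  for (int e = 0; e < 2; ++e) {
    double yie = M.y(i, e);
    if (NumericMatrix::is_na(yie)) continue;
    double denom = 0.0, num = 0.0, pv = 0.0;
    for (int k = 0; k < M.K; ++k) {
      double w = p[k] * M.q(k, e);
      denom += w;
      num += w * M.mu(k, e);
      pv += w * w * M.vr(k, e);
    }
    double mean = num / denom;
    double var = pv / (denom * denom) + sigma[e] * sigma[e];
    ll += R::dnorm(yie, mean, std::sqrt(var), 1);
  }
  return ll;
}

struct State {
  NumericMatrix Z;   // P x Km1
  NumericMatrix b;   // B x Km1 (0 x Km1 when no ranef)
  double log_sb;
  double log_s[2];
  NumericMatrix eta; // n x Km1 cached linear predictor
  std::vector<double> ll; // cached per-obs loglik
};

inline void eta_row(const Model& M, const State& S, int i, double* out) {
  for (int c = 0; c < M.Km1; ++c) {
    double v = 0.0;
    for (int j = 0; j < M.P; ++j) v += M.X(i, j) * S.Z(j, c);
    if (M.has_ranef && M.bear[i] >= 0) v += S.b(M.bear[i], c);
    out[c] = v;
  }
}

inline double log_prior_intercept(const Model& M, const State& S) {
  std::vector<double> p(M.K);
  std::vector<double> z(M.Km1);
  for (int c = 0; c < M.Km1; ++c) z[c] = S.Z(0, c);
  softmax_comp(M, z.data(), p.data());
  double lp = 0.0;
  for (int k = 0; k < M.K; ++k) lp += M.alpha[k] * std::log(p[k]);
  return lp;
}

} // namespace

// [[Rcpp::export]]
List simm_mcmc_cpp(NumericMatrix y, NumericMatrix X, IntegerVector bear,
                   int n_bears, NumericMatrix mu, NumericMatrix vr,
                   NumericMatrix q, NumericMatrix V, NumericVector alpha,
                   double beta_sd, double sb_scale, double sres_scale,
                   LogicalVector fix_sigma, NumericVector sigma_fixed,
                   int n_iter, int n_burn, int thin,
                   NumericVector init, double init_scale) {
  RNGScope scope;
  Model M;
  M.n = y.nrow();
  M.K = mu.nrow();
  M.Km1 = V.ncol();
  M.P = X.ncol();
  M.B = n_bears;
  M.y = y; M.X = X; M.bear = bear; M.mu = mu; M.vr = vr; M.q = q; M.V = V;
  M.alpha = alpha; M.beta_sd = beta_sd; M.sb_scale = sb_scale;
  M.sres_scale = sres_scale; M.fix_sigma = fix_sigma;
  M.sigma_fixed = sigma_fixed;
  M.has_ranef = n_bears > 0;

  M.obs_of_col.resize(M.P);
  for (int j = 0; j < M.P; ++j)
    for (int i = 0; i < M.n; ++i)
      if (M.X(i, j) != 0.0) M.obs_of_col[j].push_back(i);
  M.obs_of_bear.resize(std::max(M.B, 1));
  if (M.has_ranef)
    for (int i = 0; i < M.n; ++i)
      if (bear[i] >= 0) M.obs_of_bear[bear[i]].push_back(i);

  State S;
  S.Z = NumericMatrix(M.P, M.Km1);
  S.b = NumericMatrix(std::max(M.B, 1), M.Km1);
  // init: Z flattened column-major, then log_sb, log_s1, log_s2
  int pos = 0;
  for (int c = 0; c < M.Km1; ++c)
    for (int j = 0; j < M.P; ++j) S.Z(j, c) = init[pos++];
  S.log_sb = init[pos++];
  S.log_s[0] = init[pos++];
  S.log_s[1] = init[pos++];
  if (M.has_ranef)
    for (int ib = 0; ib < M.B; ++ib)
      for (int c = 0; c < M.Km1; ++c)
        S.b(ib, c) = R::rnorm(0.0, 0.1);

  double sigma[2];
  for (int e = 0; e < 2; ++e)
    sigma[e] = fix_sigma[e] ? sigma_fixed[e] : std::exp(S.log_s[e]);

  S.eta = NumericMatrix(M.n, M.Km1);
  S.ll.resize(M.n);
  std::vector<double> tmp_eta(M.Km1);
  for (int i = 0; i < M.n; ++i) {
    eta_row(M, S, i, tmp_eta.data());
    for (int c = 0; c < M.Km1; ++c) S.eta(i, c) = tmp_eta[c];
    S.ll[i] = obs_loglik(M, i, tmp_eta.data(), sigma);
  }

  // blocks: P coefficient rows, B bear rows, log_sb, two log sigmas
  int n_blocks = M.P + M.B + (M.has_ranef ? 1 : 0) + 2;
  std::vector<double> scale(n_blocks, init_scale);
  std::vector<int> acc(n_blocks, 0), att(n_blocks, 0);
  std::vector<long> acc_tot(n_blocks, 0), att_tot(n_blocks, 0);

  int n_keep = (n_iter - n_burn) / thin;
  int npar = M.P * M.Km1 + (M.has_ranef ? M.B * M.Km1 + 1 : 0) + 2;
  NumericMatrix draws(n_keep, npar);
  NumericMatrix ll_out(n_keep, M.n);
  int keep_row = 0;

  std::vector<double> prop(M.Km1), new_ll(M.n);

  for (int it = 0; it < n_iter; ++it) {
    int blk = 0;
    // --- fixed-effect coefficient rows ---
    for (int j = 0; j < M.P; ++j, ++blk) {
      att[blk]++;
      for (int c = 0; c < M.Km1; ++c)
        prop[c] = S.Z(j, c) + scale[blk] * R::norm_rand();
      double lp_old, lp_new;
      if (j == 0) {
        lp_old = log_prior_intercept(M, S);
        NumericMatrix Zsave = clone(S.Z);
        for (int c = 0; c < M.Km1; ++c) S.Z(0, c) = prop[c];
        lp_new = log_prior_intercept(M, S);
        S.Z = Zsave;
      } else {
        lp_old = lp_new = 0.0;
        for (int c = 0; c < M.Km1; ++c) {
          lp_old += R::dnorm(S.Z(j, c), 0.0, M.beta_sd, 1);
          lp_new += R::dnorm(prop[c], 0.0, M.beta_sd, 1);
        }
      }
      double dll = 0.0;
      const std::vector<int>& rows = M.obs_of_col[j];
      for (size_t r = 0; r < rows.size(); ++r) {
        int i = rows[r];
        double xij = M.X(i, j);
        for (int c = 0; c < M.Km1; ++c)
          tmp_eta[c] = S.eta(i, c) + xij * (prop[c] - S.Z(j, c));
        new_ll[i] = obs_loglik(M, i, tmp_eta.data(), sigma);
        dll += new_ll[i] - S.ll[i];
      }
      if (std::log(R::unif_rand()) < dll + lp_new - lp_old) {
        acc[blk]++;
        for (size_t r = 0; r < rows.size(); ++r) {
          int i = rows[r];
          double xij = M.X(i, j);
          for (int c = 0; c < M.Km1; ++c)
            S.eta(i, c) += xij * (prop[c] - S.Z(j, c));
          S.ll[i] = new_ll[i];
        }
        for (int c = 0; c < M.Km1; ++c) S.Z(j, c) = prop[c];
      }
    }
    // --- bear random-effect rows ---
    if (M.has_ranef) {
      double sb = std::exp(S.log_sb);
      for (int ib = 0; ib < M.B; ++ib, ++blk) {
        att[blk]++;
        for (int c = 0; c < M.Km1; ++c)
          prop[c] = S.b(ib, c) + scale[blk] * R::norm_rand();
        double lp_old = 0.0, lp_new = 0.0;
        for (int c = 0; c < M.Km1; ++c) {
          lp_old += R::dnorm(S.b(ib, c), 0.0, sb, 1);
          lp_new += R::dnorm(prop[c], 0.0, sb, 1);
        }
        double dll = 0.0;
        const std::vector<int>& rows = M.obs_of_bear[ib];
        for (size_t r = 0; r < rows.size(); ++r) {
          int i = rows[r];
          for (int c = 0; c < M.Km1; ++c)
            tmp_eta[c] = S.eta(i, c) + (prop[c] - S.b(ib, c));
          new_ll[i] = obs_loglik(M, i, tmp_eta.data(), sigma);
          dll += new_ll[i] - S.ll[i];
        }
        if (std::log(R::unif_rand()) < dll + lp_new - lp_old) {
          acc[blk]++;
          for (size_t r = 0; r < rows.size(); ++r) {
            int i = rows[r];
            for (int c = 0; c < M.Km1; ++c)
              S.eta(i, c) += (prop[c] - S.b(ib, c));
            S.ll[i] = new_ll[i];
          }
          for (int c = 0; c < M.Km1; ++c) S.b(ib, c) = prop[c];
        }
      }
      // --- log sigma_b (prior-only block) ---
      att[blk]++;
      double lsb_new = S.log_sb + scale[blk] * R::norm_rand();
      double sb_new = std::exp(lsb_new);
      double lp_old = -0.5 * sb * sb / (M.sb_scale * M.sb_scale) + S.log_sb;
      double lp_new = -0.5 * sb_new * sb_new / (M.sb_scale * M.sb_scale) +
        lsb_new;
      for (int ib = 0; ib < M.B; ++ib)
        for (int c = 0; c < M.Km1; ++c) {
          lp_old += R::dnorm(S.b(ib, c), 0.0, sb, 1);
          lp_new += R::dnorm(S.b(ib, c), 0.0, sb_new, 1);
        }
      if (std::log(R::unif_rand()) < lp_new - lp_old) {
        acc[blk]++;
        S.log_sb = lsb_new;
      }
      ++blk;
    }
    // --- residual SDs ---
    for (int e = 0; e < 2; ++e, ++blk) {
      if (fix_sigma[e]) continue;
      att[blk]++;
      double ls_new = S.log_s[e] + scale[blk] * R::norm_rand();
      double s_new = std::exp(ls_new);
      double s_old = sigma[e];
      double lp_old = -0.5 * s_old * s_old / (M.sres_scale * M.sres_scale) +
        S.log_s[e];
      double lp_new = -0.5 * s_new * s_new / (M.sres_scale * M.sres_scale) +
        ls_new;
      double sig_prop[2] = { sigma[0], sigma[1] };
      sig_prop[e] = s_new;
      double dll = 0.0;
      for (int i = 0; i < M.n; ++i) {
        for (int c = 0; c < M.Km1; ++c) tmp_eta[c] = S.eta(i, c);
        new_ll[i] = obs_loglik(M, i, tmp_eta.data(), sig_prop);
        dll += new_ll[i] - S.ll[i];
      }
      if (std::log(R::unif_rand()) < dll + lp_new - lp_old) {
        acc[blk]++;
        S.log_s[e] = ls_new;
        sigma[e] = s_new;
        for (int i = 0; i < M.n; ++i) S.ll[i] = new_ll[i];
      }
    }

    // --- proposal adaptation (burn-in only), batches of 50 ---
    if (it < n_burn && (it + 1) % 50 == 0) {
      double step = std::min(0.25, 5.0 / std::sqrt((it + 1.0) / 50.0 + 1.0));
      for (int bk = 0; bk < n_blocks; ++bk) {
        if (att[bk] == 0) continue;
        double rate = (double)acc[bk] / att[bk];
        if (rate > 0.4) scale[bk] *= std::exp(step);
        else if (rate < 0.2) scale[bk] *= std::exp(-step);
        acc_tot[bk] += acc[bk]; att_tot[bk] += att[bk];
        acc[bk] = 0; att[bk] = 0;
      }
    }

    // --- keep draw ---
    if (it >= n_burn && (it - n_burn) % thin == thin - 1 &&
        keep_row < n_keep) {
      int c0 = 0;
      for (int c = 0; c < M.Km1; ++c)
        for (int j = 0; j < M.P; ++j) draws(keep_row, c0++) = S.Z(j, c);
      if (M.has_ranef) {
        for (int c = 0; c < M.Km1; ++c)
          for (int ib = 0; ib < M.B; ++ib)
            draws(keep_row, c0++) = S.b(ib, c);
        draws(keep_row, c0++) = S.log_sb;
      }
      draws(keep_row, c0++) = fix_sigma[0] ? std::log(sigma_fixed[0])
                                           : S.log_s[0];
      draws(keep_row, c0++) = fix_sigma[1] ? std::log(sigma_fixed[1])
                                           : S.log_s[1];
      for (int i = 0; i < M.n; ++i) ll_out(keep_row, i) = S.ll[i];
      keep_row++;
    }
    if (it % 1024 == 0) checkUserInterrupt();
  }

  NumericVector acc_rate(n_blocks);
  for (int bk = 0; bk < n_blocks; ++bk) {
    long a = acc_tot[bk] + acc[bk], t = att_tot[bk] + att[bk];
    acc_rate[bk] = t > 0 ? (double)a / t : NA_REAL;
  }
  return List::create(
    _["draws"] = draws,
    _["loglik"] = ll_out,
    _["accept_rate"] = acc_rate,
    _["final_scale"] = NumericVector(scale.begin(), scale.end())
  );
}
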