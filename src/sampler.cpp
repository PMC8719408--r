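// Adaptive Metropolis-within-Gibbs sweep for the binomial-logit
// shared-component space-time model. Single-site random-walk updates for
// intercepts, covariate effects, scaling weights (proposed inside the
// sum-to-zero log subspace) and every random-effect field; conjugate Gamma
// draws for the block precisions; identifiability constraints re-applied
// after every sweep with intercept compensation. Uses R's RNG throughout so
// runs are reproducible from set.seed().
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double softplus(double x) {
  return x > 0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

namespace {

struct Counter { long att = 0, acc = 0; };

struct Sampler {
  // dimensions
  int N, J, K, P, Q;
  // data
  std::vector<double> Y, w;   // length NJK; w = n when cell observed, else 0
  std::vector<double> Xs;     // N*P
  std::vector<double> Xst;    // N*J*Q
  double lconst;              // sum of log binomial coefficients (reporting)
  // graph
  std::vector<std::vector<int>> adj;
  std::vector<int> comp;      // 0-based component id per area
  int ncomp;
  std::vector<double> csize;
  double rank_s, rank_t, rank_nu;
  std::vector<std::pair<int, int>> edges;
  // hyperpriors
  double sa, sb, sg, tshape, trate;
  // options
  int interaction;            // 0 iid, 1 per-area RW1
  int literal;                // 1 = additive spatial weight constraint
  // state
  std::vector<double> alpha, bs, bst, lgs, lgt, gs, gt;
  std::vector<double> us, usk, ut, utk, nu;
  double tau_us, tau_ut, tau_nu;
  std::vector<double> tau_usk, tau_utk;
  std::vector<double> eta;

  inline int id2(int i, int j) const { return i + N * j; }
  inline int id3(int i, int j, int k) const { return i + N * (j + J * k); }

  inline double cll(int c, double e) const {
    double wi = w[c];
    if (wi <= 0.0) return 0.0;
    return Y[c] * e - wi * softplus(e);
  }

  void recompute_eta() {
    std::vector<double> xbs(N, 0.0), xbst(N * J, 0.0);
    for (int p = 0; p < P; ++p)
      for (int i = 0; i < N; ++i) xbs[i] += Xs[i + N * p] * bs[p];
    for (int q = 0; q < Q; ++q)
      for (int c = 0; c < N * J; ++c) xbst[c] += Xst[c + N * J * q] * bst[q];
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < J; ++j)
        for (int i = 0; i < N; ++i)
          eta[id3(i, j, k)] = alpha[k] + xbs[i] + xbst[id2(i, j)]
            + gs[k] * us[i] + usk[i + N * k]
            + gt[k] * ut[j] + utk[j + J * k] + nu[id2(i, j)];
  }

  double loglik() const {
    double s = 0.0;
    for (int c = 0; c < N * J * K; ++c) s += cll(c, eta[c]);
    return s + lconst;
  }

  double quad_spatial(const double* u, int stride_base) const {
    // stride_base: offset into usk-style storage; pass u directly instead
    (void)stride_base;
    double s = 0.0;
    for (size_t e = 0; e < edges.size(); ++e) {
      double d = u[edges[e].first] - u[edges[e].second];
      s += d * d;
    }
    for (int i = 0; i < N; ++i)
      if (adj[i].empty()) s += u[i] * u[i];
    return s;
  }

  double quad_rw(const double* x, int len) const {
    double s = 0.0;
    for (int j = 0; j + 1 < len; ++j) {
      double d = x[j + 1] - x[j];
      s += d * d;
    }
    return s;
  }

  double quad_nu() const {
    if (interaction == 0) {
      double s = 0.0;
      for (int c = 0; c < N * J; ++c) s += nu[c] * nu[c];
      return s;
    }
    double s = 0.0;
    for (int i = 0; i < N; ++i)
      for (int j = 0; j + 1 < J; ++j) {
        double d = nu[id2(i, j + 1)] - nu[id2(i, j)];
        s += d * d;
      }
    return s;
  }

  double logprior_gaussian_blocks() const {
    double lp = 0.0;
    for (int k = 0; k < K; ++k) lp += R::dnorm(alpha[k], 0.0, sa, 1);
    for (int p = 0; p < P; ++p) lp += R::dnorm(bs[p], 0.0, sb, 1);
    for (int q = 0; q < Q; ++q) lp += R::dnorm(bst[q], 0.0, sb, 1);
    if (K > 1) {
      for (int k = 0; k < K; ++k) {
        lp += literal ? R::dnorm(gs[k], 0.0, sg, 1)
                      : R::dnorm(lgs[k], 0.0, sg, 1);
        lp += R::dnorm(lgt[k], 0.0, sg, 1);
      }
    }
    return lp;
  }

  double logprior_fields() const {
    double lp = 0.5 * rank_s * std::log(tau_us)
      - 0.5 * tau_us * quad_spatial(us.data(), 0);
    for (int k = 0; k < K; ++k)
      lp += 0.5 * rank_s * std::log(tau_usk[k])
        - 0.5 * tau_usk[k] * quad_spatial(&usk[(size_t)N * k], 0);
    lp += 0.5 * rank_t * std::log(tau_ut) - 0.5 * tau_ut * quad_rw(ut.data(), J);
    for (int k = 0; k < K; ++k)
      lp += 0.5 * rank_t * std::log(tau_utk[k])
        - 0.5 * tau_utk[k] * quad_rw(&utk[(size_t)J * k], J);
    lp += 0.5 * rank_nu * std::log(tau_nu) - 0.5 * tau_nu * quad_nu();
    return lp;
  }

  double logprior_tau() const {
    double sc = 1.0 / trate, lp = 0.0;
    lp += R::dgamma(tau_us, tshape, sc, 1) + R::dgamma(tau_ut, tshape, sc, 1)
      + R::dgamma(tau_nu, tshape, sc, 1);
    for (int k = 0; k < K; ++k)
      lp += R::dgamma(tau_usk[k], tshape, sc, 1)
        + R::dgamma(tau_utk[k], tshape, sc, 1);
    return lp;
  }

  double logpost() const {
    return loglik() + logprior_gaussian_blocks() + logprior_fields()
      + logprior_tau();
  }

  // ---- updates -------------------------------------------------------

  void update_alpha(std::vector<double>& sc, Counter* cnt) {
    for (int k = 0; k < K; ++k) {
      double d = sc[k] * norm_rand();
      double a1 = alpha[k], a2 = a1 + d, dll = 0.0;
      for (int j = 0; j < J; ++j)
        for (int i = 0; i < N; ++i) {
          int c = id3(i, j, k);
          dll += cll(c, eta[c] + d) - cll(c, eta[c]);
        }
      double dlp = -0.5 * (a2 * a2 - a1 * a1) / (sa * sa);
      cnt[k].att++;
      if (std::log(unif_rand()) < dll + dlp) {
        cnt[k].acc++;
        alpha[k] = a2;
        for (int j = 0; j < J; ++j)
          for (int i = 0; i < N; ++i) eta[id3(i, j, k)] += d;
      }
    }
  }

  void update_beta_s(std::vector<double>& sc, Counter* cnt) {
    for (int p = 0; p < P; ++p) {
      double d = sc[p] * norm_rand();
      double b1 = bs[p], b2 = b1 + d, dll = 0.0;
      for (int k = 0; k < K; ++k)
        for (int j = 0; j < J; ++j)
          for (int i = 0; i < N; ++i) {
            int c = id3(i, j, k);
            dll += cll(c, eta[c] + d * Xs[i + N * p]) - cll(c, eta[c]);
          }
      double dlp = -0.5 * (b2 * b2 - b1 * b1) / (sb * sb);
      cnt[p].att++;
      if (std::log(unif_rand()) < dll + dlp) {
        cnt[p].acc++;
        bs[p] = b2;
        for (int k = 0; k < K; ++k)
          for (int j = 0; j < J; ++j)
            for (int i = 0; i < N; ++i)
              eta[id3(i, j, k)] += d * Xs[i + N * p];
      }
    }
  }

  void update_beta_st(std::vector<double>& sc, Counter* cnt) {
    for (int q = 0; q < Q; ++q) {
      double d = sc[q] * norm_rand();
      double b1 = bst[q], b2 = b1 + d, dll = 0.0;
      for (int k = 0; k < K; ++k)
        for (int c2 = 0; c2 < N * J; ++c2) {
          int c = c2 + N * J * k;
          dll += cll(c, eta[c] + d * Xst[c2 + N * J * q]) - cll(c, eta[c]);
        }
      double dlp = -0.5 * (b2 * b2 - b1 * b1) / (sb * sb);
      cnt[q].att++;
      if (std::log(unif_rand()) < dll + dlp) {
        cnt[q].acc++;
        bst[q] = b2;
        for (int k = 0; k < K; ++k)
          for (int c2 = 0; c2 < N * J; ++c2)
            eta[c2 + N * J * k] += d * Xst[c2 + N * J * q];
      }
    }
  }

  // shared-weight update: move inside the sum-to-zero (log-)subspace
  void update_gamma(bool spatial, std::vector<double>& sc, Counter* cnt) {
    if (K <= 1) return;
    std::vector<double>& lg = spatial ? lgs : lgt;
    std::vector<double>& g = spatial ? gs : gt;
    const std::vector<double>& field = spatial ? us : ut;
    bool lit = spatial && literal;
    for (int k = 0; k < K; ++k) {
      double d = sc[k] * norm_rand();
      std::vector<double> ng(K), dg(K), nl(K);
      double dlp = 0.0;
      for (int l = 0; l < K; ++l) {
        double step = d * ((l == k ? 1.0 : 0.0) - 1.0 / K);
        if (lit) {
          ng[l] = g[l] + step;
          dlp += -0.5 * (ng[l] * ng[l] - g[l] * g[l]) / (sg * sg);
        } else {
          nl[l] = lg[l] + step;
          ng[l] = std::exp(nl[l]);
          dlp += -0.5 * (nl[l] * nl[l] - lg[l] * lg[l]) / (sg * sg);
        }
        dg[l] = ng[l] - g[l];
      }
      double dll = 0.0;
      if (spatial) {
        for (int l = 0; l < K; ++l) {
          if (dg[l] == 0.0) continue;
          for (int j = 0; j < J; ++j)
            for (int i = 0; i < N; ++i) {
              int c = id3(i, j, l);
              dll += cll(c, eta[c] + dg[l] * field[i]) - cll(c, eta[c]);
            }
        }
      } else {
        for (int l = 0; l < K; ++l) {
          if (dg[l] == 0.0) continue;
          for (int j = 0; j < J; ++j) {
            double de = dg[l] * field[j];
            for (int i = 0; i < N; ++i) {
              int c = id3(i, j, l);
              dll += cll(c, eta[c] + de) - cll(c, eta[c]);
            }
          }
        }
      }
      cnt[k].att++;
      if (std::log(unif_rand()) < dll + dlp) {
        cnt[k].acc++;
        if (spatial) {
          for (int l = 0; l < K; ++l) {
            if (dg[l] != 0.0)
              for (int j = 0; j < J; ++j)
                for (int i = 0; i < N; ++i)
                  eta[id3(i, j, l)] += dg[l] * field[i];
          }
        } else {
          for (int l = 0; l < K; ++l) {
            if (dg[l] != 0.0)
              for (int j = 0; j < J; ++j) {
                double de = dg[l] * field[j];
                for (int i = 0; i < N; ++i) eta[id3(i, j, l)] += de;
              }
          }
        }
        g = ng;
        if (!lit) lg = nl;
      }
    }
  }

  void update_us(double& sc, Counter& cnt) {
    for (int i = 0; i < N; ++i) {
      double d = sc * norm_rand();
      double u1 = us[i], u2 = u1 + d, dll = 0.0;
      for (int k = 0; k < K; ++k) {
        double de = gs[k] * d;
        for (int j = 0; j < J; ++j) {
          int c = id3(i, j, k);
          dll += cll(c, eta[c] + de) - cll(c, eta[c]);
        }
      }
      double dq = 0.0;
      if (adj[i].empty()) {
        dq = u2 * u2 - u1 * u1;
      } else {
        for (int b : adj[i]) {
          double d2 = u2 - us[b], d1 = u1 - us[b];
          dq += d2 * d2 - d1 * d1;
        }
      }
      cnt.att++;
      if (std::log(unif_rand()) < dll - 0.5 * tau_us * dq) {
        cnt.acc++;
        us[i] = u2;
        for (int k = 0; k < K; ++k) {
          double de = gs[k] * d;
          for (int j = 0; j < J; ++j) eta[id3(i, j, k)] += de;
        }
      }
    }
  }

  void update_usk(std::vector<double>& sc, Counter* cnt) {
    for (int k = 0; k < K; ++k) {
      double* col = &usk[(size_t)N * k];
      for (int i = 0; i < N; ++i) {
        double d = sc[k] * norm_rand();
        double u1 = col[i], u2 = u1 + d, dll = 0.0;
        for (int j = 0; j < J; ++j) {
          int c = id3(i, j, k);
          dll += cll(c, eta[c] + d) - cll(c, eta[c]);
        }
        double dq = 0.0;
        if (adj[i].empty()) {
          dq = u2 * u2 - u1 * u1;
        } else {
          for (int b : adj[i]) {
            double d2 = u2 - col[b], d1 = u1 - col[b];
            dq += d2 * d2 - d1 * d1;
          }
        }
        cnt[k].att++;
        if (std::log(unif_rand()) < dll - 0.5 * tau_usk[k] * dq) {
          cnt[k].acc++;
          col[i] = u2;
          for (int j = 0; j < J; ++j) eta[id3(i, j, k)] += d;
        }
      }
    }
  }

  double rw_dq(const double* x, int len, int j, double d) const {
    double u1 = x[j], u2 = x[j] + d, dq = 0.0;
    if (j > 0) {
      double a2 = u2 - x[j - 1], a1 = u1 - x[j - 1];
      dq += a2 * a2 - a1 * a1;
    }
    if (j + 1 < len) {
      double a2 = x[j + 1] - u2, a1 = x[j + 1] - u1;
      dq += a2 * a2 - a1 * a1;
    }
    return dq;
  }

  void update_ut(std::vector<double>& sc, Counter* cnt) {
    for (int j = 0; j < J; ++j) {
      double d = sc[j] * norm_rand();
      double dll = 0.0;
      for (int k = 0; k < K; ++k) {
        double de = gt[k] * d;
        for (int i = 0; i < N; ++i) {
          int c = id3(i, j, k);
          dll += cll(c, eta[c] + de) - cll(c, eta[c]);
        }
      }
      double dq = rw_dq(ut.data(), J, j, d);
      cnt[j].att++;
      if (std::log(unif_rand()) < dll - 0.5 * tau_ut * dq) {
        cnt[j].acc++;
        ut[j] += d;
        for (int k = 0; k < K; ++k) {
          double de = gt[k] * d;
          for (int i = 0; i < N; ++i) eta[id3(i, j, k)] += de;
        }
      }
    }
  }

  void update_utk(std::vector<double>& sc, Counter* cnt) {
    for (int k = 0; k < K; ++k) {
      double* col = &utk[(size_t)J * k];
      for (int j = 0; j < J; ++j) {
        double d = sc[k] * norm_rand();
        double dll = 0.0;
        for (int i = 0; i < N; ++i) {
          int c = id3(i, j, k);
          dll += cll(c, eta[c] + d) - cll(c, eta[c]);
        }
        double dq = rw_dq(col, J, j, d);
        cnt[k].att++;
        if (std::log(unif_rand()) < dll - 0.5 * tau_utk[k] * dq) {
          cnt[k].acc++;
          col[j] += d;
          for (int i = 0; i < N; ++i) eta[id3(i, j, k)] += d;
        }
      }
    }
  }

  void update_nu(double& sc, Counter& cnt) {
    for (int j = 0; j < J; ++j)
      for (int i = 0; i < N; ++i) {
        double d = sc * norm_rand();
        int c2 = id2(i, j);
        double v1 = nu[c2], v2 = v1 + d, dll = 0.0;
        for (int k = 0; k < K; ++k) {
          int c = c2 + N * J * k;
          dll += cll(c, eta[c] + d) - cll(c, eta[c]);
        }
        double dq;
        if (interaction == 0) {
          dq = v2 * v2 - v1 * v1;
        } else {
          dq = 0.0;
          if (j > 0) {
            double a2 = v2 - nu[id2(i, j - 1)], a1 = v1 - nu[id2(i, j - 1)];
            dq += a2 * a2 - a1 * a1;
          }
          if (j + 1 < J) {
            double a2 = nu[id2(i, j + 1)] - v2, a1 = nu[id2(i, j + 1)] - v1;
            dq += a2 * a2 - a1 * a1;
          }
        }
        cnt.att++;
        if (std::log(unif_rand()) < dll - 0.5 * tau_nu * dq) {
          cnt.acc++;
          nu[c2] = v2;
          for (int k = 0; k < K; ++k) eta[c2 + N * J * k] += d;
        }
      }
  }

  void update_tau() {
    tau_us = R::rgamma(tshape + 0.5 * rank_s,
                       1.0 / (trate + 0.5 * quad_spatial(us.data(), 0)));
    for (int k = 0; k < K; ++k)
      tau_usk[k] = R::rgamma(
        tshape + 0.5 * rank_s,
        1.0 / (trate + 0.5 * quad_spatial(&usk[(size_t)N * k], 0)));
    tau_ut = R::rgamma(tshape + 0.5 * rank_t,
                       1.0 / (trate + 0.5 * quad_rw(ut.data(), J)));
    for (int k = 0; k < K; ++k)
      tau_utk[k] = R::rgamma(tshape + 0.5 * rank_t,
                             1.0 / (trate + 0.5 * quad_rw(&utk[(size_t)J * k], J)));
    tau_nu = R::rgamma(tshape + 0.5 * rank_nu, 1.0 / (trate + 0.5 * quad_nu()));
  }

  void apply_constraints() {
    if (K > 1) {
      if (!literal) {
        double ms = 0.0;
        for (int k = 0; k < K; ++k) ms += lgs[k];
        ms /= K;
        for (int k = 0; k < K; ++k) {
          lgs[k] -= ms;
          gs[k] = std::exp(lgs[k]);
        }
        double f = std::exp(ms);
        for (int i = 0; i < N; ++i) us[i] *= f;
      } else {
        double ms = 0.0;
        for (int k = 0; k < K; ++k) ms += gs[k];
        ms /= K;
        for (int k = 0; k < K; ++k) gs[k] -= ms;
        for (int k = 0; k < K; ++k)
          for (int i = 0; i < N; ++i) usk[i + (size_t)N * k] += ms * us[i];
      }
      double mt = 0.0;
      for (int k = 0; k < K; ++k) mt += lgt[k];
      mt /= K;
      for (int k = 0; k < K; ++k) {
        lgt[k] -= mt;
        gt[k] = std::exp(lgt[k]);
      }
      double f = std::exp(mt);
      for (int j = 0; j < J; ++j) ut[j] *= f;
    }
    // shared spatial field: per-component centering, intercept compensation
    double m_all = 0.0;
    for (int i = 0; i < N; ++i) m_all += us[i];
    m_all /= N;
    std::vector<double> cm(ncomp, 0.0);
    for (int i = 0; i < N; ++i) cm[comp[i]] += us[i];
    for (int c = 0; c < ncomp; ++c) cm[c] /= csize[c];
    for (int i = 0; i < N; ++i) us[i] -= cm[comp[i]];
    for (int k = 0; k < K; ++k) alpha[k] += gs[k] * m_all;
    for (int k = 0; k < K; ++k) {
      double* col = &usk[(size_t)N * k];
      double mk = 0.0;
      for (int i = 0; i < N; ++i) mk += col[i];
      mk /= N;
      std::fill(cm.begin(), cm.end(), 0.0);
      for (int i = 0; i < N; ++i) cm[comp[i]] += col[i];
      for (int c = 0; c < ncomp; ++c) cm[c] /= csize[c];
      for (int i = 0; i < N; ++i) col[i] -= cm[comp[i]];
      alpha[k] += mk;
    }
    double mt2 = 0.0;
    for (int j = 0; j < J; ++j) mt2 += ut[j];
    mt2 /= J;
    for (int j = 0; j < J; ++j) ut[j] -= mt2;
    for (int k = 0; k < K; ++k) alpha[k] += gt[k] * mt2;
    for (int k = 0; k < K; ++k) {
      double* col = &utk[(size_t)J * k];
      double mk = 0.0;
      for (int j = 0; j < J; ++j) mk += col[j];
      mk /= J;
      for (int j = 0; j < J; ++j) col[j] -= mk;
      alpha[k] += mk;
    }
    double mn = 0.0;
    for (int c = 0; c < N * J; ++c) mn += nu[c];
    mn /= (N * J);
    for (int c = 0; c < N * J; ++c) nu[c] -= mn;
    for (int k = 0; k < K; ++k) alpha[k] += mn;
  }
};

void fill_from_list(const List& init, const char* name, std::vector<double>& x) {
  if (init.containsElementNamed(name)) {
    NumericVector v = init[name];
    if ((size_t)v.size() != x.size())
      stop("init element '%s' has wrong length", name);
    for (int i = 0; i < v.size(); ++i) x[i] = v[i];
  }
}

void fill_scalar(const List& init, const char* name, double& x) {
  if (init.containsElementNamed(name)) x = as<double>(init[name]);
}

double rate_of(const Counter& c) {
  return c.att > 0 ? (double)c.acc / (double)c.att : NA_REAL;
}

void adapt_scales(std::vector<double>& sc, std::vector<Counter>& cnt,
                  double target) {
  for (size_t i = 0; i < sc.size(); ++i) {
    if (cnt[i].att == 0) continue;
    double r = (double)cnt[i].acc / (double)cnt[i].att;
    sc[i] *= std::exp(r - target);
    if (sc[i] < 1e-4) sc[i] = 1e-4;
    if (sc[i] > 20.0) sc[i] = 20.0;
    cnt[i].att = cnt[i].acc = 0;
  }
}

}  // namespace

// [[Rcpp::export]]
List mwg_chain(IntegerVector dims, NumericVector Y, NumericVector w,
               NumericVector Xs, NumericVector Xst, double lconst,
               List graph, List hyper, List ctrl, List init) {
  Sampler s;
  s.N = dims[0]; s.J = dims[1]; s.K = dims[2]; s.P = dims[3]; s.Q = dims[4];
  const int NJK = s.N * s.J * s.K;
  s.Y.assign(Y.begin(), Y.end());
  s.w.assign(w.begin(), w.end());
  s.Xs.assign(Xs.begin(), Xs.end());
  s.Xst.assign(Xst.begin(), Xst.end());
  s.lconst = lconst;

  IntegerMatrix em = graph["edges"];          // 1-based, m x 2
  s.adj.assign(s.N, {});
  for (int e = 0; e < em.nrow(); ++e) {
    int a = em(e, 0) - 1, b = em(e, 1) - 1;
    s.adj[a].push_back(b);
    s.adj[b].push_back(a);
    s.edges.emplace_back(a, b);
  }
  IntegerVector compv = graph["component"];   // 1-based
  s.comp.resize(s.N);
  s.ncomp = 0;
  for (int i = 0; i < s.N; ++i) {
    s.comp[i] = compv[i] - 1;
    if (s.comp[i] + 1 > s.ncomp) s.ncomp = s.comp[i] + 1;
  }
  s.csize.assign(s.ncomp, 0.0);
  for (int i = 0; i < s.N; ++i) s.csize[s.comp[i]] += 1.0;
  s.rank_s = as<double>(graph["rank_s"]);
  s.rank_t = s.J - 1;
  s.interaction = as<int>(ctrl["interaction"]);
  s.rank_nu = s.interaction == 0 ? s.N * s.J - 1 : (double)s.N * (s.J - 1);

  s.sa = as<double>(hyper["sd_alpha"]);
  s.sb = as<double>(hyper["sd_beta"]);
  s.sg = as<double>(hyper["sd_loggamma"]);
  s.tshape = as<double>(hyper["tau_shape"]);
  s.trate = as<double>(hyper["tau_rate"]);
  s.literal = as<int>(ctrl["literal"]);

  const int n_iter = as<int>(ctrl["n_iter"]);
  const int burn_in = as<int>(ctrl["burn_in"]);
  const int thin = as<int>(ctrl["thin"]);
  const int adapt_interval = as<int>(ctrl["adapt_interval"]);
  const double target = as<double>(ctrl["target_accept"]);
  const bool store_pi = as<bool>(ctrl["store_pi"]);
  LogicalVector upd = ctrl["update"];  // alpha beta gamma us usk ut utk nu tau

  // initial state
  s.alpha.assign(s.K, 0.0);
  fill_from_list(init, "alpha", s.alpha);
  s.bs.assign(s.P, 0.0);  fill_from_list(init, "beta_s", s.bs);
  s.bst.assign(s.Q, 0.0); fill_from_list(init, "beta_st", s.bst);
  s.lgs.assign(s.K, 0.0); s.lgt.assign(s.K, 0.0);
  s.gs.assign(s.K, 1.0);  s.gt.assign(s.K, 1.0);
  if (init.containsElementNamed("gamma_s")) {
    NumericVector g = init["gamma_s"];
    for (int k = 0; k < s.K; ++k) {
      s.gs[k] = g[k];
      if (!s.literal) s.lgs[k] = std::log(g[k]);
    }
  }
  if (init.containsElementNamed("gamma_t")) {
    NumericVector g = init["gamma_t"];
    for (int k = 0; k < s.K; ++k) {
      s.gt[k] = g[k];
      s.lgt[k] = std::log(g[k]);
    }
  }
  s.us.assign(s.N, 0.0);          fill_from_list(init, "u_s", s.us);
  s.usk.assign((size_t)s.N * s.K, 0.0); fill_from_list(init, "u_s_k", s.usk);
  s.ut.assign(s.J, 0.0);          fill_from_list(init, "u_t", s.ut);
  s.utk.assign((size_t)s.J * s.K, 0.0); fill_from_list(init, "u_t_k", s.utk);
  s.nu.assign((size_t)s.N * s.J, 0.0);  fill_from_list(init, "nu", s.nu);
  s.tau_us = s.tau_ut = s.tau_nu = 1.0;
  s.tau_usk.assign(s.K, 1.0);
  s.tau_utk.assign(s.K, 1.0);
  fill_scalar(init, "tau_us", s.tau_us);
  fill_scalar(init, "tau_ut", s.tau_ut);
  fill_scalar(init, "tau_nu", s.tau_nu);
  fill_from_list(init, "tau_usk", s.tau_usk);
  fill_from_list(init, "tau_utk", s.tau_utk);

  s.eta.assign(NJK, 0.0);
  s.recompute_eta();

  double ll0 = s.loglik();
  if (!std::isfinite(ll0))
    stop("non-finite log-likelihood at initialization");
  double lg0 = s.logprior_gaussian_blocks();
  if (!std::isfinite(lg0))
    stop("non-finite intercept/effect/weight prior at initialization");
  double lf0 = s.logprior_fields();
  if (!std::isfinite(lf0))
    stop("non-finite random-effect prior at initialization");
  double lt0 = s.logprior_tau();
  if (!std::isfinite(lt0))
    stop("non-finite precision prior at initialization");
  const double lp0 = ll0 + lg0 + lf0 + lt0;

  // proposal scales and counters
  std::vector<double> sc_alpha(s.K, 0.05), sc_bs(s.P, 0.05),
    sc_bst(s.Q, 0.05), sc_gs(s.K, 0.1), sc_gt(s.K, 0.1), sc_ut(s.J, 0.1),
    sc_utk(s.K, 0.1), sc_usk(s.K, 0.1);
  std::vector<double> sc_us(1, 0.1), sc_nu(1, 0.05);
  std::vector<Counter> c_alpha(s.K), c_bs(s.P), c_bst(s.Q), c_gs(s.K),
    c_gt(s.K), c_ut(s.J), c_utk(s.K), c_usk(s.K), c_us(1), c_nu(1);
  // post-burn-in aggregate counters per block
  Counter p_alpha, p_beta, p_gs, p_gt, p_us, p_usk, p_ut, p_utk, p_nu;

  const int n_keep = thin > 0 ? (n_iter - burn_in) / thin : 0;
  const int n_par = s.K + s.P + s.Q + 2 * s.K + (3 + 2 * s.K) + s.N + s.J + 1;
  NumericMatrix draws(n_keep, n_par);
  NumericMatrix pim(store_pi ? n_keep : 0, store_pi ? NJK : 0);

  int row = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    bool post = iter > burn_in;
    std::vector<Counter> snap_alpha = c_alpha, snap_bs = c_bs,
      snap_bst = c_bst, snap_gs = c_gs, snap_gt = c_gt, snap_us = c_us,
      snap_usk = c_usk, snap_ut = c_ut, snap_utk = c_utk, snap_nu = c_nu;

    if (upd[0]) s.update_alpha(sc_alpha, c_alpha.data());
    if (upd[1]) {
      s.update_beta_s(sc_bs, c_bs.data());
      s.update_beta_st(sc_bst, c_bst.data());
    }
    if (upd[2]) {
      s.update_gamma(true, sc_gs, c_gs.data());
      s.update_gamma(false, sc_gt, c_gt.data());
    }
    if (upd[3]) s.update_us(sc_us[0], c_us[0]);
    if (upd[4]) s.update_usk(sc_usk, c_usk.data());
    if (upd[5]) s.update_ut(sc_ut, c_ut.data());
    if (upd[6]) s.update_utk(sc_utk, c_utk.data());
    if (upd[7]) s.update_nu(sc_nu[0], c_nu[0]);
    if (upd[8]) s.update_tau();

    s.apply_constraints();
    s.recompute_eta();

    if (post) {
      auto add = [](Counter& agg, std::vector<Counter>& now,
                    std::vector<Counter>& before) {
        for (size_t i = 0; i < now.size(); ++i) {
          agg.att += now[i].att - before[i].att;
          agg.acc += now[i].acc - before[i].acc;
        }
      };
      add(p_alpha, c_alpha, snap_alpha);
      add(p_beta, c_bs, snap_bs); add(p_beta, c_bst, snap_bst);
      add(p_gs, c_gs, snap_gs);   add(p_gt, c_gt, snap_gt);
      add(p_us, c_us, snap_us);   add(p_usk, c_usk, snap_usk);
      add(p_ut, c_ut, snap_ut);   add(p_utk, c_utk, snap_utk);
      add(p_nu, c_nu, snap_nu);
    } else if (iter % adapt_interval == 0) {
      adapt_scales(sc_alpha, c_alpha, target);
      adapt_scales(sc_bs, c_bs, target);
      adapt_scales(sc_bst, c_bst, target);
      adapt_scales(sc_gs, c_gs, target);
      adapt_scales(sc_gt, c_gt, target);
      adapt_scales(sc_us, c_us, target);
      adapt_scales(sc_usk, c_usk, target);
      adapt_scales(sc_ut, c_ut, target);
      adapt_scales(sc_utk, c_utk, target);
      adapt_scales(sc_nu, c_nu, target);
    }

    if (post && (iter - burn_in) % thin == 0 && row < n_keep) {
      int c = 0;
      for (int k = 0; k < s.K; ++k) draws(row, c++) = s.alpha[k];
      for (int p = 0; p < s.P; ++p) draws(row, c++) = s.bs[p];
      for (int q = 0; q < s.Q; ++q) draws(row, c++) = s.bst[q];
      for (int k = 0; k < s.K; ++k) draws(row, c++) = s.gs[k];
      for (int k = 0; k < s.K; ++k) draws(row, c++) = s.gt[k];
      draws(row, c++) = s.tau_us;
      for (int k = 0; k < s.K; ++k) draws(row, c++) = s.tau_usk[k];
      draws(row, c++) = s.tau_ut;
      for (int k = 0; k < s.K; ++k) draws(row, c++) = s.tau_utk[k];
      draws(row, c++) = s.tau_nu;
      for (int i = 0; i < s.N; ++i) draws(row, c++) = s.us[i];
      for (int j = 0; j < s.J; ++j) draws(row, c++) = s.ut[j];
      draws(row, c++) = s.logpost();
      if (store_pi) {
        for (int cc = 0; cc < NJK; ++cc)
          pim(row, cc) = 1.0 / (1.0 + std::exp(-s.eta[cc]));
      }
      ++row;
    }
    if (iter % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc = NumericVector::create(
    _["alpha"] = rate_of(p_alpha), _["beta"] = rate_of(p_beta),
    _["gamma_s"] = rate_of(p_gs), _["gamma_t"] = rate_of(p_gt),
    _["u_s"] = rate_of(p_us), _["u_s_k"] = rate_of(p_usk),
    _["u_t"] = rate_of(p_ut), _["u_t_k"] = rate_of(p_utk),
    _["nu"] = rate_of(p_nu));

  List fin = List::create(
    _["alpha"] = s.alpha, _["beta_s"] = s.bs, _["beta_st"] = s.bst,
    _["gamma_s"] = s.gs, _["gamma_t"] = s.gt, _["u_s"] = s.us,
    _["u_s_k"] = s.usk, _["u_t"] = s.ut, _["u_t_k"] = s.utk, _["nu"] = s.nu,
    _["tau_us"] = s.tau_us, _["tau_usk"] = s.tau_usk, _["tau_ut"] = s.tau_ut,
    _["tau_utk"] = s.tau_utk, _["tau_nu"] = s.tau_nu);

  return List::create(_["draws"] = draws,
                      _["pi"] = store_pi ? (RObject)pim : (RObject)R_NilValue,
                      _["lp0"] = lp0, _["accept"] = acc, _["final"] = fin);
}
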