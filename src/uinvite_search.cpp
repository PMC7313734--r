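// Censored-random-walk likelihood and MAP edge-toggle search.
//
// The list likelihood factorizes over steps; step t needs the absorption
// probability at the next item u for a walk from the current item over the
// visited set V = first t-1 items, i.e. e_c' (I - T_VV)^{-1} t_u. The search
// keeps, per list and step, the full inverse W = (I - T_VV)^{-1} (built
// incrementally by block inversion as V grows), the vector z = W t_u and the
// log step factor. A candidate single-edge toggle changes at most two rows of
// [T_VV | t_u], so its new step factor is a rank<=2 Woodbury correction in
// O(k) per affected step. Accepted toggles are confirmed by a guarded full
// recomputation before committing, so screening round-off can never
// accumulate into the trajectory.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

constexpr double NEG_INF = -std::numeric_limits<double>::infinity();
constexpr double SING_TOL = 1e-12;

struct StepCache {
  arma::mat W;     // (I - T_VV)^{-1}, k x k
  arma::vec z;     // W * t_u, length k
  double logf;     // log absorption probability at u
};

struct ListCache {
  std::vector<int> items;       // vocab indices (0-based)
  std::vector<int> pos;         // per vocab node: 1-based position or 0
  double init_lf = NEG_INF;
  std::vector<StepCache> steps; // steps t = 2..L -> index t-2
  double loglik = NEG_INF;
};

// Full (guarded) likelihood of one list; optionally fills the cache.
// Returns -Inf as soon as a step is impossible or numerically degenerate.
double list_loglik_full(const arma::imat& adj, const arma::ivec& deg,
                        long sumdeg, const std::vector<int>& items,
                        ListCache* cache) {
  const int L = (int)items.size();
  if (cache) cache->steps.clear();
  if (L == 0) return 0.0;
  const int x1 = items[0];
  if (deg[x1] == 0 || sumdeg == 0) return NEG_INF;
  double init_lf = std::log((double)deg[x1]) - std::log((double)sumdeg);
  double ll = init_lf;
  arma::mat W;
  for (int t = 2; t <= L; ++t) {
    const int k = t - 1;
    const int xnew = items[t - 2];  // node joining V at this step
    if (deg[xnew] == 0) return NEG_INF;
    if (k == 1) {
      W.set_size(1, 1);
      W(0, 0) = 1.0;  // no self-loops: A = [1]
    } else {
      // grow W by the new row/column for xnew via block inversion
      arma::vec b(k - 1), c(k - 1);
      for (int a = 0; a < k - 1; ++a) {
        const int na = items[a];
        b[a] = -(double)adj(na, xnew) / (double)deg[na];
        c[a] = -(double)adj(xnew, na) / (double)deg[xnew];
      }
      arma::vec Wb = W * b;
      arma::vec cW = W.t() * c;
      double S = 1.0 - arma::dot(c, Wb);
      if (!(S > SING_TOL)) return NEG_INF;
      arma::mat Wnew(k, k);
      Wnew.submat(0, 0, k - 2, k - 2) = W + (Wb * cW.t()) / S;
      Wnew.submat(0, k - 1, k - 2, k - 1) = -Wb / S;
      Wnew.submat(k - 1, 0, k - 1, k - 2) = -cW.t() / S;
      Wnew(k - 1, k - 1) = 1.0 / S;
      W = std::move(Wnew);
    }
    const int u = items[t - 1];
    arma::vec tu(k);
    for (int a = 0; a < k; ++a) {
      const int na = items[a];
      tu[a] = (double)adj(na, u) / (double)deg[na];
    }
    arma::vec z = W * tu;
    double f = z[k - 1];  // current node is the most recently produced item
    if (!std::isfinite(f) || f <= 1e-300) return NEG_INF;
    if (f > 1.0) f = 1.0;
    double lf = std::log(f);
    ll += lf;
    if (cache) cache->steps.push_back(StepCache{W, std::move(z), lf});
  }
  if (cache) {
    cache->init_lf = init_lf;
    cache->loglik = ll;
  }
  return ll;
}

// Screened delta for toggling edge (i, j): change in total log posterior,
// using cached inverses. Exact up to round-off; -Inf means certainly reject.
double toggle_delta(const arma::imat& adj, const arma::ivec& deg, long sumdeg,
                    const std::vector<ListCache>& caches,
                    const std::vector<bool>& in_any_list,
                    const arma::mat& lpe, const arma::mat& lpa,
                    int i, int j) {
  const bool adding = adj(i, j) == 0;
  const int s = adding ? 1 : -1;
  const int di = deg[i] + s, dj = deg[j] + s;
  if ((di == 0 && in_any_list[i]) || (dj == 0 && in_any_list[j])) return NEG_INF;
  const long sd = sumdeg + 2 * s;
  double delta = adding ? (lpe(i, j) - lpa(i, j)) : (lpa(i, j) - lpe(i, j));

  auto newdeg = [&](int v) { return v == i ? di : (v == j ? dj : (int)deg[v]); };
  auto newadj = [&](int a, int b) {
    if ((a == i && b == j) || (a == j && b == i)) return adding ? 1 : 0;
    return (int)adj(a, b);
  };

  // scratch buffers sized to the longest list (thread-local reuse)
  static thread_local std::vector<double> wt_buf, d0_buf, d1_buf;

  for (const ListCache& lc : caches) {
    const int L = (int)lc.items.size();
    if (L == 0) continue;
    const int x1 = lc.items[0];
    const int d1 = newdeg(x1);
    if (d1 == 0) return NEG_INF;
    delta += (std::log((double)d1) - std::log((double)sd)) - lc.init_lf;
    const int pi = lc.pos[i], pj = lc.pos[j];
    int m = INT_MAX;
    if (pi > 0) m = std::min(m, pi);
    if (pj > 0) m = std::min(m, pj);
    if (m == INT_MAX) continue;  // neither endpoint produced in this list
    if ((int)wt_buf.size() < L) {
      wt_buf.resize(L); d0_buf.resize(L); d1_buf.resize(L);
    }
    for (int t = std::max(m + 1, 2); t <= L; ++t) {
      const int k = t - 1;
      const StepCache& sc = lc.steps[t - 2];
      const int u = lc.items[t - 1];
      // rows of [T_VV | t_u] that change: toggled endpoints inside V
      int Rloc[2]; int Rnode[2]; int r = 0;
      if (pi > 0 && pi <= k) { Rloc[r] = pi - 1; Rnode[r] = i; ++r; }
      if (pj > 0 && pj <= k) { Rloc[r] = pj - 1; Rnode[r] = j; ++r; }
      if (r == 0) continue;  // endpoint is u itself or outside; t_u rows fixed
      double* wt = wt_buf.data();           // W * t_u_new
      std::memcpy(wt, sc.z.memptr(), k * sizeof(double));
      double* Drow[2] = {d0_buf.data(), d1_buf.data()};  // changed T rows
      for (int p = 0; p < r; ++p) {
        const int v = Rnode[p];
        const double inv_dn = 1.0 / (double)newdeg(v);
        const double inv_do = 1.0 / (double)deg[v];
        const auto* arow = adj.colptr(v);   // adj symmetric: column == row
        double* dp = Drow[p];
        for (int a = 0; a < k; ++a) {
          const int na = lc.items[a];
          dp[a] = (double)newadj(v, na) * inv_dn - (double)arow[na] * inv_do;
        }
        const double dtv = (double)newadj(v, u) * inv_dn -
                           (double)arow[u] * inv_do;
        if (dtv != 0.0) {
          const double* wc = sc.W.colptr(Rloc[p]);
          for (int a = 0; a < k; ++a) wt[a] += dtv * wc[a];
        }
      }
      // S = I_r - D W[:, R];  y = S^{-1} (D wt);  f = wt[c] + W(c,R) y
      double newf;
      const int c = k - 1;
      if (r == 1) {
        const double* wc = sc.W.colptr(Rloc[0]);
        const double* dp = Drow[0];
        double dw = 0.0, g = 0.0;
        for (int a = 0; a < k; ++a) { dw += dp[a] * wc[a]; g += dp[a] * wt[a]; }
        const double S = 1.0 - dw;
        if (!(std::fabs(S) > SING_TOL)) return NEG_INF;
        newf = wt[c] + wc[c] * g / S;
      } else {
        const double* w0 = sc.W.colptr(Rloc[0]);
        const double* w1 = sc.W.colptr(Rloc[1]);
        double s00 = 0.0, s01 = 0.0, s10 = 0.0, s11 = 0.0, g0 = 0.0, g1 = 0.0;
        const double* dp0 = Drow[0];
        const double* dp1 = Drow[1];
        for (int a = 0; a < k; ++a) {
          s00 += dp0[a] * w0[a]; s01 += dp0[a] * w1[a];
          s10 += dp1[a] * w0[a]; s11 += dp1[a] * w1[a];
          g0 += dp0[a] * wt[a]; g1 += dp1[a] * wt[a];
        }
        const double S00 = 1.0 - s00, S01 = -s01, S10 = -s10, S11 = 1.0 - s11;
        const double det = S00 * S11 - S01 * S10;
        if (!(std::fabs(det) > SING_TOL)) return NEG_INF;
        const double y0 = (S11 * g0 - S01 * g1) / det;
        const double y1 = (-S10 * g0 + S00 * g1) / det;
        newf = wt[c] + w0[c] * y0 + w1[c] * y1;
      }
      if (!std::isfinite(newf) || newf <= 1e-300) return NEG_INF;
      if (newf > 1.0) newf = 1.0;
      delta += std::log(newf) - sc.logf;
    }
  }
  return delta;
}

void fisher_yates(std::vector<int>& v) {
  for (int n = (int)v.size(); n > 1; --n) {
    int k = (int)std::floor(unif_rand() * n);
    if (k >= n) k = n - 1;
    std::swap(v[n - 1], v[k]);
  }
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
double cpp_list_loglik(const arma::imat& adj, const std::vector<int>& items) {
  arma::ivec deg = arma::conv_to<arma::ivec>::from(arma::sum(adj, 1));
  long sumdeg = (long)arma::accu(deg);
  return list_loglik_full(adj, deg, sumdeg, items, nullptr);
}

//' @noRd
// [[Rcpp::export]]
List cpp_uinvite_search(arma::imat adj, const List& lists,
                        const arma::mat& lpe, const arma::mat& lpa,
                        int max_sweeps, double tol) {
  const int n = (int)adj.n_rows;
  arma::ivec deg = arma::conv_to<arma::ivec>::from(arma::sum(adj, 1));
  long sumdeg = (long)arma::accu(deg);

  std::vector<ListCache> caches(lists.size());
  std::vector<bool> in_any_list(n, false);
  for (int l = 0; l < lists.size(); ++l) {
    std::vector<int> items = as<std::vector<int>>(lists[l]);
    caches[l].items = items;
    caches[l].pos.assign(n, 0);
    for (int p = 0; p < (int)items.size(); ++p) {
      caches[l].pos[items[p]] = p + 1;
      in_any_list[items[p]] = true;
    }
  }

  auto total_loglik_cached = [&]() {
    double s = 0.0;
    for (auto& lc : caches) {
      double ll = list_loglik_full(adj, deg, sumdeg, lc.items, &lc);
      if (!std::isfinite(ll)) return NEG_INF;
      s += ll;
    }
    return s;
  };
  auto total_loglik_plain = [&]() {
    double s = 0.0;
    for (auto& lc : caches) {
      double ll = list_loglik_full(adj, deg, sumdeg, lc.items, nullptr);
      if (!std::isfinite(ll)) return NEG_INF;
      s += ll;
    }
    return s;
  };
  auto total_logprior = [&]() {
    double s = 0.0;
    for (int a = 0; a < n; ++a)
      for (int b = a + 1; b < n; ++b)
        s += adj(a, b) ? lpe(a, b) : lpa(a, b);
    return s;
  };
  auto apply_toggle = [&](int i, int j) {
    const int s = adj(i, j) == 0 ? 1 : -1;
    adj(i, j) += s; adj(j, i) += s;
    deg[i] += s; deg[j] += s;
    sumdeg += 2 * s;
  };

  double cur_ll = total_loglik_cached();
  double cur_lp = total_logprior();
  if (!std::isfinite(cur_ll)) {
    stop("initial network has impossible lists; initialization must make every observed transition an edge");
  }
  double cur_post = cur_ll + cur_lp;

  std::vector<int> pair_i, pair_j;
  pair_i.reserve(n * (n - 1) / 2);
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) { pair_i.push_back(a); pair_j.push_back(b); }
  std::vector<int> order(pair_i.size());
  for (size_t q = 0; q < order.size(); ++q) order[q] = (int)q;

  std::vector<double> trace;
  int sweeps = 0, accepted = 0;
  bool converged = false;
  GetRNGstate();
  for (int sw = 0; sw < max_sweeps; ++sw) {
    ++sweeps;
    fisher_yates(order);
    bool improved = false;
    for (int q : order) {
      const int i = pair_i[q], j = pair_j[q];
      double delta = toggle_delta(adj, deg, sumdeg, caches, in_any_list,
                                  lpe, lpa, i, j);
      if (!(delta > tol)) continue;
      // confirm with a full guarded recomputation before committing
      apply_toggle(i, j);
      double new_ll = total_loglik_plain();
      double new_lp = cur_lp + (adj(i, j) ? (lpe(i, j) - lpa(i, j))
                                          : (lpa(i, j) - lpe(i, j)));
      if (std::isfinite(new_ll) && new_ll + new_lp > cur_post + tol) {
        cur_ll = total_loglik_cached();
        cur_lp = new_lp;
        cur_post = cur_ll + cur_lp;
        ++accepted;
        improved = true;
      } else {
        apply_toggle(i, j);  // revert
      }
    }
    trace.push_back(cur_post);
    if (!improved) { converged = true; break; }
  }
  PutRNGstate();

  return List::create(_["adj"] = adj,
                      _["log_posterior"] = cur_post,
                      _["log_likelihood"] = cur_ll,
                      _["log_prior"] = cur_lp,
                      _["sweeps"] = sweeps,
                      _["accepted"] = accepted,
                      _["trace"] = trace,
                      _["converged"] = converged);
}
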