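// Exact branch-and-bound solver for the Potts model alignment problem.
//
// The feasible set is the set of strictly increasing node sets of the
// L_A x L_B alignment graph; the objective is
//   sum sv(i,k) + alpha * sum_{pairs} sw(i,k,j,l) - affine gap costs.
// Matches are enumerated in row order (each alignment generated exactly
// once as an ordered sequence of matches).  At every search node the exact
// score of the committed prefix is known; an upper bound on any completion
// comes from an affine-gap Gotoh DP over the remaining subgrid in which
// each candidate cell carries its field score, its exact coupling to the
// committed prefix, and an optimistic coupling bonus to all future rows
// (each future pair counted once, at its earlier endpoint, clipped at 0).
// A node is pruned when its bound cannot beat the incumbent by more than
// the requested absolute tolerance; the largest pruned bound yields the
// final upper bound, so 2(UB-LB)/(s(A,A)+s(B,B)) <= epsilon is certified
// by construction.

#include <Rcpp.h>
#include <algorithm>
#include <chrono>
#include <vector>

using namespace Rcpp;

namespace {

const double NEG_INF = -1e300;

struct Solver {
  int LA, LB;
  const double* sv;   // LA x LB column-major
  const double* sw;   // (LA, LB, LA, LB) column-major, may be nullptr
  double alpha, go, ge;
  bool free_ends;
  double eps_abs;
  long node_limit;
  double time_limit;

  std::vector<double> B0;  // optimistic future-coupling bonus per cell
  std::vector<double> C;   // exact coupling of each cell to the prefix
  std::vector<int> prefix_i, prefix_k;
  double cur;              // exact score of the committed prefix
  double best;             // incumbent score
  std::vector<int> best_i, best_k;
  double pruned_max;       // largest bound among pruned nodes
  long nodes;
  bool aborted;
  std::chrono::steady_clock::time_point t0;

  // scratch buffers for the bound DP
  std::vector<double> M, Xg, Yg, A1;

  inline double SV(int i, int k) const { return sv[i + (size_t)LA * k]; }
  inline double SW(int i, int k, int j, int l) const {
    return sw[i + (size_t)LA * (k + (size_t)LB * (j + (size_t)LA * l))];
  }
  inline double gapc(int d) const { return d > 0 ? go + ge * d : 0.0; }

  void precompute_bonus() {
    B0.assign((size_t)LA * LB, 0.0);
    if (!sw || alpha == 0.0) return;
    for (int j = 0; j < LA; ++j) {
      for (int l = 0; l < LB; ++l) {
        double tot = 0.0;
        for (int j2 = j + 1; j2 < LA; ++j2) {
          double m = NEG_INF;
          for (int l2 = l + 1; l2 < LB; ++l2) {
            double s = SW(j, l, j2, l2);
            if (s > m) m = s;
          }
          if (m > 0.0) tot += m;
        }
        B0[j + (size_t)LA * l] = alpha * tot;
      }
    }
  }

  void push(int i, int k) {
    prefix_i.push_back(i);
    prefix_k.push_back(k);
    if (sw && alpha != 0.0) {
      for (int j = i + 1; j < LA; ++j)
        for (int l = k + 1; l < LB; ++l)
          C[j + (size_t)LA * l] += alpha * SW(i, k, j, l);
    }
  }
  void pop() {
    int i = prefix_i.back(), k = prefix_k.back();
    prefix_i.pop_back();
    prefix_k.pop_back();
    if (sw && alpha != 0.0) {
      for (int j = i + 1; j < LA; ++j)
        for (int l = k + 1; l < LB; ++l)
          C[j + (size_t)LA * l] -= alpha * SW(i, k, j, l);
    }
  }

  // Score of the prefix viewed as a complete alignment.
  double complete_value(int ic, int kc) const {
    if (prefix_i.empty()) return 0.0;
    if (free_ends) return cur;
    return cur - gapc(LA - 1 - ic) - gapc(LB - 1 - kc);
  }

  // lexicographic-after-size tie rule: fewer pairs first, then smaller
  // (i1,k1,i2,k2,...)
  bool tie_better() const {
    size_t n = prefix_i.size(), m = best_i.size();
    if (n != m) return n < m;
    for (size_t t = 0; t < n; ++t) {
      if (prefix_i[t] != best_i[t]) return prefix_i[t] < best_i[t];
      if (prefix_k[t] != best_k[t]) return prefix_k[t] < best_k[t];
    }
    return false;
  }

  void consider_incumbent(int ic, int kc) {
    double val = complete_value(ic, kc);
    if (val > best + 1e-12 ||
        (std::abs(val - best) <= 1e-12 && tie_better())) {
      best = val;
      best_i = prefix_i;
      best_k = prefix_k;
    }
  }

  // Upper bound on the best continuation after last match (ic, kc);
  // (ic, kc) = (-1, -1) at the root.  Includes the option of stopping.
  double continuation_bound(int ic, int kc) {
    bool has_prefix = !prefix_i.empty();
    double stop_val = 0.0;  // value added by stopping now
    if (has_prefix && !free_ends)
      stop_val = -gapc(LA - 1 - ic) - gapc(LB - 1 - kc);
    int m = LA - 1 - ic, n = LB - 1 - kc;
    if (m <= 0 || n <= 0) return stop_val;

    M.assign((size_t)m * n, NEG_INF);
    Xg.assign((size_t)m * n, NEG_INF);
    Yg.assign((size_t)m * n, NEG_INF);
    A1.assign((size_t)m * n, NEG_INF);
    double bound = stop_val;
    for (int a = 0; a < m; ++a) {
      int gi = ic + 1 + a;
      for (int b = 0; b < n; ++b) {
        int gk = kc + 1 + b;
        size_t id = (size_t)a * n + b;
        double gain = SV(gi, gk) + C[gi + (size_t)LA * gk] + B0[gi + (size_t)LA * gk];
        double lead;
        if (!has_prefix && free_ends)
          lead = 0.0;
        else
          lead = -gapc(a) - gapc(b);
        double prev = lead;
        if (a > 0 && b > 0) {
          size_t pd = (size_t)(a - 1) * n + (b - 1);
          double a2 = std::max(A1[pd], Yg[pd]);
          if (a2 > prev) prev = a2;
        }
        double mm = gain + prev;
        M[id] = mm;
        // row-gap state
        double xg = NEG_INF;
        if (a > 0) {
          size_t up = (size_t)(a - 1) * n + b;
          xg = std::max(M[up] - go - ge, Xg[up] - ge);
        }
        Xg[id] = xg;
        A1[id] = std::max(mm, xg);
        double yg = NEG_INF;
        if (b > 0) {
          size_t lf = (size_t)a * n + (b - 1);
          yg = std::max(A1[lf] - go - ge, Yg[lf] - ge);
        }
        Yg[id] = yg;
        double endv = mm;
        if (!free_ends) endv -= gapc(m - 1 - a) + gapc(n - 1 - b);
        if (endv > bound) bound = endv;
      }
    }
    return bound;
  }

  bool out_of_budget() {
    if (node_limit > 0 && nodes > node_limit) return true;
    if ((nodes & 255) == 0) {
      double el = std::chrono::duration<double>(
                      std::chrono::steady_clock::now() - t0)
                      .count();
      if (el > time_limit) return true;
    }
    return false;
  }

  void dfs(int ic, int kc) {
    if (aborted) return;
    // order children by optimistic value
    std::vector<std::pair<double, std::pair<int, int> > > cands;
    bool first = prefix_i.empty();
    for (int j = ic + 1; j < LA; ++j) {
      for (int l = kc + 1; l < LB; ++l) {
        double trans;
        if (first) {
          trans = free_ends ? 0.0 : -gapc(j) - gapc(l);
        } else {
          trans = -gapc(j - ic - 1) - gapc(l - kc - 1);
        }
        double est = SV(j, l) + C[j + (size_t)LA * l] + B0[j + (size_t)LA * l] + trans;
        cands.push_back(std::make_pair(est, std::make_pair(j, l)));
      }
    }
    std::sort(cands.begin(), cands.end(),
              [](const std::pair<double, std::pair<int, int> >& x,
                 const std::pair<double, std::pair<int, int> >& y) {
                if (x.first != y.first) return x.first > y.first;
                return x.second < y.second;
              });
    for (size_t c = 0; c < cands.size(); ++c) {
      int j = cands[c].second.first, l = cands[c].second.second;
      ++nodes;
      if (out_of_budget()) {
        aborted = true;
        return;
      }
      double trans;
      if (first) {
        trans = free_ends ? 0.0 : -gapc(j) - gapc(l);
      } else {
        trans = -gapc(j - ic - 1) - gapc(l - kc - 1);
      }
      double add = SV(j, l) + C[j + (size_t)LA * l] + trans;
      double save_cur = cur;
      cur += add;
      push(j, l);
      consider_incumbent(j, l);
      double ub = cur + continuation_bound(j, l);
      if (ub <= best + eps_abs + 1e-12) {
        if (ub > pruned_max) pruned_max = ub;
        pop();
        cur = save_cur;
        continue;
      }
      dfs(j, l);
      pop();
      cur = save_cur;
      if (aborted) return;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".solve_alignment_cpp")]]
List solve_alignment_cpp(NumericMatrix sv, SEXP sw_, double alpha,
                         double gap_open, double gap_extend, double eps_abs,
                         bool free_end_gaps, double time_limit,
                         double node_limit) {
  Solver s;
  s.LA = sv.nrow();
  s.LB = sv.ncol();
  s.sv = REAL(sv);
  NumericVector swv;
  s.sw = nullptr;
  if (!Rf_isNull(sw_)) {
    swv = as<NumericVector>(sw_);
    if (swv.size() > 0) s.sw = REAL(swv);
  }
  s.alpha = alpha;
  s.go = gap_open;
  s.ge = gap_extend;
  s.free_ends = free_end_gaps;
  s.eps_abs = eps_abs > 0 ? eps_abs : 0.0;
  s.node_limit = (long)node_limit;
  s.time_limit = time_limit;
  s.cur = 0.0;
  s.best = 0.0;  // empty alignment is always feasible with score 0
  s.pruned_max = NEG_INF;
  s.nodes = 0;
  s.aborted = false;
  s.t0 = std::chrono::steady_clock::now();
  s.C.assign((size_t)s.LA * s.LB, 0.0);
  s.precompute_bonus();

  double root_bound = std::max(0.0, s.continuation_bound(-1, -1));
  s.dfs(-1, -1);

  double UB;
  if (s.aborted) {
    UB = root_bound;
  } else {
    UB = std::max(s.best, s.pruned_max);
  }
  if (UB < s.best) UB = s.best;

  int n = (int)s.best_i.size();
  IntegerMatrix pairs(n, 2);
  for (int t = 0; t < n; ++t) {
    pairs(t, 0) = s.best_i[t] + 1;
    pairs(t, 1) = s.best_k[t] + 1;
  }
  return List::create(
      _["pairs"] = pairs, _["score"] = s.best, _["UB"] = UB,
      _["nodes"] = (double)s.nodes, _["aborted"] = s.aborted,
      _["root_bound"] = root_bound);
}
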