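#include <Rcpp.h>
#include <vector>
#include <cstdint>

// Exact solver for pure-binary minimization programs.  All constraints
// arrive normalized to  sum(coef * x) <= rhs.  Search: depth-first branch
// and bound over a caller-supplied variable order (insertion decisions
// first), value 0 tried before 1, with bounds-consistency propagation at
// every node and pruning against the incumbent.  Objective coefficients
// are assumed non-negative, so the committed objective of the partial
// assignment is a valid lower bound.

namespace {

struct Problem {
  int n;
  std::vector<std::vector<int>> idx;      // variable indices per constraint
  std::vector<std::vector<double>> coef;  // matching coefficients
  std::vector<double> rhs;
  std::vector<double> obj;
  std::vector<int> order;                 // branch order
  double eps = 1e-7;

  long long nodes = 0;
  long long node_limit = 0;
  bool limit_hit = false;
  double best_obj = 0.0;
  bool have_best = false;
  std::vector<int8_t> best_val;

  // Bounds propagation until fixpoint; false on conflict.
  bool propagate(std::vector<int8_t> &val) const {
    const size_t m = rhs.size();
    bool changed = true;
    while (changed) {
      changed = false;
      for (size_t c = 0; c < m; ++c) {
        const std::vector<int> &ix = idx[c];
        const std::vector<double> &cf = coef[c];
        double lb = 0.0;
        for (size_t k = 0; k < ix.size(); ++k) {
          int8_t v = val[ix[k]];
          if (v < 0) {
            if (cf[k] < 0) lb += cf[k];
          } else {
            lb += cf[k] * v;
          }
        }
        if (lb > rhs[c] + eps) return false;
        double slack = rhs[c] - lb;
        for (size_t k = 0; k < ix.size(); ++k) {
          if (val[ix[k]] >= 0) continue;
          if (cf[k] > slack + eps) {          // raising to 1 would violate
            val[ix[k]] = 0;
            changed = true;
          } else if (-cf[k] > slack + eps) {  // leaving at 0 would violate
            val[ix[k]] = 1;
            changed = true;
          }
        }
      }
    }
    return true;
  }

  double committed(const std::vector<int8_t> &val) const {
    double s = 0.0;
    for (int i = 0; i < n; ++i)
      if (val[i] == 1) s += obj[i];
    return s;
  }

  void dfs(std::vector<int8_t> val) {
    if (limit_hit) return;
    if (++nodes > node_limit) { limit_hit = true; return; }
    if (!propagate(val)) return;
    double lb = committed(val);
    if (have_best && lb >= best_obj - eps) return;
    int branch = -1;
    for (size_t k = 0; k < order.size(); ++k) {
      if (val[order[k]] < 0) { branch = order[k]; break; }
    }
    if (branch < 0) {
      best_obj = lb;
      best_val = val;
      have_best = true;
      return;
    }
    std::vector<int8_t> lo(val);
    lo[branch] = 0;
    dfs(std::move(lo));
    val[branch] = 1;
    dfs(std::move(val));
  }
};

} // namespace

// [[Rcpp::export(name = ".solve_ip_cpp")]]
Rcpp::List solve_ip_cpp(int n,
                        Rcpp::List con_idx,
                        Rcpp::List con_coef,
                        Rcpp::NumericVector con_rhs,
                        Rcpp::NumericVector obj,
                        Rcpp::IntegerVector branch_order,
                        Rcpp::IntegerVector init,
                        double node_limit) {
  Problem p;
  p.n = n;
  const int m = con_rhs.size();
  p.idx.resize(m);
  p.coef.resize(m);
  p.rhs.assign(con_rhs.begin(), con_rhs.end());
  for (int c = 0; c < m; ++c) {
    Rcpp::IntegerVector ix = con_idx[c];
    Rcpp::NumericVector cf = con_coef[c];
    p.idx[c].assign(ix.begin(), ix.end());
    p.coef[c].assign(cf.begin(), cf.end());
  }
  p.obj.assign(obj.begin(), obj.end());
  p.order.assign(branch_order.begin(), branch_order.end());
  p.node_limit = static_cast<long long>(node_limit);

  std::vector<int8_t> val(n, -1);
  for (int i = 0; i < n; ++i)
    if (init[i] == 0 || init[i] == 1) val[i] = static_cast<int8_t>(init[i]);

  p.dfs(std::move(val));

  std::string status;
  Rcpp::IntegerVector values(n, NA_INTEGER);
  double objective = NA_REAL;
  if (p.have_best) {
    status = p.limit_hit ? "limit_feasible" : "optimal";
    objective = p.best_obj;
    for (int i = 0; i < n; ++i) values[i] = p.best_val[i];
  } else {
    status = p.limit_hit ? "limit" : "infeasible";
  }
  return Rcpp::List::create(
      Rcpp::Named("status") = status,
      Rcpp::Named("objective") = objective,
      Rcpp::Named("values") = values,
      Rcpp::Named("nodes") = static_cast<double>(p.nodes));
}
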