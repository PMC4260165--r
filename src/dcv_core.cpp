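// Compiled hot path: cross-validated objectives for MLR / PCR candidates and
// the reverse-elimination-method tabu search that scores every single-variable
// flip per iteration.  Everything here is deterministic given the split sets;
// all randomness lives on the R side.
#include <RcppArmadillo.h>
#include <set>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct SplitSet {
  std::vector<uvec> con;
  std::vector<uvec> val;
};

SplitSet as_splits(const Rcpp::List& con_list, const Rcpp::List& val_list) {
  SplitSet s;
  const int m = con_list.size();
  s.con.reserve(m);
  s.val.reserve(m);
  for (int i = 0; i < m; ++i) {
    s.con.push_back(Rcpp::as<uvec>(con_list[i]));  // 0-based
    s.val.push_back(Rcpp::as<uvec>(val_list[i]));
  }
  return s;
}

// Least-squares coefficients on Xs (no intercept); minimum-norm solution when
// the Gram matrix is singular (X'X)^+ X'y = X^+ y.
bool ls_beta(const mat& Xs, const vec& ys, vec& beta) {
  mat G = Xs.t() * Xs;
  vec g = Xs.t() * ys;
  if (solve(beta, G, g, solve_opts::likely_sympd + solve_opts::no_approx))
    return true;
  mat Gi;
  if (!pinv(Gi, G)) return false;
  beta = Gi * g;
  return true;
}

// Mean squared validation error of an MLR candidate over the splits.
// centered == TRUE fits with an intercept (construction means removed).
// A restricted matrix with |subset| >= n_constr is infeasible -> +Inf.
double cv_mlr_generic(const mat& X, const vec& y, const SplitSet& sp,
                      const uvec& sub, bool centered) {
  const unsigned int m = sub.n_elem;
  double ss = 0.0, cnt = 0.0;
  for (size_t s = 0; s < sp.con.size(); ++s) {
    const uvec& ci = sp.con[s];
    const uvec& vi = sp.val[s];
    if (m == 0) {
      const double mu = mean(y(ci));
      vec r = y(vi) - mu;
      ss += dot(r, r);
      cnt += r.n_elem;
      continue;
    }
    if (m >= ci.n_elem) return datum::inf;
    mat Xc = X.submat(ci, sub);
    vec yc = y(ci);
    mat Xv = X.submat(vi, sub);
    double ybar = 0.0;
    if (centered) {
      rowvec mu = mean(Xc, 0);
      Xc.each_row() -= mu;
      Xv.each_row() -= mu;
      ybar = mean(yc);
      yc -= ybar;
    }
    vec beta;
    if (!ls_beta(Xc, yc, beta)) return datum::inf;
    vec r = (y(vi) - ybar) - Xv * beta;
    ss += dot(r, r);
    cnt += vi.n_elem;
  }
  return ss / cnt;
}

// Exact leave-one-out MSE for MLR via the hat-matrix identity
// e_loo,i = e_i / (1 - h_ii); falls back to the explicit loop when the Gram
// matrix is not SPD.  Only used when the split set is full LOO over the rows.
double cv_mlr_loo(const mat& X, const vec& y, const SplitSet& sp,
                  const uvec& sub, bool centered) {
  const unsigned int m = sub.n_elem;
  const unsigned int n = X.n_rows;
  if (m == 0 || m >= n - 1) return cv_mlr_generic(X, y, sp, sub, centered);
  mat Xs = X.cols(sub);
  vec yy = y;
  if (centered) {
    // intercept handled as an extra constant column so leverages are exact
    Xs = join_rows(ones<vec>(n), Xs);
  }
  mat G = Xs.t() * Xs;
  mat Gi;
  if (!inv_sympd(Gi, G)) return cv_mlr_generic(X, y, sp, sub, centered);
  vec beta = Gi * (Xs.t() * yy);
  vec e = yy - Xs * beta;
  vec h = sum((Xs * Gi) % Xs, 1);
  double ss = 0.0;
  for (unsigned int i = 0; i < n; ++i) {
    const double d = 1.0 - h(i);
    if (d < 1e-10) return datum::inf;
    const double r = e(i) / d;
    ss += r * r;
  }
  return ss / n;
}

// PCR validation error per rank r = 1..rmax, rmax = min(|subset|, min n_constr - 1).
// The restricted construction matrix is centered (and optionally autoscaled);
// components with negligible singular value contribute nothing.
vec cv_pcr_ranks(const mat& X, const vec& y, const SplitSet& sp,
                 const uvec& sub, bool scale_cols) {
  const unsigned int m = sub.n_elem;
  unsigned int min_ncon = X.n_rows;
  for (size_t s = 0; s < sp.con.size(); ++s)
    min_ncon = std::min(min_ncon, (unsigned int)sp.con[s].n_elem);
  const int rmax = std::min((int)m, (int)min_ncon - 1);
  if (m == 0 || rmax < 1) return vec();
  vec ss(rmax, fill::zeros);
  double cnt = 0.0;
  mat U, V;
  vec sv;
  for (size_t s = 0; s < sp.con.size(); ++s) {
    const uvec& ci = sp.con[s];
    const uvec& vi = sp.val[s];
    mat Xc = X.submat(ci, sub);
    mat Xv = X.submat(vi, sub);
    rowvec mu = mean(Xc, 0);
    Xc.each_row() -= mu;
    Xv.each_row() -= mu;
    if (scale_cols) {
      rowvec sd = stddev(Xc, 0, 0);
      sd.elem(find(sd < 1e-12)).fill(1.0);
      Xc.each_row() /= sd;
      Xv.each_row() /= sd;
    }
    vec yc = y(ci);
    const double ybar = mean(yc);
    yc -= ybar;
    if (!svd_econ(U, sv, V, Xc)) return vec();
    const double tol = (sv.n_elem ? sv.max() : 0.0) * 1e-10;
    vec resid = y(vi) - ybar;
    for (int r = 0; r < rmax; ++r) {
      if (r < (int)sv.n_elem && sv(r) > tol) {
        const double alpha = dot(U.col(r), yc) / sv(r);
        resid -= (Xv * V.col(r)) * alpha;
      }
      ss(r) += dot(resid, resid);
    }
    cnt += vi.n_elem;
  }
  return ss / cnt;
}

// Score one candidate subset: technique 0 = MLR, 1 = PCR (rank co-optimised).
void score_candidate(const mat& X, const vec& y, const SplitSet& sp,
                     const std::vector<char>& state, int technique,
                     bool centered, bool scale_cols, bool loo,
                     double& obj, int& rank) {
  uvec sub(std::count(state.begin(), state.end(), (char)1));
  unsigned int k = 0;
  for (size_t j = 0; j < state.size(); ++j)
    if (state[j]) sub(k++) = j;
  rank = NA_INTEGER;
  if (technique == 0 || sub.n_elem == 0) {
    obj = loo ? cv_mlr_loo(X, y, sp, sub, centered)
              : cv_mlr_generic(X, y, sp, sub, centered);
    return;
  }
  vec per_rank = cv_pcr_ranks(X, y, sp, sub, scale_cols);
  if (per_rank.n_elem == 0) {
    obj = datum::inf;
    return;
  }
  const uword best = per_rank.index_min();
  obj = per_rank(best);
  rank = (int)best + 1;
}

}  // namespace

// [[Rcpp::export]]
double cpp_cv_mlr(const arma::mat& X, const arma::vec& y,
                  const Rcpp::List& con_list, const Rcpp::List& val_list,
                  const arma::uvec& subset0, bool centered, bool loo_shortcut) {
  SplitSet sp = as_splits(con_list, val_list);
  if (loo_shortcut) return cv_mlr_loo(X, y, sp, subset0, centered);
  return cv_mlr_generic(X, y, sp, subset0, centered);
}

// [[Rcpp::export]]
arma::vec cpp_cv_pcr(const arma::mat& X, const arma::vec& y,
                     const Rcpp::List& con_list, const Rcpp::List& val_list,
                     const arma::uvec& subset0, bool scale_cols) {
  SplitSet sp = as_splits(con_list, val_list);
  return cv_pcr_ranks(X, y, sp, subset0, scale_cols);
}

// Reverse-elimination-method tabu search.  Per iteration every single-variable
// flip of the current subset is scored; the best non-tabu move is executed
// (steepest descent if improving, else mildest ascent); a move recreating any
// previously visited subset is tabu.  Returns the best-so-far configuration.
// [[Rcpp::export]]
Rcpp::List cpp_remts(const arma::mat& X, const arma::vec& y,
                     const Rcpp::List& con_list, const Rcpp::List& val_list,
                     int technique, int n_iterations,
                     const arma::uvec& start0, bool centered, bool scale_cols,
                     bool loo_shortcut) {
  SplitSet sp = as_splits(con_list, val_list);
  const unsigned int p = X.n_cols;

  std::vector<char> current(p, 0);
  for (uword i = 0; i < start0.n_elem; ++i) current[start0(i)] = 1;

  std::set<std::vector<char> > visited;
  std::vector<std::vector<char> > order;
  std::vector<double> objs;
  long moves_evaluated = 0;

  double cur_obj;
  int cur_rank;
  score_candidate(X, y, sp, current, technique, centered, scale_cols,
                  loo_shortcut, cur_obj, cur_rank);
  visited.insert(current);
  order.push_back(current);
  objs.push_back(cur_obj);

  std::vector<char> best_state = current;
  double best_obj = cur_obj;
  int best_rank = cur_rank;

  for (int iter = 0; iter < n_iterations; ++iter) {
    int best_j = -1, mv_rank = NA_INTEGER;
    double mv_obj = datum::inf;
    for (unsigned int j = 0; j < p; ++j) {
      std::vector<char> cand = current;
      cand[j] = cand[j] ? 0 : 1;
      if (visited.count(cand)) continue;  // tabu: already visited
      double o;
      int r;
      score_candidate(X, y, sp, cand, technique, centered, scale_cols,
                      loo_shortcut, o, r);
      ++moves_evaluated;
      if (o < mv_obj) {  // strict < keeps the lowest flipped index on ties
        mv_obj = o;
        best_j = (int)j;
        mv_rank = r;
      }
    }
    if (best_j < 0 || !std::isfinite(mv_obj)) break;  // all tabu or infeasible
    current[best_j] = current[best_j] ? 0 : 1;
    visited.insert(current);
    order.push_back(current);
    objs.push_back(mv_obj);
    if (mv_obj < best_obj) {
      best_obj = mv_obj;
      best_state = current;
      best_rank = mv_rank;
    }
  }

  Rcpp::List visited_out(order.size());
  for (size_t i = 0; i < order.size(); ++i) {
    std::vector<int> idx;
    for (unsigned int j = 0; j < p; ++j)
      if (order[i][j]) idx.push_back((int)j + 1);
    visited_out[i] = Rcpp::wrap(idx);
  }
  std::vector<int> best_idx;
  for (unsigned int j = 0; j < p; ++j)
    if (best_state[j]) best_idx.push_back((int)j + 1);

  return Rcpp::List::create(
      Rcpp::Named("visited") = visited_out,
      Rcpp::Named("objective_per_iteration") = Rcpp::wrap(objs),
      Rcpp::Named("best_subset") = Rcpp::wrap(best_idx),
      Rcpp::Named("best_rank") = best_rank,
      Rcpp::Named("best_objective") = best_obj,
      Rcpp::Named("moves_evaluated") = (double)moves_evaluated);
}
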