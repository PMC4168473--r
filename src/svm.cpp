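// C-SVM with RBF kernel, solved by SMO with maximal-violating-pair working
// set selection on a precomputed kernel matrix. Sized for the small cohorts
// this package targets (tens of subjects), where cross-validated grid
// search and greedy forward index selection dominate the cost.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct SvmModel {
  std::vector<double> alpha_y; // alpha_i * y_i
  double b;
};

// K: n x n kernel (row-major irrelevant, symmetric), y in {-1,+1}
// max_iter: for well-posed kernels at these n the MVP rule converges in
// O(n) iterations; degenerate near-constant kernels (eta ~ 0) can cycle
// between box bounds, so the cap keeps them cheap and deterministic.
SvmModel smo_solve(const std::vector<double>& K, const std::vector<int>& y,
                   int n, double C, double eps = 1e-3,
                   int max_iter = 1000) {
  std::vector<double> alpha(n, 0.0), u(n, 0.0);
  for (int it = 0; it < max_iter; ++it) {
    // violation v_i = y_i - u_i ; I_up / I_low membership
    int i = -1, j = -1;
    double m = -1e300, M = 1e300;
    for (int t = 0; t < n; ++t) {
      double v = y[t] - u[t];
      bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      bool lo = (y[t] == -1 && alpha[t] < C) || (y[t] == 1 && alpha[t] > 0);
      if (up && v > m) { m = v; i = t; }
      if (lo && v < M) { M = v; j = t; }
    }
    if (i < 0 || j < 0 || m - M < eps) break;
    const double* Ki = &K[(size_t)i * n];
    const double* Kj = &K[(size_t)j * n];
    double eta = Ki[i] + Kj[j] - 2.0 * Ki[j];
    if (eta < 1e-12) eta = 1e-12;
    // E_i - E_j = u_i - y_i - (u_j - y_j)
    double aj_old = alpha[j], ai_old = alpha[i];
    double aj = aj_old + y[j] * ((u[i] - y[i]) - (u[j] - y[j])) / eta;
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C, C + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C);
      H = std::min(C, ai_old + aj_old);
    }
    if (aj < L) aj = L;
    if (aj > H) aj = H;
    if (std::fabs(aj - aj_old) < 1e-14) break;
    double ai = ai_old + y[i] * y[j] * (aj_old - aj);
    alpha[i] = ai; alpha[j] = aj;
    double di = (ai - ai_old) * y[i], dj = (aj - aj_old) * y[j];
    for (int t = 0; t < n; ++t) u[t] += di * Ki[t] + dj * Kj[t];
  }
  // b from the violation band
  double m = -1e300, M = 1e300;
  for (int t = 0; t < n; ++t) {
    double v = y[t] - u[t];
    bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
    bool lo = (y[t] == -1 && alpha[t] < C) || (y[t] == 1 && alpha[t] > 0);
    if (up && v > m) m = v;
    if (lo && v < M) M = v;
  }
  double b;
  if (m <= -1e299) b = M;
  else if (M >= 1e299) b = m;
  else b = (m + M) / 2.0;
  SvmModel mod;
  mod.alpha_y.resize(n);
  for (int t = 0; t < n; ++t) mod.alpha_y[t] = alpha[t] * y[t];
  mod.b = b;
  return mod;
}

inline double rbf(double d2, double inv2s2) { return std::exp(-d2 * inv2s2); }

} // namespace

// Cross-validated predictions. D: n x n squared-distance matrix; fold: fold
// id per sample (samples sharing an id are held out together; id 0 = always
// in training, never predicted). Returns predictions in {-1, +1}, 0 when the
// training fold was single-class (fold skipped).
// [[Rcpp::export(name = ".cpp_svm_cv_predict")]]
IntegerVector cpp_svm_cv_predict(NumericMatrix D, IntegerVector y, double C,
                                 double sigma, IntegerVector fold) {
  int n = D.nrow();
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  IntegerVector pred(n, 0);
  std::vector<int> ids;
  for (int t = 0; t < n; ++t)
    if (fold[t] > 0 &&
        std::find(ids.begin(), ids.end(), fold[t]) == ids.end())
      ids.push_back(fold[t]);
  for (int f : ids) {
    std::vector<int> tr, te;
    for (int t = 0; t < n; ++t) (fold[t] == f ? te : tr).push_back(t);
    int ntr = tr.size();
    if (ntr == 0) continue;
    bool pos = false, neg = false;
    for (int t : tr) { if (y[t] == 1) pos = true; else neg = true; }
    if (!pos || !neg) continue; // degenerate fold, skipped
    std::vector<double> K((size_t)ntr * ntr);
    std::vector<int> ytr(ntr);
    for (int a = 0; a < ntr; ++a) {
      ytr[a] = y[tr[a]];
      for (int b = 0; b <= a; ++b) {
        double k = rbf(D(tr[a], tr[b]), inv2s2);
        K[(size_t)a * ntr + b] = k;
        K[(size_t)b * ntr + a] = k;
      }
    }
    SvmModel mod = smo_solve(K, ytr, ntr, C);
    for (int t : te) {
      double s = mod.b;
      for (int a = 0; a < ntr; ++a)
        s += mod.alpha_y[a] * rbf(D(tr[a], t), inv2s2);
      pred[t] = s >= 0 ? 1 : -1;
    }
  }
  return pred;
}

// Train on all rows of Dtrain, predict columns of Dcross (ntrain x ntest
// squared distances).
// [[Rcpp::export(name = ".cpp_svm_train_predict")]]
IntegerVector cpp_svm_train_predict(NumericMatrix Dtrain, IntegerVector y,
                                    double C, double sigma,
                                    NumericMatrix Dcross) {
  int n = Dtrain.nrow(), m = Dcross.ncol();
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  std::vector<double> K((size_t)n * n);
  std::vector<int> yy(n);
  for (int a = 0; a < n; ++a) {
    yy[a] = y[a];
    for (int b = 0; b <= a; ++b) {
      double k = rbf(Dtrain(a, b), inv2s2);
      K[(size_t)a * n + b] = k;
      K[(size_t)b * n + a] = k;
    }
  }
  SvmModel mod = smo_solve(K, yy, n, C);
  IntegerVector pred(m);
  for (int t = 0; t < m; ++t) {
    double s = mod.b;
    for (int a = 0; a < n; ++a)
      s += mod.alpha_y[a] * rbf(Dcross(a, t), inv2s2);
    pred[t] = s >= 0 ? 1 : -1;
  }
  return pred;
}

namespace {

// CV predictions from a full kernel matrix K (n x n); fold id 0 = always
// training. Writes into pred (+1/-1, 0 = skipped single-class fold).
void cv_predict_kernel(const std::vector<double>& K, const int* y, int n,
                       double C, const int* fold,
                       const std::vector<int>& fold_ids,
                       std::vector<int>& pred) {
  std::fill(pred.begin(), pred.end(), 0);
  std::vector<int> tr, te;
  std::vector<double> Ktr;
  std::vector<int> ytr;
  for (int f : fold_ids) {
    tr.clear(); te.clear();
    for (int t = 0; t < n; ++t) (fold[t] == f ? te : tr).push_back(t);
    int ntr = tr.size();
    if (ntr == 0 || te.empty()) continue;
    bool pos = false, neg = false;
    for (int t : tr) { if (y[t] == 1) pos = true; else neg = true; }
    if (!pos || !neg) continue;
    Ktr.assign((size_t)ntr * ntr, 0.0);
    ytr.resize(ntr);
    for (int a = 0; a < ntr; ++a) {
      ytr[a] = y[tr[a]];
      const double* Krow = &K[(size_t)tr[a] * n];
      for (int b = 0; b <= a; ++b) {
        double k = Krow[tr[b]];
        Ktr[(size_t)a * ntr + b] = k;
        Ktr[(size_t)b * ntr + a] = k;
      }
    }
    SvmModel mod = smo_solve(Ktr, ytr, ntr, C);
    for (int t : te) {
      double s = mod.b;
      const double* Kcol = &K[(size_t)t * n];
      for (int a = 0; a < ntr; ++a) s += mod.alpha_y[a] * Kcol[tr[a]];
      pred[t] = s >= 0 ? 1 : -1;
    }
  }
}

} // namespace

// CV predictions from an explicit kernel matrix (same engine the greedy
// selection uses); lets callers reproduce its results bit-exactly.
// [[Rcpp::export(name = ".cpp_svm_cv_predict_K")]]
IntegerVector cpp_svm_cv_predict_K(NumericMatrix K, IntegerVector y,
                                   double C, IntegerVector fold) {
  int n = K.nrow();
  std::vector<double> Kv((size_t)n * n);
  for (int a = 0; a < n; ++a)
    for (int b = 0; b < n; ++b) Kv[(size_t)a * n + b] = K(b, a);
  std::vector<int> yv(n), fv(n), pred(n);
  for (int t = 0; t < n; ++t) { yv[t] = y[t]; fv[t] = fold[t]; }
  std::vector<int> fold_ids;
  for (int t = 0; t < n; ++t)
    if (fv[t] > 0 &&
        std::find(fold_ids.begin(), fold_ids.end(), fv[t]) == fold_ids.end())
      fold_ids.push_back(fv[t]);
  cv_predict_kernel(Kv, yv.data(), n, C, fv.data(), fold_ids, pred);
  IntegerVector out(n);
  for (int t = 0; t < n; ++t) out[t] = pred[t];
  return out;
}

// Greedy forward selection over per-feature squared-distance matrices.
// Dcube: n*n*F array. The RBF kernel factorizes over features, so each
// candidate's kernel is the current kernel times a precomputed per-feature
// factor (no exp in the inner loop). At each step adds the candidate
// maximizing CV accuracy; ties go to the earliest candidate (caller passes
// features in lexicographic name order). Returns 1-based selection order
// and the CV prediction matrix (step x n).
// [[Rcpp::export(name = ".cpp_svm_greedy_select")]]
List cpp_svm_greedy_select(NumericVector Dcube, IntegerVector y, double C,
                           double sigma, int max_indices,
                           IntegerVector fold) {
  IntegerVector dim = Dcube.attr("dim");
  int n = dim[0], F = dim[2];
  int steps = std::min(max_indices, F);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  size_t nn = (size_t)n * n;
  std::vector<double> E(nn * F);           // exp(-Df/(2 sigma^2))
  for (size_t i = 0; i < nn * (size_t)F; ++i) E[i] = std::exp(-Dcube[i] * inv2s2);
  std::vector<double> Kcur(nn, 1.0), Ktmp(nn);
  std::vector<int> yv(n), fv(n);
  for (int t = 0; t < n; ++t) { yv[t] = y[t]; fv[t] = fold[t]; }
  std::vector<int> fold_ids;
  for (int t = 0; t < n; ++t)
    if (fv[t] > 0 &&
        std::find(fold_ids.begin(), fold_ids.end(), fv[t]) == fold_ids.end())
      fold_ids.push_back(fv[t]);
  std::vector<bool> used(F, false);
  IntegerVector order(steps);
  IntegerMatrix preds(steps, n);
  std::vector<int> p(n), best_pred(n);
  for (int s = 0; s < steps; ++s) {
    double best_acc = -1.0;
    int best_f = -1;
    for (int f = 0; f < F; ++f) {
      if (used[f]) continue;
      const double* Ef = &E[(size_t)f * nn];
      for (size_t i = 0; i < nn; ++i) Ktmp[i] = Kcur[i] * Ef[i];
      cv_predict_kernel(Ktmp, yv.data(), n, C, fv.data(), fold_ids, p);
      int ok = 0, tot = 0;
      for (int t = 0; t < n; ++t)
        if (p[t] != 0) { ++tot; if (p[t] == yv[t]) ++ok; }
      double acc = tot ? (double)ok / tot : 0.0;
      if (acc > best_acc + 1e-12) { best_acc = acc; best_f = f; best_pred = p; }
    }
    if (best_f < 0) break;
    used[best_f] = true;
    order[s] = best_f + 1;
    const double* Ef = &E[(size_t)best_f * nn];
    for (size_t i = 0; i < nn; ++i) Kcur[i] *= Ef[i];
    for (int t = 0; t < n; ++t) preds(s, t) = best_pred[t];
  }
  return List::create(_["order"] = order, _["preds"] = preds);
}
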