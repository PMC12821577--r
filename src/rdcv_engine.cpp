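// Repeated double cross-validation engine for PLS-LDA.
//
// The fold layout (outer fold per sample per repetition, inner fold per
// training sample per outer fold) is generated on the R side with R's
// RNG, so results are reproducible from a single seed; everything here
// is deterministic given those assignments.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct PLSFit {
  mat R;   // p x A rotation: scores = Xc * R
  mat T;   // n x A scores
  int A;
};

// NIPALS PLS1 on centered X, centered y.
PLSFit pls1(const mat& Xc, const vec& yc, int Amax) {
  const int n = Xc.n_rows, p = Xc.n_cols;
  int A = std::min(Amax, std::min(p, n - 1));
  mat W(p, A, fill::zeros), P(p, A, fill::zeros), T(n, A, fill::zeros);
  mat Xd = Xc;
  int a_eff = 0;
  for (int a = 0; a < A; ++a) {
    vec w = Xd.t() * yc;
    double nw = norm(w);
    if (nw < 1e-12) break;
    w /= nw;
    vec t = Xd * w;
    double tt = dot(t, t);
    if (tt < 1e-12) break;
    vec pv = Xd.t() * t / tt;
    Xd -= t * pv.t();
    W.col(a) = w; P.col(a) = pv; T.col(a) = t;
    a_eff = a + 1;
  }
  PLSFit f;
  f.A = a_eff;
  if (a_eff == 0) return f;
  W = W.head_cols(a_eff); P = P.head_cols(a_eff); T = T.head_cols(a_eff);
  f.R = W * inv(P.t() * W);
  f.T = T;
  return f;
}

// Two-class LDA on score matrix; dir/cutoff define: class1 iff
// t * dir > cutoff. Priors = class frequencies.
void lda2(const mat& T, const uvec& i1, const uvec& i0, double ridge,
          vec& dir, double& cutoff) {
  rowvec m1 = mean(T.rows(i1), 0);
  rowvec m0 = mean(T.rows(i0), 0);
  mat C1 = T.rows(i1); C1.each_row() -= m1;
  mat C0 = T.rows(i0); C0.each_row() -= m0;
  mat S = (C1.t() * C1 + C0.t() * C0) / (double)(T.n_rows - 2);
  S.diag() += ridge * trace(S) / (double)T.n_cols + 1e-300;
  dir = solve(S, (m1 - m0).t(), solve_opts::fast);
  cutoff = 0.5 * dot(dir, (m1 + m0).t()) -
    std::log((double)i1.n_elem / (double)i0.n_elem);
}

// Fit PLS-LDA on (Xtr, ytr) and, for every component count a = 1..A,
// classify Xval and store the unit-norm variable weight vector.
// err(a-1) = misclassification rate; Wout.col(a-1) = weights.
int fit_eval(const mat& Xtr, const ivec& ytr, const mat& Xval,
             const ivec& yval, int Amax, double ridge,
             vec& err, mat& Wout, imat* pred_out = nullptr) {
  rowvec mu = mean(Xtr, 0);
  mat Xc = Xtr; Xc.each_row() -= mu;
  vec yc = conv_to<vec>::from(ytr);
  yc -= mean(yc);
  PLSFit f = pls1(Xc, yc, Amax);
  if (f.A == 0) return 0;
  uvec i1 = find(ytr == 1), i0 = find(ytr == 0);
  mat Xv = Xval; Xv.each_row() -= mu;
  mat Tv = Xv * f.R;
  for (int a = 1; a <= f.A; ++a) {
    vec dir; double cutoff;
    lda2(f.T.head_cols(a), i1, i0, ridge, dir, cutoff);
    vec sv = Tv.head_cols(a) * dir;
    int wrong = 0;
    for (uword i = 0; i < sv.n_elem; ++i) {
      int cl = sv(i) > cutoff ? 1 : 0;
      if (cl != yval(i)) ++wrong;
      if (pred_out) (*pred_out)(i, a - 1) = cl;
    }
    err(a - 1) = (double)wrong / (double)sv.n_elem;
    vec w = f.R.head_cols(a) * dir;
    double nw = norm(w);
    Wout.col(a - 1) = nw > 0 ? vec(w / nw) : w;
  }
  return f.A;
}

// 1-SE component choice with a discreteness floor on the SE: half a
// misclassified sample in an average validation fold.
int choose_A(const mat& errs, int A_eff, double n_val_avg) {
  vec m(A_eff), se(A_eff);
  for (int a = 0; a < A_eff; ++a) {
    vec col = errs.col(a);
    m(a) = mean(col);
    se(a) = col.n_elem > 1 ? stddev(col) / std::sqrt((double)col.n_elem) : 0.0;
  }
  double floor_se = 0.5 / n_val_avg;
  uword best; m.min(best);
  double thr = m(best) + std::max(se(best), floor_se);
  for (int a = 0; a < A_eff; ++a) if (m(a) <= thr) return a + 1;
  return best + 1;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List rdcv_engine_cpp(const arma::mat& X, const arma::ivec& y,
                           const arma::imat& outer_folds,
                           const arma::icube& inner_folds,
                           int Amax, double ridge) {
  const int n = X.n_rows, p = X.n_cols;
  const int reps = outer_folds.n_cols;
  const int kout = outer_folds.max();
  const int kin = inner_folds.max();

  imat pred(n, reps, fill::value(-1));
  imat chosenA(kout, reps, fill::zeros);
  mat Wrep(reps, p, fill::zeros);
  mat Wfold(reps * kout, p, fill::zeros);
  ivec sign_pos(p, fill::zeros), sign_neg(p, fill::zeros);

  auto count_signs = [&](const vec& w) {
    for (int j = 0; j < p; ++j) {
      if (w(j) > 0) sign_pos(j)++;
      else if (w(j) < 0) sign_neg(j)++;
    }
  };

  for (int r = 0; r < reps; ++r) {
    mat wrep_sum(p, 1, fill::zeros);
    int n_fold_models = 0;
    for (int k = 1; k <= kout; ++k) {
      uvec te = find(outer_folds.col(r) == k);
      uvec tr = find(outer_folds.col(r) != k);
      if (te.n_elem == 0 || tr.n_elem < 4) continue;
      ivec ytr = y.elem(tr);

      // ---- inner loop ----
      mat errs(kin, Amax, fill::value(datum::nan));
      std::vector<mat> innerW(kin);
      int A_eff = Amax;
      double val_sum = 0; int val_folds = 0;
      for (int j = 1; j <= kin; ++j) {
        uvec loc_itr, loc_ival;
        {
          std::vector<uword> vi, vv;
          for (uword t = 0; t < tr.n_elem; ++t) {
            int f = inner_folds(tr(t), k - 1, r);
            if (f == j) vv.push_back(tr(t)); else vi.push_back(tr(t));
          }
          loc_itr = uvec(vi); loc_ival = uvec(vv);
        }
        if (loc_ival.n_elem == 0 || loc_itr.n_elem < 4) { innerW[j-1] = mat(); continue; }
        vec err(Amax, fill::value(datum::nan));
        mat Wj(p, Amax, fill::zeros);
        int Aj = fit_eval(X.rows(loc_itr), y.elem(loc_itr),
                          X.rows(loc_ival), y.elem(loc_ival),
                          Amax, ridge, err, Wj);
        if (Aj == 0) { innerW[j-1] = mat(); continue; }
        errs.row(j - 1) = err.t();
        innerW[j - 1] = Wj;
        A_eff = std::min(A_eff, Aj);
        val_sum += loc_ival.n_elem; ++val_folds;
      }
      if (val_folds == 0) continue;
      // keep only rows with results
      std::vector<uword> ok;
      for (int j = 0; j < kin; ++j)
        if (innerW[j].n_elem > 0) ok.push_back(j);
      mat errs_ok(ok.size(), A_eff);
      for (size_t j = 0; j < ok.size(); ++j)
        errs_ok.row(j) = errs.row(ok[j]).head(A_eff);
      int Ak = choose_A(errs_ok, A_eff, val_sum / val_folds);
      chosenA(k - 1, r) = Ak;

      // ---- outer refit ----
      vec err_dummy(Amax, fill::zeros);
      mat Wk(p, Amax, fill::zeros);
      imat pk(te.n_elem, Amax, fill::zeros);
      int Ao = fit_eval(X.rows(tr), ytr, X.rows(te), y.elem(te),
                        Amax, ridge, err_dummy, Wk, &pk);
      if (Ao == 0) continue;
      int Ause = std::min(Ak, Ao);
      for (uword i = 0; i < te.n_elem; ++i) pred(te(i), r) = pk(i, Ause - 1);
      vec w = Wk.col(Ause - 1);
      Wfold.row(r * kout + (k - 1)) = w.t();
      wrep_sum += w;
      ++n_fold_models;
      count_signs(w);
      for (size_t j = 0; j < ok.size(); ++j) {
        vec wi = innerW[ok[j]].col(std::min(Ause, A_eff) - 1);
        count_signs(wi);
      }
    }
    if (n_fold_models > 0) Wrep.row(r) = (wrep_sum / n_fold_models).t();
  }

  return Rcpp::List::create(
      Rcpp::Named("pred") = pred,
      Rcpp::Named("chosen_A") = chosenA,
      Rcpp::Named("weights_rep") = Wrep,
      Rcpp::Named("weights_fold") = Wfold,
      Rcpp::Named("sign_pos") = sign_pos,
      Rcpp::Named("sign_neg") = sign_neg);
}
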