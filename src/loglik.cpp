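// Marginal Gaussian likelihood machinery for the disease-age-parameterized
// mixed-effects model.  Data are stacked per patient; within a patient the
// covariance of the transformed responses is
//
//   V_j = sigma_eps^2 I + sigma_zeta^2 (w w^T) + sigma_delta^2 blockdiag_i(w_i w_i^T)
//
// where w holds the per-row random-effect loading (the working covariable
// x-tilde of the row's eye; identically 1 in the unconstrained model) and the
// inner blocks run over the eyes of the patient.  The residual variance and
// the fixed effects are profiled out, leaving a 2-dimensional optimization
// over the variance ratios psi_delta = sigma_delta^2/sigma_eps^2 and
// psi_zeta = sigma_zeta^2/sigma_eps^2 (handled by an internal Nelder-Mead on
// the log scale).
//
// Rows MUST be sorted so that patients and, within a patient, eyes occupy
// contiguous runs; `patient` and `eyeid` are 1-based consecutive codes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct BlockIndex {
  std::vector<uword> pat_start;  // start row of each patient (plus sentinel)
  std::vector<uword> eye_start;  // start row of each eye (plus sentinel)
};

BlockIndex make_blocks(const ivec& patient, const ivec& eyeid) {
  BlockIndex b;
  const uword n = patient.n_elem;
  for (uword i = 0; i < n; ++i) {
    if (i == 0 || patient[i] != patient[i - 1]) b.pat_start.push_back(i);
    if (i == 0 || eyeid[i] != eyeid[i - 1]) b.eye_start.push_back(i);
  }
  b.pat_start.push_back(n);
  b.eye_start.push_back(n);
  return b;
}

// Profiled negative log-likelihood at given variance ratios; also returns the
// GLS fixed effects, profiled residual variance and log|V-tilde|.
double profiled_nll(double psi_d, double psi_z,
                    const vec& z, const mat& X, const vec& w,
                    const BlockIndex& b,
                    vec& beta_out, double& sigma2_out, double& loglik_out) {
  const uword n = z.n_elem, p = X.n_cols;
  mat XtVX(p, p, fill::zeros);
  vec XtVz(p, fill::zeros);
  double zVz = 0.0, logdet = 0.0;
  uword e = 0;  // index into eye_start
  for (uword k = 0; k + 1 < b.pat_start.size(); ++k) {
    const uword i0 = b.pat_start[k], i1 = b.pat_start[k + 1];
    const uword m = i1 - i0;
    const vec wj = w.subvec(i0, i1 - 1);
    mat Vt(m, m, fill::eye);
    Vt += psi_z * (wj * wj.t());
    while (e + 1 < b.eye_start.size() && b.eye_start[e] < i1) {
      const uword a0 = b.eye_start[e], a1 = b.eye_start[e + 1];
      const vec we = w.subvec(a0, a1 - 1);
      Vt.submat(a0 - i0, a0 - i0, a1 - 1 - i0, a1 - 1 - i0) += psi_d * (we * we.t());
      ++e;
    }
    mat L;
    if (!chol(L, Vt, "lower")) {
      beta_out.zeros(p);
      return 1e100;  // numerically indefinite: reject this point
    }
    logdet += 2.0 * accu(log(L.diag()));
    const mat Xs = solve(trimatl(L), X.rows(i0, i1 - 1));
    const vec zs = solve(trimatl(L), z.subvec(i0, i1 - 1));
    XtVX += Xs.t() * Xs;
    XtVz += Xs.t() * zs;
    zVz += dot(zs, zs);
  }
  vec beta;
  if (!solve(beta, XtVX, XtVz, solve_opts::no_approx)) {
    beta = pinv(XtVX) * XtVz;  // rank-deficient design: minimum-norm solution
  }
  double rss = zVz - dot(XtVz, beta);
  if (rss < n * 1e-24) rss = n * 1e-24;  // exact-fit guard
  const double sigma2 = rss / n;
  const double ll = -0.5 * (n * std::log(2.0 * M_PI * sigma2) + n + logdet);
  beta_out = beta;
  sigma2_out = sigma2;
  loglik_out = ll;
  return -ll;
}

inline double clamp_lp(double x) {
  return std::min(30.0, std::max(-30.0, x));
}

// Sufficient statistics for the fast profiled evaluation.  With
// V = I + U D U^T (U = [w | w*1(eye 1) | w*1(eye 2) ...], D = diag(psi_z,
// psi_d, ...)), Woodbury gives
//   X'V^-1 X = X'X - (X'U) M^-1 (U'X),  M = D^-1 + U'U,
//   log|V| = log|D| + log|M|,
// and U'U, X'U, U'z reduce to per-eye sums, so each evaluation needs no
// O(rows) work at all.
struct FastDat {
  int p, n_pat, n_eye, n;
  mat XtX_tot;     // p x p, summed over all patients (psi-independent)
  vec Xtz_tot;     // p
  double ztz_tot;
  mat Xtw;         // p x n_eye
  vec wtz, wtw;    // n_eye
  std::vector<uword> eye_first;  // first eye index of each patient (+sentinel)
};

FastDat make_fastdat(const vec& z, const mat& X, const vec& w,
                     const BlockIndex& b) {
  FastDat d;
  d.p = X.n_cols;
  d.n = z.n_elem;
  d.n_pat = b.pat_start.size() - 1;
  d.n_eye = b.eye_start.size() - 1;
  d.XtX_tot = X.t() * X;
  d.Xtz_tot = X.t() * z;
  d.ztz_tot = dot(z, z);
  d.Xtw.zeros(d.p, d.n_eye);
  d.wtz.zeros(d.n_eye);
  d.wtw.zeros(d.n_eye);
  uword e = 0;
  for (int k = 0; k < d.n_pat; ++k) {
    const uword i1 = b.pat_start[k + 1];
    d.eye_first.push_back(e);
    while (e + 1 < b.eye_start.size() && b.eye_start[e] < i1) {
      const uword a0 = b.eye_start[e], a1 = b.eye_start[e + 1];
      const vec we = w.subvec(a0, a1 - 1);
      d.Xtw.col(e) = X.rows(a0, a1 - 1).t() * we;
      d.wtz[e] = dot(we, z.subvec(a0, a1 - 1));
      d.wtw[e] = dot(we, we);
      ++e;
    }
  }
  d.eye_first.push_back(e);
  return d;
}

// allocation-free evaluation: stack buffers for the q x q algebra (q = 1 +
// eyes of the patient; capped at 16, far beyond the anatomical 2)
double fast_profiled_nll(double psi_d, double psi_z, const FastDat& d,
                         vec& beta_out, double& sigma2_out,
                         double& loglik_out) {
  const int p = d.p, QMAX = 16;
  mat A = d.XtX_tot;
  vec c = d.Xtz_tot;
  double zVz = d.ztz_tot, logdet = 0.0;
  double M[QMAX * QMAX], L[QMAX * QMAX], u[QMAX], v[QMAX];
  std::vector<double> Cb(QMAX * p), Yb(QMAX * p);
  const double inv_pz = 1.0 / psi_z, inv_pd = 1.0 / psi_d;
  for (int k = 0; k < d.n_pat; ++k) {
    const int e0 = d.eye_first[k], e1 = d.eye_first[k + 1];
    const int ne = e1 - e0, q = 1 + ne;
    if (q > QMAX) { beta_out.zeros(p); return 1e100; }
    for (int i = 0; i < q * q; ++i) M[i] = 0.0;
    for (int i = 0; i < p; ++i) Cb[i] = 0.0;
    u[0] = 0.0;
    double S = 0.0;
    for (int s = 0; s < ne; ++s) {
      const double se = d.wtw[e0 + s];
      S += se;
      M[0 * q + (s + 1)] = M[(s + 1) * q + 0] = se;
      M[(s + 1) * q + (s + 1)] = inv_pd + se;
      const double* xw = d.Xtw.colptr(e0 + s);
      for (int i = 0; i < p; ++i) {
        Cb[(s + 1) * p + i] = xw[i];
        Cb[i] += xw[i];
      }
      u[s + 1] = d.wtz[e0 + s];
      u[0] += d.wtz[e0 + s];
    }
    M[0] = inv_pz + S;
    // Cholesky M = L L', lower, row-major
    bool ok = true;
    for (int i = 0; i < q && ok; ++i) {
      for (int j = 0; j <= i; ++j) {
        double s2 = M[i * q + j];
        for (int t = 0; t < j; ++t) s2 -= L[i * q + t] * L[j * q + t];
        if (i == j) {
          if (s2 <= 0.0) { ok = false; break; }
          L[i * q + i] = std::sqrt(s2);
        } else {
          L[i * q + j] = s2 / L[j * q + j];
        }
      }
    }
    if (!ok) { beta_out.zeros(p); return 1e100; }
    logdet += std::log(psi_z) + ne * std::log(psi_d);
    for (int i = 0; i < q; ++i) logdet += 2.0 * std::log(L[i * q + i]);
    // forward solves L*Y = C (q x p, row-major) and L*v = u
    for (int r = 0; r < q; ++r) {
      for (int cc = 0; cc < p; ++cc) {
        double s2 = Cb[r * p + cc];
        for (int t = 0; t < r; ++t) s2 -= L[r * q + t] * Yb[t * p + cc];
        Yb[r * p + cc] = s2 / L[r * q + r];
      }
      double s2 = u[r];
      for (int t = 0; t < r; ++t) s2 -= L[r * q + t] * v[t];
      v[r] = s2 / L[r * q + r];
    }
    for (int i = 0; i < p; ++i) {
      double ci = 0.0;
      for (int r = 0; r < q; ++r) {
        ci += Yb[r * p + i] * v[r];
        double aij;
        for (int j = 0; j <= i; ++j) {
          aij = Yb[r * p + i] * Yb[r * p + j];
          A(i, j) -= aij;
          if (j < i) A(j, i) -= aij;
        }
      }
      c[i] -= ci;
    }
    for (int r = 0; r < q; ++r) zVz -= v[r] * v[r];
  }
  vec beta;
  if (!solve(beta, A, c, solve_opts::no_approx)) beta = pinv(A) * c;
  double rss = zVz - dot(c, beta);
  if (rss < d.n * 1e-24) rss = d.n * 1e-24;
  const double sigma2 = rss / d.n;
  const double ll = -0.5 * (d.n * std::log(2.0 * M_PI * sigma2) + d.n + logdet);
  beta_out = beta;
  sigma2_out = sigma2;
  loglik_out = ll;
  return -ll;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_profile_eval(const arma::vec& z, const arma::mat& X,
                            const arma::vec& w,
                            const arma::ivec& patient, const arma::ivec& eyeid,
                            double psi_delta, double psi_zeta) {
  BlockIndex b = make_blocks(patient, eyeid);
  vec beta;
  double sigma2 = 0.0, ll = -datum::inf;
  profiled_nll(psi_delta, psi_zeta, z, X, w, b, beta, sigma2, ll);
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("beta") = beta,
                            Rcpp::Named("sigma2") = sigma2);
}

// Nelder-Mead over (log psi_delta, log psi_zeta) with profiled everything else.
// [[Rcpp::export]]
Rcpp::List cpp_fit_core(const arma::vec& z, const arma::mat& X,
                        const arma::vec& w,
                        const arma::ivec& patient, const arma::ivec& eyeid,
                        const arma::vec& lp_start,
                        double reltol = 1e-10, int maxit = 500,
                        double step = 1.0) {
  BlockIndex b = make_blocks(patient, eyeid);
  FastDat d = make_fastdat(z, X, w, b);
  vec beta;
  double sigma2 = 0.0, ll = 0.0;
  auto f = [&](const vec& lp) {
    return fast_profiled_nll(std::exp(clamp_lp(lp[0])),
                             std::exp(clamp_lp(lp[1])),
                             d, beta, sigma2, ll);
  };

  // simplex of 3 points in 2-D
  std::vector<vec> s(3);
  vec fv(3);
  s[0] = lp_start;
  s[1] = lp_start + vec{step, 0.0};
  s[2] = lp_start + vec{0.0, step};
  for (int i = 0; i < 3; ++i) fv[i] = f(s[i]);
  int nev = 3, it = 0;
  while (it++ < maxit) {
    // order: l best, h worst, m middle
    uword l = fv.index_min(), h = fv.index_max();
    if (std::abs(fv[h] - fv[l]) <= reltol * (std::abs(fv[l]) + 1e-10)) break;
    uword m = 3 - l - h;
    if (l == h) break;
    vec cen = 0.5 * (s[l] + s[m]);
    vec xr = cen + (cen - s[h]);          // reflection
    double fr = f(xr); ++nev;
    if (fr < fv[l]) {
      vec xe = cen + 2.0 * (cen - s[h]);  // expansion
      double fe = f(xe); ++nev;
      if (fe < fr) { s[h] = xe; fv[h] = fe; } else { s[h] = xr; fv[h] = fr; }
    } else if (fr < fv[m]) {
      s[h] = xr; fv[h] = fr;
    } else {
      vec xc = cen + 0.5 * (s[h] - cen);  // contraction
      double fc = f(xc); ++nev;
      if (fc < fv[h]) { s[h] = xc; fv[h] = fc; }
      else {                               // shrink toward best
        for (int i = 0; i < 3; ++i) {
          if ((uword)i == l) continue;
          s[i] = s[l] + 0.5 * (s[i] - s[l]);
          fv[i] = f(s[i]); ++nev;
        }
      }
    }
  }
  uword l = fv.index_min();
  vec lp = {clamp_lp(s[l][0]), clamp_lp(s[l][1])};
  double nll = f(lp); ++nev;
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("beta") = beta,
                            Rcpp::Named("sigma2") = sigma2,
                            Rcpp::Named("lp") = lp,
                            Rcpp::Named("psi") = vec{std::exp(lp[0]), std::exp(lp[1])},
                            Rcpp::Named("nll") = nll,
                            Rcpp::Named("n_eval") = nev,
                            Rcpp::Named("iterations") = it);
}

// Exact Gaussian log-likelihood of residuals r under the block covariance
// with absolute variance components (used by the brute-force ML oracle).
// [[Rcpp::export]]
double cpp_gauss_loglik(const arma::vec& resid, const arma::vec& w,
                        const arma::ivec& patient, const arma::ivec& eyeid,
                        double s2_delta, double s2_zeta, double s2_eps) {
  BlockIndex b = make_blocks(patient, eyeid);
  const uword n = resid.n_elem;
  if (s2_eps <= 0.0) return -datum::inf;
  double quad = 0.0, logdet = 0.0;
  uword e = 0;
  for (uword k = 0; k + 1 < b.pat_start.size(); ++k) {
    const uword i0 = b.pat_start[k], i1 = b.pat_start[k + 1];
    const uword m = i1 - i0;
    const vec wj = w.subvec(i0, i1 - 1);
    mat V = s2_eps * mat(m, m, fill::eye);
    V += s2_zeta * (wj * wj.t());
    while (e + 1 < b.eye_start.size() && b.eye_start[e] < i1) {
      const uword a0 = b.eye_start[e], a1 = b.eye_start[e + 1];
      const vec we = w.subvec(a0, a1 - 1);
      V.submat(a0 - i0, a0 - i0, a1 - 1 - i0, a1 - 1 - i0) += s2_delta * (we * we.t());
      ++e;
    }
    mat L;
    if (!chol(L, V, "lower")) return -datum::inf;
    logdet += 2.0 * accu(log(L.diag()));
    const vec rs = solve(trimatl(L), resid.subvec(i0, i1 - 1));
    quad += dot(rs, rs);
  }
  return -0.5 * (n * std::log(2.0 * M_PI) + logdet + quad);
}

// Conditional (posterior) modes of the Gaussian random effects given the
// fixed-part residuals and plugged-in ML variance components:
// b_hat = G U^T V^{-1} r per patient, U = [w, w * 1(eye)], G = diag(s2z, s2d...).
// [[Rcpp::export]]
Rcpp::List cpp_cond_modes(const arma::vec& resid, const arma::vec& w,
                          const arma::ivec& patient, const arma::ivec& eyeid,
                          double s2_delta, double s2_zeta, double s2_eps) {
  BlockIndex b = make_blocks(patient, eyeid);
  const uword n_pat = b.pat_start.size() - 1;
  const uword n_eye = b.eye_start.size() - 1;
  vec zeta(n_pat, fill::zeros), gamma(n_eye, fill::zeros);
  uword e = 0;
  for (uword k = 0; k < n_pat; ++k) {
    const uword i0 = b.pat_start[k], i1 = b.pat_start[k + 1];
    const uword m = i1 - i0;
    const vec wj = w.subvec(i0, i1 - 1);
    mat V = s2_eps * mat(m, m, fill::eye);
    V += s2_zeta * (wj * wj.t());
    const uword e_first = e;
    while (e + 1 < b.eye_start.size() && b.eye_start[e] < i1) {
      const uword a0 = b.eye_start[e], a1 = b.eye_start[e + 1];
      const vec we = w.subvec(a0, a1 - 1);
      V.submat(a0 - i0, a0 - i0, a1 - 1 - i0, a1 - 1 - i0) += s2_delta * (we * we.t());
      ++e;
    }
    vec vr;
    if (!solve(vr, V, resid.subvec(i0, i1 - 1))) {
      Rcpp::stop("singular covariance block for patient code %d", patient[i0]);
    }
    zeta[k] = s2_zeta * dot(wj, vr);
    for (uword ee = e_first; ee < e; ++ee) {
      const uword a0 = b.eye_start[ee], a1 = b.eye_start[ee + 1];
      gamma[ee] = s2_delta * dot(w.subvec(a0, a1 - 1), vr.subvec(a0 - i0, a1 - 1 - i0));
    }
  }
  return Rcpp::List::create(Rcpp::Named("zeta") = zeta,
                            Rcpp::Named("gamma") = gamma);
}
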