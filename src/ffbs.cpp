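// Forward-filtering backward-sampling kernels for the TVP-VAR-SV Gibbs
// sampler, and the time-varying impulse-response surface accumulator.
//
// All state equations are identity random walks with diagonal innovation
// covariance; observation noise is diagonal after premultiplying by the
// contemporaneous matrix A_t, so the filter uses sequential scalar updates.
// Random numbers come from R's RNG (via Rcpp), so draws are reproducible
// under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double JITTER = 1e-10;

// multivariate normal draw N(mu, S) with jitter retry on chol failure
static vec mvn_draw(const vec& mu, mat S) {
  if (!S.is_finite() || !mu.is_finite())
    Rcpp::stop("filter produced non-finite moments");
  S = 0.5 * (S + S.t());
  mat L;
  double eps = JITTER;
  while (!chol(L, S + eps * eye(S.n_rows, S.n_rows), "lower")) {
    eps *= 10.0;
    if (eps > 1e-2) Rcpp::stop("filter covariance lost positive definiteness");
  }
  vec z(mu.n_elem);
  for (uword i = 0; i < z.n_elem; ++i) z(i) = R::norm_rand();
  return mu + L * z;
}

// Generic FFBS for y_t = Z_t a_t + e_t, e_t ~ N(0, diag(hvar_t)),
// a_{t+1} = a_t + w, w ~ N(0, diag(wdiag)), a_1 ~ N(a0, diag(p0)).
// Returns sampled path (k x T) and/or RTS smoother means.
static Rcpp::List ffbs_core(const mat& y, const cube& Z, const mat& hvar,
                            const vec& wdiag, const vec& a0, const vec& p0,
                            bool want_draw, bool want_mean) {
  const uword p = y.n_rows, T = y.n_cols, k = a0.n_elem;
  mat afilt(k, T);
  cube Pfilt(k, k, T);
  vec a = a0;
  mat P = diagmat(p0);
  for (uword t = 0; t < T; ++t) {
    if (t > 0) P.diag() += wdiag;       // predict (identity transition)
    for (uword i = 0; i < p; ++i) {     // sequential scalar updates
      rowvec zi = Z.slice(t).row(i);
      vec PZ = P * zi.t();
      double f = dot(zi, PZ) + hvar(i, t);
      if (!std::isfinite(f) || f <= 0)
        Rcpp::stop("non-positive innovation variance in filter");
      vec K = PZ / f;
      a += K * (y(i, t) - dot(zi, a));
      P -= K * PZ.t();
      P = 0.5 * (P + P.t());
    }
    afilt.col(t) = a;
    Pfilt.slice(t) = P;
  }

  Rcpp::List out;
  if (want_draw) {
    mat draw(k, T);
    draw.col(T - 1) = mvn_draw(afilt.col(T - 1), Pfilt.slice(T - 1));
    for (uword t = T - 1; t-- > 0; ) {
      mat Pt = Pfilt.slice(t);
      mat Ppred = Pt;
      Ppred.diag() += wdiag;
      mat G = Pt * inv_sympd(0.5 * (Ppred + Ppred.t()) +
                             JITTER * eye(k, k));
      vec mu = afilt.col(t) + G * (draw.col(t + 1) - afilt.col(t));
      mat S = Pt - G * Pt;
      draw.col(t) = mvn_draw(mu, S);
    }
    out["draw"] = draw;
  }
  if (want_mean) {
    mat sm(k, T);
    sm.col(T - 1) = afilt.col(T - 1);
    for (uword t = T - 1; t-- > 0; ) {
      mat Pt = Pfilt.slice(t);
      mat Ppred = Pt;
      Ppred.diag() += wdiag;
      mat G = Pt * inv_sympd(0.5 * (Ppred + Ppred.t()) +
                             JITTER * eye(k, k));
      sm.col(t) = afilt.col(t) + G * (sm.col(t + 1) - afilt.col(t));
    }
    out["mean"] = sm;
  }
  return out;
}

// Coefficient block.  Y (m x T) observations, Xlag (p x T) stacked lag
// regressors, Aarr (m x m x T) contemporaneous matrices, H (m x T) structural
// shock variances exp(h_jt).  Transforms to A_t y_t = (A_t X_t) beta_t + e_t
// with diagonal noise.
// [[Rcpp::export]]
Rcpp::List ffbs_beta_cpp(const arma::mat& Y, const arma::mat& Xlag,
                         const arma::cube& Aarr, const arma::mat& H,
                         const arma::vec& wdiag, const arma::vec& a0,
                         const arma::vec& p0, bool want_draw,
                         bool want_mean) {
  const uword m = Y.n_rows, T = Y.n_cols, p = Xlag.n_rows;
  const uword k = m * p;
  mat ytil(m, T);
  cube Z(m, k, T, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    const mat& A = Aarr.slice(t);
    ytil.col(t) = A * Y.col(t);
    // row i of A_t X_t: concat_j A(i,j) * x_t'
    for (uword i = 0; i < m; ++i)
      for (uword j = 0; j < m; ++j)
        for (uword q = 0; q < p; ++q)
          Z(i, j * p + q, t) = A(i, j) * Xlag(q, t);
  }
  return ffbs_core(ytil, Z, H, wdiag, a0, p0, want_draw, want_mean);
}

// Contemporaneous-relation block.  Yhat (m x T) are residuals y_t - X_t b_t;
// row j >= 2 regresses yhat_j on -yhat_{1..j-1} with noise exp(h_jt).
// [[Rcpp::export]]
Rcpp::List ffbs_alpha_cpp(const arma::mat& Yhat, const arma::mat& H,
                          const arma::vec& wdiag, const arma::vec& a0,
                          const arma::vec& p0, bool want_draw,
                          bool want_mean) {
  const uword m = Yhat.n_rows, T = Yhat.n_cols;
  const uword ka = m * (m - 1) / 2, pobs = m - 1;
  mat y(pobs, T);
  mat hv(pobs, T);
  cube Z(pobs, ka, T, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    uword off = 0;
    for (uword j = 1; j < m; ++j) {     // equation j (0-based), j entries
      y(j - 1, t) = Yhat(j, t);
      hv(j - 1, t) = H(j, t);
      for (uword i = 0; i < j; ++i)
        Z(j - 1, off + i, t) = -Yhat(i, t);
      off += j;
    }
  }
  return ffbs_core(y, Z, hv, wdiag, a0, p0, want_draw, want_mean);
}

// Univariate block (used per series for the log-volatility state after the
// mixture linearization): yadj_t = h_t + e_t, e_t ~ N(0, vs_t).
// [[Rcpp::export]]
Rcpp::List ffbs_uni_cpp(const arma::vec& yadj, const arma::vec& vs,
                        double w, double a0, double p0, bool want_draw,
                        bool want_mean) {
  const uword T = yadj.n_elem;
  mat y(1, T);
  y.row(0) = yadj.t();
  mat hv(1, T);
  hv.row(0) = vs.t();
  cube Z(1, 1, T, fill::ones);
  vec wv(1); wv(0) = w;
  vec a0v(1); a0v(0) = a0;
  vec p0v(1); p0v(0) = p0;
  return ffbs_core(y, Z, hv, wv, a0v, p0v, want_draw, want_mean);
}

// Observation-equation residuals: yhat_t = y_t - X_t beta_t (reduced form)
// and e_t = A_t yhat_t (structural).  Y (m x T), beta (k x T),
// Xlag (p x T), alpha (k_alpha x T).
// [[Rcpp::export]]
Rcpp::List resid_cpp(const arma::mat& Y, const arma::mat& beta,
                     const arma::mat& Xlag, const arma::mat& alpha) {
  const uword m = Y.n_rows, T = Y.n_cols, p = Xlag.n_rows;
  mat yhat(m, T), e(m, T);
  for (uword t = 0; t < T; ++t) {
    for (uword i = 0; i < m; ++i) {
      double fit = 0.0;
      for (uword q = 0; q < p; ++q) fit += beta(i * p + q, t) * Xlag(q, t);
      yhat(i, t) = Y(i, t) - fit;
    }
    mat A = eye(m, m);
    uword kk = 0;
    for (uword i = 1; i < m; ++i)
      for (uword j = 0; j < i; ++j) A(i, j) = alpha(kk++, t);
    e.col(t) = A * yhat.col(t);
  }
  return Rcpp::List::create(Rcpp::Named("yhat") = yhat,
                            Rcpp::Named("e") = e);
}

// Impulse responses for one (beta, alpha, scale) configuration:
// psi_0 = A^{-1} diag(scale); psi_k = sum_{i<=min(k,s)} B_i psi_{k-i}.
static cube irf_one(const vec& beta, const vec& alpha, const vec& scale,
                    uword m, uword s, uword off, uword H) {
  const uword p = off + m * s;
  // lag matrices from the equation-stacked state vector
  std::vector<mat> B(s, mat(m, m));
  for (uword l = 0; l < s; ++l)
    for (uword i = 0; i < m; ++i)
      for (uword j = 0; j < m; ++j)
        B[l](i, j) = beta(i * p + off + l * m + j);
  mat A = eye(m, m);
  uword kk = 0;
  for (uword i = 1; i < m; ++i)
    for (uword j = 0; j < i; ++j) A(i, j) = alpha(kk++);
  cube psi(m, m, H + 1);
  psi.slice(0) = solve(trimatl(A), diagmat(scale));
  for (uword k = 1; k <= H; ++k) {
    mat acc(m, m, fill::zeros);
    for (uword i = 1; i <= std::min<uword>(k, s); ++i)
      acc += B[i - 1] * psi.slice(k - i);
    psi.slice(k) = acc;
  }
  return psi;
}

// [[Rcpp::export]]
arma::cube irf_at_cpp(const arma::vec& beta, const arma::vec& alpha,
                      const arma::vec& scale, int m, int s, int off, int H) {
  return irf_one(beta, alpha, scale, m, s, off, H);
}

// Posterior-mean IRF surface over dates x horizons x shock x response,
// averaging over retained draws.  Bdraws (k_beta x Te x R),
// Adraws (k_alpha x Te x R), scales (m x Te x R).  Returns the running
// mean as a (m*m*(H+1)) x Te matrix (response i, shock j, horizon flattened
// column-major: index = i + m*j + m*m*h).
// [[Rcpp::export]]
arma::mat irf_mean_cpp(const arma::cube& Bdraws, const arma::cube& Adraws,
                       const arma::cube& scales, int m_, int s_, int off_,
                       int H_) {
  const uword m = m_, s = s_, off = off_, H = H_;
  const uword Te = Bdraws.n_cols, R = Bdraws.n_slices;
  mat acc(m * m * (H + 1), Te, fill::zeros);
  for (uword r = 0; r < R; ++r) {
    for (uword t = 0; t < Te; ++t) {
      vec al = Adraws.n_rows > 0 ? vec(Adraws.slice(r).col(t)) : vec();
      cube psi = irf_one(Bdraws.slice(r).col(t), al,
                         scales.slice(r).col(t), m, s, off, H);
      acc.col(t) += vectorise(psi);
    }
  }
  return acc / double(R);
}

// Per-draw IRF values for a subset of draws (for credible bands); returns
// cube (m*m*(H+1), Te, Rsub).
// [[Rcpp::export]]
arma::cube irf_draws_cpp(const arma::cube& Bdraws, const arma::cube& Adraws,
                         const arma::cube& scales, int m_, int s_, int off_,
                         int H_) {
  const uword m = m_, s = s_, off = off_, H = H_;
  const uword Te = Bdraws.n_cols, R = Bdraws.n_slices;
  cube out(m * m * (H + 1), Te, R);
  for (uword r = 0; r < R; ++r)
    for (uword t = 0; t < Te; ++t) {
      vec al = Adraws.n_rows > 0 ? vec(Adraws.slice(r).col(t)) : vec();
      out.slice(r).col(t) = vectorise(
        irf_one(Bdraws.slice(r).col(t), al, scales.slice(r).col(t),
                m, s, off, H));
    }
  return out;
}
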