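// Marginal log-likelihood of the first-order linear-linear SLCM for counts:
// NB2 measurement model with exposure offset, random effects on the growth
// parameters entering through the min/max Taylor-series basis, integrated by
// adaptive Gauss-Hermite quadrature centred at each individual's posterior
// mode.  Also returns the Fisher-identity score (posterior-weighted data
// score evaluated on the grid) and empirical-Bayes summaries.
//
// Key reduction: with b = L s (s standard normal), the integrand depends on
// s only through G s where G = Lambda L, so the integral is taken over the
// rank(G) <= min(n_obs, d) directions of the row space of G; the orthogonal
// complement integrates to one exactly.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// cap the linear predictor before exponentiation so extreme optimizer
// trial points stay finite (counts this large are outside any data range)
static const double ETA_MAX = 40.0;
static inline double mu_of(double eta) { return std::exp(std::min(eta, ETA_MAX)); }


// [[Rcpp::export]]
Rcpp::List slcm_loglik_cpp(const arma::vec& tt, const arma::vec& y,
                           const arma::vec& logu,
                           const arma::ivec& id_ptr,   // 0-based, length N+1
                           const arma::vec& beta,      // intercept, slope1, slope2, changepoint
                           const arma::vec& phi,       // per observation
                           const arma::ivec& bin_index, // 0-based bin per obs
                           const int W,
                           const arma::mat& L,         // d x d lower Cholesky of T
                           const arma::ivec& rmask,    // 0-based basis columns with REs
                           const Rcpp::List& nodes,    // nodes[[rho]]: list(z = rho x K, logv = K)
                           const bool want_grad,
                           const bool want_scores,
                           const bool want_eb,
                           const bool adaptive) {
  const int N = id_ptr.n_elem - 1;
  const int d = rmask.n_elem;
  const double g = beta(3), b1 = beta(1), b2 = beta(2);

  vec ll(N, fill::zeros);
  vec grad_beta(4, fill::zeros);
  mat grad_L(std::max(d, 1), std::max(d, 1), fill::zeros);
  vec grad_phi(W, fill::zeros);
  const int p_raw = 4 + d * d + W;
  mat scores;
  if (want_scores) scores.zeros(N, p_raw);
  mat eb_mode;
  cube eb_cov;
  if (want_eb) { eb_mode.zeros(N, std::max(d, 1)); eb_cov.zeros(std::max(d, 1), std::max(d, 1), N); }

  // indices of the slope1 / slope2 / changepoint random effects inside rmask
  int jg = -1, js1 = -1, js2 = -1;
  for (int j = 0; j < d; ++j) {
    if (rmask(j) == 3) jg = j;
    if (rmask(j) == 1) js1 = j;
    if (rmask(j) == 2) js2 = j;
  }

  for (int i = 0; i < N; ++i) {
    const int a = id_ptr(i), b_end = id_ptr(i + 1);
    const int n = b_end - a;
    const vec ti = tt.subvec(a, b_end - 1);
    const vec yi = y.subvec(a, b_end - 1);
    const vec li = logu.subvec(a, b_end - 1);
    const vec ph = phi.subvec(a, b_end - 1);
    const vec r = 1.0 / ph;

    const vec tmin = arma::min(ti, g * ones(n));
    const vec tpos = arma::max(ti - g, zeros(n));
    const uvec after = ti > g;               // strict: left value at the knot
    const vec aft = conv_to<vec>::from(after);

    const vec eta0 = li + beta(0) + b1 * tmin + b2 * tpos;

    // per-obs pmf constants
    const vec c0 = lgamma(yi + r) - lgamma(r) - lgamma(yi + 1.0) + r % log(r);
    vec a0;                                   // for d/dphi
    if (want_grad) {
      a0.set_size(n);
      for (int w = 0; w < n; ++w)
        a0(w) = R::digamma(yi(w) + r(w)) - R::digamma(r(w)) + std::log(r(w)) + 1.0;
    }

    // factor-loading basis (n x d) and its L-rotated version
    mat Lam(n, std::max(d, 1), fill::zeros);
    for (int j = 0; j < d; ++j) {
      switch (rmask(j)) {
        case 0: Lam.col(j).ones(); break;
        case 1: Lam.col(j) = tmin; break;
        case 2: Lam.col(j) = tpos; break;
        case 3: Lam.col(j) = (b1 - b2) * aft; break;
      }
    }

    int rho = 0;
    mat A, P;
    if (d > 0) {
      mat G = Lam.head_cols(d) * L;
      mat U, V; vec sv;
      if (!svd_econ(U, sv, V, G)) Rcpp::stop("SVD failure in loglik kernel");
      double tol = std::max(1e-12, (sv.n_elem ? sv.max() : 0.0) * 1e-10);
      rho = (int) sum(sv > tol);
      if (rho > 0) {
        A = U.head_cols(rho) * diagmat(sv.head(rho));   // n x rho
        P = V.head_cols(rho);                           // d x rho
      }
    }

    // helper: data log-likelihood pieces at eta matrix (n x K)
    auto obj_terms = [&](const mat& ETA, mat& LRMU, vec& Fdata) {
      // LRMU = log(r + mu); Fdata_k = sum_w [c0 + y eta - (y+r) log(r+mu)]
      const int K = ETA.n_cols;
      LRMU.set_size(n, K);
      Fdata.set_size(K);
      for (int k = 0; k < K; ++k) {
        double acc = 0.0;
        for (int w = 0; w < n; ++w) {
          const double e = std::min(ETA(w, k), ETA_MAX);
          const double mu = std::exp(e);
          const double lr = std::log(r(w) + mu);
          LRMU(w, k) = lr;
          acc += c0(w) + yi(w) * e - (yi(w) + r(w)) * lr;
        }
        Fdata(k) = acc;
      }
    };

    if (rho == 0) {
      // no effective random variation: likelihood at b = 0
      mat LRMU; vec Fd;
      mat ETA(eta0);
      obj_terms(ETA, LRMU, Fd);
      ll(i) = Fd(0);
      if (want_grad) {
        vec mu = exp(clamp(eta0, -datum::inf, ETA_MAX));
        vec gv = yi - (yi + r) % mu / (r + mu);
        vec sc(p_raw, fill::zeros);
        sc(0) = sum(gv);
        sc(1) = dot(gv, tmin);
        sc(2) = dot(gv, tpos);
        sc(3) = dot(gv, aft) * (b1 - b2);
        for (int w = 0; w < n; ++w) {
          const double mu_w = mu(w);
          const double dldr = a0(w) - LRMU(w, 0) - (yi(w) + r(w)) / (r(w) + mu_w);
          const double dldphi = -r(w) * r(w) * dldr;
          grad_phi(bin_index(a + w)) += dldphi;
          sc(4 + d * d + bin_index(a + w)) += dldphi;
        }
        grad_beta(0) += sc(0); grad_beta(1) += sc(1);
        grad_beta(2) += sc(2); grad_beta(3) += sc(3);
        if (want_scores) scores.row(i) = sc.t();
      }
      if (want_eb) { /* mode 0, covariance = T */
        if (d > 0) eb_cov.slice(i) = L * L.t();
      }
      continue;
    }

    // ---- posterior mode (Newton on a concave objective) ----
    vec s(rho, fill::zeros);
    mat H(rho, rho, fill::eye);
    double Fcur = -datum::inf;
    if (adaptive) {
      vec eta = eta0;                 // at s = 0
      for (int iter = 0; iter < 50; ++iter) {
        vec mu = exp(clamp(eta, -datum::inf, ETA_MAX));
        vec gv = yi - (yi + r) % mu / (r + mu);
        vec wv = (yi + r) % r % mu / square(r + mu);
        vec grad = A.t() * gv - s;
        H = A.t() * (A.each_col() % wv) + eye(rho, rho);
        if (norm(grad, "inf") < 1e-9 && iter > 0) break;
        vec step = solve(H, grad, solve_opts::likely_sympd);
        // objective for step halving
        auto fval = [&](const vec& sv_) {
          vec e = eta0 + A * sv_;
          double acc = -0.5 * dot(sv_, sv_);
          for (int w = 0; w < n; ++w) {
            const double ec = std::min(e(w), ETA_MAX);
            acc += c0(w) + yi(w) * ec -
              (yi(w) + r(w)) * std::log(r(w) + std::exp(ec));
          }
          return acc;
        };
        if (!std::isfinite(Fcur)) Fcur = fval(s);
        double alpha = 1.0;
        vec s_new = s + step;
        double Fnew = fval(s_new);
        int halve = 0;
        while (!(Fnew >= Fcur - 1e-12) && halve < 30) {
          alpha *= 0.5; s_new = s + alpha * step; Fnew = fval(s_new); ++halve;
        }
        if (Fnew < Fcur) break;       // cannot improve further
        s = s_new; Fcur = Fnew; eta = eta0 + A * s;
        if (norm(alpha * step, "inf") < 1e-10) break;
      }
      // refresh curvature at the mode
      vec mu = exp(clamp(eta0 + A * s, -datum::inf, ETA_MAX));
      vec wv = (yi + r) % r % mu / square(r + mu);
      H = A.t() * (A.each_col() % wv) + eye(rho, rho);
    }

    mat R_ = chol(H);                 // upper triangular
    const Rcpp::List nd = nodes[rho - 1];
    const mat Z = nd["z"];            // rho x K
    const vec logv = nd["logv"];
    const int K = Z.n_cols;

    mat S_nodes = solve(trimatu(R_), std::sqrt(2.0) * Z);
    S_nodes.each_col() += s;          // rho x K
    mat ETA = A * S_nodes;            // n x K
    ETA.each_col() += eta0;

    mat LRMU; vec Fd;
    obj_terms(ETA, LRMU, Fd);
    // log integrand at each node, plus the e^{z'z} factor of the
    // Gauss-Hermite substitution and the normalized prior weights
    vec val(K);
    for (int k = 0; k < K; ++k)
      val(k) = Fd(k) - 0.5 * dot(S_nodes.col(k), S_nodes.col(k)) +
        dot(Z.col(k), Z.col(k)) + logv(k);
    const double M = val.max();
    const vec ex = exp(val - M);
    const double sumex = sum(ex);
    double logdetR = 0.0;
    for (int j = 0; j < rho; ++j) logdetR += std::log(R_(j, j));
    ll(i) = M + std::log(sumex) - logdetR;

    if (want_grad) {
      const vec om = ex / sumex;      // posterior node weights
      vec sc(p_raw, fill::zeros);
      mat GL(std::max(d, 1), std::max(d, 1), fill::zeros); // dF/dL accumulator
      for (int k = 0; k < K; ++k) {
        const double wk = om(k);
        if (wk < 1e-14) continue;
        vec sfull = P * S_nodes.col(k);          // d-vector in standardized space
        vec bfull = L * sfull;                   // random effects b
        const double bg = (jg >= 0) ? bfull(jg) : 0.0;
        const double bs1 = (js1 >= 0) ? bfull(js1) : 0.0;
        const double bs2 = (js2 >= 0) ? bfull(js2) : 0.0;
        double s0 = 0, s1 = 0, s2 = 0, s3 = 0;
        vec gv(n);
        for (int w = 0; w < n; ++w) {
          const double mu = mu_of(ETA(w, k));
          const double gw = yi(w) - (yi(w) + r(w)) * mu / (r(w) + mu);
          gv(w) = gw;
          s0 += gw;
          s1 += gw * (tmin(w) + aft(w) * bg);
          s2 += gw * (tpos(w) - aft(w) * bg);
          s3 += gw * aft(w);
          const double dldr = a0(w) - LRMU(w, k) - (yi(w) + r(w)) / (r(w) + mu);
          const double dldphi = -r(w) * r(w) * dldr;
          sc(4 + d * d + bin_index(a + w)) += wk * dldphi;
        }
        s3 *= (b1 - b2 + bs1 - bs2);
        sc(0) += wk * s0; sc(1) += wk * s1; sc(2) += wk * s2; sc(3) += wk * s3;
        if (d > 0) {
          vec q = Lam.head_cols(d).t() * gv;     // d-vector
          GL += wk * (q * sfull.t());
        }
      }
      // keep only the lower triangle (free Cholesky elements)
      for (int c2 = 0; c2 < d; ++c2)
        for (int r2 = 0; r2 < d; ++r2)
          if (r2 < c2) GL(r2, c2) = 0.0;
      grad_beta(0) += sc(0); grad_beta(1) += sc(1);
      grad_beta(2) += sc(2); grad_beta(3) += sc(3);
      grad_L += GL;
      for (int w = 0; w < W; ++w) grad_phi(w) += sc(4 + d * d + w);
      if (want_scores) {
        for (int c2 = 0; c2 < d; ++c2)
          for (int r2 = 0; r2 < d; ++r2)
            sc(4 + c2 * d + r2) = GL(r2, c2);
        scores.row(i) = sc.t();
      }
    }

    if (want_eb) {
      vec bhat = L * (P * s);
      mat Hinv = inv_sympd(H);
      mat C = P * Hinv * P.t() + (eye(d, d) - P * P.t());
      eb_mode.row(i) = bhat.t();
      eb_cov.slice(i) = L * C * L.t();
    }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("loglik") = sum(ll),
    Rcpp::Named("ll_i") = ll,
    Rcpp::Named("grad_beta") = grad_beta,
    Rcpp::Named("grad_L") = grad_L,
    Rcpp::Named("grad_phi") = grad_phi);
  if (want_scores) out["scores"] = scores;
  if (want_eb) { out["eb_mode"] = eb_mode; out["eb_cov"] = eb_cov; }
  return out;
}
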