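// Block Gibbs sampler for the diallel GLMM shared by the zero-truncated
// Poisson, Gaussian, and binomial outcome models.
//
// Model (latent scale):
//   l_i  = eta_i + eps_i,  eps_i ~ N(0, sigma2)          [overdispersion]
//   eta_i = mu + order_{r[i]} + batch_{h[i]} + d(j,k)[i]' beta
//   d'beta = a_j + a_k + (m_j - m_k)
//          + I{j=k} (beta_inbred + b_j)
//          + I{j!=k} (v_jk + S{j<k} w_jk),  S = +-1/2
// with sum-to-zero constraints on a, m, b, v, w; order_r ~ N(r*alpha,
// tau2_order); batch_h ~ N(0, tau2_batch); fixed effects ~ N(0, fixed_var);
// variances ~ InvGamma(shape, scale).
//
// Outcomes: gaussian (l observed directly), ztp (y ~ ZTPois(exp(l))),
// binomial (y ~ Binom(n, expit(l))). For the two discrete models l is a
// latent vector updated by single-site slice sampling; all Gaussian layers
// are conjugate block updates. Sum-to-zero is enforced exactly by
// conditioning each class's unconstrained conjugate Gaussian draw on a
// zero sum (a rank-one projection using the class posterior covariance).
//
// All randomness comes from R's RNG so results are reproducible with
// set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2 = 0.6931471805599453;

static inline double log1mexp_pos(double lam) {
  // log(1 - exp(-lam)) for lam > 0
  if (lam < LOG2) return std::log(-std::expm1(-lam));
  return std::log1p(-std::exp(-lam));
}

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// ZTP log-likelihood in the latent log-rate l (constants in y dropped)
static inline double ll_ztp(double l, double y) {
  if (l > 500.0) return -1e300;          // exp(l) overflows; impossible region
  double lam = std::exp(l);
  double t = (lam > 1e-12) ? log1mexp_pos(lam) : std::log(lam);
  return y * l - lam - t;
}

static inline double ll_binom(double l, double y, double n) {
  return y * l - n * softplus(l);
}

struct SliceTarget {
  int model;          // 1 ztp, 2 binomial
  double y, ntr, eta, inv2s2;
  double operator()(double l) const {
    double ll = (model == 1) ? ll_ztp(l, y) : ll_binom(l, y, ntr);
    double d = l - eta;
    return ll - d * d * inv2s2;
  }
};

// Univariate slice sampler (Neal 2003, stepping out + shrinkage)
static double slice_draw(double x0, const SliceTarget& f) {
  double f0 = f(x0);
  double z = f0 - R::exp_rand();
  double w = 1.0;
  double L = x0 - w * R::unif_rand();
  double Rr = L + w;
  for (int i = 0; i < 50 && f(L) > z; ++i) L -= w;
  for (int i = 0; i < 50 && f(Rr) > z; ++i) Rr += w;
  for (int i = 0; i < 100; ++i) {
    double x1 = L + R::unif_rand() * (Rr - L);
    if (f(x1) > z) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
  return x0;
}

// Draw from N(P^-1 rhs, P^-1), optionally conditioned on sum(x) = 0.
static arma::vec draw_gaussian_block(const arma::mat& P, const arma::vec& rhs,
                                     bool stz) {
  const int K = P.n_rows;
  arma::mat U = arma::chol(P);                       // P = U'U
  arma::vec mu = arma::solve(arma::trimatu(U),
                             arma::solve(arma::trimatl(U.t()), rhs));
  arma::vec zeta(K);
  for (int i = 0; i < K; ++i) zeta(i) = R::norm_rand();
  arma::vec x = mu + arma::solve(arma::trimatu(U), zeta);
  if (stz) {
    // condition on 1'x = 0: x <- x - (Sigma 1) (1'x) / (1' Sigma 1)
    arma::vec s = arma::solve(arma::trimatu(U),
                              arma::solve(arma::trimatl(U.t()),
                                          arma::ones<arma::vec>(K)));
    x -= s * (arma::accu(x) / arma::accu(s));
  }
  return x;
}

static inline double rinvgamma(double shape, double scale) {
  // X ~ IG(shape, scale) <=> 1/X ~ Gamma(shape, rate = scale)
  double g = R::rgamma(shape, 1.0 / scale);
  double v = scale > 0 ? 1.0 / g : 1.0;
  if (!std::isfinite(v) || v < 1e-12) v = 1e-12;
  if (v > 1e12) v = 1e12;
  return v;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix diallel_gibbs_cpp(
    int model,                     // 0 gaussian, 1 ztp, 2 binomial
    Rcpp::NumericVector y,         // response (counts / males / transformed)
    Rcpp::NumericVector ntrials,   // binomial totals (ignored otherwise)
    Rcpp::IntegerVector jdx,       // dam strain, 0-based
    Rcpp::IntegerVector kdx,       // sire strain, 0-based
    Rcpp::IntegerVector pairdx,    // unordered pair, 0-based, -1 if inbred
    Rcpp::NumericVector asign,     // +-0.5 or 0
    Rcpp::IntegerVector batchdx,   // 0-based, < n_batch
    Rcpp::IntegerVector orddx,     // 0-based parity, < n_ord
    int n_iter, int n_burn, int thin,
    double fixed_var, double ig_shape, double ig_scale,
    Rcpp::LogicalVector include    // a, m, b, v, w, batch, order
) {
  const int n = y.size();
  const int NA_ = 8, NP = 28, NB = 48, NO = 12;
  const bool inc_a = include[0], inc_m = include[1], inc_b = include[2],
             inc_v = include[3], inc_w = include[4], inc_batch = include[5],
             inc_order = include[6];

  // ---- precomputed cross-products (design is fixed) ----
  arma::mat XtX_a(NA_, NA_, arma::fill::zeros);
  arma::mat XtX_m(NA_, NA_, arma::fill::zeros);
  arma::vec cnt_b(NA_, arma::fill::zeros);
  arma::vec cnt_v(NP, arma::fill::zeros);
  arma::vec ssq_w(NP, arma::fill::zeros);
  arma::vec cnt_batch(NB, arma::fill::zeros);
  arma::vec cnt_ord(NO, arma::fill::zeros);
  double n_inb = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = jdx[i], k = kdx[i];
    if (j == k) {
      XtX_a(j, j) += 4.0;
      cnt_b(j) += 1.0;
      n_inb += 1.0;
    } else {
      XtX_a(j, j) += 1.0; XtX_a(k, k) += 1.0;
      XtX_a(j, k) += 1.0; XtX_a(k, j) += 1.0;
      XtX_m(j, j) += 1.0; XtX_m(k, k) += 1.0;
      XtX_m(j, k) -= 1.0; XtX_m(k, j) -= 1.0;
      cnt_v(pairdx[i]) += 1.0;
      ssq_w(pairdx[i]) += asign[i] * asign[i];
    }
    cnt_batch(batchdx[i]) += 1.0;
    cnt_ord(orddx[i]) += 1.0;
  }

  // ---- state ----
  double mu = 0.0, alpha = 0.0, beta_inb = 0.0;
  arma::vec a(NA_, arma::fill::zeros), m(NA_, arma::fill::zeros),
            b(NA_, arma::fill::zeros), v(NP, arma::fill::zeros),
            w(NP, arma::fill::zeros), batch(NB, arma::fill::zeros),
            ord(NO, arma::fill::zeros);
  double sigma2 = 1.0;
  double t2a = 0.1, t2m = 0.1, t2b = 0.1, t2v = 0.1, t2w = 0.1,
         t2batch = 0.1, t2order = 0.1;

  arma::vec lat(n), eta(n);
  if (n > 0) {
    for (int i = 0; i < n; ++i) {
      if (model == 1)      lat(i) = std::log(std::max(y[i], 0.5));
      else if (model == 2) lat(i) = std::log((y[i] + 0.5) / (ntrials[i] - y[i] + 0.5));
      else                 lat(i) = y[i];
    }
    mu = arma::mean(lat);
    double sv = arma::var(lat);
    sigma2 = (std::isfinite(sv) && sv > 0.01) ? sv : 0.01;
  }

  auto recompute_eta = [&]() {
    for (int i = 0; i < n; ++i) {
      int j = jdx[i], k = kdx[i];
      double e = mu + ord(orddx[i]) + batch(batchdx[i]) + a(j) + a(k);
      if (j == k) {
        e += beta_inb + b(j);
      } else {
        e += m(j) - m(k) + v(pairdx[i]) + asign[i] * w(pairdx[i]);
      }
      eta(i) = e;
    }
  };

  // ---- output ----
  const int n_keep = (n_iter - n_burn + thin - 1) / thin;
  const int NCOL = 3 + NA_ * 3 + NP * 2 + NO + NB + 1 + 7;
  Rcpp::NumericMatrix out(n_keep, NCOL);
  int row = 0;

  for (int it = 0; it < n_iter; ++it) {
    recompute_eta();

    // latent update (discrete outcomes only)
    if (model != 0 && n > 0) {
      SliceTarget tgt; tgt.model = model; tgt.inv2s2 = 0.5 / sigma2;
      for (int i = 0; i < n; ++i) {
        tgt.y = y[i]; tgt.ntr = (model == 2) ? ntrials[i] : 0.0;
        tgt.eta = eta(i);
        lat(i) = slice_draw(lat(i), tgt);
        if (!std::isfinite(lat(i)))
          Rcpp::stop("sampler diverged: non-finite latent value at observation %d, iteration %d",
                     i + 1, it + 1);
      }
    }

    // mu
    {
      double sr = 0.0;
      for (int i = 0; i < n; ++i) sr += lat(i) - eta(i) + mu;
      double prec = n / sigma2 + 1.0 / fixed_var;
      double mnew = (sr / sigma2) / prec + R::norm_rand() / std::sqrt(prec);
      eta += (mnew - mu);
      mu = mnew;
    }

    // parity: alpha given order levels, then order deviations
    if (inc_order) {
      double sr2 = 0.0, srx = 0.0;
      for (int r = 0; r < NO; ++r) { sr2 += (r + 1.0) * (r + 1.0); srx += (r + 1.0) * ord(r); }
      double prec = sr2 / t2order + 1.0 / fixed_var;
      alpha = (srx / t2order) / prec + R::norm_rand() / std::sqrt(prec);
      arma::vec rhs(NO, arma::fill::zeros);
      for (int i = 0; i < n; ++i)
        rhs(orddx[i]) += lat(i) - eta(i) + ord(orddx[i]);
      arma::vec old = ord;
      for (int r = 0; r < NO; ++r) {
        double p = cnt_ord(r) / sigma2 + 1.0 / t2order;
        double mn = (rhs(r) / sigma2 + (r + 1.0) * alpha / t2order) / p;
        ord(r) = mn + R::norm_rand() / std::sqrt(p);
      }
      for (int i = 0; i < n; ++i) eta(i) += ord(orddx[i]) - old(orddx[i]);
    }

    // batch
    if (inc_batch) {
      arma::vec rhs(NB, arma::fill::zeros);
      for (int i = 0; i < n; ++i)
        rhs(batchdx[i]) += lat(i) - eta(i) + batch(batchdx[i]);
      arma::vec old = batch;
      for (int h = 0; h < NB; ++h) {
        double p = cnt_batch(h) / sigma2 + 1.0 / t2batch;
        batch(h) = (rhs(h) / sigma2) / p + R::norm_rand() / std::sqrt(p);
      }
      for (int i = 0; i < n; ++i) eta(i) += batch(batchdx[i]) - old(batchdx[i]);
    }

    // additive block
    if (inc_a) {
      arma::vec rhs(NA_, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        int j = jdx[i], k = kdx[i];
        double r = lat(i) - eta(i) + a(j) + a(k);
        rhs(j) += r; rhs(k) += r;
      }
      arma::mat P = XtX_a / sigma2; P.diag() += 1.0 / t2a;
      arma::vec old = a;
      a = draw_gaussian_block(P, rhs / sigma2, true);
      for (int i = 0; i < n; ++i)
        eta(i) += a(jdx[i]) + a(kdx[i]) - old(jdx[i]) - old(kdx[i]);
    }

    // parental-sex block
    if (inc_m) {
      arma::vec rhs(NA_, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        int j = jdx[i], k = kdx[i];
        if (j == k) continue;
        double r = lat(i) - eta(i) + m(j) - m(k);
        rhs(j) += r; rhs(k) -= r;
      }
      arma::mat P = XtX_m / sigma2; P.diag() += 1.0 / t2m;
      arma::vec old = m;
      m = draw_gaussian_block(P, rhs / sigma2, true);
      for (int i = 0; i < n; ++i) {
        int j = jdx[i], k = kdx[i];
        if (j != k) eta(i) += m(j) - m(k) - old(j) + old(k);
      }
    }

    // overall inbred penalty (fixed effect)
    {
      double sr = 0.0;
      for (int i = 0; i < n; ++i)
        if (jdx[i] == kdx[i]) sr += lat(i) - eta(i) + beta_inb;
      double prec = n_inb / sigma2 + 1.0 / fixed_var;
      double bnew = (sr / sigma2) / prec + R::norm_rand() / std::sqrt(prec);
      for (int i = 0; i < n; ++i)
        if (jdx[i] == kdx[i]) eta(i) += bnew - beta_inb;
      beta_inb = bnew;
    }

    // strain-specific inbred block
    if (inc_b) {
      arma::vec rhs(NA_, arma::fill::zeros);
      for (int i = 0; i < n; ++i)
        if (jdx[i] == kdx[i]) rhs(jdx[i]) += lat(i) - eta(i) + b(jdx[i]);
      arma::mat P(NA_, NA_, arma::fill::zeros);
      P.diag() = cnt_b / sigma2 + 1.0 / t2b;
      arma::vec old = b;
      b = draw_gaussian_block(P, rhs / sigma2, true);
      for (int i = 0; i < n; ++i)
        if (jdx[i] == kdx[i]) eta(i) += b(jdx[i]) - old(jdx[i]);
    }

    // symmetric epistasis block
    if (inc_v) {
      arma::vec rhs(NP, arma::fill::zeros);
      for (int i = 0; i < n; ++i)
        if (pairdx[i] >= 0) rhs(pairdx[i]) += lat(i) - eta(i) + v(pairdx[i]);
      arma::mat P(NP, NP, arma::fill::zeros);
      P.diag() = cnt_v / sigma2 + 1.0 / t2v;
      arma::vec old = v;
      v = draw_gaussian_block(P, rhs / sigma2, true);
      for (int i = 0; i < n; ++i)
        if (pairdx[i] >= 0) eta(i) += v(pairdx[i]) - old(pairdx[i]);
    }

    // asymmetric epistasis block
    if (inc_w) {
      arma::vec rhs(NP, arma::fill::zeros);
      for (int i = 0; i < n; ++i)
        if (pairdx[i] >= 0)
          rhs(pairdx[i]) += asign[i] * (lat(i) - eta(i) + asign[i] * w(pairdx[i]));
      arma::mat P(NP, NP, arma::fill::zeros);
      P.diag() = ssq_w / sigma2 + 1.0 / t2w;
      arma::vec old = w;
      w = draw_gaussian_block(P, rhs / sigma2, true);
      for (int i = 0; i < n; ++i)
        if (pairdx[i] >= 0) eta(i) += asign[i] * (w(pairdx[i]) - old(pairdx[i]));
    }

    // residual / overdispersion variance
    {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = lat(i) - eta(i);
        ss += d * d;
      }
      sigma2 = rinvgamma(ig_shape + 0.5 * n, ig_scale + 0.5 * ss);
    }

    // variance components (sum-to-zero classes have K-1 free dimensions)
    if (inc_a) t2a = rinvgamma(ig_shape + 0.5 * (NA_ - 1), ig_scale + 0.5 * arma::dot(a, a));
    if (inc_m) t2m = rinvgamma(ig_shape + 0.5 * (NA_ - 1), ig_scale + 0.5 * arma::dot(m, m));
    if (inc_b) t2b = rinvgamma(ig_shape + 0.5 * (NA_ - 1), ig_scale + 0.5 * arma::dot(b, b));
    if (inc_v) t2v = rinvgamma(ig_shape + 0.5 * (NP - 1), ig_scale + 0.5 * arma::dot(v, v));
    if (inc_w) t2w = rinvgamma(ig_shape + 0.5 * (NP - 1), ig_scale + 0.5 * arma::dot(w, w));
    if (inc_batch)
      t2batch = rinvgamma(ig_shape + 0.5 * NB, ig_scale + 0.5 * arma::dot(batch, batch));
    if (inc_order) {
      double ss = 0.0;
      for (int r = 0; r < NO; ++r) {
        double d = ord(r) - (r + 1.0) * alpha;
        ss += d * d;
      }
      t2order = rinvgamma(ig_shape + 0.5 * NO, ig_scale + 0.5 * ss);
    }

    if (it >= n_burn && (it - n_burn) % thin == 0 && row < n_keep) {
      int c = 0;
      out(row, c++) = mu; out(row, c++) = alpha; out(row, c++) = beta_inb;
      for (int q = 0; q < NA_; ++q) out(row, c++) = a(q);
      for (int q = 0; q < NA_; ++q) out(row, c++) = m(q);
      for (int q = 0; q < NA_; ++q) out(row, c++) = b(q);
      for (int q = 0; q < NP; ++q) out(row, c++) = v(q);
      for (int q = 0; q < NP; ++q) out(row, c++) = w(q);
      for (int q = 0; q < NO; ++q) out(row, c++) = ord(q);
      for (int q = 0; q < NB; ++q) out(row, c++) = batch(q);
      out(row, c++) = sigma2;
      out(row, c++) = t2a; out(row, c++) = t2m; out(row, c++) = t2b;
      out(row, c++) = t2v; out(row, c++) = t2w;
      out(row, c++) = t2batch; out(row, c++) = t2order;
      ++row;
    }
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }

  return out;
}
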