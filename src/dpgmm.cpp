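// Collapsed Gibbs sampler for a Dirichlet-process mixture of Gaussians
// with a conjugate Normal-inverse-Wishart base measure (full covariance)
// or a per-dimension Normal-Gamma base measure (diagonal covariance).
// Component parameters are integrated out; only indicator variables are
// sampled. All randomness goes through R's RNG so set.seed() governs runs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double lmvgamma(double a, int d) {
  double r = 0.25 * d * (d - 1) * std::log(M_PI);
  for (int j = 1; j <= d; ++j) r += std::lgamma(a + 0.5 * (1.0 - j));
  return r;
}

struct Prior {
  arma::vec m0;     // prior mean
  double kappa0;    // prior mean strength (pseudo-observations)
  double nu0;       // degrees of freedom (> d - 1)
  arma::mat S0;     // inverse-Wishart scale matrix
  bool diagonal;    // use independent per-dimension Normal-Gamma instead
  double logdetS0;  // cached
  arma::vec b0;     // diagonal model: per-dim rate, a0 = nu0 / 2
};

struct Comp {
  int n = 0;
  arma::vec sum;
  arma::mat ss;  // sum of outer products x x'
};

static void comp_init(Comp& c, int d) {
  c.n = 0;
  c.sum.zeros(d);
  c.ss.zeros(d, d);
}

static void comp_add(Comp& c, const arma::vec& x) {
  c.n += 1;
  c.sum += x;
  c.ss += x * x.t();
}

static void comp_remove(Comp& c, const arma::vec& x) {
  c.n -= 1;
  c.sum -= x;
  c.ss -= x * x.t();
}

// Posterior predictive density of x given the points currently in the
// component: multivariate Student-t (full) or a product of univariate
// Student-t (diagonal).
static double log_predictive(const Prior& pr, const Comp& c, const arma::vec& x) {
  const int d = x.n_elem;
  const double kap = pr.kappa0 + c.n;
  if (!pr.diagonal) {
    const double nu = pr.nu0 + c.n;
    arma::vec mn;
    arma::mat Sn;
    if (c.n > 0) {
      arma::vec xbar = c.sum / c.n;
      arma::mat Sc = c.ss - c.n * (xbar * xbar.t());
      arma::vec dm = xbar - pr.m0;
      mn = (pr.kappa0 * pr.m0 + c.sum) / kap;
      Sn = pr.S0 + Sc + (pr.kappa0 * c.n / kap) * (dm * dm.t());
    } else {
      mn = pr.m0;
      Sn = pr.S0;
    }
    const double df = nu - d + 1.0;
    arma::mat scale = Sn * ((kap + 1.0) / (kap * df));
    arma::mat L = arma::chol(arma::symmatu(scale), "lower");
    const double logdet = 2.0 * arma::sum(arma::log(L.diag()));
    arma::vec y = arma::solve(arma::trimatl(L), x - mn);
    const double q = arma::dot(y, y);
    return std::lgamma(0.5 * (df + d)) - std::lgamma(0.5 * df)
         - 0.5 * d * std::log(df * M_PI) - 0.5 * logdet
         - 0.5 * (df + d) * std::log1p(q / df);
  }
  // diagonal: independent Normal-Gamma in each dimension
  const double a0 = 0.5 * pr.nu0;
  const double an = a0 + 0.5 * c.n;
  double lp = 0.0;
  for (int j = 0; j < d; ++j) {
    double mn, bn;
    if (c.n > 0) {
      const double xbar = c.sum(j) / c.n;
      const double sc = c.ss(j, j) - c.n * xbar * xbar;
      const double dm = xbar - pr.m0(j);
      mn = (pr.kappa0 * pr.m0(j) + c.sum(j)) / kap;
      bn = pr.b0(j) + 0.5 * sc + 0.5 * (pr.kappa0 * c.n / kap) * dm * dm;
    } else {
      mn = pr.m0(j);
      bn = pr.b0(j);
    }
    const double df = 2.0 * an;
    const double s2 = bn * (kap + 1.0) / (an * kap);
    const double z = (x(j) - mn);
    lp += std::lgamma(0.5 * (df + 1.0)) - std::lgamma(0.5 * df)
        - 0.5 * std::log(df * M_PI * s2)
        - 0.5 * (df + 1.0) * std::log1p(z * z / (df * s2));
  }
  return lp;
}

// Marginal likelihood of all points currently in a component.
static double log_marginal(const Prior& pr, const Comp& c) {
  if (c.n == 0) return 0.0;
  const int d = c.sum.n_elem;
  const double kap = pr.kappa0 + c.n;
  if (!pr.diagonal) {
    const double nu = pr.nu0 + c.n;
    arma::vec xbar = c.sum / c.n;
    arma::mat Sc = c.ss - c.n * (xbar * xbar.t());
    arma::vec dm = xbar - pr.m0;
    arma::mat Sn = pr.S0 + Sc + (pr.kappa0 * c.n / kap) * (dm * dm.t());
    double ld, sign;
    arma::log_det(ld, sign, arma::symmatu(Sn));
    return -0.5 * c.n * d * std::log(M_PI)
         + lmvgamma(0.5 * nu, d) - lmvgamma(0.5 * pr.nu0, d)
         + 0.5 * pr.nu0 * pr.logdetS0 - 0.5 * nu * ld
         + 0.5 * d * (std::log(pr.kappa0) - std::log(kap));
  }
  const double a0 = 0.5 * pr.nu0;
  const double an = a0 + 0.5 * c.n;
  double lm = 0.0;
  for (int j = 0; j < d; ++j) {
    const double xbar = c.sum(j) / c.n;
    const double sc = c.ss(j, j) - c.n * xbar * xbar;
    const double dm = xbar - pr.m0(j);
    const double bn = pr.b0(j) + 0.5 * sc + 0.5 * (pr.kappa0 * c.n / kap) * dm * dm;
    lm += -0.5 * c.n * std::log(2.0 * M_PI)
        + std::lgamma(an) - std::lgamma(a0)
        + a0 * std::log(pr.b0(j)) - an * std::log(bn)
        + 0.5 * (std::log(pr.kappa0) - std::log(kap));
  }
  return lm;
}

static Prior make_prior(const arma::vec& m0, double kappa0, double nu0,
                        const arma::mat& S0, bool diagonal) {
  Prior pr;
  pr.m0 = m0;
  pr.kappa0 = kappa0;
  pr.nu0 = nu0;
  pr.S0 = S0;
  pr.diagonal = diagonal;
  double ld, sign;
  arma::log_det(ld, sign, arma::symmatu(S0));
  pr.logdetS0 = ld;
  pr.b0 = 0.5 * S0.diag();
  return pr;
}

// Exposed for unit tests: predictive / marginal given an explicit member set.
// [[Rcpp::export]]
double niw_log_predictive_cpp(const arma::vec& x, const arma::mat& members,
                              const arma::vec& m0, double kappa0, double nu0,
                              const arma::mat& S0, bool diagonal) {
  Prior pr = make_prior(m0, kappa0, nu0, S0, diagonal);
  Comp c;
  comp_init(c, x.n_elem);
  for (arma::uword i = 0; i < members.n_rows; ++i) comp_add(c, members.row(i).t());
  return log_predictive(pr, c, x);
}

// [[Rcpp::export]]
double niw_log_marginal_cpp(const arma::mat& members, const arma::vec& m0,
                            double kappa0, double nu0, const arma::mat& S0,
                            bool diagonal) {
  Prior pr = make_prior(m0, kappa0, nu0, S0, diagonal);
  Comp c;
  comp_init(c, m0.n_elem);
  for (arma::uword i = 0; i < members.n_rows; ++i) comp_add(c, members.row(i).t());
  return log_marginal(pr, c);
}

// Draw W ~ Wishart(df, Scale) via the Bartlett decomposition, using R's RNG.
static arma::mat rwishart(double df, const arma::mat& Scale) {
  const int d = Scale.n_rows;
  arma::mat L = arma::chol(arma::symmatu(Scale), "lower");
  arma::mat A(d, d, arma::fill::zeros);
  for (int i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

// One hierarchical update of the base-measure scale: instantiate each
// occupied component's covariance from its inverse-Wishart posterior, then
// draw S0 from its conjugate Wishart full conditional
//   S0 ~ Wishart(nu_h + k * nu0, (H^-1 + sum_j Sigma_j^-1)^-1).
// This lets the prior expected cluster size track the actual cluster sizes
// instead of being pinned to a fixed fraction of the data spread.
static void update_scale_full(Prior& pr, const std::vector<Comp>& comps,
                              double nu_h, const arma::mat& Hinv) {
  const int d = pr.m0.n_elem;
  arma::mat acc = Hinv;
  double df = nu_h;
  for (const Comp& c : comps) {
    const double kap = pr.kappa0 + c.n;
    const double nu = pr.nu0 + c.n;
    arma::vec xbar = c.sum / c.n;
    arma::mat Sc = c.ss - c.n * (xbar * xbar.t());
    arma::vec dm = xbar - pr.m0;
    arma::mat Sn = pr.S0 + Sc + (pr.kappa0 * c.n / kap) * (dm * dm.t());
    // Sigma_j ~ IW(nu, Sn)  <=>  Sigma_j^-1 ~ Wishart(nu, Sn^-1)
    arma::mat Sigma_inv = rwishart(nu, arma::inv_sympd(arma::symmatu(Sn)));
    acc += Sigma_inv;
    df += pr.nu0;
  }
  pr.S0 = rwishart(df, arma::inv_sympd(arma::symmatu(acc)));
  double ld, sign;
  arma::log_det(ld, sign, arma::symmatu(pr.S0));
  pr.logdetS0 = ld;
  pr.b0 = 0.5 * pr.S0.diag();
}

// Diagonal analogue: per-dimension precisions 1/sigma2 ~ Gamma(a0, b0_j);
// each b0_j gets a conjugate Gamma(h1, h2_j) hyperprior.
static void update_scale_diag(Prior& pr, const std::vector<Comp>& comps,
                              double h1, const arma::vec& h2) {
  const int d = pr.m0.n_elem;
  const double a0 = 0.5 * pr.nu0;
  arma::vec rate = h2;
  double shape = h1;
  for (const Comp& c : comps) {
    const double kap = pr.kappa0 + c.n;
    const double an = a0 + 0.5 * c.n;
    for (int j = 0; j < d; ++j) {
      const double xbar = c.sum(j) / c.n;
      const double sc = c.ss(j, j) - c.n * xbar * xbar;
      const double dm = xbar - pr.m0(j);
      const double bn = pr.b0(j) + 0.5 * sc
                      + 0.5 * (pr.kappa0 * c.n / kap) * dm * dm;
      const double prec = R::rgamma(an, 1.0 / bn);  // 1/sigma2_j
      rate(j) += prec;
    }
  }
  shape += comps.size() * a0;
  for (int j = 0; j < d; ++j) {
    pr.b0(j) = R::rgamma(shape, 1.0 / rate(j));
    pr.S0(j, j) = 2.0 * pr.b0(j);
  }
  double ld, sign;
  arma::log_det(ld, sign, arma::symmatu(pr.S0));
  pr.logdetS0 = ld;
}

// Chinese-restaurant-process partition probability.
static double log_crp(const std::vector<Comp>& comps, double alpha, int n) {
  double lp = std::lgamma(alpha) - std::lgamma(alpha + n);
  for (const Comp& c : comps) {
    lp += std::log(alpha) + std::lgamma((double)c.n);
  }
  return lp;
}

// Escobar & West (1995) auxiliary-variable update for the concentration
// parameter under a Gamma(a, b) prior.
static double resample_alpha(double alpha, int k, int n, double a, double b) {
  const double eta = R::rbeta(alpha + 1.0, (double)n);
  const double num = a + k - 1.0;
  const double den = n * (b - std::log(eta));
  const double pi = num / (num + den);
  if (R::unif_rand() < pi) {
    return R::rgamma(a + k, 1.0 / (b - std::log(eta)));
  }
  return R::rgamma(a + k - 1.0, 1.0 / (b - std::log(eta)));
}

// [[Rcpp::export]]
List dpgmm_gibbs_cpp(const arma::mat& X, int n_iter, int burn_in,
                     double alpha, bool learn_alpha,
                     double alpha_a, double alpha_b,
                     const arma::vec& m0, double kappa0, double nu0,
                     const arma::mat& S0, bool diagonal, bool learn_scale,
                     bool init_singletons) {
  const int n = X.n_rows;
  const int d = X.n_cols;
  if (!X.is_finite()) stop("non-finite values in input matrix");
  Prior pr = make_prior(m0, kappa0, nu0, S0, diagonal);
  // hyperprior for the base-measure scale, centered on the initial S0:
  // full model S0 ~ Wishart(nu_h, H) with nu_h * H = S0_init;
  // diagonal model b0_j ~ Gamma(h1, h2_j) with h1 / h2_j = b0_init_j
  const double nu_h = d;
  const arma::mat Hinv = nu_h * arma::inv_sympd(arma::symmatu(S0));
  const double h1 = 1.0;
  const arma::vec h2 = 1.0 / (0.5 * S0.diag());

  // Start either from singleton components (default: merge moves mix much
  // better than split nucleation for well-separated clusters) or from a
  // single all-in-one component.
  std::vector<Comp> comps;
  std::vector<int> z(n, 0);
  if (init_singletons) {
    comps.resize(n);
    for (int i = 0; i < n; ++i) {
      comp_init(comps[i], d);
      comp_add(comps[i], X.row(i).t());
      z[i] = i;
    }
  } else {
    comps.resize(1);
    comp_init(comps[0], d);
    for (int i = 0; i < n; ++i) comp_add(comps[0], X.row(i).t());
  }

  std::vector<int> best_z = z;
  double best_lp = -std::numeric_limits<double>::infinity();
  IntegerVector k_trace(n_iter);

  std::vector<double> logp;
  for (int t = 0; t < n_iter; ++t) {
    for (int i = 0; i < n; ++i) {
      const arma::vec x = X.row(i).t();
      const int zi = z[i];
      comp_remove(comps[zi], x);
      if (comps[zi].n == 0) {
        // swap-erase empty component, relabel indicators pointing at the tail
        const int last = (int)comps.size() - 1;
        if (zi != last) {
          comps[zi] = comps[last];
          for (int j = 0; j < n; ++j) if (z[j] == last) z[j] = zi;
        }
        comps.pop_back();
      }
      const int k = (int)comps.size();
      logp.assign(k + 1, 0.0);
      for (int c = 0; c < k; ++c) {
        logp[c] = std::log((double)comps[c].n) + log_predictive(pr, comps[c], x);
      }
      Comp empty;
      comp_init(empty, d);
      logp[k] = std::log(alpha) + log_predictive(pr, empty, x);
      double m = logp[0];
      for (int c = 1; c <= k; ++c) m = std::max(m, logp[c]);
      double tot = 0.0;
      for (int c = 0; c <= k; ++c) {
        logp[c] = std::exp(logp[c] - m);
        tot += logp[c];
      }
      double u = R::unif_rand() * tot;
      int pick = 0;
      for (; pick < k; ++pick) {
        u -= logp[pick];
        if (u <= 0.0) break;
      }
      if (pick == k) {
        comps.push_back(empty);
      }
      comp_add(comps[pick], x);
      z[i] = pick;
    }
    if (learn_alpha) {
      alpha = resample_alpha(alpha, (int)comps.size(), n, alpha_a, alpha_b);
      if (alpha < 1e-8) alpha = 1e-8;
    }
    if (learn_scale) {
      if (diagonal) update_scale_diag(pr, comps, h1, h2);
      else update_scale_full(pr, comps, nu_h, Hinv);
    }
    k_trace[t] = (int)comps.size();
    if (t >= burn_in) {
      double lp = log_crp(comps, alpha, n);
      for (const Comp& c : comps) lp += log_marginal(pr, c);
      if (lp > best_lp) {
        best_lp = lp;
        best_z = z;
      }
    }
  }

  IntegerVector zz(n);
  for (int i = 0; i < n; ++i) zz[i] = best_z[i] + 1;
  int kbest = 0;
  for (int i = 0; i < n; ++i) kbest = std::max(kbest, (int)zz[i]);
  return List::create(_["assignment"] = zz,
                      _["k"] = kbest,
                      _["log_posterior"] = best_lp,
                      _["alpha"] = alpha,
                      _["k_trace"] = k_trace);
}
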