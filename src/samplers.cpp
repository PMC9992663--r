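// Summary-statistic solvers: blockwise coordinate descent for the L1
// objective, a truncated Dirichlet-process normal-mixture Gibbs sampler, and
// a continuous-shrinkage (gamma-gamma local scale) Gibbs sampler.
//
// All samplers draw from R's RNG (norm_rand/unif_rand/R::rgamma/R::rbeta) so
// that set.seed() on the R side makes runs bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft(double x, double lambda) {
  if (x > lambda) return x - lambda;
  if (x < -lambda) return x + lambda;
  return 0.0;
}

// Cholesky with escalating diagonal jitter; throws after `tries` escalations.
static arma::mat chol_jitter_cpp(const arma::mat& A, double jitter, int tries) {
  arma::mat U;
  for (int k = 0; k <= tries; ++k) {
    double eps = (k == 0) ? 0.0 : jitter * std::pow(10.0, k - 1);
    arma::mat Aj = A;
    if (eps > 0) Aj.diag() += eps;
    if (arma::chol(U, Aj)) return U;
  }
  stop("LD block not positive definite after jitter escalation");
  return U; // unreachable
}

// ---------------------------------------------------------------------------
// lassosum-style coordinate descent
// ---------------------------------------------------------------------------
// Minimizes f(w) = (1-s) w'Rw + s w'w - 2 beta'w + 2 lambda ||w||_1 over each
// LD block independently (cross-block R entries are ignored by construction).
// With unit-diagonal R the coordinate update is
//   w_j <- soft(beta_j - (1-s) sum_{k != j} R_jk w_k, lambda).

static double lasso_objective(const arma::vec& w, const arma::vec& beta,
                              const std::vector<arma::mat>& Rb,
                              const std::vector<arma::uvec>& idx,
                              double s, double lambda) {
  double quad = 0.0;
  for (size_t b = 0; b < Rb.size(); ++b) {
    arma::vec wb = w.elem(idx[b]);
    quad += arma::as_scalar(wb.t() * Rb[b] * wb);
  }
  return (1.0 - s) * quad + s * arma::dot(w, w) - 2.0 * arma::dot(beta, w) +
         2.0 * lambda * arma::norm(w, 1);
}

// [[Rcpp::export]]
List lassosum_cd_cpp(const arma::vec& beta, const arma::mat& R, const List& blocks,
                     double s, double lambda, int max_iter, double tol,
                     const arma::vec& w_init) {
  const int m = beta.n_elem;
  arma::vec w = w_init;
  std::vector<arma::uvec> idx;
  std::vector<arma::mat> Rb;
  for (int b = 0; b < blocks.size(); ++b) {
    arma::uvec ib = as<arma::uvec>(blocks[b]) - 1; // 1-based from R
    idx.push_back(ib);
    Rb.push_back(R.submat(ib, ib));
  }
  std::vector<double> obj;
  obj.push_back(lasso_objective(w, beta, Rb, idx, s, lambda));
  bool converged = false;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    double max_change = 0.0;
    for (size_t b = 0; b < idx.size(); ++b) {
      const arma::uvec& ib = idx[b];
      const arma::mat& Rblk = Rb[b];
      const int mb = ib.n_elem;
      arma::vec wb = w.elem(ib);
      arma::vec betab = beta.elem(ib);
      for (int j = 0; j < mb; ++j) {
        double cross = arma::dot(Rblk.col(j), wb) - wb(j); // unit diagonal
        double wj = soft(betab(j) - (1.0 - s) * cross, lambda);
        double change = std::abs(wj - wb(j));
        if (change > max_change) max_change = change;
        wb(j) = wj;
      }
      w.elem(ib) = wb;
    }
    obj.push_back(lasso_objective(w, beta, Rb, idx, s, lambda));
    if (max_change <= tol) { converged = true; ++it; break; }
  }
  return List::create(_["w"] = w, _["converged"] = converged,
                      _["iterations"] = it, _["objective"] = obj);
}

// ---------------------------------------------------------------------------
// Dirichlet-process normal-mixture Gibbs sampler (SDPR-style)
// ---------------------------------------------------------------------------
// Model: w_j ~ sum_{k=0..M} pi_k N(0, sigma2_k) with sigma2_0 = 0 (null
// spike); stick-breaking pi with concentration alpha; inverse-gamma base for
// sigma2_k (k >= 1); residual variance sigma2_eps with a vague inverse-gamma
// prior. Only the summary sufficient statistics (n * beta, n * R) enter the
// likelihood. Single-site sweeps update (assignment, w_j) jointly with w_j
// marginalized out of the assignment probability, which accommodates the
// point-mass null exactly.

// [[Rcpp::export]]
List sdpr_gibbs_cpp(const arma::vec& beta, double n, const arma::mat& R,
                    const List& blocks, int M, double alpha,
                    double a0, double b0, double a_eps, double b_eps,
                    int iters, int burnin, int thin,
                    double fixed_sigma2 = -1.0, double fixed_sigma2_eps = -1.0) {
  const int m = beta.n_elem;
  std::vector<arma::uvec> idx;
  std::vector<arma::mat> Rb;
  for (int b = 0; b < blocks.size(); ++b) {
    arma::uvec ib = as<arma::uvec>(blocks[b]) - 1;
    idx.push_back(ib);
    Rb.push_back(R.submat(ib, ib));
  }
  const bool oracle = fixed_sigma2 > 0.0;

  arma::vec w(m, arma::fill::zeros);
  arma::ivec zassign(m, arma::fill::zeros);       // component labels 0..M
  arma::vec sigma2(M + 1, arma::fill::zeros);      // sigma2[0] = 0 spike
  for (int k = 1; k <= M; ++k) sigma2(k) = 0.1 / M * k;
  arma::vec pi(M + 1, arma::fill::value(1.0 / (M + 1)));
  double s2e = (fixed_sigma2_eps > 0.0) ? fixed_sigma2_eps : 1.0;

  arma::vec w_sum(m, arma::fill::zeros);
  arma::vec pi_sum(M + 1, arma::fill::zeros);
  arma::ivec counts_last(M + 1, arma::fill::zeros);
  int n_rec = 0;

  for (int it = 0; it < iters; ++it) {
    // --- (z_j, w_j) single-site sweeps ---
    for (size_t b = 0; b < idx.size(); ++b) {
      const arma::uvec& ib = idx[b];
      const arma::mat& Rblk = Rb[b];
      const int mb = ib.n_elem;
      arma::vec wb = w.elem(ib);
      arma::vec betab = beta.elem(ib);
      for (int j = 0; j < mb; ++j) {
        double rj = betab(j) - (arma::dot(Rblk.col(j), wb) - wb(j));
        if (oracle) {
          double tau2 = 1.0 / (n / s2e + 1.0 / fixed_sigma2);
          double mu = tau2 * n * rj / s2e;
          wb(j) = mu + std::sqrt(tau2) * norm_rand();
          continue;
        }
        // marginalized assignment probabilities
        arma::vec logp(M + 1);
        arma::vec mu(M + 1, arma::fill::zeros), tau2(M + 1, arma::fill::zeros);
        logp(0) = std::log(pi(0) + 1e-300);
        for (int k = 1; k <= M; ++k) {
          tau2(k) = 1.0 / (n / s2e + 1.0 / sigma2(k));
          mu(k) = tau2(k) * n * rj / s2e;
          logp(k) = std::log(pi(k) + 1e-300) +
                    0.5 * std::log(tau2(k) / sigma2(k)) +
                    0.5 * mu(k) * mu(k) / tau2(k);
        }
        logp -= logp.max();
        arma::vec prob = arma::exp(logp);
        prob /= arma::accu(prob);
        double u = unif_rand();
        int k = 0;
        double cum = prob(0);
        while (u > cum && k < M) { ++k; cum += prob(k); }
        int gj = ib(j);
        zassign(gj) = k;
        wb(j) = (k == 0) ? 0.0 : mu(k) + std::sqrt(tau2(k)) * norm_rand();
      }
      w.elem(ib) = wb;
    }

    if (!oracle) {
      // --- component counts / stick-breaking weights ---
      arma::ivec nk(M + 1, arma::fill::zeros);
      arma::vec ssk(M + 1, arma::fill::zeros);
      for (int j = 0; j < m; ++j) {
        nk(zassign(j)) += 1;
        ssk(zassign(j)) += w(j) * w(j);
      }
      double stick = 1.0;
      for (int k = 0; k <= M; ++k) {
        if (k == M) { pi(k) = stick; break; }
        int tail = 0;
        for (int l = k + 1; l <= M; ++l) tail += nk(l);
        double v = R::rbeta(1.0 + nk(k), alpha + tail);
        pi(k) = stick * v;
        stick *= (1.0 - v);
      }
      // --- component variances (k >= 1), conjugate inverse-gamma ---
      for (int k = 1; k <= M; ++k) {
        double shape = a0 + 0.5 * nk(k);
        double rate = b0 + 0.5 * ssk(k);
        sigma2(k) = rate / R::rgamma(shape, 1.0);
        if (sigma2(k) < 1e-10) sigma2(k) = 1e-10;
      }
      // --- residual variance ---
      if (fixed_sigma2_eps <= 0.0) {
        double quad = 0.0;
        for (size_t b = 0; b < idx.size(); ++b) {
          arma::vec wb = w.elem(idx[b]);
          quad += arma::as_scalar(wb.t() * Rb[b] * wb);
        }
        double rss = 1.0 - 2.0 * arma::dot(w, beta) + quad;
        if (rss < 1e-8) rss = 1e-8;
        double shape = a_eps + 0.5 * n;
        double rate = b_eps + 0.5 * n * rss;
        s2e = rate / R::rgamma(shape, 1.0);
      }
    }

    if (it >= burnin && ((it - burnin) % thin == 0)) {
      w_sum += w;
      pi_sum += pi;
      ++n_rec;
      counts_last.zeros();
      for (int j = 0; j < m; ++j) counts_last(zassign(j)) += 1;
    }
  }
  return List::create(_["w_mean"] = w_sum / std::max(n_rec, 1),
                      _["pi_mean"] = pi_sum / std::max(n_rec, 1),
                      _["counts"] = counts_last,
                      _["n_recorded"] = n_rec,
                      _["sigma2_eps"] = s2e);
}

// ---------------------------------------------------------------------------
// generalized inverse-Gaussian sampler
// ---------------------------------------------------------------------------
// Density gig(p, a, b) proportional to x^(p-1) exp(-(a x + b / x) / 2).
// Devroye (2014) rejection sampler on the log scale (the same construction
// used by continuous-shrinkage PRS software).

static inline double gig_psi(double x, double alpha, double lam) {
  return -alpha * (std::cosh(x) - 1.0) - lam * (std::exp(x) - x - 1.0);
}
static inline double gig_dpsi(double x, double alpha, double lam) {
  return -alpha * std::sinh(x) - lam * (std::exp(x) - 1.0);
}

// [[Rcpp::export]]
double gigrnd(double p, double a, double b) {
  if (b < 1e-300) {
    if (p <= 0) stop("gigrnd: b ~ 0 requires p > 0");
    return R::rgamma(p, 2.0 / a); // gig(p, a, 0) = Gamma(p, rate a/2)
  }
  if (a < 1e-300) {
    if (p >= 0) stop("gigrnd: a ~ 0 requires p < 0");
    return 1.0 / R::rgamma(-p, 2.0 / b); // inverse-gamma limit
  }
  double lam = p;
  bool swap = false;
  if (lam < 0) { lam = -lam; swap = true; }
  double omega = std::sqrt(a * b);
  double alpha = std::sqrt(omega * omega + lam * lam) - lam;

  double x = -gig_psi(1.0, alpha, lam);
  double t;
  if (x >= 0.5 && x <= 2.0) t = 1.0;
  else if (x > 2.0) t = std::sqrt(2.0 / (alpha + lam));
  else t = std::log(4.0 / (alpha + 2.0 * lam));

  x = -gig_psi(-1.0, alpha, lam);
  double s;
  if (x >= 0.5 && x <= 2.0) s = 1.0;
  else if (x > 2.0) s = std::sqrt(4.0 / (alpha * std::cosh(1.0) + lam));
  else {
    double cand = std::log(1.0 + 1.0 / alpha + std::sqrt(1.0 / (alpha * alpha) + 2.0 / alpha));
    s = (lam > 0) ? std::min(1.0 / lam, cand) : cand;
  }

  double eta = -gig_psi(t, alpha, lam);
  double zeta = -gig_dpsi(t, alpha, lam);
  double theta = -gig_psi(-s, alpha, lam);
  double xi = gig_dpsi(-s, alpha, lam);
  double pp = 1.0 / xi;
  double r = 1.0 / zeta;
  double td = t - r * eta;
  double sd = s - pp * theta;
  double q = td + sd;

  double rnd = 0.0;
  for (int tries = 0; tries < 100000; ++tries) {
    double U = unif_rand(), V = unif_rand(), W = unif_rand();
    if (U < q / (pp + q + r)) rnd = -sd + q * V;
    else if (U < (q + r) / (pp + q + r)) rnd = td - r * std::log(V);
    else rnd = -sd + pp * std::log(V);
    double f1 = std::exp(-eta - zeta * (rnd - t));
    double f2 = std::exp(-theta + xi * (rnd + s));
    double gx;
    if (rnd >= -sd && rnd <= td) gx = 1.0;
    else if (rnd > td) gx = f1;
    else gx = f2;
    if (W * gx <= std::exp(gig_psi(rnd, alpha, lam))) break;
  }
  rnd = std::exp(rnd) * (lam / omega + std::sqrt(1.0 + (lam / omega) * (lam / omega)));
  if (swap) rnd = 1.0 / rnd;
  return rnd / std::sqrt(a / b);
}

// ---------------------------------------------------------------------------
// continuous-shrinkage Gibbs sampler (PRS-CS-style)
// ---------------------------------------------------------------------------
// Prior: w_j ~ N(0, (sigma2_eps / n) * psi_j), psi_j ~ Gamma(a, delta_j),
// delta_j ~ Gamma(b, phi); scale-invariant Jeffreys prior on sigma2_eps.
// The global scale phi acts through delta: small phi pushes the local scales
// toward zero while the heavy gamma-gamma tail lets true signals escape.
// Gibbs cycle: per-block MVN draw of w, GIG draw of psi, gamma draw of delta,
// inverse-gamma draw of sigma2_eps. Local scales are capped at psi_j <= 1
// (the per-SNP prior variance never exceeds sigma2_eps / n).

// [[Rcpp::export]]
List prscs_gibbs_cpp(const arma::vec& beta, double n, const arma::mat& R,
                     const List& blocks, double a, double b, double phi,
                     int iters, int burnin, int thin, double jitter,
                     const arma::vec& psi_fixed) {
  const int m = beta.n_elem;
  std::vector<arma::uvec> idx;
  std::vector<arma::mat> Rb;
  for (int bb = 0; bb < blocks.size(); ++bb) {
    arma::uvec ib = as<arma::uvec>(blocks[bb]) - 1;
    idx.push_back(ib);
    Rb.push_back(R.submat(ib, ib));
  }
  const bool freeze_psi = psi_fixed.n_elem == (unsigned)m;

  arma::vec w(m, arma::fill::zeros);
  arma::vec psi = freeze_psi ? psi_fixed : arma::vec(m, arma::fill::ones);
  arma::vec delta(m, arma::fill::ones);
  double s2e = 1.0;

  arma::vec w_sum(m, arma::fill::zeros);
  arma::vec psi_sum(m, arma::fill::zeros);
  int n_rec = 0;

  for (int it = 0; it < iters; ++it) {
    // --- w | psi, sigma2_eps: per-block MVN ---
    for (size_t bb = 0; bb < idx.size(); ++bb) {
      const arma::uvec& ib = idx[bb];
      const int mb = ib.n_elem;
      arma::mat A = Rb[bb];
      for (int j = 0; j < mb; ++j) A(j, j) += 1.0 / psi(ib(j));
      arma::mat U = chol_jitter_cpp(A, jitter, 3);
      arma::vec mu = arma::solve(arma::trimatu(U),
                                 arma::solve(arma::trimatl(U.t()), beta.elem(ib)));
      arma::vec zdraw(mb);
      for (int j = 0; j < mb; ++j) zdraw(j) = norm_rand();
      w.elem(ib) = mu + std::sqrt(s2e / n) * arma::solve(arma::trimatu(U), zdraw);
    }

    // --- sigma2_eps | w, psi (Jeffreys 1/sigma2) ---
    double quad = 0.0;
    for (size_t bb = 0; bb < idx.size(); ++bb) {
      arma::vec wb = w.elem(idx[bb]);
      quad += arma::as_scalar(wb.t() * Rb[bb] * wb);
    }
    double rss = 1.0 - 2.0 * arma::dot(w, beta) + quad;
    if (rss < 1e-8) rss = 1e-8;
    double prior_quad = 0.0;
    for (int j = 0; j < m; ++j) prior_quad += w(j) * w(j) / psi(j);
    double shape = 0.5 * (n + m);
    double rate = 0.5 * n * (rss + prior_quad);
    s2e = rate / R::rgamma(shape, 1.0);

    if (!freeze_psi) {
      // --- psi_j | w_j, delta_j : GIG(a - 1/2, 2 delta_j, n w_j^2 / sigma2) ---
      for (int j = 0; j < m; ++j) {
        double chi = n * w(j) * w(j) / s2e;
        psi(j) = gigrnd(a - 0.5, 2.0 * delta(j), chi);
        if (psi(j) > 1.0) psi(j) = 1.0;
        if (psi(j) < 1e-12) psi(j) = 1e-12;
      }
      // --- delta_j | psi_j ~ Gamma(a + b, rate psi_j + phi) ---
      for (int j = 0; j < m; ++j) {
        delta(j) = R::rgamma(a + b, 1.0 / (psi(j) + phi));
        if (delta(j) < 1e-12) delta(j) = 1e-12;
      }
    }

    if (it >= burnin && ((it - burnin) % thin == 0)) {
      w_sum += w;
      psi_sum += psi;
      ++n_rec;
    }
  }
  return List::create(_["w_mean"] = w_sum / std::max(n_rec, 1),
                      _["psi_mean"] = psi_sum / std::max(n_rec, 1),
                      _["n_recorded"] = n_rec,
                      _["sigma2_eps"] = s2e);
}
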