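// Fast kernels for the univariate animal model y = Xb + Za + e,
// a | s2a ~ N(0, A s2a), flat priors on b and both variances.
//
// The gradient-based samplers work on the unconstrained vector
//   theta = (b, u, log s2a, log s2e),  a = sigma_a L u,  L L' = A,
// the fully non-centered parameterization: the prior on u is N(0, I)
// (no coupling with sigma2_a, which removes the funnel geometry), and the
// log-Jacobian of the log-variance transform contributes
// +log s2a + log s2e.
//
// Products with L and L' use the pedigree decomposition A = T D T'
// (L = T D^{1/2}; T^{-1} = I - half the parent incidences), so both are
// O(q) recurrences over the pedigree instead of dense O(q^2) products.
// A dense fallback covers relationship factors supplied as raw matrices.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct AMCtx {
  arma::vec y;        // n phenotypes
  arma::mat X;        // n x p fixed-effect incidence
  arma::uvec zidx;    // record -> animal (0-based), one entry per record
  int n, p, q;
  bool has_ped;       // pedigree-structured L available
  arma::ivec sire, dam;   // 0-based parent indices, -1 = unknown
  arma::vec dsqrt;        // sqrt of Mendelian-sampling variance scalers
  arma::mat L;            // dense factor (fallback path)
  std::vector<std::vector<arma::uword>> recs;  // records per animal

  void index_records() {
    recs.assign(q, {});
    for (arma::uword r = 0; r < zidx.n_elem; ++r)
      recs[zidx[r]].push_back(r);
  }

  // v = L u = T D^{1/2} u
  arma::vec Lu(const arma::vec& u) const {
    if (!has_ped) return arma::trimatl(L) * u;
    arma::vec v(q);
    for (int i = 0; i < q; ++i) {
      double acc = dsqrt[i] * u[i];
      if (sire[i] >= 0) acc += 0.5 * v[sire[i]];
      if (dam[i] >= 0) acc += 0.5 * v[dam[i]];
      v[i] = acc;
    }
    return v;
  }

  // y = L' x = D^{1/2} T' x  (reverse accumulation toward parents)
  arma::vec Ltx(const arma::vec& x) const {
    if (!has_ped) return arma::trimatl(L).t() * x;
    arma::vec yv = x;
    for (int i = q - 1; i >= 0; --i) {
      if (sire[i] >= 0) yv[sire[i]] += 0.5 * yv[i];
      if (dam[i] >= 0) yv[dam[i]] += 0.5 * yv[i];
    }
    return dsqrt % yv;
  }
};

static AMCtx* ctx_ptr(SEXP xp) {
  Rcpp::XPtr<AMCtx> p(xp);
  return p.get();
}

// Dense-factor context (fallback when no pedigree structure is known).
// [[Rcpp::export]]
SEXP am_ctx_new(const arma::vec& y, const arma::mat& X,
                const arma::uvec& zidx1, const arma::mat& L) {
  AMCtx* c = new AMCtx();
  c->y = y; c->X = X; c->zidx = zidx1 - 1; c->L = L;
  c->n = (int) y.n_elem; c->p = (int) X.n_cols; c->q = (int) L.n_rows;
  c->has_ped = false;
  c->index_records();
  return Rcpp::XPtr<AMCtx>(c, true);
}

// Pedigree-structured context: sire/dam are 1-based (0 = unknown) in the
// topological order of the relationship factor; dsqrt = sqrt(D diagonal).
// [[Rcpp::export]]
SEXP am_ctx_new_ped(const arma::vec& y, const arma::mat& X,
                    const arma::uvec& zidx1, const arma::ivec& sire1,
                    const arma::ivec& dam1, const arma::vec& dsqrt) {
  AMCtx* c = new AMCtx();
  c->y = y; c->X = X; c->zidx = zidx1 - 1;
  c->n = (int) y.n_elem; c->p = (int) X.n_cols; c->q = (int) dsqrt.n_elem;
  c->has_ped = true;
  c->sire = sire1 - 1; c->dam = dam1 - 1;
  c->dsqrt = dsqrt;
  c->index_records();
  return Rcpp::XPtr<AMCtx>(c, true);
}

// [[Rcpp::export]]
Rcpp::List am_ctx_dims(SEXP xp) {
  AMCtx* c = ctx_ptr(xp);
  return List::create(_["n"] = c->n, _["p"] = c->p, _["q"] = c->q,
                      _["has_ped"] = c->has_ped);
}

struct Eval { double lp; arma::vec g; };

// One fused evaluation of the unconstrained log density and its gradient
// (shares the a = sigma_a L u and residual computations).
static Eval eval_theta(const AMCtx* c, const arma::vec& theta,
                       bool want_grad) {
  arma::vec b = theta.subvec(0, c->p - 1);
  arma::vec u = theta.subvec(c->p, c->p + c->q - 1);
  const double lsa = theta[c->p + c->q], lse = theta[c->p + c->q + 1];
  const double s2e = std::exp(lse), sa = std::exp(0.5 * lsa);
  arma::vec a = sa * c->Lu(u);
  arma::vec r = c->y - c->X * b - a.elem(c->zidx);
  const double rss = arma::dot(r, r);
  Eval ev;
  ev.lp = -0.5 * c->n * lse - 0.5 * rss / s2e - 0.5 * arma::dot(u, u)
          + lsa + lse;
  if (want_grad) {
    ev.g.set_size(theta.n_elem);
    ev.g.subvec(0, c->p - 1) = c->X.t() * r / s2e;
    arma::vec ztr(c->q, arma::fill::zeros);
    for (arma::uword k = 0; k < c->zidx.n_elem; ++k) ztr[c->zidx[k]] += r[k];
    ev.g.subvec(c->p, c->p + c->q - 1) = sa * c->Ltx(ztr) / s2e - u;
    ev.g[c->p + c->q] = 0.5 * arma::dot(a.elem(c->zidx), r) / s2e + 1.0;
    ev.g[c->p + c->q + 1] = -0.5 * c->n + 0.5 * rss / s2e + 1.0;
  }
  return ev;
}

// [[Rcpp::export]]
double am_logpost(SEXP xp, const arma::vec& theta) {
  return eval_theta(ctx_ptr(xp), theta, false).lp;
}

// [[Rcpp::export]]
arma::vec am_grad(SEXP xp, const arma::vec& theta) {
  return eval_theta(ctx_ptr(xp), theta, true).g;
}

// [[Rcpp::export]]
Rcpp::List am_lp_grad(SEXP xp, const arma::vec& theta) {
  Eval ev = eval_theta(ctx_ptr(xp), theta, true);
  return List::create(_["lp"] = ev.lp, _["grad"] = ev.g);
}

// One leapfrog step with the gradient carried in: a single fused
// evaluation at the new position. minv is the diagonal of M^{-1}
// (recycled if scalar).
// [[Rcpp::export]]
Rcpp::List am_step(SEXP xp, const arma::vec& theta, const arma::vec& p,
                   double epsilon, const arma::vec& g,
                   const arma::vec& minv) {
  AMCtx* c = ctx_ptr(xp);
  arma::vec ph = p + 0.5 * epsilon * g;
  arma::vec th(theta.n_elem);
  if (minv.n_elem == 1) th = theta + epsilon * minv[0] * ph;
  else th = theta + epsilon * (minv % ph);
  Eval ev = eval_theta(c, th, true);
  arma::vec pn = ph + 0.5 * epsilon * ev.g;
  return List::create(_["theta"] = th, _["p"] = pn, _["grad"] = ev.g,
                      _["lp"] = ev.lp);
}

// Map unconstrained draws (rows of theta_mat) to the constrained scalars
// (b, s2a, s2e, h2) and accumulate the posterior mean of a = sigma_a L u.
// [[Rcpp::export]]
Rcpp::List am_constrain_draws(SEXP xp, const arma::mat& theta_mat) {
  AMCtx* c = ctx_ptr(xp);
  const arma::uword m = theta_mat.n_rows;
  arma::mat b(m, c->p);
  arma::vec s2a(m), s2e(m), h2(m);
  arma::vec su_mean(c->q, arma::fill::zeros);   // mean of sigma_a * u
  for (arma::uword i = 0; i < m; ++i) {
    arma::vec th = theta_mat.row(i).t();
    b.row(i) = th.subvec(0, c->p - 1).t();
    double va = std::exp(th[c->p + c->q]), ve = std::exp(th[c->p + c->q + 1]);
    su_mean += std::sqrt(va) * th.subvec(c->p, c->p + c->q - 1);
    s2a[i] = va; s2e[i] = ve; h2[i] = va / (va + ve);
  }
  su_mean /= (double) m;
  arma::vec a_mean = c->Lu(su_mean);
  return List::create(_["b"] = b, _["sigma2_a"] = s2a, _["sigma2_e"] = s2e,
                      _["h2"] = h2, _["a_mean"] = a_mean);
}

static inline double rinvgamma(double shape, double rate) {
  // density ~ x^{-shape-1} exp(-rate/x)
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// Single-site Gibbs sampler. Update order: b, a, s2a, s2e.
// Uses R's RNG (set.seed on the R side governs reproducibility).
// update_loc / update_var allow freezing blocks so that the conditional
// distributions of the remaining blocks can be checked directly.
// [[Rcpp::export]]
Rcpp::List am_gibbs(SEXP xp, const arma::mat& Ainv,
                    int n_iter, int burn_in,
                    const arma::vec& b0, const arma::vec& a0,
                    double s2a0, double s2e0,
                    bool update_loc, bool update_var,
                    bool store_a) {
  AMCtx* c = ctx_ptr(xp);
  RNGScope scope;
  const int keep = n_iter - burn_in;
  arma::vec b = b0, a = a0;
  double s2a = s2a0, s2e = s2e0;

  arma::vec r = c->y - c->X * b - a.elem(c->zidx);
  arma::vec xtx(c->p);
  for (int j = 0; j < c->p; ++j) xtx[j] = arma::dot(c->X.col(j), c->X.col(j));
  arma::vec ni(c->q);
  for (int i = 0; i < c->q; ++i) ni[i] = (double) c->recs[i].size();

  arma::mat b_out(keep, c->p);
  arma::vec s2a_out(keep), s2e_out(keep), h2_out(keep);
  arma::vec a_mean(c->q, arma::fill::zeros);
  arma::mat a_out;
  if (store_a) a_out.set_size(keep, c->q);

  for (int it = 0; it < n_iter; ++it) {
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
    if (update_loc) {
      for (int j = 0; j < c->p; ++j) {
        double m = arma::dot(c->X.col(j), r) / xtx[j] + b[j];
        double bn = R::rnorm(m, std::sqrt(s2e / xtx[j]));
        r -= c->X.col(j) * (bn - b[j]);
        b[j] = bn;
      }
      for (int i = 0; i < c->q; ++i) {
        double sr = 0.0;
        for (arma::uword k : c->recs[i]) sr += r[k];
        double prec = ni[i] / s2e + Ainv.at(i, i) / s2a;
        double cross = arma::dot(Ainv.col(i), a) - Ainv.at(i, i) * a[i];
        double rhs = (sr + ni[i] * a[i]) / s2e - cross / s2a;
        double an = R::rnorm(rhs / prec, std::sqrt(1.0 / prec));
        double d = a[i] - an;
        for (arma::uword k : c->recs[i]) r[k] += d;
        a[i] = an;
      }
    }
    if (update_var) {
      double S = arma::as_scalar(a.t() * Ainv * a);
      s2a = rinvgamma(0.5 * c->q - 1.0, 0.5 * S);
      double rss = arma::dot(r, r);
      s2e = rinvgamma(0.5 * c->n - 1.0, 0.5 * rss);
    }
    if (it >= burn_in) {
      int k = it - burn_in;
      b_out.row(k) = b.t();
      s2a_out[k] = s2a; s2e_out[k] = s2e;
      h2_out[k] = s2a / (s2a + s2e);
      a_mean += a;
      if (store_a) a_out.row(k) = a.t();
    }
  }
  a_mean /= (double) keep;
  List out = List::create(_["b"] = b_out, _["sigma2_a"] = s2a_out,
                          _["sigma2_e"] = s2e_out, _["h2"] = h2_out,
                          _["a_mean"] = a_mean);
  if (store_a) out["a"] = a_out;
  return out;
}
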