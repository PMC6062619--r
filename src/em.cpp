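#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Accelerated EM for the supervised admixture likelihood with the panel
// held fixed.
// a: per-marker counted-allele counts on the allele scale (dosage for
//    diploid data, dosage/2 for pseudo-haploid), missing markers removed
// P: K x M panel frequencies, already clamped into (0, 1)
// c: alleles observed per marker (2 diploid, 1 pseudo-haploid)
//
// Each iteration is a SQUAREM cycle (two EM steps plus a squared
// extrapolation), safeguarded so the accepted log-likelihood never
// decreases: if the extrapolated point is worse than the second EM step,
// the EM step is taken instead. Zero components stay zero (the boundary
// is absorbing for EM). An extrapolation that leaves the simplex is
// clipped to a tiny positive floor, never to exact zero: landing exactly
// on a face mid-run would absorb the iteration there prematurely. After
// convergence, components below SNAP_TOL (beneath the resolution any
// realistic marker count can support) are reported as exactly zero.
// Convergence: |ll - ll_prev| < tol * |ll_prev| over an accepted cycle.

static const double CLIP_FLOOR = 1e-8;
static const double SNAP_TOL = 1e-7;

struct EmResult {
  arma::vec q;
  double ll;
  int it;
  bool converged;
};

static inline double loglik(const arma::vec& a, const arma::vec& b,
                            const arma::mat& P, const arma::vec& q) {
  const arma::vec f = P.t() * q;
  return arma::dot(a, arma::log(f)) + arma::dot(b, arma::log(1.0 - f));
}

static inline arma::vec em_step(const arma::vec& a, const arma::vec& b,
                                const arma::mat& P, const arma::mat& Pc,
                                double C, const arma::vec& q) {
  const arma::vec f = P.t() * q;
  arma::vec out = q % (P * (a / f) + Pc * (b / (1.0 - f))) / C;
  return out / arma::accu(out);
}

static EmResult em_fit_core(const arma::vec& a, const arma::mat& P, double c,
                            arma::vec q, double tol, int max_iter) {
  const arma::uword M = P.n_cols;
  const double C = c * static_cast<double>(M);
  const arma::vec b = c - a;            // other-allele counts
  const arma::mat Pc = 1.0 - P;

  double ll_prev = loglik(a, b, P, q);
  double ll = ll_prev;
  bool converged = false;
  int it = 0;
  double step_cap = 1.0;                // adaptive extrapolation bound
  for (it = 1; it <= max_iter; ++it) {
    const arma::vec q1 = em_step(a, b, P, Pc, C, q);
    const arma::vec q2 = em_step(a, b, P, Pc, C, q1);
    const arma::vec r = q1 - q;
    const arma::vec v = (q2 - q1) - r;
    const double vn = arma::dot(v, v);
    arma::vec qn;
    double alpha = -1.0;
    if (vn > 0) {
      alpha = -std::sqrt(arma::dot(r, r) / vn);
      if (alpha > -1.0) alpha = -1.0;
      if (alpha < -step_cap) alpha = -step_cap;
      qn = q - 2.0 * alpha * r + (alpha * alpha) * v;
      for (arma::uword k = 0; k < qn.n_elem; ++k) {
        if (q(k) == 0.0) qn(k) = 0.0;                 // boundary stays put
        else if (qn(k) < CLIP_FLOOR) qn(k) = CLIP_FLOOR;
      }
      qn /= arma::accu(qn);
    } else {
      qn = q2;
    }
    double lln = qn.is_finite() ? loglik(a, b, P, qn) : -arma::datum::inf;
    const double ll2 = loglik(a, b, P, q2);
    if (lln >= ll2) {
      if (alpha <= -step_cap) step_cap *= 2.0;        // grow when trusted
    } else {                            // safeguard: never worse than EM
      qn = q2;
      lln = ll2;
      step_cap = 1.0;
    }
    q = qn;
    ll = lln;
    if (std::abs(ll - ll_prev) < tol * std::abs(ll_prev)) {
      converged = true;
      break;
    }
    ll_prev = ll;
  }
  if (it > max_iter) it = max_iter;
  // Boundary resolution. At an interior stationary point every supported
  // component has EM growth factor g_k = 1; a component the flow is still
  // pushing downhill (g_k < 1) while already tiny has its constrained
  // optimum exactly on the boundary (KKT), so report it as exact zero
  // rather than leaving slowly-decaying numerical dust. Components below
  // SNAP_TOL are zeroed unconditionally. The removed mass is < K * 1e-3
  // in the worst case and in practice orders of magnitude smaller; the
  // survivors are renormalized and the log-likelihood recomputed.
  {
    const arma::vec f = P.t() * q;
    const arma::vec growth = (P * (a / f) + Pc * ((c - a) / (1.0 - f))) / C;
    bool snapped = false;
    for (arma::uword k = 0; k < q.n_elem; ++k) {
      if (q(k) > 0.0 &&
          (q(k) < SNAP_TOL ||
           (q(k) < 1e-3 && growth(k) < 1.0 - 1e-6))) {
        q(k) = 0.0;
        snapped = true;
      }
    }
    if (snapped) {
      q /= arma::accu(q);
      ll = loglik(a, b, P, q);
    }
  }
  return EmResult{q, ll, it, converged};
}

// [[Rcpp::export(name = ".em_fit_cpp")]]
List em_fit_cpp(const arma::vec& a, const arma::mat& P, double c,
                arma::vec q, double tol, int max_iter) {
  EmResult r = em_fit_core(a, P, c, q, tol, max_iter);
  return List::create(_["q"] = r.q, _["log_likelihood"] = r.ll,
                      _["n_iterations"] = r.it, _["converged"] = r.converged);
}

// Marker-bootstrap refits. a and P cover the full aligned marker set in
// original column order (P clamped; missing markers carry a = 0); `keep`
// flags non-missing markers; idx is an M x B matrix of 0-based resampled
// column indices. Each replicate keeps the non-missing part of its
// resample and refits from q_start. Returns a B x K matrix.
// [[Rcpp::export(name = ".em_bootstrap_cpp")]]
arma::mat em_bootstrap_cpp(const arma::vec& a, const arma::mat& P, double c,
                           const arma::uvec& keep, const arma::umat& idx,
                           const arma::vec& q_start, double tol, int max_iter) {
  const arma::uword B = idx.n_cols;
  const arma::uword K = P.n_rows;
  arma::mat out(B, K);
  for (arma::uword r = 0; r < B; ++r) {
    const arma::uvec col = idx.col(r);
    const arma::uvec sub = col.elem(arma::find(keep.elem(col) == 1));
    EmResult res = em_fit_core(a.elem(sub), P.cols(sub), c, q_start,
                               tol, max_iter);
    out.row(r) = res.q.t();
  }
  return out;
}
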