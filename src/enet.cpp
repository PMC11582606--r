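// Coordinate-descent elastic net on standardized data.
//
// Solves, for each lambda in a decreasing sequence (warm starts),
//   min_b (1/2n) * ||y - X b||^2 + lambda * (alpha*||b||_1 + (1-alpha)/2*||b||_2^2)
// X must arrive with centered columns of unit (population) variance and y centered,
// so the intercept drops out and each coordinate update is closed-form.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// One full sweep over the given index set; returns max |coef change|.
static double cd_sweep(const arma::mat& X, arma::vec& r, arma::vec& b,
                       const arma::uvec& idx, double n, double lam_l1,
                       double denom) {
  double maxdel = 0.0;
  for (arma::uword k = 0; k < idx.n_elem; ++k) {
    arma::uword j = idx[k];
    double bj = b[j];
    double rho = arma::dot(X.col(j), r) / n + bj;
    double bnew = soft_threshold(rho, lam_l1) / denom;
    if (bnew != bj) {
      r -= X.col(j) * (bnew - bj);
      b[j] = bnew;
      double d = std::abs(bnew - bj);
      if (d > maxdel) maxdel = d;
    }
  }
  return maxdel;
}

// [[Rcpp::export]]
List cd_enet_path(const arma::mat& X, const arma::vec& y, double alpha,
                  const arma::vec& lambda, double tol = 1e-7,
                  int max_sweeps = 100000) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  const double dn = static_cast<double>(n);
  arma::mat beta(p, lambda.n_elem, arma::fill::zeros);
  arma::vec b(p, arma::fill::zeros);
  arma::vec r = y;
  arma::uvec all = arma::regspace<arma::uvec>(0, p > 0 ? p - 1 : 0);
  IntegerVector sweeps(lambda.n_elem);
  LogicalVector converged(lambda.n_elem);

  for (arma::uword l = 0; l < lambda.n_elem; ++l) {
    double lam = lambda[l];
    double lam_l1 = lam * alpha;
    double denom = 1.0 + lam * (1.0 - alpha);
    int used = 0;
    bool ok = false;
    if (p > 0) {
      // Alternate: converge on the current active set, then one full sweep to
      // pick up KKT violations; done when the full sweep itself moves nothing.
      while (used < max_sweeps) {
        arma::uvec act = arma::find(b != 0.0);
        if (act.n_elem > 0) {
          while (used < max_sweeps) {
            double d = cd_sweep(X, r, b, act, dn, lam_l1, denom);
            ++used;
            if (d < tol) break;
          }
        }
        double dfull = cd_sweep(X, r, b, all, dn, lam_l1, denom);
        ++used;
        if (dfull < tol) { ok = true; break; }
      }
    } else {
      ok = true;
    }
    beta.col(l) = b;
    sweeps[l] = used;
    converged[l] = ok;
  }
  return List::create(_["beta"] = beta, _["sweeps"] = sweeps,
                      _["converged"] = converged);
}

// FNV-1a 64-bit hash of a raw vector, as a hex string (used for run manifests).
// [[Rcpp::export]]
std::string fnv1a64(const RawVector& bytes) {
  uint64_t h = 14695981039346656037ULL;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    h ^= static_cast<uint64_t>(bytes[i]);
    h *= 1099511628211ULL;
  }
  char buf[17];
  std::snprintf(buf, sizeof(buf), "%016llx", static_cast<unsigned long long>(h));
  return std::string(buf);
}
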