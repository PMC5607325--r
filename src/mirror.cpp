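#include <Rcpp.h>
using namespace Rcpp;

// Reflective (mirror) random walk over the polytope {q : A q >= b} in the
// null-space parameterisation of the equality constraints. Each step draws
// an isotropic Gaussian displacement and folds it across every constraint
// hyperplane met along the way, so hyperplanes act as mirrors and the
// stationary distribution is uniform over the polytope. Uses R's RNG, so
// chains are reproducible under set.seed().
//
// A: m x k constraint matrix (rows a_i), b: length m, q0: strictly
// feasible start. Returns n_keep x k matrix of the post-burn-in states.
// [[Rcpp::export]]
NumericMatrix mirror_walk_cpp(const NumericMatrix& A,
                              const NumericVector& b,
                              const NumericVector& q0,
                              double jump, int n_iter, int burn_in,
                              int max_reflect = 100000) {
  const int m = A.nrow(), k = A.ncol();
  NumericMatrix out(n_iter, k);
  std::vector<double> q(q0.begin(), q0.end());
  std::vector<double> qn(k), eta(k), resid(m), aeta(m);
  std::vector<double> arow2(m);  // squared row norms
  for (int i = 0; i < m; ++i) {
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += A(i, j) * A(i, j);
    arow2[i] = s;
  }
  GetRNGstate();
  const int total = n_iter + burn_in;
  for (int it = 0; it < total; ++it) {
    for (int j = 0; j < k; ++j) {
      eta[j] = jump * norm_rand();
      qn[j] = q[j];
    }
    // current slack per constraint
    for (int i = 0; i < m; ++i) {
      double s = 0.0;
      for (int j = 0; j < k; ++j) s += A(i, j) * qn[j];
      resid[i] = s - b[i];            // >= 0 when feasible
    }
    bool ok = true;
    int nref = 0;
    double remaining = 1.0;           // fraction of the step still to take
    while (remaining > 1e-14) {
      // A * eta for the current direction
      double tmin = 1.0;
      int hit = -1;
      for (int i = 0; i < m; ++i) {
        double s = 0.0;
        for (int j = 0; j < k; ++j) s += A(i, j) * eta[j];
        aeta[i] = s;
        if (s < 0.0) {
          double t = -resid[i] / s;   // crossing time along eta in [0, 1]
          if (t < tmin) { tmin = t; hit = i; }
        }
      }
      if (tmin < 0.0) tmin = 0.0;
      for (int j = 0; j < k; ++j) qn[j] += tmin * eta[j];
      for (int i = 0; i < m; ++i) resid[i] += tmin * aeta[i];
      if (hit < 0) break;             // full step completed inside
      // reflect the unused part of the displacement across hyperplane hit
      double frac = 1.0 - tmin;
      double dot = aeta[hit];
      resid[hit] = 0.0;               // exactly on the mirror
      for (int j = 0; j < k; ++j) {
        double e = frac * eta[j];
        eta[j] = e - 2.0 * (frac * dot) / arow2[hit] * A(hit, j);
      }
      remaining *= frac;
      if (++nref > max_reflect) { ok = false; break; }
    }
    if (ok) {
      // guard against accumulated rounding: reject moves that end outside
      double worst = 0.0;
      for (int i = 0; i < m; ++i) if (resid[i] < worst) worst = resid[i];
      if (worst < -1e-10) ok = false;
    }
    if (ok) {
      for (int j = 0; j < k; ++j) q[j] = qn[j];
    }
    if (it >= burn_in) {
      for (int j = 0; j < k; ++j) out(it - burn_in, j) = q[j];
    }
    if ((it & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();
  return out;
}
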