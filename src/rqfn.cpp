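#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Frisch-Newton primal-dual interior point solver for linear conditional
// quantile regression.  The pinball-loss problem
//
//     min_b sum_i rho_tau(y_i - x_i' b)
//
// is solved through its bounded-variables LP dual
//
//     max_a y'a   s.t.  X'a = (1 - tau) X'1,   0 <= a <= 1,
//
// written below in minimisation form (c = -y).  The multipliers of the
// equality constraints, negated, are the regression coefficients.  A
// Mehrotra predictor-corrector step is used; the start point
// a = (1 - tau) 1 is primal feasible by construction and the dual start is
// made feasible explicitly, so primal and dual residuals stay at zero and
// only the complementarity gap is driven down.

static double step_len(const vec& v, const vec& dv) {
  // largest alpha in (0, 1] keeping v + alpha * dv strictly positive
  double a = 1.0;
  for (uword i = 0; i < v.n_elem; ++i) {
    if (dv[i] < 0.0) {
      double cand = -v[i] / dv[i];
      if (cand < a) a = cand;
    }
  }
  return a;
}

// [[Rcpp::export]]
Rcpp::List rqfn_cpp(const arma::mat& X, const arma::vec& y, double tau,
                    double eps = 1e-10, int max_it = 200) {
  const uword n = X.n_rows;
  const uword p = X.n_cols;
  const double big = 0.99995;  // fraction-to-boundary

  mat A = X.t();               // p x n
  vec c = -y;                  // minimise c'a  <=> maximise y'a

  // primal LP variables: a in [0,1]^n with slack s = 1 - a
  vec a(n, fill::value(1.0 - tau));
  vec s(n, fill::value(tau));

  // dual start: d free, z, w > 0 with A'd + z - w = c
  mat AAt = A * A.t();
  vec d = solve(AAt, A * c, solve_opts::likely_sympd);
  vec r = c - A.t() * d;
  double shift = 1e-4 * std::max(1.0, norm(r, "inf"));
  vec z = clamp(r, 0.0, datum::inf) + shift;
  vec w = z - r;               // = (-r)_+ + shift > 0

  double gap = dot(z, a) + dot(w, s);
  const double denom = std::max(1.0, std::abs(dot(y, y)) > 0 ? norm(y, 2) : 1.0);
  int it = 0;
  bool converged = false;

  vec q(n), g(n), rhs(p), dd(p), da(n), dz(n), dw(n), ds(n);

  while (it < max_it) {
    if (gap < eps * denom * n || gap < eps) { converged = true; break; }
    ++it;

    q = z / a + w / s;                       // diagonal of Q
    vec qinv = 1.0 / q;

    // ---- affine (predictor) direction: mu = 0
    g = w - z;
    mat AQ = A.each_row() % qinv.t();        // p x n
    mat M = AQ * A.t();                      // A Q^{-1} A'
    rhs = -(AQ * g);
    // near the solution M becomes numerically singular; stop cleanly then
    bool ok = solve(dd, M, rhs, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) { converged = gap < 1e-6 * std::max(1.0, denom); break; }
    da = qinv % (A.t() * dd + g);
    ds = -da;
    dz = -z - (z / a) % da;
    dw = -w + (w / s) % da;

    double ap = big * std::min(step_len(a, da), step_len(s, ds));
    double ad = big * std::min(step_len(z, dz), step_len(w, dw));
    ap = std::min(ap, 1.0); ad = std::min(ad, 1.0);

    double gap_aff = dot(z + ad * dz, a + ap * da) + dot(w + ad * dw, s + ap * ds);
    double sigma = std::pow(gap_aff / gap, 3.0);
    double mu = sigma * gap / (2.0 * n);

    // ---- corrector: include mu and second-order terms
    vec corr_a = (mu - da % dz) / a;
    vec corr_s = (mu - ds % dw) / s;
    g = corr_a - corr_s - z + w;
    rhs = -(AQ * g);
    ok = solve(dd, M, rhs, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) { converged = gap < 1e-6 * std::max(1.0, denom); break; }
    da = qinv % (A.t() * dd + g);
    ds = -da;
    dz = corr_a - z - (z / a) % da;
    dw = corr_s - w + (w / s) % da;

    ap = big * std::min(step_len(a, da), step_len(s, ds));
    ad = big * std::min(step_len(z, dz), step_len(w, dw));
    ap = std::min(ap, 1.0); ad = std::min(ad, 1.0);

    a += ap * da;  s += ap * ds;
    d += ad * dd;  z += ad * dz;  w += ad * dw;

    gap = dot(z, a) + dot(w, s);
  }

  vec coef = -d;                 // regression coefficients
  vec resid = y - X * coef;

  return Rcpp::List::create(
    Rcpp::Named("coefficients") = coef,
    Rcpp::Named("residuals") = resid,
    Rcpp::Named("dual") = a,
    Rcpp::Named("gap") = gap,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged);
}
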