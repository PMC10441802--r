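#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Euclidean projection of a vector onto the probability simplex
// (sort-based algorithm; O(K log K) per row).
static void project_row_simplex(rowvec &v) {
  const uword K = v.n_elem;
  rowvec u = sort(v, "descend");
  double css = 0.0, theta = 0.0;
  for (uword j = 0; j < K; ++j) {
    css += u(j);
    double t = (css - 1.0) / double(j + 1);
    if (u(j) - t > 0.0) theta = t;
  }
  for (uword j = 0; j < K; ++j) v(j) = std::max(v(j) - theta, 0.0);
}

// Regularised symmetric factorisation objective on the off-diagonal of C:
//   f(A) = sum_{i != j} (C_ij - (A A')_ij)^2 + lambda * ||A||_F^2
// M is overwritten with A A' - C, diagonal zeroed.
static double ssmf_objective(const mat &A, const mat &C, double lambda,
                             mat &M) {
  M = A * A.t();
  M -= C;
  M.diag().zeros();
  const double *m = M.memptr();
  double f = 0.0;
  for (uword i = 0; i < M.n_elem; ++i) f += m[i] * m[i];
  const double *a = A.memptr();
  double pen = 0.0;
  for (uword i = 0; i < A.n_elem; ++i) pen += a[i] * a[i];
  return f + lambda * pen;
}

// Projected gradient descent with backtracking line search from a single
// initialisation. Rows of A stay on the probability simplex throughout.
// [[Rcpp::export(name = ".ssmf_pgd")]]
Rcpp::List ssmf_pgd(const arma::mat &C, const arma::mat &A0, int max_iter,
                    double tol, double lambda) {
  mat A = A0;
  const uword N = C.n_rows;
  mat M(N, N);
  double f = ssmf_objective(A, C, lambda, M);
  std::vector<double> trace;
  trace.reserve(256);
  trace.push_back(f);
  double step = 1.0 / double(N); // scale-aware initial step
  bool converged = false;

  for (int it = 0; it < max_iter; ++it) {
    // gradient of the off-diagonal objective: 4 * M_offdiag * A + 2*lambda*A
    mat G = 4.0 * (M * A) + 2.0 * lambda * A;
    double fnew = f;
    mat Anew;
    bool accepted = false;
    for (int ls = 0; ls < 40; ++ls) {
      Anew = A - step * G;
      for (uword i = 0; i < Anew.n_rows; ++i) {
        rowvec r = Anew.row(i);
        project_row_simplex(r);
        Anew.row(i) = r;
      }
      fnew = ssmf_objective(Anew, C, lambda, M);
      if (fnew <= f) { accepted = true; break; }
      step *= 0.5;
    }
    if (!accepted) { // no decrease found at machine-small steps
      ssmf_objective(A, C, lambda, M);
      break;
    }
    double drop = f - fnew;
    A = std::move(Anew);
    f = fnew;
    trace.push_back(f);
    step *= 1.5; // tentative growth; line search shrinks as needed
    if (drop <= tol * std::max(1.0, std::abs(f))) { converged = true; break; }
  }

  return Rcpp::List::create(Rcpp::Named("A") = A, Rcpp::Named("objective") = f,
                            Rcpp::Named("trace") = trace,
                            Rcpp::Named("converged") = converged);
}

// Damped affinity-propagation message passing on a similarity matrix S
// (negative squared distances with preference on the diagonal). All
// updates are fused in-place column scans to stay memory-light. Returns
// exemplar indices (1-based) and per-point exemplar assignment.
// [[Rcpp::export(name = ".ap_messages")]]
Rcpp::List ap_messages(const arma::mat &S, double damping, int max_iter,
                       int conv_iter) {
  const uword N = S.n_rows;
  mat R(N, N, fill::zeros), A(N, N, fill::zeros);
  vec m1(N), m2(N);
  uvec k1(N);
  uvec ex_old;
  int stable = 0, it = 0;
  const double keep = damping, mix = 1.0 - damping;

  for (it = 0; it < max_iter; ++it) {
    // per-row top-2 of A + S, scanned by column
    m1.fill(-datum::inf);
    m2.fill(-datum::inf);
    for (uword k = 0; k < N; ++k) {
      const double *ac = A.colptr(k), *sc = S.colptr(k);
      for (uword i = 0; i < N; ++i) {
        double v = ac[i] + sc[i];
        if (v > m1(i)) { m2(i) = m1(i); m1(i) = v; k1(i) = k; }
        else if (v > m2(i)) m2(i) = v;
      }
    }
    // responsibilities, damped in place
    for (uword k = 0; k < N; ++k) {
      double *rc = R.colptr(k);
      const double *sc = S.colptr(k);
      for (uword i = 0; i < N; ++i) {
        double rnew = sc[i] - (k1(i) == k ? m2(i) : m1(i));
        rc[i] = keep * rc[i] + mix * rnew;
      }
    }
    // availabilities, damped in place
    for (uword k = 0; k < N; ++k) {
      const double *rc = R.colptr(k);
      double cs = 0.0;
      for (uword i = 0; i < N; ++i)
        if (i != k && rc[i] > 0.0) cs += rc[i];
      double rkk = rc[k];
      double *acol = A.colptr(k);
      for (uword i = 0; i < N; ++i) {
        double anew;
        if (i == k) anew = cs;
        else {
          double rp = rc[i] > 0.0 ? rc[i] : 0.0;
          anew = rkk + cs - rp;
          if (anew > 0.0) anew = 0.0;
        }
        acol[i] = keep * acol[i] + mix * anew;
      }
    }

    uvec ex = find((A.diag() + R.diag()) > 0);
    if (ex.n_elem > 0 && ex.n_elem == ex_old.n_elem && all(ex == ex_old))
      ++stable;
    else
      stable = 0;
    ex_old = ex;
    if (stable >= conv_iter) break;
  }

  uvec ex = find((A.diag() + R.diag()) > 0);
  if (ex.n_elem == 0) ex = uvec{ (A.diag() + R.diag()).index_max() };
  // assign every point to its best exemplar; exemplars to themselves
  uvec assign(N);
  for (uword i = 0; i < N; ++i) {
    double best = -datum::inf;
    uword bk = 0;
    for (uword e = 0; e < ex.n_elem; ++e)
      if (S(i, ex(e)) > best) { best = S(i, ex(e)); bk = e; }
    assign(i) = bk + 1;
  }
  for (uword e = 0; e < ex.n_elem; ++e) assign(ex(e)) = e + 1;

  return Rcpp::List::create(Rcpp::Named("exemplars") = ex + 1,
                            Rcpp::Named("assignment") = assign,
                            Rcpp::Named("iterations") = it + 1);
}
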