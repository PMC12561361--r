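#include <Rcpp.h>
using namespace Rcpp;

// Sequence-alignment dynamic programs.
//
// Conventions: the cost matrix delta has m rows (reference sequence y) and n
// columns (query/prediction z); delta(i,j) = ||y_i - z_j||^2.  Admissible
// alignment paths run from (1,1) to (m,n) with steps (1,0), (0,1), (1,1).

static inline double sq(double x) { return x * x; }

// exp with an underflow cutoff: alignment weights use arguments <= 0, and
// anything below -37 is < 1e-16 of the leading term, i.e. exactly 0 at
// double precision after the max-shift.  Skipping the libm call makes the
// near-hard regime (gamma ~ 1e-3 against O(1) costs) several-fold faster.
static inline double exp0(double x) { return x < -37.0 ? 0.0 : std::exp(x); }
// log with the same shortcut: in the near-hard regime the softmin weight sum
// is exactly 1 for most cells.
static inline double log1(double s) { return s == 1.0 ? 0.0 : std::log(s); }

// [[Rcpp::export]]
NumericMatrix cpp_pairwise_cost(NumericMatrix y, NumericMatrix z) {
  const int m = y.nrow(), n = z.nrow(), d = y.ncol();
  NumericMatrix out(m, n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < m; ++i) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) s += sq(y(i, k) - z(j, k));
      out(i, j) = s;
    }
  return out;
}

// Hard DTW over an explicit cost matrix, optionally restricted to a window
// (allowed cells).  Backtracking prefers diagonal, then vertical (i-1,j),
// then horizontal (i,j-1) so paths are deterministic under ties.
// [[Rcpp::export]]
List cpp_dtw(NumericMatrix delta, Nullable<LogicalMatrix> allowed_ = R_NilValue) {
  const int m = delta.nrow(), n = delta.ncol();
  const double inf = R_PosInf;
  LogicalMatrix allowed;
  bool masked = allowed_.isNotNull();
  if (masked) allowed = LogicalMatrix(allowed_);

  NumericMatrix g(m + 1, n + 1);
  for (int i = 0; i <= m; ++i)
    for (int j = 0; j <= n; ++j) g(i, j) = inf;
  g(0, 0) = 0.0;

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      if (masked && !allowed(i - 1, j - 1)) continue;
      double best = g(i - 1, j - 1);
      if (g(i - 1, j) < best) best = g(i - 1, j);
      if (g(i, j - 1) < best) best = g(i, j - 1);
      if (best < inf) g(i, j) = delta(i - 1, j - 1) + best;
    }
  }
  if (!R_FINITE(g(m, n))) stop("no admissible alignment path within the window");

  // Backtrack.
  std::vector<int> pi, pj;
  int i = m, j = n;
  pi.push_back(i); pj.push_back(j);
  while (i > 1 || j > 1) {
    double diag = (i > 1 && j > 1) ? g(i - 1, j - 1) : inf;
    double vert = (i > 1) ? g(i - 1, j) : inf;
    double horz = (j > 1) ? g(i, j - 1) : inf;
    double best = std::min(diag, std::min(vert, horz));
    if (diag <= best) { --i; --j; }
    else if (vert <= best) { --i; }
    else { --j; }
    pi.push_back(i); pj.push_back(j);
  }
  const int L = (int) pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {  // reverse so path starts at (1,1)
    path(k, 0) = pi[L - 1 - k];
    path(k, 1) = pj[L - 1 - k];
  }
  return List::create(_["distance"] = g(m, n), _["path"] = path);
}

static inline double softmin3(double a, double b, double c, double gamma) {
  double mn = std::min(a, std::min(b, c));
  if (!R_FINITE(mn)) return mn;  // all +Inf
  double s = exp0(-(a - mn) / gamma) + exp0(-(b - mn) / gamma) +
             exp0(-(c - mn) / gamma);
  return mn - gamma * log1(s);
}

// Soft-DTW forward pass.  Returns the loss value and the padded cumulative
// matrix R ((m+2) x (n+2), 0-based pad) needed by the backward pass.
// [[Rcpp::export]]
List cpp_softdtw(NumericMatrix delta, double gamma) {
  const int m = delta.nrow(), n = delta.ncol();
  NumericMatrix R(m + 2, n + 2);
  const double inf = R_PosInf;
  for (int i = 0; i < m + 2; ++i)
    for (int j = 0; j < n + 2; ++j) R(i, j) = inf;
  R(0, 0) = 0.0;
  for (int j = 1; j <= n; ++j)      // column-major walk: contiguous access
    for (int i = 1; i <= m; ++i)
      R(i, j) = delta(i - 1, j - 1) +
                softmin3(R(i - 1, j - 1), R(i - 1, j), R(i, j - 1), gamma);
  return List::create(_["value"] = R(m, n), _["R"] = R);
}

// Soft-DTW backward pass: E = d softDTW / d delta, the Gibbs-expected
// alignment matrix (relaxed optimal path), entries in [0,1].
// [[Rcpp::export]]
NumericMatrix cpp_softdtw_grad(NumericMatrix delta, NumericMatrix R, double gamma) {
  const int m = delta.nrow(), n = delta.ncol();
  const double ninf = R_NegInf;
  // Pad costs with a zero rim and rewrite R's rim for the reverse recursion.
  NumericMatrix D(m + 2, n + 2), E(m + 2, n + 2);
  for (int i = 1; i <= m; ++i)
    for (int j = 1; j <= n; ++j) D(i, j) = delta(i - 1, j - 1);
  for (int i = 0; i <= m + 1; ++i) R(i, n + 1) = ninf;
  for (int j = 0; j <= n + 1; ++j) R(m + 1, j) = ninf;
  R(m + 1, n + 1) = R(m, n);
  E(m + 1, n + 1) = 1.0;
  for (int j = n; j >= 1; --j) {
    for (int i = m; i >= 1; --i) {
      double a = exp0((R(i + 1, j) - R(i, j) - D(i + 1, j)) / gamma);
      double b = exp0((R(i, j + 1) - R(i, j) - D(i, j + 1)) / gamma);
      double c = exp0((R(i + 1, j + 1) - R(i, j) - D(i + 1, j + 1)) / gamma);
      E(i, j) = a * E(i + 1, j) + b * E(i, j + 1) + c * E(i + 1, j + 1);
    }
  }
  NumericMatrix out(m, n);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) out(i, j) = E(i + 1, j + 1);
  return out;
}

// Directional derivative of the relaxed path E(delta) along Z, i.e. the
// Hessian-vector product (d^2 softDTW / d delta^2) %*% Z obtained by
// forward-mode differentiation through both soft-DTW recursions.  This is
// the gradient of <E, Z> with respect to delta (the Hessian is symmetric),
// which is what the soft-TDI term needs with Z = Omega.
// [[Rcpp::export]]
NumericMatrix cpp_softdtw_hvp(NumericMatrix delta, NumericMatrix Z, double gamma) {
  const int m = delta.nrow(), n = delta.ncol();
  const double inf = R_PosInf, ninf = R_NegInf;
  NumericMatrix R(m + 2, n + 2), Rd(m + 2, n + 2);
  for (int i = 0; i < m + 2; ++i)
    for (int j = 0; j < n + 2; ++j) { R(i, j) = inf; Rd(i, j) = 0.0; }
  R(0, 0) = 0.0;
  for (int j = 1; j <= n; ++j) {    // column-major walk
    for (int i = 1; i <= m; ++i) {
      double r1 = R(i - 1, j - 1), r2 = R(i - 1, j), r3 = R(i, j - 1);
      double mn = std::min(r1, std::min(r2, r3));
      double e1 = exp0(-(r1 - mn) / gamma);
      double e2 = exp0(-(r2 - mn) / gamma);
      double e3 = exp0(-(r3 - mn) / gamma);
      double S = e1 + e2 + e3;
      R(i, j) = delta(i - 1, j - 1) + mn - gamma * log1(S);
      double md = (e1 * Rd(i - 1, j - 1) + e2 * Rd(i - 1, j) + e3 * Rd(i, j - 1)) / S;
      Rd(i, j) = Z(i - 1, j - 1) + md;
    }
  }
  NumericMatrix D(m + 2, n + 2), Zp(m + 2, n + 2), E(m + 2, n + 2), Ed(m + 2, n + 2);
  for (int i = 1; i <= m; ++i)
    for (int j = 1; j <= n; ++j) {
      D(i, j) = delta(i - 1, j - 1);
      Zp(i, j) = Z(i - 1, j - 1);
    }
  for (int i = 0; i <= m + 1; ++i) R(i, n + 1) = ninf;
  for (int j = 0; j <= n + 1; ++j) R(m + 1, j) = ninf;
  R(m + 1, n + 1) = R(m, n);
  Rd(m + 1, n + 1) = Rd(m, n);
  E(m + 1, n + 1) = 1.0;
  Ed(m + 1, n + 1) = 0.0;
  for (int j = n; j >= 1; --j) {
    for (int i = m; i >= 1; --i) {
      double a = exp0((R(i + 1, j) - R(i, j) - D(i + 1, j)) / gamma);
      double b = exp0((R(i, j + 1) - R(i, j) - D(i, j + 1)) / gamma);
      double c = exp0((R(i + 1, j + 1) - R(i, j) - D(i + 1, j + 1)) / gamma);
      double ad = a * (Rd(i + 1, j) - Rd(i, j) - Zp(i + 1, j)) / gamma;
      double bd = b * (Rd(i, j + 1) - Rd(i, j) - Zp(i, j + 1)) / gamma;
      double cd = c * (Rd(i + 1, j + 1) - Rd(i, j) - Zp(i + 1, j + 1)) / gamma;
      E(i, j) = a * E(i + 1, j) + b * E(i, j + 1) + c * E(i + 1, j + 1);
      Ed(i, j) = ad * E(i + 1, j) + a * Ed(i + 1, j) +
                 bd * E(i, j + 1) + b * Ed(i, j + 1) +
                 cd * E(i + 1, j + 1) + c * Ed(i + 1, j + 1);
    }
  }
  NumericMatrix out(m, n);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) out(i, j) = Ed(i + 1, j + 1);
  return out;
}

// Full DILATE evaluation: loss (and optionally its gradient with respect to
// the prediction z) for reference y (m x d) and prediction z (n x d).
// [[Rcpp::export]]
List cpp_dilate(NumericMatrix y, NumericMatrix z, double alpha, double gamma,
                bool normalize, bool want_grad) {
  const int m = y.nrow(), n = z.nrow(), d = y.ncol();
  NumericMatrix delta = cpp_pairwise_cost(y, z);
  List fw = cpp_softdtw(delta, gamma);
  double shape = as<double>(fw["value"]);
  NumericMatrix R = fw["R"];
  NumericMatrix E = cpp_softdtw_grad(delta, R, gamma);
  NumericMatrix omega(m, n);
  double scale = normalize ? 1.0 / ((double) m * (double) n) : 1.0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) omega(i, j) = sq((double) (i - j)) * scale;
  double tloss = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) tloss += E(i, j) * omega(i, j);
  double loss = alpha * shape + (1.0 - alpha) * tloss;
  List out = List::create(_["loss"] = loss, _["shape"] = shape,
                          _["time"] = tloss, _["path"] = E);
  if (want_grad) {
    NumericMatrix HZ = cpp_softdtw_hvp(delta, omega, gamma);
    // G = d loss / d delta, then chain through delta(i,j) = ||y_i - z_j||^2.
    NumericMatrix grad(n, d);
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < m; ++i) {
        double g = alpha * E(i, j) + (1.0 - alpha) * HZ(i, j);
        for (int k = 0; k < d; ++k)
          grad(j, k) += 2.0 * g * (z(j, k) - y(i, k));
      }
    }
    out["grad"] = grad;
  }
  return out;
}
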