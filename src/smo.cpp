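#include <Rcpp.h>
using namespace Rcpp;

// Soft-margin SVM dual solver: sequential minimal optimization with
// maximal-violating-pair working-set selection. Each iteration picks the
// pair (i, j) that most violates the KKT conditions, optimizes the two
// dual variables jointly in closed form (with endpoint evaluation when
// the pair's curvature vanishes, e.g. duplicated points), and updates
// the dual gradient in O(n). Convergence: m(a) - M(a) < tol, the
// standard KKT gap. Ties in the pair selection are broken uniformly at
// random through R's RNG, so a set.seed() in calling R code makes
// training deterministic.

// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix X, NumericVector y, double gamma,
               double C, double tol, int max_passes) {
  const int n = X.nrow(), d = X.ncol();
  if (n < 1) stop("empty training set");
  RNGScope rngscope;

  // kernel matrix (K(x,x) = 1 for the RBF)
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double d2 = 0.0;
      for (int k = 0; k < d; ++k) {
        double df = X(i, k) - X(j, k);
        d2 += df * df;
      }
      double v = std::exp(-gamma * d2);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }

  std::vector<double> alpha(n, 0.0);
  // grad_i = y_i * f_nob(x_i) - 1 (gradient of the minimization dual)
  std::vector<double> grad(n, -1.0);

  const long max_iter = (long)max_passes * std::max(n, 100);
  long iter = 0;
  double m_up = 0.0, m_low = 0.0;

  auto in_up = [&](int i) {
    return (y[i] > 0 && alpha[i] < C) || (y[i] < 0 && alpha[i] > 0);
  };
  auto in_low = [&](int i) {
    return (y[i] > 0 && alpha[i] > 0) || (y[i] < 0 && alpha[i] < C);
  };

  const double snap = 1e-12 * C; // pull near-bound alphas onto the bound

  // joint closed-form optimization of the pair (i1, i2); returns false
  // when the pair admits no progress
  auto take_step = [&](int i1, int i2) -> bool {
    if (i1 == i2) return false;
    const double *K1 = &K[(size_t)i1 * n], *K2 = &K[(size_t)i2 * n];
    double y1 = y[i1], y2 = y[i2], s = y1 * y2;
    double a1 = alpha[i1], a2 = alpha[i2];
    double L, H;
    if (s < 0) { L = std::max(0.0, a2 - a1); H = std::min(C, C + a2 - a1); }
    else       { L = std::max(0.0, a1 + a2 - C); H = std::min(C, a1 + a2); }
    if (L >= H) return false;

    double eta = K1[i1] + K2[i2] - 2.0 * K1[i2];
    // Platt's update a2 += y2*(E1 - E2)/eta, with E_i = f_nob(x_i) - y_i
    // recovered from the gradient: grad_i = y_i f_nob - 1 => E_i = y_i grad_i
    double delta = y1 * grad[i1] - y2 * grad[i2]; // E1 - E2
    double a2new;
    if (eta > 1e-12) {
      a2new = a2 + y2 * delta / eta;
    } else {
      // zero curvature: the dual is linear along the pair; move to the
      // better endpoint of the feasible segment. The Newton step is
      // y2*delta/eta, so the improving direction for a2 is sign(y2*delta).
      double step_dir = y2 * delta;
      if (step_dir == 0) return false;
      a2new = step_dir > 0 ? H : L;
    }
    if (a2new < L) a2new = L; else if (a2new > H) a2new = H;
    if (std::fabs(a2new - a2) < 1e-14) return false;
    double a1new = a1 + s * (a2 - a2new);
    if (a1new < 0) { a2new += s * a1new; a1new = 0; }
    else if (a1new > C) { a2new += s * (a1new - C); a1new = C; }
    if (a1new < snap) a1new = 0; else if (a1new > C - snap) a1new = C;
    if (a2new < snap) a2new = 0; else if (a2new > C - snap) a2new = C;
    double da1 = a1new - a1, da2 = a2new - a2;
    if (da1 == 0 && da2 == 0) return false;

    alpha[i1] = a1new;
    alpha[i2] = a2new;
    for (int k = 0; k < n; ++k)
      grad[k] += y[k] * (y1 * da1 * K1[k] + y2 * da2 * K2[k]);
    return true;
  };

  while (iter < max_iter) {
    ++iter;
    // maximal violating pair: i = argmax_{I_up} -y g, j = argmin_{I_low} -y g
    int i1 = -1, i2 = -1;
    m_up = -HUGE_VAL; m_low = HUGE_VAL;
    int nup = 0, nlow = 0;
    for (int k = 0; k < n; ++k) {
      double v = -y[k] * grad[k];
      if (in_up(k)) {
        if (v > m_up + 1e-12) { m_up = v; i1 = k; nup = 1; }
        else if (v > m_up - 1e-12) { ++nup; if (unif_rand() * nup < 1.0) i1 = k; }
      }
      if (in_low(k)) {
        if (v < m_low - 1e-12) { m_low = v; i2 = k; nlow = 1; }
        else if (v < m_low + 1e-12) { ++nlow; if (unif_rand() * nlow < 1.0) i2 = k; }
      }
    }
    if (i1 < 0 || i2 < 0 || m_up - m_low < tol) break;

    if (take_step(i1, i2)) continue;
    // the maximal pair is numerically stuck: pair i1 (then i2) with any
    // other violating partner before giving up
    bool moved = false;
    for (int k = 0; k < n && !moved; ++k)
      if (in_low(k) && m_up - (-y[k] * grad[k]) >= tol)
        moved = take_step(i1, k);
    for (int k = 0; k < n && !moved; ++k)
      if (in_up(k) && (-y[k] * grad[k]) - m_low >= tol)
        moved = take_step(k, i2);
    if (!moved) break;
  }

  // bias: average of y_i - f_nob(x_i) over free support vectors; when
  // every alpha sits at a bound, the midpoint of the KKT interval
  double bsum = 0.0;
  int bcount = 0;
  for (int i = 0; i < n; ++i) {
    if (alpha[i] > tol && alpha[i] < C - tol) {
      // y_i - f_nob = -y_i * grad_i  (since grad_i = y_i f_nob - 1)
      bsum += -y[i] * grad[i];
      ++bcount;
    }
  }
  double b = bcount > 0 ? bsum / bcount : 0.5 * (m_up + m_low);

  return List::create(
      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
      _["b"] = b,
      _["passes"] = (double)((iter + n - 1) / std::max(n, 1)),
      _["kkt_gap"] = m_up - m_low);
}
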