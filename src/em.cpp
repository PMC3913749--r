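#include <Rcpp.h>
using namespace Rcpp;

// A1(kappa) = I1(kappa)/I0(kappa), expected resultant length of a von Mises
// sample; computed with exponentially scaled Bessel functions so it is
// stable for arbitrarily large kappa.
static double A1(double k) {
  if (k < 1e-12) return 0.0;
  return R::bessel_i(k, 1.0, 2.0) / R::bessel_i(k, 0.0, 2.0);
}

static const double KAPPA_MAX = 1e4; // cap against degenerate spikes

// Invert A1 by Newton refinement of the standard piecewise seed
// (Fisher 1993); monotone and smooth, so a handful of steps reach 1e-10.
static double A1inv(double Rbar) {
  if (Rbar <= 1e-12) return 0.0;
  if (Rbar >= 1.0 - 1e-12) return KAPPA_MAX;
  double k;
  if (Rbar < 0.53)
    k = 2.0 * Rbar + Rbar * Rbar * Rbar + 5.0 * std::pow(Rbar, 5) / 6.0;
  else if (Rbar < 0.85)
    k = -0.4 + 1.39 * Rbar + 0.43 / (1.0 - Rbar);
  else
    k = 1.0 / (std::pow(Rbar, 3) - 4.0 * Rbar * Rbar + 3.0 * Rbar);
  if (k > KAPPA_MAX) return KAPPA_MAX;
  if (k < 1e-10) k = 1e-10;
  for (int it = 0; it < 50; ++it) {
    double a = A1(k);
    double da = 1.0 - a / k - a * a; // d A1 / d kappa
    if (da <= 0.0) break;
    double step = (a - Rbar) / da;
    k -= step;
    if (k < 1e-10) { k = 1e-10; }
    if (k >= KAPPA_MAX) return KAPPA_MAX;
    if (std::fabs(step) <= 1e-10 * (1.0 + k)) break;
  }
  return k;
}

// [[Rcpp::export(name = ".em_fit_core")]]
List em_fit_core(NumericMatrix dev, NumericMatrix starts,
                 double tol, int max_iter, bool trace) {
  const int n = dev.nrow();
  const int K = dev.ncol();     // 1 target column + m nontarget columns
  const int m = K - 1;
  const int S = starts.nrow();
  const double inv2pi = 1.0 / (2.0 * M_PI);

  std::vector<double> cosd(n * K);
  for (int j = 0; j < K; ++j)
    for (int i = 0; i < n; ++i)
      cosd[j * n + i] = std::cos(dev(i, j));

  double best_ll = R_NegInf;
  int best_s = -1, best_iter = 0;
  bool best_conv = false;
  double best_a = 0, best_b = 0, best_k = 1;
  List traces(trace ? S : 0);

  for (int s = 0; s < S; ++s) {
    double alpha = starts(s, 0), beta = starts(s, 1), kappa = starts(s, 2);
    if (m == 0) beta = 0.0;
    double gamma = 1.0 - alpha - beta;
    double ll_prev = R_NegInf, ll = R_NegInf;
    bool conv = false;
    int iter = 0;
    std::vector<double> tr;
    for (iter = 1; iter <= max_iter; ++iter) {
      double lognorm = std::log(2.0 * M_PI * R::bessel_i(kappa, 0.0, 2.0));
      double sa = 0.0, sb = 0.0, C = 0.0;
      ll = 0.0;
      for (int i = 0; i < n; ++i) {
        // scaled von Mises densities: exp(kappa (cos d - 1) - log(2 pi I0e))
        double pt = alpha * std::exp(kappa * (cosd[i] - 1.0) - lognorm);
        double pu = gamma * inv2pi;
        double denom = pt + pu;
        double pnt[8];
        for (int j = 1; j <= m; ++j) {
          pnt[j - 1] = (beta / m) *
            std::exp(kappa * (cosd[j * n + i] - 1.0) - lognorm);
          denom += pnt[j - 1];
        }
        if (denom <= 0.0 || !R_finite(denom)) { denom = 1e-300; }
        ll += std::log(denom);
        double rt = pt / denom;
        sa += rt;
        C += rt * cosd[i];
        for (int j = 1; j <= m; ++j) {
          double rn = pnt[j - 1] / denom;
          sb += rn;
          C += rn * cosd[j * n + i];
        }
      }
      if (trace) tr.push_back(ll);
      if (R_finite(ll) && ll - ll_prev < tol && iter > 1) {
        conv = true;
        break;
      }
      ll_prev = ll;
      // M-step
      alpha = sa / n;
      beta = (m > 0) ? sb / n : 0.0;
      gamma = 1.0 - alpha - beta;
      if (gamma < 0) gamma = 0;
      // mean direction is fixed at 0, so the kappa update solves
      // A1(kappa) = weighted mean cosine (not the resultant length);
      // a nonpositive mean cosine collapses to the uniform limit
      double w = sa + sb;
      if (w > 1e-12) {
        double mc = C / w;
        if (mc > 1.0) mc = 1.0;
        kappa = A1inv(mc);
      } else {
        kappa = 0.0;
      }
    }
    if (iter > max_iter) iter = max_iter;
    if (trace) traces[s] = wrap(tr);
    if (ll > best_ll) { // strict: ties broken by lowest start index
      best_ll = ll; best_s = s; best_iter = iter; best_conv = conv;
      best_a = alpha; best_b = beta; best_k = kappa;
    }
  }

  List out = List::create(
    _["alpha"] = best_a, _["beta"] = best_b,
    _["gamma"] = 1.0 - best_a - best_b, _["kappa"] = best_k,
    _["log_likelihood"] = best_ll, _["n_iterations"] = best_iter,
    _["converged"] = best_conv, _["start_index"] = best_s + 1,
    _["n_starts"] = S);
  if (trace) out["trace"] = traces;
  return out;
}
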