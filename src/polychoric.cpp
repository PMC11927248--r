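// Polychoric correlation core: bivariate-normal CDF, pairwise two-step
// likelihood estimation, and full-matrix driver. Compiled because the
// parallel-analysis reference distribution re-estimates the full matrix
// hundreds of times.
#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline double phi1(double x) { return R::pnorm(x, 0.0, 1.0, 1, 0); }

// Upper-quadrant probability P(X > dh, Y > dk) for a standard bivariate
// normal with correlation r. Gauss-Legendre adaptation of the
// Drezner-Wesolowsky method (Genz 2004); absolute accuracy ~5e-16 for
// |r| < 0.925 and ~1e-14 near the boundary.
static double bvnu(double dh, double dk, double r) {
  const double twopi = 6.283185307179586;
  if (!std::isfinite(dh) || !std::isfinite(dk)) {
    if (dh == R_PosInf || dk == R_PosInf) return 0.0;
    if (dh == R_NegInf) return (dk == R_NegInf) ? 1.0 : phi1(-dk);
    if (dk == R_NegInf) return phi1(-dh);
  }
  // Gauss-Legendre points/weights on (-1, 1): 6, 12, 20 nodes (half listed)
  static const double x6[3] = {-0.9324695142031522, -0.6612093864662647,
                               -0.2386191860831970};
  static const double w6[3] = {0.1713244923791705, 0.3607615730481384,
                               0.4679139345726904};
  static const double x12[6] = {-0.9815606342467191, -0.9041172563704750,
                                -0.7699026741943050, -0.5873179542866171,
                                -0.3678314989981802, -0.1252334085114692};
  static const double w12[6] = {0.04717533638651177, 0.1069393259953183,
                                0.1600783285433464,  0.2031674267230659,
                                0.2334925365383547,  0.2491470458134029};
  static const double x20[10] = {-0.9931285991850949, -0.9639719272779138,
                                 -0.9122344282513259, -0.8391169718222188,
                                 -0.7463319064601508, -0.6360536807265150,
                                 -0.5108670019508271, -0.3737060887154196,
                                 -0.2277858511416451, -0.07652652113349733};
  static const double w20[10] = {0.01761400713915212, 0.04060142980038694,
                                 0.06267204833410906, 0.08327674157670475,
                                 0.1019301198172404,  0.1181945319615184,
                                 0.1316886384491766,  0.1420961093183821,
                                 0.1491729864726037,  0.1527533871307259};
  const double *xg;
  const double *wg;
  int ng;
  double ar = std::fabs(r);
  if (ar < 0.3)      { xg = x6;  wg = w6;  ng = 3; }
  else if (ar < 0.75) { xg = x12; wg = w12; ng = 6; }
  else               { xg = x20; wg = w20; ng = 10; }

  double h = dh, k = dk, hk = h * k, bvn = 0.0;
  if (ar < 0.925) {
    double hs = (h * h + k * k) / 2.0;
    double asr = std::asin(r);
    for (int i = 0; i < ng; i++) {
      for (int is = -1; is <= 1; is += 2) {
        double sn = std::sin(asr * (is * xg[i] + 1.0) / 2.0);
        bvn += wg[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
      }
    }
    bvn = bvn * asr / (2.0 * twopi) + phi1(-h) * phi1(-k);
  } else {
    if (r < 0) { k = -k; hk = -hk; }
    if (ar < 1.0) {
      double as = (1.0 - r) * (1.0 + r), a = std::sqrt(as);
      double bs = (h - k) * (h - k);
      double c = (4.0 - hk) / 8.0, d = (12.0 - hk) / 16.0;
      double asq = -(bs / as + hk) / 2.0;
      if (asq > -100.0) {
        bvn = a * std::exp(asq) *
              (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
               c * d * as * as / 5.0);
      }
      if (-hk < 100.0) {
        double b = std::sqrt(bs);
        bvn -= std::exp(-hk / 2.0) * std::sqrt(twopi) * phi1(-b / a) * b *
               (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a = a / 2.0;
      for (int i = 0; i < ng; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double xs = a * (is * xg[i] + 1.0);
          xs = xs * xs;
          double rs = std::sqrt(1.0 - xs);
          asq = -(bs / xs + hk) / 2.0;
          if (asq > -100.0) {
            bvn += a * wg[i] * std::exp(asq) *
                   (std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs -
                    (1.0 + c * xs * (1.0 + d * xs)));
          }
        }
      }
      bvn = -bvn / twopi;
    }
    if (r > 0) {
      bvn += phi1(-std::max(h, k));
    } else {
      bvn = -bvn;
      if (k > h) bvn += phi1(k) - phi1(h);
    }
  }
  if (bvn < 0.0) bvn = 0.0;
  if (bvn > 1.0) bvn = 1.0;
  return bvn;
}

// CDF P(X <= h, Y <= k)
static inline double bvn_cdf_d(double h, double k, double r) {
  return bvnu(-h, -k, r);
}

// [[Rcpp::export(name = ".bvn_cdf_cpp")]]
NumericVector bvn_cdf_cpp(NumericVector h, NumericVector k, NumericVector r) {
  int n = h.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = bvn_cdf_d(h[i], k[i], r[i]);
  return out;
}

// Rectangle probabilities for all cells given augmented thresholds
// (-Inf, t_1, ..., t_{c-1}, +Inf).
static void cell_probs(const std::vector<double> &ta,
                       const std::vector<double> &tb, double rho,
                       std::vector<double> &P) {
  int a = (int)ta.size() - 1, b = (int)tb.size() - 1;
  // CDF grid
  std::vector<double> G((a + 1) * (b + 1));
  for (int i = 0; i <= a; i++)
    for (int j = 0; j <= b; j++)
      G[i * (b + 1) + j] = bvn_cdf_d(ta[i], tb[j], rho);
  for (int i = 0; i < a; i++) {
    for (int j = 0; j < b; j++) {
      double p = G[(i + 1) * (b + 1) + (j + 1)] - G[i * (b + 1) + (j + 1)] -
                 G[(i + 1) * (b + 1) + j] + G[i * (b + 1) + j];
      P[i * b + j] = (p > 1e-14) ? p : 1e-14;
    }
  }
}

static double pair_negloglik(const std::vector<double> &tab,
                             const std::vector<double> &ta,
                             const std::vector<double> &tb, double rho) {
  int a = (int)ta.size() - 1, b = (int)tb.size() - 1;
  std::vector<double> P(a * b);
  cell_probs(ta, tb, rho, P);
  double nll = 0.0;
  for (int i = 0; i < a * b; i++)
    if (tab[i] > 0) nll -= tab[i] * std::log(P[i]);
  return nll;
}

// Brent's bounded scalar minimization (localmin), tol ~1e-7 on rho.
static double brent_min(const std::vector<double> &tab,
                        const std::vector<double> &ta,
                        const std::vector<double> &tb, double lo, double hi,
                        double tol) {
  const double gold = 0.3819660112501051;
  double a = lo, b = hi;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = pair_negloglik(tab, ta, tb, x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 100; iter++) {
    double xm = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-10, tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool golden = true;
    if (std::fabs(e) > tol1) {
      double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etemp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etemp) && p > q * (a - x) &&
          p < q * (b - x)) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x) ? tol1 : -tol1;
        golden = false;
      }
    }
    if (golden) {
      e = (x >= xm) ? a - x : b - x;
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d >= 0) ? tol1 : -tol1);
    double fu = pair_negloglik(tab, ta, tb, u);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  return x;
}

// Estimate one pair. tab: a x b contingency counts (row-major as passed),
// ta/tb augmented thresholds. Empty cells get a 0.5 continuity correction.
// Structurally perfect 2x2 tables short-circuit to +/-0.999.
// Returns (rho, asymptotic variance, boundary flag).
// [[Rcpp::export(name = ".polychoric_pair_cpp")]]
NumericVector polychoric_pair_cpp(NumericMatrix table, NumericVector th_row,
                                  NumericVector th_col) {
  int a = table.nrow(), b = table.ncol();
  std::vector<double> ta(a + 1), tb(b + 1);
  ta[0] = R_NegInf; ta[a] = R_PosInf;
  tb[0] = R_NegInf; tb[b] = R_PosInf;
  for (int i = 0; i < a - 1; i++) ta[i + 1] = th_row[i];
  for (int j = 0; j < b - 1; j++) tb[j + 1] = th_col[j];

  bool boundary = false;
  if (a == 2 && b == 2) {
    double n11 = table(0, 0), n12 = table(0, 1), n21 = table(1, 0),
           n22 = table(1, 1);
    if (n12 == 0 && n21 == 0 && n11 > 0 && n22 > 0)
      return NumericVector::create(0.999, NA_REAL, 1.0);
    if (n11 == 0 && n22 == 0 && n12 > 0 && n21 > 0)
      return NumericVector::create(-0.999, NA_REAL, 1.0);
  }

  std::vector<double> tab(a * b);
  for (int i = 0; i < a; i++)
    for (int j = 0; j < b; j++)
      tab[i * b + j] = (table(i, j) == 0.0) ? 0.5 : table(i, j);

  double rho = brent_min(tab, ta, tb, -0.999, 0.999, 1e-7);
  if (rho >= 0.9985) { rho = 0.999; boundary = true; }
  if (rho <= -0.9985) { rho = -0.999; boundary = true; }

  // Asymptotic variance from the curvature of the profile log-likelihood
  // (thresholds fixed): var = 1 / (d^2 nll / d rho^2).
  double eps = 5e-4;
  double f0 = pair_negloglik(tab, ta, tb, rho);
  double fp = pair_negloglik(tab, ta, tb, std::min(rho + eps, 0.9995));
  double fm = pair_negloglik(tab, ta, tb, std::max(rho - eps, -0.9995));
  double hess = (fp - 2.0 * f0 + fm) / (eps * eps);
  double avar = (hess > 0) ? 1.0 / hess : NA_REAL;
  return NumericVector::create(rho, avar, boundary ? 1.0 : 0.0);
}

// Full-matrix driver. x: n x p integer codes 0..c-1 (no NA), thresholds:
// list of per-item threshold vectors (length c_i - 1), ncat: c_i.
// Returns list(rho = p x p, avar = p x p, boundary = p x p 0/1).
// [[Rcpp::export(name = ".polychoric_matrix_cpp")]]
List polychoric_matrix_cpp(IntegerMatrix x, List thresholds,
                           IntegerVector ncat) {
  int n = x.nrow(), p = x.ncol();
  NumericMatrix rho(p, p), avar(p, p), bnd(p, p);
  rho.fill_diag(1.0);
  for (int i = 0; i < p; i++) {
    NumericVector thi = thresholds[i];
    int ci = ncat[i];
    for (int j = i + 1; j < p; j++) {
      NumericVector thj = thresholds[j];
      int cj = ncat[j];
      NumericMatrix tab(ci, cj);
      for (int t = 0; t < n; t++) {
        int xi = x(t, i), xj = x(t, j);
        tab(xi, xj) += 1.0;
      }
      NumericVector res = polychoric_pair_cpp(tab, thi, thj);
      rho(i, j) = rho(j, i) = res[0];
      avar(i, j) = avar(j, i) = res[1];
      bnd(i, j) = bnd(j, i) = res[2];
    }
  }
  return List::create(_["rho"] = rho, _["avar"] = avar, _["boundary"] = bnd);
}
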