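#include <Rcpp.h>
using namespace Rcpp;

// Image kernels for the shading-correction and rendering pipeline.
// All filters use replicate-edge padding (index clamping): division by an
// illumination field estimated with truncated windows would amplify border
// artifacts, so edges are extended instead.

static inline int clampi(int i, int lo, int hi) {
  return i < lo ? lo : (i > hi ? hi : i);
}

// Separable running extreme (min or max) over a k x k square window.
// A square structuring element factorises into a horizontal then a
// vertical 1-D pass for min/max.
static NumericMatrix sep_extreme(const NumericMatrix &im, int k, bool take_max) {
  const int nr = im.nrow(), nc = im.ncol(), r = k / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double v = im(i, clampi(j - r, 0, nc - 1));
      for (int q = j - r + 1; q <= j + r; ++q) {
        double x = im(i, clampi(q, 0, nc - 1));
        if (take_max ? (x > v) : (x < v)) v = x;
      }
      tmp(i, j) = v;
    }
  }
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = tmp(clampi(i - r, 0, nr - 1), j);
      for (int q = i - r + 1; q <= i + r; ++q) {
        double x = tmp(clampi(q, 0, nr - 1), j);
        if (take_max ? (x > v) : (x < v)) v = x;
      }
      out(i, j) = v;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_erode")]]
NumericMatrix cpp_erode(NumericMatrix im, int k) { return sep_extreme(im, k, false); }

// [[Rcpp::export(name = ".cpp_dilate")]]
NumericMatrix cpp_dilate(NumericMatrix im, int k) { return sep_extreme(im, k, true); }

// [[Rcpp::export(name = ".cpp_mean_filter")]]
NumericMatrix cpp_mean_filter(NumericMatrix im, int k) {
  const int nr = im.nrow(), nc = im.ncol(), r = k / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double w = 1.0 / k;
  for (int i = 0; i < nr; ++i) {
    double s = 0.0;
    for (int q = -r; q <= r; ++q) s += im(i, clampi(q, 0, nc - 1));
    tmp(i, 0) = s * w;
    for (int j = 1; j < nc; ++j) {
      s += im(i, clampi(j + r, 0, nc - 1)) - im(i, clampi(j - r - 1, 0, nc - 1));
      tmp(i, j) = s * w;
    }
  }
  for (int j = 0; j < nc; ++j) {
    double s = 0.0;
    for (int q = -r; q <= r; ++q) s += tmp(clampi(q, 0, nr - 1), j);
    out(0, j) = s * w;
    for (int i = 1; i < nr; ++i) {
      s += tmp(clampi(i + r, 0, nr - 1), j) - tmp(clampi(i - r - 1, 0, nr - 1), j);
      out(i, j) = s * w;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_gaussian_blur")]]
NumericMatrix cpp_gaussian_blur(NumericMatrix im, double sigma) {
  const int nr = im.nrow(), nc = im.ncol();
  if (sigma <= 0) return clone(im);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  double s = 0.0;
  for (int q = -r; q <= r; ++q) {
    ker[q + r] = std::exp(-0.5 * q * q / (sigma * sigma));
    s += ker[q + r];
  }
  for (double &v : ker) v /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double acc = 0.0;
      for (int q = -r; q <= r; ++q) acc += ker[q + r] * im(i, clampi(j + q, 0, nc - 1));
      tmp(i, j) = acc;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int q = -r; q <= r; ++q) acc += ker[q + r] * tmp(clampi(i + q, 0, nr - 1), j);
      out(i, j) = acc;
    }
  return out;
}

// ---------------------------------------------------------------------------
// 2-D diffusion with spatially varying diffusivity (zero inside obstacles),
// no-flux outer boundaries, optional replenished source region (Dirichlet)
// and optional first-order trapping into an immobile bound pool.
//
// Grid convention: rows = y, cols = x, square cells of side h (um).
// Face diffusivities are harmonic means of the adjacent cell values (zero
// if either side is an obstacle), which gives a conservative finite-volume
// operator: mass is conserved to round-off under no-flux boundaries.
// ---------------------------------------------------------------------------

// Thomas tridiagonal solve: a = sub, b = diag, c = super, d = rhs (in/out).
static void thomas(std::vector<double> &a, std::vector<double> &b,
                   std::vector<double> &c, std::vector<double> &d) {
  const int n = (int)b.size();
  for (int i = 1; i < n; ++i) {
    double m = a[i] / b[i - 1];
    b[i] -= m * c[i - 1];
    d[i] -= m * d[i - 1];
  }
  d[n - 1] /= b[n - 1];
  for (int i = n - 2; i >= 0; --i) d[i] = (d[i] - c[i] * d[i + 1]) / b[i];
}

// [[Rcpp::export(name = ".cpp_diffuse")]]
List cpp_diffuse(NumericMatrix C0, NumericMatrix D, double h, double dt, int nsteps,
                 LogicalMatrix src_mask, double src_value, bool replenish,
                 double k_on, NumericMatrix B0, std::string method) {
  const int nr = C0.nrow(), nc = C0.ncol();
  NumericMatrix C = clone(C0), B = clone(B0);

  // face diffusivities / h^2 (flux coefficients)
  NumericMatrix De(nr, nc), Dn(nr, nc); // east face (col j -> j+1), south face (row i -> i+1)
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      if (j + 1 < nc) {
        double a = D(i, j), b = D(i, j + 1);
        De(i, j) = (a > 0 && b > 0) ? (2.0 * a * b / (a + b)) / (h * h) : 0.0;
      }
      if (i + 1 < nr) {
        double a = D(i, j), b = D(i + 1, j);
        Dn(i, j) = (a > 0 && b > 0) ? (2.0 * a * b / (a + b)) / (h * h) : 0.0;
      }
    }

  const bool explicit_scheme = (method == "explicit");
  const double aa = explicit_scheme ? dt : dt / 2.0;

  std::vector<double> ta, tb, tc, td;
  NumericMatrix Cs(nr, nc);

  for (int step = 0; step < nsteps; ++step) {
    if (explicit_scheme) {
      for (int i = 0; i < nr; ++i)
        for (int j = 0; j < nc; ++j) {
          double lap = 0.0;
          if (j + 1 < nc) lap += De(i, j) * (C(i, j + 1) - C(i, j));
          if (j > 0)      lap -= De(i, j - 1) * (C(i, j) - C(i, j - 1));
          if (i + 1 < nr) lap += Dn(i, j) * (C(i + 1, j) - C(i, j));
          if (i > 0)      lap -= Dn(i - 1, j) * (C(i, j) - C(i - 1, j));
          Cs(i, j) = C(i, j) + aa * lap;
        }
      C = clone(Cs);
    } else {
      // Peaceman-Rachford ADI.  A replenished source is a Dirichlet
      // condition imposed as identity rows inside each solve.
      // Half-step 1: implicit in x, explicit in y.
      for (int i = 0; i < nr; ++i) {
        ta.assign(nc, 0.0); tb.assign(nc, 0.0); tc.assign(nc, 0.0); td.assign(nc, 0.0);
        for (int j = 0; j < nc; ++j) {
          if (replenish && src_mask(i, j)) {
            tb[j] = 1.0; td[j] = src_value;
            continue;
          }
          double ly = 0.0;
          if (i + 1 < nr) ly += Dn(i, j) * (C(i + 1, j) - C(i, j));
          if (i > 0)      ly -= Dn(i - 1, j) * (C(i, j) - C(i - 1, j));
          td[j] = C(i, j) + aa * ly;
          double de = (j + 1 < nc) ? De(i, j) : 0.0;
          double dw = (j > 0) ? De(i, j - 1) : 0.0;
          tb[j] = 1.0 + aa * (de + dw);
          if (j + 1 < nc) tc[j] = -aa * de;
          if (j > 0)      ta[j] = -aa * dw;
        }
        thomas(ta, tb, tc, td);
        for (int j = 0; j < nc; ++j) Cs(i, j) = td[j];
      }
      // Half-step 2: implicit in y, explicit in x.
      for (int j = 0; j < nc; ++j) {
        ta.assign(nr, 0.0); tb.assign(nr, 0.0); tc.assign(nr, 0.0); td.assign(nr, 0.0);
        for (int i = 0; i < nr; ++i) {
          if (replenish && src_mask(i, j)) {
            tb[i] = 1.0; td[i] = src_value;
            continue;
          }
          double lx = 0.0;
          if (j + 1 < nc) lx += De(i, j) * (Cs(i, j + 1) - Cs(i, j));
          if (j > 0)      lx -= De(i, j - 1) * (Cs(i, j) - Cs(i, j - 1));
          td[i] = Cs(i, j) + aa * lx;
          double dn = (i + 1 < nr) ? Dn(i, j) : 0.0;
          double ds = (i > 0) ? Dn(i - 1, j) : 0.0;
          tb[i] = 1.0 + aa * (dn + ds);
          if (i + 1 < nr) tc[i] = -aa * dn;
          if (i > 0)      ta[i] = -aa * ds;
        }
        thomas(ta, tb, tc, td);
        for (int i = 0; i < nr; ++i) C(i, j) = td[i];
      }
    }

    if (replenish) {
      for (int i = 0; i < nr; ++i)
        for (int j = 0; j < nc; ++j)
          if (src_mask(i, j)) C(i, j) = src_value;
    }
    if (k_on > 0) {
      // weak binding: mobile -> immobile, first order, outside the source
      for (int i = 0; i < nr; ++i)
        for (int j = 0; j < nc; ++j)
          if (!src_mask(i, j)) {
            double db = k_on * dt * C(i, j);
            C(i, j) -= db;
            B(i, j) += db;
          }
    }
  }
  return List::create(_["C"] = C, _["B"] = B);
}
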