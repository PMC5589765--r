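#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Reduce x into [0, period).
static inline double wrap_into(double x, double period) {
  return x - period * std::floor(x / period);
}

// Minimal-image displacement for periodic coordinates.
static inline double wrap_disp(double d, double period) {
  d = wrap_into(d, period);
  if (d > 0.5 * period) d -= period;
  return d;
}

// terms: 4 x n matrix, rows = (type, p1, p2, p3)
//   type 0 gaussian: center, height, width
//   type 1 harmonic: center, k
//   type 2 morse:    r0, a, D
//   type 3 constant: value
static inline double pot_value(const double *tm, int nterm, double x,
                               bool periodic, double period) {
  double v = 0.0;
  for (int j = 0; j < nterm; ++j) {
    const double *p = tm + 4 * j;
    int type = (int)p[0];
    switch (type) {
    case 0: {
      double d = x - p[1];
      if (periodic) d = wrap_disp(d, period);
      double w = p[3];
      v += p[2] * std::exp(-0.5 * d * d / (w * w));
      break;
    }
    case 1: {
      double d = x - p[1];
      if (periodic) d = wrap_disp(d, period);
      v += 0.5 * p[2] * d * d;
      break;
    }
    case 2: {
      double e = 1.0 - std::exp(-p[2] * (x - p[1]));
      v += p[3] * e * e - p[3];
      break;
    }
    case 3:
      v += p[1];
      break;
    }
  }
  return v;
}

static inline double pot_deriv(const double *tm, int nterm, double x,
                               bool periodic, double period) {
  double g = 0.0;
  for (int j = 0; j < nterm; ++j) {
    const double *p = tm + 4 * j;
    int type = (int)p[0];
    switch (type) {
    case 0: {
      double d = x - p[1];
      if (periodic) d = wrap_disp(d, period);
      double w2 = p[3] * p[3];
      g += -p[2] * d / w2 * std::exp(-0.5 * d * d / w2);
      break;
    }
    case 1: {
      double d = x - p[1];
      if (periodic) d = wrap_disp(d, period);
      g += p[2] * d;
      break;
    }
    case 2: {
      double ex = std::exp(-p[2] * (x - p[1]));
      g += 2.0 * p[3] * (1.0 - ex) * p[2] * ex;
      break;
    }
    default:
      break;
    }
  }
  return g;
}

// [[Rcpp::export]]
NumericVector eval_potential_cpp(NumericMatrix terms, NumericVector x,
                                 bool periodic, double period) {
  int n = x.size(), nterm = terms.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = pot_value(terms.begin(), nterm, x[i], periodic, period);
  return out;
}

// [[Rcpp::export]]
NumericVector eval_deriv_cpp(NumericMatrix terms, NumericVector x,
                             bool periodic, double period) {
  int n = x.size(), nterm = terms.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = pot_deriv(terms.begin(), nterm, x[i], periodic, period);
  return out;
}

// Overdamped Langevin (Euler-Maruyama):
//   x_{t+dt} = x_t - dt/gamma * [V'(x) + k_bias * wrap(x - lambda(t))]
//             + sqrt(2 kB T dt / gamma) * N(0,1)
// lambda(t) = lambda0 + lambda_rate * t (steering) or constant (umbrella).
// Uses R's RNG so set.seed() gives bit-identical trajectories.
// Returns saved positions (every save_stride steps, including step 0).
// If a non-periodic trajectory leaves the domain by more than 10% of its
// span, returns early with attribute "escaped" = step index.
// [[Rcpp::export]]
List langevin_cpp(NumericMatrix terms, double x0, double kBT, double gamma,
                  double dt, int n_steps, int save_stride,
                  bool periodic, double period,
                  double k_bias, double lambda0, double lambda_rate,
                  double dom_lo, double dom_hi) {
  int nterm = terms.ncol();
  int n_save = n_steps / save_stride + 1;
  NumericVector xs(n_save), lams(n_save);
  double x = x0;
  double pref = dt / gamma;
  double noise = std::sqrt(2.0 * kBT * dt / gamma);
  double slack = 0.10 * (dom_hi - dom_lo);
  int escaped = -1;
  xs[0] = x;
  lams[0] = lambda0;
  int isave = 1;
  GetRNGstate();
  for (int s = 1; s <= n_steps; ++s) {
    double lam = lambda0 + lambda_rate * (s - 1) * dt;
    double f = -pot_deriv(terms.begin(), nterm, x, periodic, period);
    if (k_bias > 0.0) {
      double d = x - lam;
      if (periodic) d = wrap_disp(d, period);
      f -= k_bias * d;
    }
    x += pref * f + noise * norm_rand();
    if (periodic) {
      x = wrap_into(x, period);
    } else if (x < dom_lo - slack || x > dom_hi + slack) {
      escaped = s;
      break;
    }
    if (s % save_stride == 0) {
      xs[isave] = x;
      lams[isave] = lambda0 + lambda_rate * s * dt;
      ++isave;
    }
  }
  PutRNGstate();
  if (escaped >= 0) {
    xs = NumericVector(xs.begin(), xs.begin() + isave);
    lams = NumericVector(lams.begin(), lams.begin() + isave);
  }
  return List::create(_["x"] = xs, _["lambda"] = lams,
                      _["escaped"] = escaped, _["x_final"] = x);
}
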