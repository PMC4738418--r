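#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Single-covariate Cox partial likelihood with the Efron tie correction.
// Data must be sorted by increasing time. Returns loglik, score, information
// at a given beta in one pass from the largest time downwards.
static void efron_pass(const std::vector<double>& x,
                       const std::vector<double>& time,
                       const std::vector<int>& event,
                       double beta,
                       double& loglik, double& score, double& info) {
  const int n = x.size();
  loglik = 0.0; score = 0.0; info = 0.0;
  double s0 = 0.0, s1 = 0.0, s2 = 0.0;
  int i = n - 1;
  while (i >= 0) {
    int j = i;
    while (j >= 0 && time[j] == time[i]) --j;
    // subjects (j, i] share this time; all enter the risk set here
    double q0 = 0.0, q1 = 0.0, q2 = 0.0, sumx = 0.0;
    int d = 0;
    for (int k = i; k > j; --k) {
      double w = std::exp(beta * x[k]);
      s0 += w; s1 += w * x[k]; s2 += w * x[k] * x[k];
      if (event[k]) {
        q0 += w; q1 += w * x[k]; q2 += w * x[k] * x[k];
        sumx += x[k]; ++d;
      }
    }
    if (d > 0) {
      // group contribution: beta*sumx - sum_r log(d0_r); score sumx - sum_r m_r
      loglik += beta * sumx;
      score += sumx;
      for (int r = 0; r < d; ++r) {
        double f = (double)r / d;
        double d0 = s0 - f * q0, d1 = s1 - f * q1, d2 = s2 - f * q2;
        loglik -= std::log(d0);
        double m = d1 / d0;
        score -= m;
        info += d2 / d0 - m * m;
      }
    }
    i = j;
  }
}

// Newton-Raphson fit. Returns {beta, se, loglik, loglik_null, converged, iter}.
// converged = 0 flags divergence (|beta| > 20) or iteration overrun; callers
// treat those estimates as missing.
// [[Rcpp::export]]
List cox_fit1_cpp(NumericVector x, NumericVector time, IntegerVector event,
                  int max_iter = 50, double tol = 1e-9) {
  const int n = x.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return time[a] < time[b]; });
  std::vector<double> xs(n), ts(n);
  std::vector<int> ev(n);
  double xbar = 0.0;
  int nev = 0;
  for (int i = 0; i < n; ++i) {
    xs[i] = x[ord[i]]; ts[i] = time[ord[i]]; ev[i] = event[ord[i]];
    xbar += xs[i];
    nev += ev[i];
  }
  xbar /= n;
  bool constant = true;
  for (int i = 0; i < n; ++i) {
    xs[i] -= xbar; // centering: invariant fit, better conditioning
    if (std::fabs(xs[i] - xs[0]) > 1e-12) constant = false;
  }
  if (nev == 0 || constant)
    return List::create(_["beta"] = NA_REAL, _["se"] = NA_REAL,
                        _["loglik"] = NA_REAL, _["loglik_null"] = NA_REAL,
                        _["converged"] = false, _["iter"] = 0,
                        _["error"] = nev == 0 ? "no events" : "constant covariate");

  double ll0, sc0, in0;
  efron_pass(xs, ts, ev, 0.0, ll0, sc0, in0);
  if (in0 <= 0.0)
    return List::create(_["beta"] = NA_REAL, _["se"] = NA_REAL,
                        _["loglik"] = NA_REAL, _["loglik_null"] = ll0,
                        _["converged"] = false, _["iter"] = 0,
                        _["error"] = "no information");

  double beta = 0.0, ll = ll0, sc = sc0, info = in0;
  bool converged = false, diverged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    double step = sc / info;
    double newbeta = beta + step, newll, newsc, newinfo;
    int halvings = 0;
    efron_pass(xs, ts, ev, newbeta, newll, newsc, newinfo);
    while ((!std::isfinite(newll) || newll < ll - 1e-10) && halvings < 30) {
      step /= 2.0; newbeta = beta + step; ++halvings;
      efron_pass(xs, ts, ev, newbeta, newll, newsc, newinfo);
    }
    beta = newbeta; ll = newll; sc = newsc; info = newinfo;
    if (std::fabs(beta) > 20.0) { diverged = true; break; }
    if (std::fabs(step) < tol * (1.0 + std::fabs(beta)) ||
        std::fabs(sc) < tol) { converged = true; break; }
  }
  double se = info > 0 ? std::sqrt(1.0 / info) : NA_REAL;
  return List::create(_["beta"] = beta, _["se"] = se, _["loglik"] = ll,
                      _["loglik_null"] = ll0,
                      _["converged"] = converged && !diverged,
                      _["iter"] = iter,
                      _["error"] = diverged ? "divergent" : "");
}

struct Fit1 {
  double beta, se, lldiff;
  bool ok;
};

static Fit1 fit_sorted(std::vector<double>& xs, const std::vector<double>& ts,
                       const std::vector<int>& ev) {
  Fit1 out{NA_REAL, NA_REAL, NA_REAL, false};
  const int n = xs.size();
  double xbar = 0.0;
  int nev = 0;
  for (int i = 0; i < n; ++i) { xbar += xs[i]; nev += ev[i]; }
  xbar /= n;
  bool constant = true;
  for (int i = 0; i < n; ++i) {
    xs[i] -= xbar;
    if (std::fabs(xs[i] - xs[0]) > 1e-12) constant = false;
  }
  if (nev == 0 || constant) return out;
  double ll0, sc, info;
  efron_pass(xs, ts, ev, 0.0, ll0, sc, info);
  if (info <= 0.0) return out;
  double beta = 0.0, ll = ll0;
  bool converged = false;
  for (int iter = 1; iter <= 50; ++iter) {
    double step = sc / info;
    double newbeta = beta + step, newll, newsc, newinfo;
    int halvings = 0;
    efron_pass(xs, ts, ev, newbeta, newll, newsc, newinfo);
    while ((!std::isfinite(newll) || newll < ll - 1e-10) && halvings < 30) {
      step /= 2.0; newbeta = beta + step; ++halvings;
      efron_pass(xs, ts, ev, newbeta, newll, newsc, newinfo);
    }
    beta = newbeta; ll = newll; sc = newsc; info = newinfo;
    if (std::fabs(beta) > 20.0) return out;
    if (std::fabs(step) < 1e-9 * (1.0 + std::fabs(beta)) ||
        std::fabs(sc) < 1e-9) { converged = true; break; }
  }
  if (!converged || info <= 0.0) return out;
  out.beta = beta; out.se = std::sqrt(1.0 / info); out.lldiff = ll - ll0;
  out.ok = true;
  return out;
}

// Nonparametric bootstrap of the single-covariate Cox fit: resamples rows with
// replacement `nboot` times using R's RNG and refits. Returns an nboot x 4
// matrix (beta, se, loglik - loglik_null, n_events); degenerate or divergent
// replicates are rows of NA.
// [[Rcpp::export]]
NumericMatrix cox_boot_cpp(NumericVector x, NumericVector time,
                           IntegerVector event, int nboot) {
  const int n = x.size();
  NumericMatrix out(nboot, 4);
  std::vector<double> xs(n), ts(n);
  std::vector<int> ev(n), idx(n);
  for (int b = 0; b < nboot; ++b) {
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k == n) k = n - 1;
      idx[i] = k;
    }
    std::sort(idx.begin(), idx.end(),
              [&](int a, int c) { return time[a] < time[c]; });
    int nev = 0;
    for (int i = 0; i < n; ++i) {
      xs[i] = x[idx[i]]; ts[i] = time[idx[i]]; ev[i] = event[idx[i]];
      nev += ev[i];
    }
    Fit1 f = fit_sorted(xs, ts, ev);
    out(b, 0) = f.ok ? f.beta : NA_REAL;
    out(b, 1) = f.ok ? f.se : NA_REAL;
    out(b, 2) = f.ok ? f.lldiff : NA_REAL;
    out(b, 3) = nev;
  }
  return out;
}

// Bootstrap of the D statistic: per replicate the prognostic index is
// resampled with replacement, re-ranked, mapped to (pre-computed, already
// kappa-scaled) Blom normal order scores with ties averaged, and fed to the
// Cox fit. `blom` has length n: score for rank r at position r-1.
// [[Rcpp::export]]
NumericMatrix d_boot_cpp(NumericVector pi_, NumericVector time,
                         IntegerVector event, NumericVector blom, int nboot) {
  const int n = pi_.size();
  NumericMatrix out(nboot, 2);
  std::vector<double> xs(n), ts(n), scr(n);
  std::vector<int> ev(n), idx(n), ordx(n);
  for (int b = 0; b < nboot; ++b) {
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k == n) k = n - 1;
      idx[i] = k;
    }
    std::sort(idx.begin(), idx.end(),
              [&](int a, int c) { return time[a] < time[c]; });
    for (int i = 0; i < n; ++i) {
      xs[i] = pi_[idx[i]]; ts[i] = time[idx[i]]; ev[i] = event[idx[i]];
      ordx[i] = i;
    }
    std::sort(ordx.begin(), ordx.end(),
              [&](int a, int c) { return xs[a] < xs[c]; });
    // averaged Blom scores within tie groups of the resampled PI
    int i = 0;
    while (i < n) {
      int j = i;
      double s = 0.0;
      while (j < n && xs[ordx[j]] == xs[ordx[i]]) { s += blom[j]; ++j; }
      double m = s / (j - i);
      for (int k = i; k < j; ++k) scr[ordx[k]] = m;
      i = j;
    }
    std::vector<double> xcopy(scr);
    Fit1 f = fit_sorted(xcopy, ts, ev);
    out(b, 0) = f.ok ? f.beta : NA_REAL;
    out(b, 1) = f.ok ? f.se : NA_REAL;
  }
  return out;
}
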