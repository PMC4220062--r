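// Core numerics for the ARSER-style rhythmicity detector.
//
// Per gene: linear detrend -> autoregressive spectral period candidates
// (Yule-Walker, Burg and exact-Gaussian-ML fits, AIC order selection, union
// of spectral peaks in the allowed period band) -> harmonic regression at
// each candidate with AIC model selection -> golden-section refinement of
// the period against the regression RSS -> F test of the harmonic terms.
//
// Implemented in C++ because the simulation benchmark runs this on the
// order of 10^5-10^6 gene-level series.

#include <Rcpp.h>
#include <vector>
#include <set>
#include <cmath>

using namespace Rcpp;

namespace {

const double SIG_FLOOR = 1e-300;

struct MethodFit {
  int order;                 // selected AR order (0 = white noise)
  std::vector<double> phi;   // AR coefficients, length order
  double sigma2;
  bool ok;
};

// biased autocovariance of a (zero-mean) series
void acvf(const double* x, int n, int m, std::vector<double>& c) {
  c.assign(m + 1, 0.0);
  for (int k = 0; k <= m; ++k) {
    double s = 0.0;
    for (int i = k; i < n; ++i) s += x[i] * x[i - k];
    c[k] = s / n;
  }
}

// Levinson-Durbin over orders 1..m: records per-order sigma2, pacf and
// the coefficient rows (row k has length k).
bool levinson(const std::vector<double>& c, int m,
              std::vector<double>& sigma2, std::vector<double>& pacf,
              std::vector< std::vector<double> >& phiRows) {
  sigma2.assign(m + 1, 0.0);
  pacf.assign(m + 1, 0.0);
  phiRows.assign(m + 1, std::vector<double>());
  if (c[0] <= 0.0) return false;
  sigma2[0] = c[0];
  std::vector<double> phi, phiNew;
  for (int k = 1; k <= m; ++k) {
    double acc = c[k];
    for (int j = 1; j < k; ++j) acc -= phi[j - 1] * c[k - j];
    double kap = acc / sigma2[k - 1];
    if (!std::isfinite(kap)) return false;
    if (kap > 0.999999) kap = 0.999999;
    if (kap < -0.999999) kap = -0.999999;
    phiNew.assign(k, 0.0);
    phiNew[k - 1] = kap;
    for (int j = 1; j < k; ++j)
      phiNew[j - 1] = phi[j - 1] - kap * phi[k - j - 1];
    phi = phiNew;
    pacf[k] = kap;
    sigma2[k] = sigma2[k - 1] * (1.0 - kap * kap);
    if (sigma2[k] < SIG_FLOOR) sigma2[k] = SIG_FLOOR;
    phiRows[k] = phi;
  }
  return true;
}

MethodFit fitYuleWalker(const std::vector<double>& c, int m, int n) {
  MethodFit out; out.order = 0; out.sigma2 = c[0]; out.ok = false;
  std::vector<double> sigma2, pacf;
  std::vector< std::vector<double> > rows;
  if (!levinson(c, m, sigma2, pacf, rows)) return out;
  out.ok = true;
  double best = n * std::log(std::max(sigma2[0], SIG_FLOOR)) + 2.0;
  for (int k = 1; k <= m; ++k) {
    double aic = n * std::log(std::max(sigma2[k], SIG_FLOOR)) + 2.0 * (k + 1);
    if (aic < best) { best = aic; out.order = k; }
  }
  if (out.order > 0) { out.phi = rows[out.order]; out.sigma2 = sigma2[out.order]; }
  return out;
}

MethodFit fitBurg(const double* x, int n, int m) {
  MethodFit out; out.order = 0; out.ok = true;
  double c0 = 0.0;
  for (int i = 0; i < n; ++i) c0 += x[i] * x[i];
  c0 /= n;
  out.sigma2 = c0;
  if (c0 <= 0.0) { out.ok = false; return out; }
  std::vector<double> f(x, x + n), b(x, x + n);
  std::vector<double> a, aNew;
  std::vector<double> sigma2(m + 1, 0.0);
  std::vector< std::vector<double> > rows(m + 1);
  sigma2[0] = c0;
  for (int k = 1; k <= m; ++k) {
    double num = 0.0, den = 0.0;
    for (int i = k; i < n; ++i) {
      num += f[i] * b[i - 1];
      den += f[i] * f[i] + b[i - 1] * b[i - 1];
    }
    double kap = (den > 0.0) ? 2.0 * num / den : 0.0;
    if (kap > 0.999999) kap = 0.999999;
    if (kap < -0.999999) kap = -0.999999;
    aNew.assign(k, 0.0);
    aNew[k - 1] = kap;
    for (int j = 1; j < k; ++j) aNew[j - 1] = a[j - 1] - kap * a[k - j - 1];
    a = aNew;
    for (int i = n - 1; i >= k; --i) {
      double fo = f[i], bo = b[i - 1];
      f[i] = fo - kap * bo;
      b[i] = bo - kap * fo;
    }
    sigma2[k] = sigma2[k - 1] * (1.0 - kap * kap);
    if (sigma2[k] < SIG_FLOOR) sigma2[k] = SIG_FLOOR;
    rows[k] = a;
  }
  double best = n * std::log(std::max(sigma2[0], SIG_FLOOR)) + 2.0;
  for (int k = 1; k <= m; ++k) {
    double aic = n * std::log(std::max(sigma2[k], SIG_FLOOR)) + 2.0 * (k + 1);
    if (aic < best) { best = aic; out.order = k; }
  }
  if (out.order > 0) { out.phi = rows[out.order]; out.sigma2 = sigma2[out.order]; }
  return out;
}

// Exact Gaussian AR(p) negative log-likelihood (innovation variance
// profiled out), parameterised by partial autocorrelations r = tanh(z).
// Returns 0.5*(n log sigma2hat + sum log v); also exposes sigma2hat,
// sum log v and the order-p coefficient row on demand.
double mleObjective(const std::vector<double>& z, const double* x, int n, int p,
                    double* sigma2hatOut, double* sumlogvOut,
                    std::vector<double>* phiOut) {
  std::vector<double> r(p);
  double gamma0 = 1.0;
  for (int j = 0; j < p; ++j) {
    double rj = std::tanh(z[j]);
    if (rj > 0.99999) rj = 0.99999;
    if (rj < -0.99999) rj = -0.99999;
    r[j] = rj;
    gamma0 /= (1.0 - rj * rj);
  }
  // Durbin-Levinson coefficient rows 1..p from the pacf sequence
  std::vector< std::vector<double> > rows(p + 1);
  std::vector<double> phi, phiNew;
  for (int k = 1; k <= p; ++k) {
    double kap = r[k - 1];
    phiNew.assign(k, 0.0);
    phiNew[k - 1] = kap;
    for (int j = 1; j < k; ++j)
      phiNew[j - 1] = phi[j - 1] - kap * phi[k - j - 1];
    phi = phiNew;
    rows[k] = phi;
  }
  // one-step prediction errors and (unit-innovation) error variances
  double q = 0.0, sumlogv = 0.0;
  double v = gamma0;
  for (int t = 1; t <= n; ++t) {
    int m = std::min(t - 1, p);
    double pred = 0.0;
    if (m > 0) {
      const std::vector<double>& ph = rows[m];
      for (int j = 1; j <= m; ++j) pred += ph[j - 1] * x[t - 1 - j];
    }
    double e = x[t - 1] - pred;
    q += e * e / v;
    sumlogv += std::log(v);
    if (t <= p) v *= (1.0 - r[t - 1] * r[t - 1]);
  }
  double sigma2hat = q / n;
  if (sigma2hat < SIG_FLOOR) sigma2hat = SIG_FLOOR;
  if (sigma2hatOut) *sigma2hatOut = sigma2hat;
  if (sumlogvOut) *sumlogvOut = sumlogv;
  if (phiOut) *phiOut = rows[p];
  return 0.5 * (n * std::log(sigma2hat) + sumlogv);
}

// minimal Nelder-Mead for dimension d <= 8
void nelderMead(std::vector<double>& z, const double* x, int n, int p,
                int maxit) {
  int d = p;
  std::vector< std::vector<double> > S(d + 1, z);
  std::vector<double> fv(d + 1);
  for (int i = 1; i <= d; ++i) S[i][i - 1] += 0.4;
  for (int i = 0; i <= d; ++i)
    fv[i] = mleObjective(S[i], x, n, p, NULL, NULL, NULL);
  for (int it = 0; it < maxit; ++it) {
    // order
    int lo = 0, hi = 0, nh = 0;
    for (int i = 1; i <= d; ++i) {
      if (fv[i] < fv[lo]) lo = i;
      if (fv[i] > fv[hi]) hi = i;
    }
    nh = lo;
    for (int i = 0; i <= d; ++i)
      if (i != hi && fv[i] > fv[nh]) nh = i;
    if (std::fabs(fv[hi] - fv[lo]) < 1e-8 * (std::fabs(fv[lo]) + 1e-8)) break;
    // centroid excluding worst
    std::vector<double> cen(d, 0.0);
    for (int i = 0; i <= d; ++i)
      if (i != hi) for (int j = 0; j < d; ++j) cen[j] += S[i][j];
    for (int j = 0; j < d; ++j) cen[j] /= d;
    std::vector<double> xr(d), xe(d), xc(d);
    for (int j = 0; j < d; ++j) xr[j] = cen[j] + (cen[j] - S[hi][j]);
    double fr = mleObjective(xr, x, n, p, NULL, NULL, NULL);
    if (fr < fv[lo]) {
      for (int j = 0; j < d; ++j) xe[j] = cen[j] + 2.0 * (cen[j] - S[hi][j]);
      double fe = mleObjective(xe, x, n, p, NULL, NULL, NULL);
      if (fe < fr) { S[hi] = xe; fv[hi] = fe; }
      else { S[hi] = xr; fv[hi] = fr; }
    } else if (fr < fv[nh]) {
      S[hi] = xr; fv[hi] = fr;
    } else {
      for (int j = 0; j < d; ++j) xc[j] = cen[j] + 0.5 * (S[hi][j] - cen[j]);
      double fc = mleObjective(xc, x, n, p, NULL, NULL, NULL);
      if (fc < fv[hi]) { S[hi] = xc; fv[hi] = fc; }
      else {
        for (int i = 0; i <= d; ++i) {
          if (i == lo) continue;
          for (int j = 0; j < d; ++j)
            S[i][j] = S[lo][j] + 0.5 * (S[i][j] - S[lo][j]);
          fv[i] = mleObjective(S[i], x, n, p, NULL, NULL, NULL);
        }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i <= p; ++i) if (fv[i] < fv[lo]) lo = i;
  z = S[lo];
}

MethodFit fitMle(const double* x, int n, int m,
                 const std::vector<double>& pacfInit) {
  MethodFit out; out.order = 0; out.ok = true;
  double c0 = 0.0;
  for (int i = 0; i < n; ++i) c0 += x[i] * x[i];
  c0 /= n;
  out.sigma2 = c0;
  if (c0 <= 0.0) { out.ok = false; return out; }
  const double LOG2PI = 1.8378770664093453;
  double bestAic = n * LOG2PI + n * std::log(std::max(c0, SIG_FLOOR)) + n + 2.0;
  for (int p = 1; p <= m; ++p) {
    std::vector<double> z(p, 0.0);
    for (int j = 0; j < p; ++j) {
      double r0 = (j + 1 < (int)pacfInit.size()) ? pacfInit[j + 1] : 0.0;
      if (r0 > 0.95) r0 = 0.95;
      if (r0 < -0.95) r0 = -0.95;
      z[j] = std::atanh(r0);
    }
    nelderMead(z, x, n, p, 60 + 50 * p);
    double s2, slv;
    std::vector<double> phi;
    mleObjective(z, x, n, p, &s2, &slv, &phi);
    double aic = n * LOG2PI + n * std::log(s2) + slv + n + 2.0 * (p + 1);
    if (aic < bestAic) {
      bestAic = aic; out.order = p; out.phi = phi; out.sigma2 = s2;
    }
  }
  return out;
}

// spectral peak grid indices for one fitted AR model
void spectralPeaks(const MethodFit& fit, const std::vector<double>& omega,
                   const std::vector< std::vector<double> >& cosTab,
                   const std::vector< std::vector<double> >& sinTab,
                   std::set<int>& peakIdx) {
  if (!fit.ok || fit.order < 1) return;
  int nf = omega.size();
  std::vector<double> S(nf);
  for (int j = 0; j < nf; ++j) {
    double re = 1.0, im = 0.0;
    for (int k = 0; k < fit.order; ++k) {
      re -= fit.phi[k] * cosTab[j][k];
      im += fit.phi[k] * sinTab[j][k];
    }
    double den = re * re + im * im;
    S[j] = fit.sigma2 / std::max(den, 1e-300);
  }
  for (int j = 1; j < nf - 1; ++j)
    if (S[j] > S[j - 1] && S[j] > S[j + 1]) peakIdx.insert(j);
}

// harmonic regression with a joint linear baseline:
// x ~ mu + bt*(t - tbar) + a*cos(2*pi*t/tau) + b*sin(2*pi*t/tau).
// The baseline is estimated together with the harmonic terms rather than
// by sequential detrending, because on short grids a sampled cosine is
// not orthogonal to time and detrend-then-fit would bias the amplitude.
// Returns false on a singular system.
bool harmonicFit(const double* x, const double* t, int n, double tau,
                 double* mu, double* bt, double* a, double* b,
                 double* rss) {
  const int K = 4;
  double tbar = 0.0;
  for (int i = 0; i < n; ++i) tbar += t[i];
  tbar /= n;
  std::vector<double> cv(n), sv(n), dv(n);
  const double w = 2.0 * M_PI / tau;
  double A[4][5];
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K + 1; ++j) A[i][j] = 0.0;
  for (int i = 0; i < n; ++i) {
    dv[i] = t[i] - tbar;
    cv[i] = std::cos(w * t[i]);
    sv[i] = std::sin(w * t[i]);
    double col[4] = {1.0, dv[i], cv[i], sv[i]};
    for (int r2 = 0; r2 < K; ++r2) {
      for (int c2 = r2; c2 < K; ++c2) A[r2][c2] += col[r2] * col[c2];
      A[r2][K] += col[r2] * x[i];
    }
  }
  for (int r2 = 1; r2 < K; ++r2)
    for (int c2 = 0; c2 < r2; ++c2) A[r2][c2] = A[c2][r2];
  // Gaussian elimination with partial pivoting
  for (int col = 0; col < K; ++col) {
    int best = col;
    for (int r2 = col + 1; r2 < K; ++r2)
      if (std::fabs(A[r2][col]) > std::fabs(A[best][col])) best = r2;
    if (std::fabs(A[best][col]) < 1e-10) return false;
    if (best != col)
      for (int j = 0; j < K + 1; ++j) std::swap(A[col][j], A[best][j]);
    for (int r2 = col + 1; r2 < K; ++r2) {
      double f = A[r2][col] / A[col][col];
      for (int j = col; j < K + 1; ++j) A[r2][j] -= f * A[col][j];
    }
  }
  double beta[4];
  for (int i = K - 1; i >= 0; --i) {
    double s = A[i][K];
    for (int j = i + 1; j < K; ++j) s -= A[i][j] * beta[j];
    beta[i] = s / A[i][i];
  }
  double r = 0.0;
  for (int i = 0; i < n; ++i) {
    double e = x[i] - beta[0] - beta[1] * dv[i] - beta[2] * cv[i] -
               beta[3] * sv[i];
    r += e * e;
  }
  *mu = beta[0]; *bt = beta[1]; *a = beta[2]; *b = beta[3]; *rss = r;
  return true;
}

double rssAt(const double* x, const double* t, int n, double tau) {
  double mu, bt, a, b, rss;
  if (!harmonicFit(x, t, n, tau, &mu, &bt, &a, &b, &rss)) return R_PosInf;
  return rss;
}

double goldenRefine(const double* x, const double* t, int n,
                    double lo, double hi) {
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = rssAt(x, t, n, c), fd = rssAt(x, t, n, d);
  for (int it = 0; it < 80 && (b - a) > 1e-10; ++it) {
    if (fc < fd) { b = d; d = c; fd = fc; c = b - gr * (b - a); fc = rssAt(x, t, n, c); }
    else { a = c; c = d; fc = fd; d = a + gr * (b - a); fd = rssAt(x, t, n, d); }
  }
  return 0.5 * (a + b);
}

// union of AR spectral candidate periods for one zero-mean series
std::vector<double> candidatePeriods(const double* xd, int n, double dt,
                                     double periodMin, double periodMax,
                                     int maxOrder, int nFreq) {
  std::vector<double> c;
  acvf(xd, n, maxOrder, c);
  std::vector<double> sigma2, pacf;
  std::vector< std::vector<double> > rows;
  bool lev = levinson(c, maxOrder, sigma2, pacf, rows);
  std::vector<double> omega(nFreq - 1);
  for (int j = 1; j < nFreq; ++j) omega[j - 1] = M_PI * j / nFreq;
  std::vector< std::vector<double> > cosTab(nFreq - 1, std::vector<double>(maxOrder)),
      sinTab(nFreq - 1, std::vector<double>(maxOrder));
  for (int j = 0; j < nFreq - 1; ++j)
    for (int k = 0; k < maxOrder; ++k) {
      cosTab[j][k] = std::cos(omega[j] * (k + 1));
      sinTab[j][k] = std::sin(omega[j] * (k + 1));
    }
  std::set<int> peaks;
  if (lev) {
    MethodFit yw = fitYuleWalker(c, maxOrder, n);
    spectralPeaks(yw, omega, cosTab, sinTab, peaks);
    MethodFit bg = fitBurg(xd, n, maxOrder);
    spectralPeaks(bg, omega, cosTab, sinTab, peaks);
    MethodFit ml = fitMle(xd, n, maxOrder, pacf);
    spectralPeaks(ml, omega, cosTab, sinTab, peaks);
  }
  std::vector<double> out;
  for (std::set<int>::const_iterator it = peaks.begin(); it != peaks.end(); ++it) {
    double tau = 2.0 * M_PI * dt / omega[*it];
    if (tau >= periodMin && tau <= periodMax) out.push_back(tau);
  }
  return out;
}

} // namespace

// Candidate periods (AR spectral analysis) for a single series.
// The series is demeaned internally; dt is the uniform sampling interval.
// [[Rcpp::export(name = ".arCandidatesCpp")]]
NumericVector arCandidatesCpp(NumericVector x, double dt,
                              double periodMin, double periodMax,
                              int maxOrder, int nFreq) {
  int n = x.size();
  std::vector<double> xd(n);
  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += x[i];
  mu /= n;
  for (int i = 0; i < n; ++i) xd[i] = x[i] - mu;
  std::vector<double> out =
      candidatePeriods(&xd[0], n, dt, periodMin, periodMax, maxOrder, nFreq);
  return wrap(out);
}

// Full ARSER-style pipeline (without the FDR step) for a genes x timepoints
// matrix. Returns per-gene period/amplitude/phase/meanLevel/pvalue plus the
// candidate count and a numeric-failure flag.
// [[Rcpp::export(name = ".arserCoreCpp")]]
List arserCoreCpp(NumericMatrix X, NumericVector times,
                  double periodMin, double periodMax,
                  int maxOrder, int nFreq, double fallbackPeriod,
                  bool refine) {
  const int G = X.nrow(), n = X.ncol();
  if ((int)times.size() != n) stop("times length must match ncol(X)");
  const double dt = times[1] - times[0];
  // precompute spectral tables once
  std::vector<double> omega(nFreq - 1);
  for (int j = 1; j < nFreq; ++j) omega[j - 1] = M_PI * j / nFreq;
  std::vector< std::vector<double> > cosTab(nFreq - 1, std::vector<double>(maxOrder)),
      sinTab(nFreq - 1, std::vector<double>(maxOrder));
  for (int j = 0; j < nFreq - 1; ++j)
    for (int k = 0; k < maxOrder; ++k) {
      cosTab[j][k] = std::cos(omega[j] * (k + 1));
      sinTab[j][k] = std::sin(omega[j] * (k + 1));
    }
  // detrend projection pieces
  double tbar = 0.0;
  for (int i = 0; i < n; ++i) tbar += times[i];
  tbar /= n;
  double stt = 0.0;
  for (int i = 0; i < n; ++i) stt += (times[i] - tbar) * (times[i] - tbar);
  // grid half-width (in hours) used as the refinement bracket near a peak
  NumericVector period(G, NA_REAL), amplitude(G, NA_REAL), phase(G, NA_REAL),
      meanLevel(G), pvalue(G, 1.0);
  IntegerVector nCand(G, 0), flagged(G, 0);
  std::vector<double> xd(n), tvec(n);
  for (int i = 0; i < n; ++i) tvec[i] = times[i];
  for (int g = 0; g < G; ++g) {
    double xbar = 0.0;
    for (int i = 0; i < n; ++i) xbar += X(g, i);
    xbar /= n;
    meanLevel[g] = xbar;
    double sxt = 0.0;
    for (int i = 0; i < n; ++i) sxt += (tvec[i] - tbar) * (X(g, i) - xbar);
    double slope = sxt / stt;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      xd[i] = X(g, i) - xbar - slope * (tvec[i] - tbar);
      ss += xd[i] * xd[i];
    }
    if (!std::isfinite(ss) || ss < 1e-20) {  // flat / degenerate series
      flagged[g] = 1;
      continue;
    }
    // AR spectral candidates
    std::vector<double> c;
    acvf(&xd[0], n, maxOrder, c);
    std::vector<double> sigma2, pacf;
    std::vector< std::vector<double> > rows;
    std::set<int> peaks;
    if (levinson(c, maxOrder, sigma2, pacf, rows)) {
      MethodFit yw = fitYuleWalker(c, maxOrder, n);
      spectralPeaks(yw, omega, cosTab, sinTab, peaks);
      MethodFit bg = fitBurg(&xd[0], n, maxOrder);
      spectralPeaks(bg, omega, cosTab, sinTab, peaks);
      MethodFit ml = fitMle(&xd[0], n, maxOrder, pacf);
      spectralPeaks(ml, omega, cosTab, sinTab, peaks);
    }
    std::vector<double> cand;
    for (std::set<int>::const_iterator it = peaks.begin(); it != peaks.end(); ++it) {
      double tau = 2.0 * M_PI * dt / omega[*it];
      if (tau >= periodMin && tau <= periodMax) cand.push_back(tau);
    }
    bool usedFallback = false;
    if (cand.empty()) { cand.push_back(fallbackPeriod); usedFallback = true; }
    nCand[g] = usedFallback ? 0 : (int)cand.size();
    // harmonic regression (with joint linear baseline) on the original
    // series, per candidate, AIC selection
    std::vector<double> xrow(n);
    for (int i = 0; i < n; ++i) xrow[i] = X(g, i);
    double bestAic = R_PosInf, bestTau = cand[0];
    double mu, bt, a, b, rss;
    for (size_t ci = 0; ci < cand.size(); ++ci) {
      if (!harmonicFit(&xrow[0], &tvec[0], n, cand[ci], &mu, &bt, &a, &b,
                       &rss))
        continue;
      double aic = n * std::log(std::max(rss, 1e-300) / n) + 10.0;
      if (aic < bestAic) { bestAic = aic; bestTau = cand[ci]; }
    }
    if (!std::isfinite(bestAic) && usedFallback) {
      flagged[g] = 1;
      continue;
    }
    double tau = bestTau;
    if (refine && !usedFallback) {
      // bracket: two spectral grid steps on either side (in period units)
      double dOmega = M_PI / nFreq;
      double dTau = tau * tau * dOmega / (2.0 * M_PI * dt);
      double half = std::max(2.0 * dTau, 0.05);
      double lo = std::max(periodMin, tau - half);
      double hi = std::min(periodMax, tau + half);
      if (hi > lo) tau = goldenRefine(&xrow[0], &tvec[0], n, lo, hi);
    }
    if (!harmonicFit(&xrow[0], &tvec[0], n, tau, &mu, &bt, &a, &b, &rss)) {
      flagged[g] = 1;
      continue;
    }
    period[g] = tau;
    amplitude[g] = std::sqrt(a * a + b * b);
    meanLevel[g] = mu;  // baseline value at the window centre
    double ph = (tau / (2.0 * M_PI)) * std::atan2(b, a);
    ph -= tau * std::floor(ph / tau);   // wrap into [0, tau)
    phase[g] = ph;
    // F test of the harmonic terms against the [1, t] baseline;
    // baseline RSS equals the detrended sum of squares
    double rss0 = ss;
    if (rss <= 1e-18 * rss0) {
      pvalue[g] = 0.0;
    } else {
      double F = ((rss0 - rss) / 2.0) / (rss / (n - 4));
      if (F < 0) F = 0;
      pvalue[g] = R::pf(F, 2.0, n - 4.0, 0, 0);
    }
  }
  return List::create(_["period"] = period, _["amplitude"] = amplitude,
                      _["phase"] = phase, _["meanLevel"] = meanLevel,
                      _["pvalue"] = pvalue, _["nCandidates"] = nCand,
                      _["flagged"] = flagged);
}
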