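#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Window motif scoring HMM, computed in "background-ratio" form.
//
// Generative model: scanning left to right with site-entry probability p,
// position i is emitted as a background base with factor (1-p)*bg(x_i|ctx),
// or (if i >= w) as the final base of a motif site with factor
// p * 1/2 * (P_W(x[i-w+1..i]) + P_W(revcomp)).  The forward recursion
//   F(i) = (1-p)*bg(x_i|.)*F(i-1) + [i>=w]*p*e(i)*F(i-w),  F(0)=1
// gives L(p) = F(n).  Dividing through by the running background product
// turns this into
//   G(i) = (1-p)*G(i-1) + p*r(i)*G(i-w),  G(0)=1,
// with r(i) = e(i)/prod(bg over the site span), so that
// log G(n) = log L(p) - log L(0) -- exactly the reported score scale.
//
// The E-step uses the matching backward recursion
//   H(i) = (1-p)*H(i+1) + p*r(i+w)*H(i+w),  H(n)=1,
// and the posterior expected site count
//   n_s = sum_j G(j-w)*H(j)*p*r(j) / G(n);
// every position is either inside a site or a background emission, so
// n_b = n - w*n_s and the M-step is p <- n_s/(n_s + n_b).
//
// The fast path works in plain doubles; 500 bp windows stay far from the
// double range for realistic inputs.  If the forward pass ever leaves
// [1e-280, 1e280], the window is redone in a slow path that rescales by
// powers of 1e250 with per-position integer offsets.

static const double RESCALE = 1e250;
static const double RESCALE_INV = 1e-250;
static const double LOG_RESCALE = std::log(1e250);
static const double OFLOW = 1e280;
static const double UFLOW = 1e-280;
static const double P_BOUNDARY = 1e-8;   // p below this is the 0 boundary

// Conditional background probability per position (order-k Markov chain).
// codes: 0..3 for ACGT, 4 for non-ACGT.  trans: 4^k x 4 matrix, marg: length 4.
// Positions with incomplete or invalid context fall back to the marginal;
// non-ACGT bases emit probability 0.25.
// [[Rcpp::export]]
NumericVector bg_probs_cpp(IntegerVector codes, NumericMatrix trans,
                           NumericVector marg, int k) {
  int n = codes.size();
  NumericVector out(n);
  int pow4k = 1;
  for (int j = 0; j < k; ++j) pow4k *= 4;
  for (int i = 0; i < n; ++i) {
    int b = codes[i];
    if (b >= 4 || b < 0) { out[i] = 0.25; continue; }
    bool ctx_ok = (i >= k);
    int ctx = 0;
    if (ctx_ok) {
      for (int j = i - k; j < i; ++j) {
        int c = codes[j];
        if (c >= 4 || c < 0) { ctx_ok = false; break; }
        ctx = ctx * 4 + c;
      }
    }
    if (k == 0) {
      out[i] = marg[b];
    } else if (ctx_ok && ctx < pow4k) {
      out[i] = trans(ctx, b);
    } else {
      out[i] = marg[b];
    }
  }
  return out;
}

// Strand-averaged motif emission for the site ending at each (1-based)
// position: 1/2 (P_W^+ + P_W^-).  Sites covering a non-ACGT base are
// impossible (emission 0).
// [[Rcpp::export]]
NumericVector motif_emission_cpp(IntegerVector codes, NumericMatrix pwm) {
  int n = codes.size(), w = pwm.ncol();
  NumericVector out(n);
  for (int i = w - 1; i < n; ++i) {
    double fwd = 1.0, rev = 1.0;
    bool ok = true;
    for (int j = 0; j < w; ++j) {
      int b = codes[i - w + 1 + j];
      if (b >= 4 || b < 0) { ok = false; break; }
      fwd *= pwm(b, j);
      rev *= pwm(3 - b, w - 1 - j);
    }
    out[i] = ok ? 0.5 * (fwd + rev) : 0.0;
  }
  return out;
}

// r(i) = e(i) / prod(bg[i-w+1..i]), via a cumulative log-background sum.
// [[Rcpp::export]]
NumericVector site_ratio_cpp(NumericVector emission, NumericVector bgp, int w) {
  int n = emission.size();
  NumericVector out(n);
  std::vector<double> clog(n + 1, 0.0);
  for (int i = 0; i < n; ++i) clog[i + 1] = clog[i] + std::log(bgp[i]);
  for (int i = w - 1; i < n; ++i) {
    if (emission[i] > 0.0)
      out[i] = emission[i] * std::exp(-(clog[i + 1] - clog[i + 1 - w]));
  }
  return out;
}

struct Workspace {
  std::vector<double> G;    // forward values (fast path / slow path)
  std::vector<double> H;    // backward values (slow path only)
  std::vector<int> offF, offB;
};

struct EmResult {
  double score;    // max(0, logL(p_hat) - logL(0))
  double gain;     // logL(p_hat) - logL(0), 0 at the boundary
  double p_hat;
  int iters;
  std::vector<double> trace;  // logL(p_t) - logL(0) per EM iterate
};

// ---------- fast path: plain doubles, no rescaling --------------------

// forward; returns log G(n), or NaN when the range check fails
static double forward_fast(const double* r, int n, int w, double p,
                           std::vector<double>& G) {
  if ((int)G.size() < n + 1) G.resize(n + 1);
  G[0] = 1.0;
  const double q = 1.0 - p;
  double lo = 1.0, hi = 1.0;
  for (int i = 1; i <= n; ++i) {
    double v = q * G[i - 1];
    if (i >= w) {
      double ri = r[i - 1];
      if (ri > 0.0) v += p * ri * G[i - w];
    }
    G[i] = v;
    if (v > hi) hi = v;
    if (v < lo) lo = v;
  }
  if (hi > OFLOW || lo < UFLOW || G[n] <= 0.0) return NA_REAL;
  return std::log(G[n]);
}

// backward sweep fused with the E-step site-count accumulation; G holds
// the forward values.  Returns n_s, or NaN when the range check fails.
static double estep_fast(const double* r, int n, int w, double p,
                         const std::vector<double>& G) {
  // ring buffer of the last w+1 backward values
  std::vector<double> ring(w + 1);
  const double q = 1.0 - p;
  const double denom = G[n];
  double ns = 0.0;
  double hi = 1.0, lo = 1.0;
  // H(i) for i = n..0; ring[i % (w+1)]
  ring[n % (w + 1)] = 1.0;
  for (int i = n - 1; i >= 0; --i) {
    double v = q * ring[(i + 1) % (w + 1)];
    int j = i + w;            // site occupying positions i+1..i+w
    if (j <= n) {
      double rj = r[j - 1];
      if (rj > 0.0) {
        double Hj = ring[j % (w + 1)];
        v += p * rj * Hj;
        ns += G[i] * Hj * p * rj;   // site ending at j starts after i
      }
    }
    ring[i % (w + 1)] = v;
    if (v > hi) hi = v;
    if (v < lo && v > 0.0) lo = v;
  }
  if (hi > OFLOW || lo < UFLOW) return NA_REAL;
  return ns / denom;
}

// ---------- slow path: power-of-1e250 rescaling with offsets ----------

static double forward_slow(const double* r, int n, int w, double p,
                           std::vector<double>& G, std::vector<int>& off) {
  if ((int)G.size() < n + 1) G.resize(n + 1);
  if ((int)off.size() < n + 1) off.resize(n + 1);
  G[0] = 1.0; off[0] = 0;
  const double q = 1.0 - p;
  for (int i = 1; i <= n; ++i) {
    double v = q * G[i - 1];
    int o = off[i - 1];
    if (i >= w && r[i - 1] > 0.0) {
      int o2 = off[i - w];
      double t = p * r[i - 1] * G[i - w];
      if (o2 == o) v += t;
      else if (o2 < o) v += t * std::pow(RESCALE, o2 - o);
      else { v = v * std::pow(RESCALE, o - o2) + t; o = o2; }
    }
    if (v > RESCALE) { v *= RESCALE_INV; o += 1; }
    else if (v > 0.0 && v < RESCALE_INV) { v *= RESCALE; o -= 1; }
    G[i] = v; off[i] = o;
  }
  if (G[n] <= 0.0) return R_NegInf;
  return std::log(G[n]) + off[n] * LOG_RESCALE;
}

static double estep_slow(const double* r, int n, int w, double p,
                         const std::vector<double>& G,
                         const std::vector<int>& offF,
                         std::vector<double>& H, std::vector<int>& offB) {
  if ((int)H.size() < n + 1) H.resize(n + 1);
  if ((int)offB.size() < n + 1) offB.resize(n + 1);
  const double q = 1.0 - p;
  H[n] = 1.0; offB[n] = 0;
  for (int i = n - 1; i >= 0; --i) {
    double v = q * H[i + 1];
    int o = offB[i + 1];
    if (i + w <= n && r[i + w - 1] > 0.0) {
      int o2 = offB[i + w];
      double t = p * r[i + w - 1] * H[i + w];
      if (o2 == o) v += t;
      else if (o2 < o) v += t * std::pow(RESCALE, o2 - o);
      else { v = v * std::pow(RESCALE, o - o2) + t; o = o2; }
    }
    if (v > RESCALE) { v *= RESCALE_INV; o += 1; }
    else if (v > 0.0 && v < RESCALE_INV) { v *= RESCALE; o -= 1; }
    H[i] = v; offB[i] = o;
  }
  double ns = 0.0;
  const double denom = G[n];
  for (int j = w; j <= n; ++j) {
    if (r[j - 1] <= 0.0) continue;
    double term = G[j - w] * H[j] * p * r[j - 1] / denom;
    int d = offF[j - w] + offB[j] - offF[n];
    if (d != 0) term *= std::pow(RESCALE, d);
    ns += term;
  }
  return ns;
}

static EmResult stubb_em_core(const double* r, int n, int w, double p_init,
                              double p_max, double tol, int max_iter,
                              bool keep_trace, Workspace& ws) {
  EmResult res;
  bool any_site = false;
  for (int i = w - 1; i < n; ++i) if (r[i] > 0.0) { any_site = true; break; }
  if (n == 0 || !any_site) {
    res.score = 0.0; res.gain = 0.0; res.p_hat = 0.0; res.iters = 0;
    if (keep_trace) res.trace.push_back(0.0);
    return res;
  }
  double p = std::min(p_init, p_max);
  if (p <= 0.0) p = P_BOUNDARY * 10;
  double prev_gain = R_NegInf;
  bool slow = false;
  int it = 0;
  for (; it < max_iter; ++it) {
    double gain, ns;
    if (!slow) {
      gain = forward_fast(r, n, w, p, ws.G);
      if (ISNAN(gain)) slow = true;
    }
    if (slow) gain = forward_slow(r, n, w, p, ws.G, ws.offF);
    if (keep_trace) res.trace.push_back(gain);
    if (std::isfinite(prev_gain) && std::fabs(gain - prev_gain) < tol) {
      prev_gain = gain;
      break;
    }
    prev_gain = gain;
    if (!slow) {
      ns = estep_fast(r, n, w, p, ws.G);
      if (ISNAN(ns)) {
        slow = true;
        forward_slow(r, n, w, p, ws.G, ws.offF);
      }
    }
    if (slow) ns = estep_slow(r, n, w, p, ws.G, ws.offF, ws.H, ws.offB);
    double nb = (double)n - (double)w * ns;
    double p_new = (ns + nb > 0.0) ? ns / (ns + nb) : 0.0;
    if (p_new > p_max) p_new = p_max;
    if (p_new < 0.0) p_new = 0.0;
    if (p_new < P_BOUNDARY) {      // boundary: logL(0) - logL(0) = 0
      p = 0.0;
      prev_gain = 0.0;
      if (keep_trace) res.trace.push_back(0.0);
      ++it;
      break;
    }
    if (p_new == p) { ++it; break; }
    p = p_new;
  }
  res.iters = it;
  if (std::isfinite(prev_gain) && prev_gain > 0.0 && p > 0.0) {
    res.score = prev_gain;
    res.gain = prev_gain;
    res.p_hat = p;
  } else {
    // likelihood maximised at (or indistinguishable from) the p=0 boundary
    res.score = 0.0;
    res.gain = 0.0;
    res.p_hat = 0.0;
  }
  return res;
}

// Fit the site-entry probability by EM on one window, given the
// precomputed site/background ratio vector r (zero where no site can end).
// [[Rcpp::export]]
List stubb_em_cpp(NumericVector r, int w, double p_init, double p_max,
                  double tol, int max_iter, bool keep_trace) {
  Workspace ws;
  EmResult res = stubb_em_core(REAL(r), r.size(), w, p_init, p_max, tol,
                               max_iter, keep_trace, ws);
  return List::create(_["score"] = res.score, _["p_hat"] = res.p_hat,
                      _["gain"] = res.gain, _["iters"] = res.iters,
                      _["trace"] = NumericVector(res.trace.begin(),
                                                 res.trace.end()));
}

// log L(p) - log L(0) at a fixed p (used by likelihood-equivalence tests).
// [[Rcpp::export]]
double stubb_loglik_ratio_cpp(NumericVector r, int w, double p) {
  Workspace ws;
  double g = forward_fast(REAL(r), r.size(), w, p, ws.G);
  if (ISNAN(g)) g = forward_slow(REAL(r), r.size(), w, p, ws.G, ws.offF);
  return g;
}

// Batch scorer: windows are slices [starts[i], starts[i]+win_len) (0-based)
// of a chromosome-wide ratio vector.  Ratio entries whose site would start
// before the window are zeroed, giving isolated-window semantics.
// [[Rcpp::export]]
List stubb_windows_cpp(NumericVector r, IntegerVector starts, int win_len,
                       int w, double p_init, double p_max, double tol,
                       int max_iter) {
  int m = starts.size(), n_total = r.size();
  NumericVector score(m), p_hat(m);
  IntegerVector iters(m);
  std::vector<double> buf(win_len);
  Workspace ws;
  for (int i = 0; i < m; ++i) {
    int s = starts[i];
    int len = std::min(win_len, n_total - s);
    if (len < 0) len = 0;
    for (int j = 0; j < len; ++j)
      buf[j] = (j >= w - 1) ? r[s + j] : 0.0;
    EmResult res = stubb_em_core(buf.data(), len, w, p_init, p_max, tol,
                                 max_iter, false, ws);
    score[i] = res.score; p_hat[i] = res.p_hat; iters[i] = res.iters;
  }
  return List::create(_["score"] = score, _["p_hat"] = p_hat,
                      _["iters"] = iters);
}
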