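// Inner loops of the speckle-tracking pipeline: RF frame rendering,
// zero-normalized cross-correlation over lag grids, iterative Bayesian
// regularization of correlation surfaces, 2-D sinc subsample peak
// refinement, and the windowed least-squares strain estimator.
// R wrappers own all validation; these assume well-formed inputs.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sum of Gaussian-cosine (axial) x Gaussian (lateral) point responses.
// kRF is the pulse-echo spatial angular frequency 4*pi*fc/c so that the
// axial oscillation, read as echo time t = 2z/c, sits at fc.
// [[Rcpp::export]]
NumericMatrix cpp_render_frame(NumericMatrix scat, NumericVector axPos,
                               NumericVector latPos, double sigmaA,
                               double sigmaL, double kRF) {
  const int nAx = axPos.size(), nLat = latPos.size(), nS = scat.nrow();
  NumericMatrix out(nAx, nLat);
  const double dzA = nAx > 1 ? axPos[1] - axPos[0] : 1.0;
  const double dzL = nLat > 1 ? latPos[1] - latPos[0] : 1.0;
  const double winA = 4.0 * sigmaA, winL = 4.0 * sigmaL;
  for (int s = 0; s < nS; ++s) {
    const double za = scat(s, 0), xl = scat(s, 1), amp = scat(s, 2);
    int i0 = (int)std::ceil((za - winA - axPos[0]) / dzA);
    int i1 = (int)std::floor((za + winA - axPos[0]) / dzA);
    int j0 = (int)std::ceil((xl - winL - latPos[0]) / dzL);
    int j1 = (int)std::floor((xl + winL - latPos[0]) / dzL);
    if (i0 < 0) i0 = 0; if (i1 > nAx - 1) i1 = nAx - 1;
    if (j0 < 0) j0 = 0; if (j1 > nLat - 1) j1 = nLat - 1;
    if (i0 > i1 || j0 > j1) continue;
    for (int j = j0; j <= j1; ++j) {
      const double dl = latPos[j] - xl;
      const double wl = std::exp(-dl * dl / (2.0 * sigmaL * sigmaL));
      for (int i = i0; i <= i1; ++i) {
        const double da = axPos[i] - za;
        out(i, j) += amp * wl *
          std::exp(-da * da / (2.0 * sigmaA * sigmaA)) * std::cos(kRF * da);
      }
    }
  }
  return out;
}

static inline double zncc(const double* a, const double* b, int n) {
  double ma = 0, mb = 0;
  for (int i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double sab = 0, saa = 0, sbb = 0;
  for (int i = 0; i < n; ++i) {
    const double da = a[i] - ma, db = b[i] - mb;
    sab += da * db; saa += da * da; sbb += db * db;
  }
  if (saa <= 0.0 || sbb <= 0.0) return NA_REAL;
  return sab / std::sqrt(saa * sbb);
}

// Full NCC surface of `ref` against every admissible placement in `region`.
// [[Rcpp::export]]
NumericMatrix cpp_ncc_surface(NumericMatrix ref, NumericMatrix region) {
  const int kr = ref.nrow(), kc = ref.ncol();
  const int nr = region.nrow() - kr + 1, nc = region.ncol() - kc + 1;
  NumericMatrix out(nr, nc);
  const int n = kr * kc;
  std::vector<double> a(n), b(n);
  int t = 0;
  for (int j = 0; j < kc; ++j)
    for (int i = 0; i < kr; ++i) a[t++] = ref(i, j);
  for (int dc = 0; dc < nc; ++dc) {
    for (int dr = 0; dr < nr; ++dr) {
      t = 0;
      for (int j = 0; j < kc; ++j)
        for (int i = 0; i < kr; ++i) b[t++] = region(i + dr, j + dc);
      out(dr, dc) = zncc(a.data(), b.data(), n);
    }
  }
  return out;
}

// NCC surfaces for a grid of kernels between two frames.
// rows/cols: 0-based node centers in frame a; prior: integer lag offsets
// (rows x 2) added to the search center in frame b.  khA/khL: kernel half
// spans; mA/mL: search margins (surface is (2mA+1) x (2mL+1) per node).
// Out-of-frame lags are NA.  flag: 0 ok, 1 zero-variance reference.
// Search-block mean/variance come from summed-area tables of b and b^2,
// so each lag costs one pass for the cross term only.
// [[Rcpp::export]]
List cpp_ncc_field(NumericMatrix a, NumericMatrix b, IntegerVector rows,
                   IntegerVector cols, IntegerMatrix prior, int khA, int khL,
                   int mA, int mL) {
  const int nNode = rows.size();
  const int nr = b.nrow(), nc = b.ncol();
  const int sA = 2 * mA + 1, sL = 2 * mL + 1;
  const int kr = 2 * khA + 1, kc = 2 * khL + 1, n = kr * kc;
  NumericVector surf(Dimension(sA, sL, nNode));
  std::fill(surf.begin(), surf.end(), NA_REAL);
  IntegerVector flag(nNode);
  // summed-area tables, (nr + 1) x (nc + 1), column-major
  const int tr = nr + 1;
  std::vector<double> S1((size_t)tr * (nc + 1), 0.0);
  std::vector<double> S2((size_t)tr * (nc + 1), 0.0);
  for (int j = 0; j < nc; ++j) {
    double c1 = 0, c2 = 0;
    for (int i = 0; i < nr; ++i) {
      const double v = b(i, j);
      c1 += v; c2 += v * v;
      S1[(i + 1) + (size_t)tr * (j + 1)] = S1[(i + 1) + (size_t)tr * j] + c1;
      S2[(i + 1) + (size_t)tr * (j + 1)] = S2[(i + 1) + (size_t)tr * j] + c2;
    }
  }
  auto rectSum = [&](const std::vector<double>& S, int r0, int c0) {
    // kr x kc rectangle with top-left (r0, c0)
    return S[(r0 + kr) + (size_t)tr * (c0 + kc)] -
           S[r0 + (size_t)tr * (c0 + kc)] -
           S[(r0 + kr) + (size_t)tr * c0] + S[r0 + (size_t)tr * c0];
  };
  const double* bp = b.begin();
  std::vector<double> a0(n);
  for (int p = 0; p < nNode; ++p) {
    const int r = rows[p], c = cols[p];
    int t = 0;
    double mean = 0;
    for (int j = c - khL; j <= c + khL; ++j)
      for (int i = r - khA; i <= r + khA; ++i) {
        a0[t] = a(i, j); mean += a0[t]; ++t;
      }
    mean /= n;
    double saa = 0;
    for (int i = 0; i < n; ++i) { a0[i] -= mean; saa += a0[i] * a0[i]; }
    if (saa <= 0.0) { flag[p] = 1; continue; }
    for (int dl = -mL; dl <= mL; ++dl) {
      for (int da = -mA; da <= mA; ++da) {
        const int rr = r + prior(p, 0) + da, cc = c + prior(p, 1) + dl;
        const int r0 = rr - khA, c0 = cc - khL;
        if (r0 < 0 || rr + khA >= nr || c0 < 0 || cc + khL >= nc) continue;
        // cross term sum(a0 * b) over the block (sum(a0) == 0)
        double cross = 0;
        t = 0;
        for (int j = c0; j < c0 + kc; ++j) {
          const double* col = bp + (size_t)nr * j + r0;
          for (int i = 0; i < kr; ++i) cross += a0[t++] * col[i];
        }
        const double sb = rectSum(S1, r0, c0);
        const double sbb = rectSum(S2, r0, c0) - sb * sb / n;
        surf[(da + mA) + sA * (dl + mL) + (size_t)sA * sL * p] =
          (sbb <= 0.0) ? NA_REAL : cross / std::sqrt(saa * sbb);
      }
    }
  }
  return List::create(_["surfaces"] = surf, _["flag"] = flag);
}

// Separable zero-padded Gaussian convolution of one lag surface.
static void conv_gauss(const double* in, double* out, int nA, int nL,
                       const std::vector<double>& g, int rad,
                       std::vector<double>& tmp) {
  for (int j = 0; j < nL; ++j) {       // axial pass
    for (int i = 0; i < nA; ++i) {
      double s = 0;
      for (int d = -rad; d <= rad; ++d) {
        const int ii = i + d;
        if (ii >= 0 && ii < nA) s += g[d + rad] * in[ii + nA * j];
      }
      tmp[i + nA * j] = s;
    }
  }
  for (int j = 0; j < nL; ++j) {       // lateral pass
    for (int i = 0; i < nA; ++i) {
      double s = 0;
      for (int d = -rad; d <= rad; ++d) {
        const int jj = j + d;
        if (jj >= 0 && jj < nL) s += g[d + rad] * tmp[i + nA * jj];
      }
      out[i + nA * j] = s;
    }
  }
}

// Iterative Bayesian regularization on a node grid (nr x nc, column-major
// node index).  lik: normalized likelihood surfaces (nA x nL x nNode).
// iters: per-node iteration budget.  Synchronous update: posterior of node
// p at step k+1 is proportional to lik_p times the product over available
// 4-neighbours of their step-k posterior convolved with a Gaussian lag
// compatibility kernel; products run in log space.
// [[Rcpp::export]]
List cpp_abr(NumericVector lik, int nr, int nc, IntegerVector iters,
             double sigma) {
  IntegerVector dims = lik.attr("dim");
  const int nA = dims[0], nL = dims[1], nNode = dims[2], sz = nA * nL;
  const int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> g(2 * rad + 1);
  double gs = 0;
  for (int d = -rad; d <= rad; ++d) {
    g[d + rad] = std::exp(-0.5 * d * d / (sigma * sigma)); gs += g[d + rad];
  }
  for (double& v : g) v /= gs;
  const double eps = 1e-12;
  NumericVector cur = clone(lik);
  int maxIt = 0;
  for (int p = 0; p < nNode; ++p) if (iters[p] > maxIt) maxIt = iters[p];
  IntegerVector applied(nNode);
  if (maxIt == 0 || nNode == 1)
    return List::create(_["posterior"] = cur, _["applied"] = applied);
  NumericVector nxt(cur.size());
  std::vector<double> cv(sz), tmp(sz), logs(sz);
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  for (int k = 0; k < maxIt; ++k) {
    for (int p = 0; p < nNode; ++p) {
      double* outp = &nxt[sz * p];
      const double* likp = &lik[sz * p];
      if (iters[p] <= k) {
        std::copy(&cur[sz * p], &cur[sz * p] + sz, outp);
        continue;
      }
      for (int t = 0; t < sz; ++t)
        logs[t] = std::log(likp[t] > eps ? likp[t] : eps);
      const int r = p % nr, c = p / nr;
      for (int nb = 0; nb < 4; ++nb) {
        const int rr = r + dr[nb], cc = c + dc[nb];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const int q = rr + nr * cc;
        conv_gauss(&cur[sz * q], cv.data(), nA, nL, g, rad, tmp);
        for (int t = 0; t < sz; ++t)
          logs[t] += std::log(cv[t] > eps ? cv[t] : eps);
      }
      double mx = logs[0];
      for (int t = 1; t < sz; ++t) if (logs[t] > mx) mx = logs[t];
      double tot = 0;
      for (int t = 0; t < sz; ++t) { outp[t] = std::exp(logs[t] - mx); tot += outp[t]; }
      for (int t = 0; t < sz; ++t) outp[t] /= tot;
      applied[p] = k + 1;
    }
    std::swap(cur, nxt);
  }
  return List::create(_["posterior"] = cur, _["applied"] = applied);
}

// Component-wise 2-D median with window truncation at the edges.
// halfR/halfC: window half spans in nodes.  NA entries are ignored.
// [[Rcpp::export]]
NumericMatrix cpp_median2d(NumericMatrix x, int halfR, int halfC) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((2 * halfR + 1) * (2 * halfC + 1));
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int jj = std::max(0, j - halfC); jj <= std::min(nc - 1, j + halfC); ++jj)
        for (int ii = std::max(0, i - halfR); ii <= std::min(nr - 1, i + halfR); ++ii)
          if (!ISNAN(x(ii, jj))) buf.push_back(x(ii, jj));
      if (buf.empty()) { out(i, j) = NA_REAL; continue; }
      std::sort(buf.begin(), buf.end());
      const size_t n = buf.size();
      out(i, j) = (n % 2 == 1) ? buf[n / 2]
                               : 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
    }
  }
  return out;
}

// Normalized likelihood stack from NCC surfaces: clamp negatives and NA
// to zero, raise to gamma, normalize each surface to unit mass (uniform
// when degenerate).
// [[Rcpp::export]]
NumericVector cpp_lik_from_ncc(NumericVector surf, double gamma) {
  IntegerVector dims = surf.attr("dim");
  const int sz = dims[0] * dims[1], nNode = dims[2];
  NumericVector out(surf.size());
  out.attr("dim") = dims;
  for (int p = 0; p < nNode; ++p) {
    const double* ss = &surf[(size_t)sz * p];
    double* oo = &out[(size_t)sz * p];
    double tot = 0;
    for (int t = 0; t < sz; ++t) {
      double v = (ISNAN(ss[t]) || ss[t] <= 0) ? 0.0 : std::pow(ss[t], gamma);
      oo[t] = v; tot += v;
    }
    if (tot <= 0) for (int t = 0; t < sz; ++t) oo[t] = 1.0 / sz;
    else for (int t = 0; t < sz; ++t) oo[t] /= tot;
  }
  return out;
}

// sinc weights w[m] = sinc(X - m), m = 0..len-1, using one sin() call:
// sin(pi (X - m)) = (-1)^m sin(pi X).
static void sincWeights(double X, int len, double* w) {
  const double s = std::sin(M_PI * X);
  for (int m = 0; m < len; ++m) {
    const double d = X - m;
    if (std::fabs(d) < 1e-9) w[m] = 1.0;
    else w[m] = ((m & 1) ? -s : s) / (M_PI * d);
  }
}

// Whittaker (2-D sinc) interpolation of `surf` around the integer peak
// (pr, pc), argmax located by staged grid refinement down to `res` lags.
// Returns fractional offsets (dA, dL) in [-1, 1].
static void sincPeakCore(const double* surf, int nA, int nL, int pr, int pc,
                         int window, double res, int lateralMode,
                         double* out) {
  const int r0 = std::max(0, pr - window), r1 = std::min(nA - 1, pr + window);
  const int c0 = std::max(0, pc - window), c1 = std::min(nL - 1, pc + window);
  const int wr = r1 - r0 + 1, wc = c1 - c0 + 1;
  std::vector<double> S(wr * wc);
  // subtract the window baseline: the truncated sinc expansion of a
  // constant pedestal ripples with maxima at the integer samples, biasing
  // broad peaks toward integer lags; the remaining bump decays within the
  // window and interpolates cleanly
  double mn = 1e300;
  for (int j = 0; j < wc; ++j)
    for (int i = 0; i < wr; ++i) {
      const double v = surf[(r0 + i) + nA * (c0 + j)];
      if (!ISNAN(v) && v < mn) mn = v;
    }
  if (mn == 1e300) mn = 0.0;
  for (int j = 0; j < wc; ++j)
    for (int i = 0; i < wr; ++i) {
      const double v = surf[(r0 + i) + nA * (c0 + j)];
      S[i + wr * j] = ISNAN(v) ? 0.0 : v - mn;
    }
  double bx = 0.0, by = 0.0;         // offsets relative to (pr, pc)
  double span = 1.0, step = 0.25;
  std::vector<double> wy(wc), gm(wr), xs, WX;
  while (true) {
    double best = -1e300, bbx = bx, bby = by;
    const int nsteps = (int)std::round(2.0 * span / step);
    xs.clear();
    for (int jx = 0; jx <= nsteps; ++jx) {
      const double x = bx - span + jx * step;
      if (x >= -1.0 && x <= 1.0) xs.push_back(x);
    }
    WX.resize(xs.size() * wr);       // sinc weight table, one row per x
    for (size_t jx = 0; jx < xs.size(); ++jx)
      sincWeights(pr - r0 + xs[jx], wr, &WX[jx * wr]);
    for (int jy = 0; jy <= nsteps; ++jy) {
      const double y = by - span + jy * step;
      if (y < -1.0 || y > 1.0) continue;
      sincWeights(pc - c0 + y, wc, wy.data());
      for (int m = 0; m < wr; ++m) {
        double s = 0;
        for (int n = 0; n < wc; ++n) s += S[m + wr * n] * wy[n];
        gm[m] = s;
      }
      for (size_t jx = 0; jx < xs.size(); ++jx) {
        const double* wx = &WX[jx * wr];
        double f = 0;
        for (int m = 0; m < wr; ++m) f += gm[m] * wx[m];
        if (f > best) { best = f; bbx = xs[jx]; bby = y; }
      }
    }
    bx = bbx; by = bby;
    if (step <= res) break;
    span = 2.0 * step;
    step = std::max(res, step / 5.0);
  }
  // Lateral offset re-estimated on 1-D lag profiles through the peak row
  // (optionally pooled with the carrier-in-phase rows 4 samples away):
  // at fractional axial coordinates the 2-D expansion mixes adjacent
  // carrier rows through negative sinc lobes, biasing broad lateral peaks
  // towards integer lags; single-row profiles avoid the ripple at the
  // price of more speckle noise.
  out[0] = bx;
  out[1] = by;                       // joint
  out[2] = out[3] = by;
  if (lateralMode == 0) return;      // profile variants not needed
  const int prow = pr - r0;
  std::vector<double> prof(wc, 0.0), prof3(wc, 0.0);
  for (int n = 0; n < wc; ++n) {
    prof[n] = S[prow + wr * n];
    prof3[n] = prof[n];
    if (prow - 4 >= 0) prof3[n] += 0.5 * S[(prow - 4) + wr * n];
    if (prow + 4 < wr) prof3[n] += 0.5 * S[(prow + 4) + wr * n];
  }
  auto refine1d = [&](std::vector<double>& pr1) {
    double mn2 = 1e300;
    for (int n = 0; n < wc; ++n) if (pr1[n] < mn2) mn2 = pr1[n];
    for (int n = 0; n < wc; ++n) pr1[n] -= mn2;
    double ly = 0.0, sp = 1.0, st = 0.25;
    while (true) {
      double best = -1e300, bb = ly;
      const int ns = (int)std::round(2.0 * sp / st);
      for (int jy = 0; jy <= ns; ++jy) {
        const double y = ly - sp + jy * st;
        if (y < -1.0 || y > 1.0) continue;
        sincWeights(pc - c0 + y, wc, wy.data());
        double f = 0;
        for (int n = 0; n < wc; ++n) f += pr1[n] * wy[n];
        if (f > best) { best = f; bb = y; }
      }
      ly = bb;
      if (st <= res) break;
      sp = 2.0 * st;
      st = std::max(res, st / 5.0);
    }
    return ly;
  };
  out[2] = refine1d(prof);           // peak-row profile
  out[3] = refine1d(prof3);          // in-phase pooled profile
}

// [[Rcpp::export]]
NumericVector cpp_sinc_peak(NumericMatrix surf, int pr, int pc, int window,
                            double res) {
  NumericVector out(4);
  sincPeakCore(surf.begin(), surf.nrow(), surf.ncol(), pr, pc, window, res,
               1, out.begin());
  return out;
}

// Per-surface quality of a stack: peak value and peak-to-mean SNR of the
// nonnegative-shifted surface (NA lags ignored; constant surface SNR 1).
// [[Rcpp::export]]
List cpp_surface_quality(NumericVector surf) {
  IntegerVector dims = surf.attr("dim");
  const int sz = dims[0] * dims[1], nNode = dims[2];
  NumericVector peak(nNode), snr(nNode);
  for (int p = 0; p < nNode; ++p) {
    const double* ss = &surf[(size_t)sz * p];
    double mx = -1e300, mn = 1e300, sum = 0;
    int n = 0;
    for (int t = 0; t < sz; ++t) {
      if (ISNAN(ss[t])) continue;
      if (ss[t] > mx) mx = ss[t];
      if (ss[t] < mn) mn = ss[t];
      sum += ss[t]; ++n;
    }
    if (n == 0) { peak[p] = NA_REAL; snr[p] = NA_REAL; continue; }
    peak[p] = mx;
    const double shift = mn < 0 ? -mn : 0;
    const double mean = sum / n + shift;
    snr[p] = (mean <= 0) ? 1.0 : (mx + shift) / mean;
  }
  return List::create(_["peak"] = peak, _["snr"] = snr);
}

// Peak extraction for a stack of surfaces: integer argmax of `post` with
// deterministic tie-breaking (smallest lag magnitude, then axial, then
// lateral), 2-D sinc refinement on `surf` for interior peaks.  Lags are
// relative to the surface center (margins mA, mL).  flag: 0 ok, 1 no
// finite value, 2 border peak (integer lag kept).
// lateralMode: 0 joint 2-D argmax, 1 peak-row profile, 2 in-phase pooled
// profile, 3 mean of joint and peak-row.
// [[Rcpp::export]]
List cpp_extract_peaks(NumericVector post, NumericVector surf, int mA,
                       int mL, int window, double res, int lateralMode) {
  IntegerVector dims = post.attr("dim");
  const int sA = dims[0], sL = dims[1], nNode = dims[2], sz = sA * sL;
  NumericVector lagA(nNode), lagL(nNode), peak(nNode);
  IntegerVector flag(nNode);
  double fr[4];
  for (int p = 0; p < nNode; ++p) {
    const double* ps = &post[(size_t)sz * p];
    const double* ss = &surf[(size_t)sz * p];
    double mx = -1e300;
    for (int t = 0; t < sz; ++t)
      if (!ISNAN(ps[t]) && ps[t] > mx) mx = ps[t];
    if (mx == -1e300) {
      lagA[p] = NA_REAL; lagL[p] = NA_REAL; peak[p] = NA_REAL;
      flag[p] = 1;
      continue;
    }
    int br = -1, bc = -1;
    double bestKey0 = 0, bestKey1 = 0, bestKey2 = 0;
    for (int j = 0; j < sL; ++j)
      for (int i = 0; i < sA; ++i) {
        const double v = ps[i + sA * j];
        if (ISNAN(v) || v != mx) continue;
        const double la = i - mA, ll = j - mL;
        const double k0 = la * la + ll * ll;
        if (br < 0 || k0 < bestKey0 ||
            (k0 == bestKey0 && (la < bestKey1 ||
                                (la == bestKey1 && ll < bestKey2)))) {
          br = i; bc = j; bestKey0 = k0; bestKey1 = la; bestKey2 = ll;
        }
      }
    peak[p] = ss[br + sA * bc];
    const bool border = br == 0 || br == sA - 1 || bc == 0 || bc == sL - 1;
    if (border) {
      flag[p] = 2;
      lagA[p] = br - mA; lagL[p] = bc - mL;
    } else if (peak[p] >= 1.0 - 1e-12) {
      // perfect match: alignment is exact, no subsample correction
      lagA[p] = br - mA;
      lagL[p] = bc - mL;
    } else {
      sincPeakCore(ss, sA, sL, br, bc, window, res, lateralMode, fr);
      lagA[p] = br - mA + fr[0];
      double ly = fr[1];
      if (lateralMode == 1) ly = fr[2];
      else if (lateralMode == 2) ly = fr[3];
      else if (lateralMode == 3) ly = 0.5 * (fr[1] + fr[2]);
      lagL[p] = bc - mL + ly;
    }
  }
  return List::create(_["lagA"] = lagA, _["lagL"] = lagL,
                      _["peak"] = peak, _["flag"] = flag);
}

// Windowed plane fit of accumulated displacements over mesh nodes.
// posA/posL/uA/uL: nT x nC reference positions and displacements (meters);
// circumferential index wraps.  halfAx/halfLat: physical window half-sizes;
// radT/radC: index search radii guaranteed to cover the window.
// Returns displacement-gradient components and a validity flag.
// [[Rcpp::export]]
List cpp_lsq_strain(NumericMatrix posA, NumericMatrix posL, NumericMatrix uA,
                    NumericMatrix uL, LogicalMatrix ok, double halfAx,
                    double halfLat, int radT, int radC) {
  const int nT = posA.nrow(), nC = posA.ncol();
  NumericMatrix gaa(nT, nC), gal(nT, nC), gla(nT, nC), gll(nT, nC);
  LogicalMatrix valid(nT, nC);
  for (int j = 0; j < nC; ++j) {
    for (int i = 0; i < nT; ++i) {
      const double x0 = posA(i, j), y0 = posL(i, j);
      double n = 0, Sx = 0, Sy = 0, Sxx = 0, Sxy = 0, Syy = 0;
      double SuA = 0, SxuA = 0, SyuA = 0, SuL = 0, SxuL = 0, SyuL = 0;
      for (int dj = -radC; dj <= radC; ++dj) {
        int jj = (j + dj) % nC; if (jj < 0) jj += nC;
        for (int di = -radT; di <= radT; ++di) {
          const int ii = i + di;
          if (ii < 0 || ii >= nT || !ok(ii, jj)) continue;
          const double dx = posA(ii, jj) - x0, dy = posL(ii, jj) - y0;
          if (std::fabs(dx) > halfAx || std::fabs(dy) > halfLat) continue;
          n += 1; Sx += dx; Sy += dy;
          Sxx += dx * dx; Sxy += dx * dy; Syy += dy * dy;
          SuA += uA(ii, jj); SxuA += dx * uA(ii, jj); SyuA += dy * uA(ii, jj);
          SuL += uL(ii, jj); SxuL += dx * uL(ii, jj); SyuL += dy * uL(ii, jj);
        }
      }
      // 3x3 normal equations via cofactor expansion
      const double A11 = Sxx * Syy - Sxy * Sxy;
      const double A12 = Sy * Sxy - Sx * Syy;
      const double A13 = Sx * Sxy - Sy * Sxx;
      const double det = n * A11 + Sx * A12 + Sy * A13;
      double scale = Sxx + Syy;
      if (n < 3 || scale <= 0 || std::fabs(det) < 1e-12 * scale * scale) {
        valid(i, j) = false; continue;
      }
      const double A22 = n * Syy - Sy * Sy, A23 = Sx * Sy - n * Sxy;
      const double A33 = n * Sxx - Sx * Sx;
      gaa(i, j) = (A12 * SuA + A22 * SxuA + A23 * SyuA) / det;
      gal(i, j) = (A13 * SuA + A23 * SxuA + A33 * SyuA) / det;
      gla(i, j) = (A12 * SuL + A22 * SxuL + A23 * SyuL) / det;
      gll(i, j) = (A13 * SuL + A23 * SxuL + A33 * SyuL) / det;
      valid(i, j) = true;
    }
  }
  return List::create(_["duA_dA"] = gaa, _["duA_dL"] = gal,
                      _["duL_dA"] = gla, _["duL_dL"] = gll,
                      _["valid"] = valid);
}
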