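// Windowed texture features for IVUS plaque pixels.
//
// Conventions (documented in the R-level help and the methods vignette):
//  - reflect padding is edge-excluding: index -1 maps to +1, n maps to n-2
//  - GLCM/GLRLM quantization: uniform bins of [0,255], bin = floor(g*Ng/256),
//    clamped to Ng-1; formulas weight by the 1-based bin index
//  - GLCM offset for angle t pairs (r,c) with (r+dr, c+dc):
//      0 -> (0,+d), 45 -> (-d,+d), 90 -> (-d,0), 135 -> (-d,-d)
//    single direction unless `symmetric`; probabilities normalized over
//    accumulated pairs; 0*log(0) := 0, natural log throughout
//  - LBP neighbor order: clockwise from the top-left neighbor, bit n
//    weighted 2^n in acquisition order

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

static inline int quantize(double g, int ng) {
  int b = (int)std::floor(g * ng / 256.0);
  if (b < 0) b = 0;
  if (b >= ng) b = ng - 1;
  return b;
}

static void theta_offset(int theta, int d, int &dr, int &dc) {
  switch (theta) {
  case 0:   dr = 0;  dc = d;  break;
  case 45:  dr = -d; dc = d;  break;
  case 90:  dr = -d; dc = 0;  break;
  case 135: dr = -d; dc = -d; break;
  default: stop("angle must be one of 0, 45, 90, 135 degrees");
  }
}

// ---- first-order statistics ------------------------------------------------

// population moments over all window pixels; excess kurtosis; zero-variance
// windows get skewness = kurtosis = 0 by convention
static void fos_core(const double *w, int n, double *out5) {
  double m = 0.0;
  for (int i = 0; i < n; ++i) m += w[i];
  m /= n;
  double v = 0.0, s3 = 0.0, s4 = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = w[i] - m;
    v += d * d;
  }
  v /= n;
  double sd = std::sqrt(v);
  double sk = 0.0, ku = 0.0;
  if (v > 0.0) {
    for (int i = 0; i < n; ++i) {
      double z = (w[i] - m) / sd;
      s3 += z * z * z;
      s4 += z * z * z * z;
    }
    sk = s3 / n;
    ku = s4 / n - 3.0;
  }
  out5[0] = m; out5[1] = v; out5[2] = sd; out5[3] = ku; out5[4] = sk;
}

// ---- GLCM (17 Haralick-style features) -------------------------------------

// out17 order: autocorrelation, contrast, cluster prominence, cluster shade,
// dissimilarity, energy, entropy, homogeneity, maximum probability, variance,
// sum average, sum variance, sum entropy, difference variance,
// difference entropy, IMC1, normalized IDM
static bool glcm_core(const double *w, int K, int d, int theta, int ng,
                      bool symmetric, double *out17) {
  int dr, dc;
  theta_offset(theta, d, dr, dc);
  std::vector<double> p(ng * ng, 0.0);
  double total = 0.0;
  for (int r = 0; r < K; ++r) {
    for (int c = 0; c < K; ++c) {
      int r2 = r + dr, c2 = c + dc;
      if (r2 < 0 || r2 >= K || c2 < 0 || c2 >= K) continue;
      int i = quantize(w[r * K + c], ng);
      int j = quantize(w[r2 * K + c2], ng);
      p[i * ng + j] += 1.0;
      total += 1.0;
      if (symmetric) { p[j * ng + i] += 1.0; total += 1.0; }
    }
  }
  if (total == 0.0) return false;
  for (int k = 0; k < ng * ng; ++k) p[k] /= total;

  std::vector<double> px(ng, 0.0), py(ng, 0.0);
  std::vector<double> psum(2 * ng + 1, 0.0);   // index k = i + j, 1-based i,j
  std::vector<double> pdiff(ng, 0.0);          // index k = |i - j|
  for (int i = 0; i < ng; ++i)
    for (int j = 0; j < ng; ++j) {
      double v = p[i * ng + j];
      if (v == 0.0) continue;
      px[i] += v; py[j] += v;
      psum[(i + 1) + (j + 1)] += v;
      pdiff[std::abs(i - j)] += v;
    }

  double mux = 0.0, muy = 0.0;
  for (int i = 0; i < ng; ++i) { mux += (i + 1) * px[i]; muy += (i + 1) * py[i]; }

  double autoc = 0, contrast = 0, prom = 0, shade = 0, dissim = 0;
  double energy = 0, entropy = 0, homog = 0, maxp = 0, var = 0, idmn = 0;
  for (int i = 0; i < ng; ++i)
    for (int j = 0; j < ng; ++j) {
      double v = p[i * ng + j];
      if (v == 0.0) continue;
      double ii = i + 1, jj = j + 1, dif = ii - jj, s = ii + jj - mux - muy;
      autoc += ii * jj * v;
      contrast += dif * dif * v;
      prom += s * s * s * s * v;
      shade += s * s * s * v;
      dissim += std::fabs(dif) * v;
      energy += v * v;
      entropy -= v * std::log(v);
      homog += v / (1.0 + dif * dif);
      if (v > maxp) maxp = v;
      var += (ii - mux) * (ii - mux) * v;
      idmn += v / (1.0 + dif * dif / ((double)ng * ng));
    }

  double sumavg = 0, sumvar = 0, sument = 0;
  for (int k = 2; k <= 2 * ng; ++k) {
    double v = psum[k];
    if (v == 0.0) continue;
    sumavg += k * v;
    sument -= v * std::log(v);
  }
  for (int k = 2; k <= 2 * ng; ++k) {
    double v = psum[k];
    if (v == 0.0) continue;
    sumvar += (k - sumavg) * (k - sumavg) * v;
  }

  double dmean = 0, dvar = 0, dent = 0;
  for (int k = 0; k < ng; ++k) {
    double v = pdiff[k];
    if (v == 0.0) continue;
    dmean += k * v;
    dent -= v * std::log(v);
  }
  for (int k = 0; k < ng; ++k) {
    double v = pdiff[k];
    if (v == 0.0) continue;
    dvar += (k - dmean) * (k - dmean) * v;
  }

  // information measure of correlation, first variant
  double hx = 0, hy = 0, hxy1 = 0;
  for (int i = 0; i < ng; ++i) if (px[i] > 0) hx -= px[i] * std::log(px[i]);
  for (int j = 0; j < ng; ++j) if (py[j] > 0) hy -= py[j] * std::log(py[j]);
  for (int i = 0; i < ng; ++i)
    for (int j = 0; j < ng; ++j) {
      double v = p[i * ng + j];
      if (v == 0.0) continue;
      double m = px[i] * py[j];
      if (m > 0) hxy1 -= v * std::log(m);
    }
  double hmax = std::max(hx, hy);
  double imc1 = (hmax > 0.0) ? (entropy - hxy1) / hmax : 0.0;

  out17[0] = autoc;   out17[1] = contrast; out17[2] = prom;   out17[3] = shade;
  out17[4] = dissim;  out17[5] = energy;   out17[6] = entropy; out17[7] = homog;
  out17[8] = maxp;    out17[9] = var;      out17[10] = sumavg; out17[11] = sumvar;
  out17[12] = sument; out17[13] = dvar;    out17[14] = dent;   out17[15] = imc1;
  out17[16] = idmn;
  return true;
}

// ---- Laws' energy measures -------------------------------------------------

static const double L5[5] = { 1,  4, 6,  4, 1};
static const double E5[5] = {-1, -2, 0,  2, 1};
static const double S5[5] = {-1,  0, 2,  0, -1};
static const double R5[5] = { 1, -4, 6, -4, 1};

// nine 5x5 masks; asymmetric outer products averaged with their transpose
static void laws_masks(std::vector<std::vector<double> > &masks) {
  const double *a[9] = {E5, S5, R5, E5, S5, R5, S5, R5, R5};
  const double *b[9] = {L5, L5, L5, E5, E5, E5, S5, S5, R5};
  masks.assign(9, std::vector<double>(25));
  for (int m = 0; m < 9; ++m)
    for (int i = 0; i < 5; ++i)
      for (int j = 0; j < 5; ++j)
        masks[m][i * 5 + j] =
          0.5 * (a[m][i] * b[m][j] + a[m][j] * b[m][i]);
}

// correlate each mask with the reflect-padded window (same-size output),
// then MSS = mean squared response, MAS = mean absolute response
static void lem_core(const double *w, int K, double *out18) {
  static std::vector<std::vector<double> > masks;
  if (masks.empty()) laws_masks(masks);
  for (int m = 0; m < 9; ++m) {
    double mss = 0.0, mas = 0.0;
    for (int r = 0; r < K; ++r)
      for (int c = 0; c < K; ++c) {
        double acc = 0.0;
        for (int a = -2; a <= 2; ++a)
          for (int b = -2; b <= 2; ++b) {
            int rr = reflect_idx(r + a, K), cc = reflect_idx(c + b, K);
            acc += masks[m][(a + 2) * 5 + (b + 2)] * w[rr * K + cc];
          }
        mss += acc * acc;
        mas += std::fabs(acc);
      }
    out18[m] = mss / (K * K);
    out18[9 + m] = mas / (K * K);
  }
}

// ---- extended GLRLM (11 features) ------------------------------------------

// out11: SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE
static void glrlm_core(const double *w, int K, int theta, int ng,
                       double *out11) {
  int dr, dc;
  theta_offset(theta, 1, dr, dc);
  // counts[level][length], 1-based length up to K (diagonals still <= K)
  std::vector<double> counts(ng * (K + 1), 0.0);
  // trace maximal runs: start cells are those with no valid predecessor of
  // the same level along (-dr,-dc)
  for (int r = 0; r < K; ++r)
    for (int c = 0; c < K; ++c) {
      int pr = r - dr, pc = c - dc;
      int lvl = quantize(w[r * K + c], ng);
      bool has_pred = pr >= 0 && pr < K && pc >= 0 && pc < K &&
        quantize(w[pr * K + pc], ng) == lvl;
      if (has_pred) continue;
      int len = 1, rr = r + dr, cc = c + dc;
      while (rr >= 0 && rr < K && cc >= 0 && cc < K &&
             quantize(w[rr * K + cc], ng) == lvl) {
        ++len; rr += dr; cc += dc;
      }
      counts[lvl * (K + 1) + len] += 1.0;
    }
  double nr = 0.0;
  for (size_t k = 0; k < counts.size(); ++k) nr += counts[k];
  double np = (double)K * K;
  double sre = 0, lre = 0, lgre = 0, hgre = 0,
    srlge = 0, srhge = 0, lrlge = 0, lrhge = 0;
  std::vector<double> bylvl(ng, 0.0), bylen(K + 1, 0.0);
  for (int i = 0; i < ng; ++i)
    for (int j = 1; j <= K; ++j) {
      double v = counts[i * (K + 1) + j];
      if (v == 0.0) continue;
      double gi = i + 1.0, rj = j;
      bylvl[i] += v; bylen[j] += v;
      sre += v / (rj * rj);        lre += v * rj * rj;
      lgre += v / (gi * gi);       hgre += v * gi * gi;
      srlge += v / (gi * gi * rj * rj);
      srhge += v * gi * gi / (rj * rj);
      lrlge += v * rj * rj / (gi * gi);
      lrhge += v * gi * gi * rj * rj;
    }
  double gln = 0, rln = 0;
  for (int i = 0; i < ng; ++i) gln += bylvl[i] * bylvl[i];
  for (int j = 1; j <= K; ++j) rln += bylen[j] * bylen[j];
  out11[0] = sre / nr;   out11[1] = lre / nr;   out11[2] = gln / nr;
  out11[3] = rln / nr;   out11[4] = nr / np;    out11[5] = lgre / nr;
  out11[6] = hgre / nr;  out11[7] = srlge / nr; out11[8] = srhge / nr;
  out11[9] = lrlge / nr; out11[10] = lrhge / nr;
}

// ---- LBP -------------------------------------------------------------------

// neighbor offsets clockwise from top-left
static const int LBP_DR[8] = {-1, -1, -1, 0, 1, 1, 1, 0};
static const int LBP_DC[8] = {-1, 0, 1, 1, 1, 0, -1, -1};

static void lbp_core(const double *w3, double *out2) {
  double gc = w3[1 * 3 + 1];
  int s[8], basic = 0, sum = 0;
  for (int n = 0; n < 8; ++n) {
    double gn = w3[(LBP_DR[n] + 1) * 3 + (LBP_DC[n] + 1)];
    s[n] = (gn - gc >= 0.0) ? 1 : 0;
    basic += s[n] << n;
    sum += s[n];
  }
  int u = std::abs(s[7] - s[0]);
  for (int n = 1; n < 8; ++n) u += std::abs(s[n] - s[n - 1]);
  out2[0] = basic;
  out2[1] = (u <= 2) ? sum : 9;
}

// ---- exported per-window entry points --------------------------------------

// [[Rcpp::export]]
NumericVector cpp_fos(NumericMatrix w) {
  NumericVector out(5);
  std::vector<double> buf(w.begin(), w.end());
  // R matrices are column-major; row/col order is irrelevant for FOS
  fos_core(buf.data(), (int)buf.size(), out.begin());
  return out;
}

// copy an R (column-major) matrix into a row-major buffer
static std::vector<double> row_major(const NumericMatrix &w) {
  int K = w.nrow();
  std::vector<double> buf(K * w.ncol());
  for (int r = 0; r < K; ++r)
    for (int c = 0; c < w.ncol(); ++c)
      buf[r * w.ncol() + c] = w(r, c);
  return buf;
}

// [[Rcpp::export]]
NumericVector cpp_glcm(NumericMatrix w, int d, int theta, int ng,
                       bool symmetric) {
  if (w.nrow() != w.ncol()) stop("window must be square");
  std::vector<double> buf = row_major(w);
  NumericVector out(17);
  if (!glcm_core(buf.data(), w.nrow(), d, theta, ng, symmetric, out.begin()))
    stop("degenerate co-occurrence matrix: no valid pixel pair at this offset");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_lem(NumericMatrix w) {
  if (w.nrow() != w.ncol()) stop("window must be square");
  std::vector<double> buf = row_major(w);
  NumericVector out(18);
  lem_core(buf.data(), w.nrow(), out.begin());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_glrlm(NumericMatrix w, int theta, int ng) {
  if (w.nrow() != w.ncol()) stop("window must be square");
  std::vector<double> buf = row_major(w);
  NumericVector out(11);
  glrlm_core(buf.data(), w.nrow(), theta, ng, out.begin());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_lbp(NumericMatrix w) {
  if (w.nrow() != 3 || w.ncol() != 3) stop("LBP window must be 3x3");
  std::vector<double> buf = row_major(w);
  NumericVector out(2);
  lbp_core(buf.data(), out.begin());
  return out;
}

// ---- bulk extraction over a masked frame -----------------------------------

// one row per TRUE mask pixel, visited in row-major (row, then col) order;
// windows reflect-padded at the frame border; 54 columns in canonical order
// [[Rcpp::export]]
List cpp_extract_all(IntegerMatrix frame, LogicalMatrix mask, int K,
                     int glcm_d, int glcm_theta, int glcm_ng,
                     bool glcm_symmetric, int glrlm_theta, int glrlm_ng) {
  int nr = frame.nrow(), nc = frame.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("mask shape must match frame shape");
  int n = 0;
  for (int i = 0; i < nr * nc; ++i) if (mask[i]) ++n;
  IntegerVector out_r(n), out_c(n);
  NumericMatrix feats(n, 54);
  std::vector<double> win(K * K), w3(9);
  int half = K / 2, idx = 0;
  double fos[5], glcm[17], lem[18], glrlm[11], lbp[2];
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c)) continue;
      for (int a = -half; a <= half; ++a)
        for (int b = -half; b <= half; ++b)
          win[(a + half) * K + (b + half)] =
            frame(reflect_idx(r + a, nr), reflect_idx(c + b, nc));
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          w3[(a + 1) * 3 + (b + 1)] =
            frame(reflect_idx(r + a, nr), reflect_idx(c + b, nc));
      fos_core(win.data(), K * K, fos);
      if (!glcm_core(win.data(), K, glcm_d, glcm_theta, glcm_ng,
                     glcm_symmetric, glcm))
        stop("degenerate co-occurrence matrix at pixel (%d, %d)", r, c);
      lem_core(win.data(), K, lem);
      glrlm_core(win.data(), K, glrlm_theta, glrlm_ng, glrlm);
      lbp_core(w3.data(), lbp);
      feats(idx, 0) = frame(r, c);
      for (int j = 0; j < 5; ++j)  feats(idx, 1 + j) = fos[j];
      for (int j = 0; j < 17; ++j) feats(idx, 6 + j) = glcm[j];
      for (int j = 0; j < 18; ++j) feats(idx, 23 + j) = lem[j];
      for (int j = 0; j < 11; ++j) feats(idx, 41 + j) = glrlm[j];
      feats(idx, 52) = lbp[0];
      feats(idx, 53) = lbp[1];
      out_r[idx] = r;
      out_c[idx] = c;
      ++idx;
    }
  }
  return List::create(_["row"] = out_r, _["col"] = out_c,
                      _["features"] = feats);
}
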