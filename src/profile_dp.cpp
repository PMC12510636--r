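#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

// Glocal profile HMM dynamic programming in odds space (emissions divided by
// the null), so the final quantity is P(seq | profile) / P(seq | null).
// Architecture: N flank (self-loop eta, background emission) -> B -> core
// (M/I/D chain) -> E -> C flank (self-loop eta) -> T. Flank emissions cancel
// against the null; eta is supplied per sequence (length-calibrated
// n/(n+2) when a negative sentinel is passed).
//
// Transition vectors are 0-indexed from R's 1-indexed convention:
// mm[k-1] = t(M_k -> M_{k+1}) for k < L, and mm[L-1] = t(M_L -> E);
// likewise dm[L-1] = t(D_L -> E).

struct ProfilePar {
  int L;
  std::vector<double> eo;  // L*21 match odds (code 20 = X -> 1)
  std::vector<double> io;  // 21 insert odds
  std::vector<double> mm, mi, md, im, ii, dm, dd;
  double bm, bd;
};

static ProfilePar unpack(const List& prof) {
  ProfilePar p;
  NumericMatrix me = prof["me"];
  NumericVector ie = prof["ie"];
  NumericVector nul = prof["null"];
  p.L = me.nrow();
  p.eo.resize((size_t)p.L * 21);
  for (int k = 0; k < p.L; ++k) {
    for (int c = 0; c < 20; ++c) p.eo[(size_t)k * 21 + c] = me(k, c) / nul[c];
    p.eo[(size_t)k * 21 + 20] = 1.0;
  }
  p.io.resize(21);
  for (int c = 0; c < 20; ++c) p.io[c] = ie[c] / nul[c];
  p.io[20] = 1.0;
  p.mm = as<std::vector<double>>(prof["mm"]);
  p.mi = as<std::vector<double>>(prof["mi"]);
  p.md = as<std::vector<double>>(prof["md"]);
  p.im = as<std::vector<double>>(prof["im"]);
  p.ii = as<std::vector<double>>(prof["ii"]);
  p.dm = as<std::vector<double>>(prof["dm"]);
  p.dd = as<std::vector<double>>(prof["dd"]);
  p.bm = as<double>(prof["bm"]);
  p.bd = as<double>(prof["bd"]);
  return p;
}

static double forward_one(const ProfilePar& p, const std::vector<int>& x,
                          double eta) {
  const int n = (int)x.size();
  const int L = p.L;
  const double leave = 1.0 - eta;
  const double log_eta = (eta > 0.0) ? std::log(eta) : 0.0;

  std::vector<double> M(L + 1, 0.0), I(L + 1, 0.0), D(L + 1, 0.0);
  std::vector<double> nM(L + 1, 0.0), nI(L + 1, 0.0), nD(L + 1, 0.0);
  std::vector<double> logE(n + 1, -std::numeric_limits<double>::infinity());

  double nval = 1.0;   // N-state odds on the current row's scale
  double cumlog = 0.0;

  // row 0: nothing emitted; only the all-delete path reaches E
  D[1] = nval * leave * p.bd;
  for (int k = 2; k <= L; ++k) D[k] = D[k - 1] * p.dd[k - 2];
  if (D[L] > 0.0) {
    double e0 = D[L] * p.dm[L - 1];
    if (e0 > 0.0) logE[0] = std::log(e0);
  }

  // Cells more than ~280 orders of magnitude below the row maximum cannot
  // influence the result at 1e-9 relative tolerance; flushing them to zero
  // keeps the arithmetic out of the subnormal range (rows are rescaled to
  // max 1 below).
  const double FLUSH = 1e-280;
  const double* Mv = M.data(); (void)Mv;
  for (int i = 1; i <= n; ++i) {
    const int c = x[(size_t)i - 1];
    const double io_c = p.io[c];
    const double* eo_c = &p.eo[0];
    const double nnval = nval * eta;
    double s = nnval;
    nM[1] = p.eo[c] * (nval * leave * p.bm);
    nD[1] = nnval * leave * p.bd;
    nI[1] = (L > 1) ? io_c * (M[1] * p.mi[0] + I[1] * p.ii[0]) : 0.0;
    if (nM[1] > s) s = nM[1];
    if (nI[1] > s) s = nI[1];
    if (nD[1] > s) s = nD[1];
    for (int k = 2; k <= L; ++k) {
      const double acc = M[k - 1] * p.mm[k - 2] + I[k - 1] * p.im[k - 2] +
                         D[k - 1] * p.dm[k - 2];
      const double m_k = eo_c[(size_t)(k - 1) * 21 + c] * acc;
      const double d_k = nM[k - 1] * p.md[k - 2] + nD[k - 1] * p.dd[k - 2];
      const double i_k =
          (k < L) ? io_c * (M[k] * p.mi[k - 1] + I[k] * p.ii[k - 1]) : 0.0;
      nM[k] = m_k; nD[k] = d_k; nI[k] = i_k;
      if (m_k > s) s = m_k;
      if (i_k > s) s = i_k;
      if (d_k > s) s = d_k;
    }
    double ei = nM[L] * p.mm[L - 1] + nD[L] * p.dm[L - 1];
    if (ei > 0.0) logE[i] = std::log(ei) + cumlog;

    if (s <= 0.0) s = 1.0;
    const double inv = 1.0 / s;
    for (int k = 1; k <= L; ++k) {
      double m_k = nM[k] * inv, i_k = nI[k] * inv, d_k = nD[k] * inv;
      M[k] = (m_k < FLUSH) ? 0.0 : m_k;
      I[k] = (i_k < FLUSH) ? 0.0 : i_k;
      D[k] = (d_k < FLUSH) ? 0.0 : d_k;
    }
    nval = nnval * inv;
    if (nval < FLUSH) nval = 0.0;
    cumlog += std::log(s);
  }

  // terminate: (1-eta) * sum_i E_i * eta^(n-i); no C flank factor when n==0
  double best = -std::numeric_limits<double>::infinity();
  for (int i = 0; i <= n; ++i) {
    double v = logE[i] + (n > 0 ? (double)(n - i) * log_eta : 0.0);
    if (v > best) best = v;
  }
  if (!std::isfinite(best)) return -std::numeric_limits<double>::infinity();
  double acc = 0.0;
  for (int i = 0; i <= n; ++i) {
    double v = logE[i] + (n > 0 ? (double)(n - i) * log_eta : 0.0);
    if (std::isfinite(v)) acc += std::exp(v - best);
  }
  double logodds = best + std::log(acc) + (n > 0 ? std::log(leave) : 0.0);
  return logodds / std::log(2.0);  // bits
}

// [[Rcpp::export]]
NumericVector cpp_forward_batch(List prof, List seqs, NumericVector eta) {
  ProfilePar p = unpack(prof);
  const int ns = seqs.size();
  NumericVector out(ns);
  for (int j = 0; j < ns; ++j) {
    std::vector<int> x = as<std::vector<int>>(seqs[j]);
    double e = (eta.size() == 1) ? eta[0] : eta[j];
    if (e < 0.0) e = (double)x.size() / ((double)x.size() + 2.0);
    out[j] = forward_one(p, x, e);
  }
  return out;
}

static inline double l2(double v) {
  return v > 0.0 ? std::log2(v) : -std::numeric_limits<double>::infinity();
}

// Viterbi in log2-odds space with traceback.
// [[Rcpp::export]]
List cpp_viterbi(List prof, IntegerVector seq, double eta_in) {
  ProfilePar p = unpack(prof);
  const int n = seq.size();
  const int L = p.L;
  double eta = eta_in;
  if (eta < 0.0) eta = (double)n / ((double)n + 2.0);
  const double NEG = -std::numeric_limits<double>::infinity();
  const double l2eta = (eta > 0.0) ? std::log2(eta) : 0.0;
  const double l2leave = l2(1.0 - eta);

  std::vector<double> l2mm(L), l2mi(L), l2md(L), l2im(L), l2ii(L), l2dm(L),
      l2dd(L);
  for (int k = 0; k < L; ++k) {
    l2mm[k] = l2(p.mm[k]); l2mi[k] = l2(p.mi[k]); l2md[k] = l2(p.md[k]);
    l2im[k] = l2(p.im[k]); l2ii[k] = l2(p.ii[k]);
    l2dm[k] = l2(p.dm[k]); l2dd[k] = l2(p.dd[k]);
  }
  const double l2bm = l2(p.bm), l2bd = l2(p.bd);
  std::vector<double> l2eo((size_t)L * 21), l2io(21);
  for (size_t t = 0; t < l2eo.size(); ++t) l2eo[t] = l2(p.eo[t]);
  for (int t = 0; t < 21; ++t) l2io[t] = l2(p.io[t]);

  auto idx = [L](int i, int k) { return (size_t)i * (L + 1) + k; };
  std::vector<double> VM((size_t)(n + 1) * (L + 1), NEG),
      VI((size_t)(n + 1) * (L + 1), NEG), VD((size_t)(n + 1) * (L + 1), NEG);
  // predecessor codes: 0 = B, 1 = M, 2 = I, 3 = D
  std::vector<signed char> PM(VM.size(), -1), PI(VI.size(), -1),
      PD(VD.size(), -1);

  // best log2 odds of standing at B having consumed i flank residues
  auto VB = [&](int i) {
    return (n > 0 ? (double)i * l2eta : 0.0) + l2leave;
  };

  VD[idx(0, 1)] = VB(0) + l2bd; PD[idx(0, 1)] = 0;
  for (int k = 2; k <= L; ++k) {
    VD[idx(0, k)] = VD[idx(0, k - 1)] + l2dd[k - 2];
    PD[idx(0, k)] = 3;
  }
  for (int i = 1; i <= n; ++i) {
    const int c = seq[i - 1];
    for (int k = 1; k <= L; ++k) {
      double le = l2eo[(size_t)(k - 1) * 21 + c];
      double best; signed char ptr;
      if (k == 1) {
        best = VB(i - 1) + l2bm; ptr = 0;
      } else {
        best = VM[idx(i - 1, k - 1)] + l2mm[k - 2]; ptr = 1;
        double v = VI[idx(i - 1, k - 1)] + l2im[k - 2];
        if (v > best) { best = v; ptr = 2; }
        v = VD[idx(i - 1, k - 1)] + l2dm[k - 2];
        if (v > best) { best = v; ptr = 3; }
      }
      VM[idx(i, k)] = le + best; PM[idx(i, k)] = ptr;
      if (k < L) {
        double li = l2io[c];
        double bi = VM[idx(i - 1, k)] + l2mi[k - 1]; signed char pi2 = 1;
        double v = VI[idx(i - 1, k)] + l2ii[k - 1];
        if (v > bi) { bi = v; pi2 = 2; }
        VI[idx(i, k)] = li + bi; PI[idx(i, k)] = pi2;
      }
    }
    VD[idx(i, 1)] = VB(i) + l2bd; PD[idx(i, 1)] = 0;
    for (int k = 2; k <= L; ++k) {
      double bd2 = VM[idx(i, k - 1)] + l2md[k - 2]; signed char pd2 = 1;
      double v = VD[idx(i, k - 1)] + l2dd[k - 2];
      if (v > bd2) { bd2 = v; pd2 = 3; }
      VD[idx(i, k)] = bd2; PD[idx(i, k)] = pd2;
    }
  }

  double best = NEG; int bi = -1; signed char bstate = 1;
  for (int i = 0; i <= n; ++i) {
    double tail = (n > 0 ? (double)(n - i) * l2eta : 0.0) + l2leave;
    double vm = VM[idx(i, L)] + l2mm[L - 1] + tail;
    if (vm > best) { best = vm; bi = i; bstate = 1; }
    double vd = VD[idx(i, L)] + l2dm[L - 1] + tail;
    if (vd > best) { best = vd; bi = i; bstate = 3; }
  }

  std::vector<std::string> rev;
  if (std::isfinite(best)) {
    for (int t = 0; t < n - bi; ++t) rev.push_back("C");
    int i = bi, k = L;
    signed char st = bstate;
    while (true) {
      signed char ptr;
      if (st == 1) {
        rev.push_back("M" + std::to_string(k));
        ptr = PM[idx(i, k)]; --i; --k;
      } else if (st == 2) {
        rev.push_back("I" + std::to_string(k));
        ptr = PI[idx(i, k)]; --i;
      } else {
        rev.push_back("D" + std::to_string(k));
        ptr = PD[idx(i, k)]; --k;
      }
      if (ptr == 0) break;
      st = ptr;
    }
    for (int t = 0; t < i; ++t) rev.push_back("N");
  }
  std::vector<std::string> path(rev.rbegin(), rev.rend());
  return List::create(Named("bits") = best, Named("path") = wrap(path));
}

// [[Rcpp::export]]
NumericVector cpp_viterbi_batch(List prof, List seqs, NumericVector eta) {
  const int ns = seqs.size();
  NumericVector out(ns);
  for (int j = 0; j < ns; ++j) {
    IntegerVector x = seqs[j];
    double e = (eta.size() == 1) ? eta[0] : eta[j];
    List r = cpp_viterbi(prof, x, e);
    out[j] = as<double>(r["bits"]);
  }
  return out;
}
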