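// Log-space dynamic programming for profile HMMs (match/insert/delete
// nodes, uni-local: local in the target sequence and local in the model).
//
// Conventions shared with the R side (see hmm_kernel):
//  - residues are encoded 0..19 (alphabetical AA order) and 20 for 'X';
//    the match odds matrix `em` has 21 columns with column 21 == 1
//    (X is score-neutral under model and null);
//  - insert states emit at background frequencies, so their odds are 1;
//  - `tr` is a (K+1) x 7 matrix of transition probabilities, rows =
//    nodes 0..K (node 0 = begin), columns = MM MI MD IM II DM DD, with
//    the pre-terminal match rows already scaled by (1 - exit prob);
//  - `entry[j]` is the begin -> M_{j+1} probability (uniform over match
//    states), `exitp[j]` the M_{j+1} -> end probability;
//  - unscored flanking residues before entry and after exit contribute
//    nothing, which implements sequence-locality.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

enum { MM = 0, MI = 1, MD = 2, IM = 3, II = 4, DM = 5, DD = 6 };

// Forward in scaled linear space: row i of the DP is rescaled by its
// maximum; the running log-scale keeps everything finite for sequences of
// any practical length, and the begin state re-enters each row with
// weight exp(-S) (the accumulated scale), implementing the free flanks.
// [[Rcpp::export]]
double phmm_forward_nats(NumericMatrix em, NumericMatrix tr,
                         NumericVector entry, NumericVector exitp,
                         IntegerVector seq) {
  const int K = em.nrow();
  const int L = seq.size();

  std::vector<double> Mp(K + 1, 0.0), Ip(K + 1, 0.0), Dp(K + 1, 0.0);
  std::vector<double> Mc(K + 1, 0.0), Ic(K + 1, 0.0), Dc(K + 1, 0.0);

  // i = 0 (unscaled, S = 0): only delete-chain paths from B.
  Dp[1] = tr(0, MD);
  for (int j = 2; j <= K; ++j) Dp[j] = Dp[j - 1] * tr(j - 1, DD);
  double total = (Dp[K] * tr(K, DM) > 0)
                     ? std::log(Dp[K] * tr(K, DM)) : NEG_INF;

  double S = 0.0;  // log of the accumulated scaling factor

  for (int i = 1; i <= L; ++i) {
    const int a = seq[i - 1];
    const double B = std::exp(-S);  // begin-state weight in scaled units
    Mc[1] = em(0, a) * (B * entry[0] + Ip[0] * tr(0, IM));
    for (int j = 2; j <= K; ++j) {
      Mc[j] = em(j - 1, a) * (Mp[j - 1] * tr(j - 1, MM) +
                              Ip[j - 1] * tr(j - 1, IM) +
                              Dp[j - 1] * tr(j - 1, DM) +
                              B * entry[j - 1]);
    }
    Ic[0] = B * tr(0, MI) + Ip[0] * tr(0, II);
    for (int j = 1; j <= K; ++j)
      Ic[j] = Mp[j] * tr(j, MI) + Ip[j] * tr(j, II);
    Dc[1] = B * tr(0, MD);
    for (int j = 2; j <= K; ++j)
      Dc[j] = Mc[j - 1] * tr(j - 1, MD) + Dc[j - 1] * tr(j - 1, DD);

    double Ei = Ic[K] * tr(K, IM) + Dc[K] * tr(K, DM);
    for (int j = 1; j <= K; ++j) Ei += Mc[j] * exitp[j - 1];
    if (Ei > 0) total = lse2(total, std::log(Ei) + S);

    // rescale the row by its maximum
    double c = 0.0;
    for (int j = 0; j <= K; ++j) {
      if (Mc[j] > c) c = Mc[j];
      if (Ic[j] > c) c = Ic[j];
      if (Dc[j] > c) c = Dc[j];
    }
    if (c <= 0) c = 1.0;
    const double inv = 1.0 / c;
    for (int j = 0; j <= K; ++j) { Mc[j] *= inv; Ic[j] *= inv; Dc[j] *= inv; }
    S += std::log(c);

    Mp.swap(Mc); Ip.swap(Ic); Dp.swap(Dc);
  }
  return total;
}

// [[Rcpp::export]]
NumericVector phmm_forward_batch_nats(NumericMatrix em, NumericMatrix tr,
                                      NumericVector entry,
                                      NumericVector exitp, List seqs) {
  const int n = seqs.size();
  NumericVector out(n);
  for (int s = 0; s < n; ++s)
    out[s] = phmm_forward_nats(em, tr, entry, exitp,
                               as<IntegerVector>(seqs[s]));
  return out;
}

// Viterbi with traceback, in log space (`lm`, `ltr`, `lentry`, `lexit`
// are the natural logs of the forward inputs).  Returns the best
// log-odds score and the state path as parallel vectors: state (0 = M,
// 1 = I, 2 = D), node index, and the 1-based residue index consumed at
// that step (0 for deletes).
// [[Rcpp::export]]
List phmm_viterbi_nats(NumericMatrix lm, NumericMatrix ltr,
                       NumericVector lentry, NumericVector lexit,
                       IntegerVector seq) {
  const int K = lm.nrow();
  const int L = seq.size();

  NumericMatrix M(L + 1, K + 1), I(L + 1, K + 1), D(L + 1, K + 1);
  // traceback codes: 0 from M, 1 from I, 2 from D, 3 from B
  std::vector<signed char> bM((L + 1) * (K + 1), -1), bI((L + 1) * (K + 1), -1),
      bD((L + 1) * (K + 1), -1);
  auto at = [K](int i, int j) { return i * (K + 1) + j; };

  std::fill(M.begin(), M.end(), NEG_INF);
  std::fill(I.begin(), I.end(), NEG_INF);
  std::fill(D.begin(), D.end(), NEG_INF);

  for (int i = 0; i <= L; ++i) {
    D(i, 1) = ltr(0, MD);
    bD[at(i, 1)] = 3;
  }
  for (int j = 2; j <= K; ++j) {
    D(0, j) = D(0, j - 1) + ltr(j - 1, DD);
    bD[at(0, j)] = 2;
  }

  for (int i = 1; i <= L; ++i) {
    const int a = seq[i - 1];
    for (int j = 1; j <= K; ++j) {
      double best = lentry[j - 1];  // from B (flank scores 0)
      signed char who = 3;
      if (j >= 2) {
        double vm = M(i - 1, j - 1) + ltr(j - 1, MM);
        double vi = I(i - 1, j - 1) + ltr(j - 1, IM);
        double vd = D(i - 1, j - 1) + ltr(j - 1, DM);
        if (vm > best) { best = vm; who = 0; }
        if (vi > best) { best = vi; who = 1; }
        if (vd > best) { best = vd; who = 2; }
      } else {
        double vi = I(i - 1, 0) + ltr(0, IM);
        if (vi > best) { best = vi; who = 1; }
      }
      M(i, j) = lm(j - 1, a) + best;
      bM[at(i, j)] = who;
    }
    {
      double fromB = ltr(0, MI), fromI = I(i - 1, 0) + ltr(0, II);
      if (fromB >= fromI) { I(i, 0) = fromB; bI[at(i, 0)] = 3; }
      else                { I(i, 0) = fromI; bI[at(i, 0)] = 1; }
    }
    for (int j = 1; j <= K; ++j) {
      double vm = M(i - 1, j) + ltr(j, MI);
      double vi = I(i - 1, j) + ltr(j, II);
      if (vm >= vi) { I(i, j) = vm; bI[at(i, j)] = 0; }
      else          { I(i, j) = vi; bI[at(i, j)] = 1; }
    }
    for (int j = 2; j <= K; ++j) {
      double vm = M(i, j - 1) + ltr(j - 1, MD);
      double vd = D(i, j - 1) + ltr(j - 1, DD);
      if (vm >= vd) { D(i, j) = vm; bD[at(i, j)] = 0; }
      else          { D(i, j) = vd; bD[at(i, j)] = 2; }
    }
  }

  // best end: exit from any match state, or I_K / D_K into E
  double best = NEG_INF; int bi = -1, bj = -1; signed char bstate = -1;
  for (int i = 0; i <= L; ++i) {
    for (int j = 1; j <= K; ++j) {
      double vm = M(i, j) + lexit[j - 1];
      if (vm > best) { best = vm; bi = i; bj = j; bstate = 0; }
    }
    double vi = I(i, K) + ltr(K, IM);
    if (vi > best) { best = vi; bi = i; bj = K; bstate = 1; }
    double vd = D(i, K) + ltr(K, DM);
    if (vd > best) { best = vd; bi = i; bj = K; bstate = 2; }
  }

  // traceback
  std::vector<int> st, nd, rs;
  int i = bi, j = bj; signed char s = bstate;
  while (true) {
    st.push_back(s); nd.push_back(j);
    signed char prev;
    if (s == 0) { rs.push_back(i); prev = bM[at(i, j)]; --i; --j; }
    else if (s == 1) { rs.push_back(i); prev = bI[at(i, j)]; --i; }
    else { rs.push_back(0); prev = bD[at(i, j)]; --j; }
    if (prev == 3) break;
    s = prev;
  }
  std::reverse(st.begin(), st.end());
  std::reverse(nd.begin(), nd.end());
  std::reverse(rs.begin(), rs.end());

  return List::create(_["score"] = best,
                      _["state"] = IntegerVector(st.begin(), st.end()),
                      _["node"] = IntegerVector(nd.begin(), nd.end()),
                      _["residue"] = IntegerVector(rs.begin(), rs.end()));
}
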