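// Compiled population pass over one chromosome window. Mirrors the R
// reference implementation (.windowPassR / processIndividual) exactly:
// likelihood-ratio selection of H1/H2 with running-product pruning,
// admission of new haplotype tracks, and in-place posterior updates of
// the two selected tracks per individual.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double clamp01(double p, double c) {
  if (p < c) return c;
  if (p > 1.0 - c) return 1.0 - c;
  return p;
}

// joint probability of the observed counts given two haplotype A-probs
static inline double ju(double a, double b, double laa, double lab,
                        double lbb) {
  return a * b * laa + (1.0 - a) * (1.0 - b) * lbb +
         (a + b - 2.0 * a * b) * lab;
}

// [[Rcpp::export]]
List cpp_window_pass(IntegerMatrix nA, IntegerMatrix nB, LogicalMatrix arr,
                     IntegerVector ord, IntegerVector sire,
                     IntegerVector dam, NumericMatrix probs0,
                     IntegerVector usage0, IntegerVector h1v,
                     IntegerVector h2v, NumericVector freqs, double errate,
                     double arrErr, double clamp) {
  const int L = nA.nrow();
  const int nInd = nA.ncol();

  std::vector<std::vector<double> > tracks;
  std::vector<int> usage;
  tracks.reserve(usage0.size() + 2 * nInd);
  for (int t = 0; t < usage0.size(); ++t) {
    std::vector<double> col(L);
    for (int j = 0; j < L; ++j) col[j] = probs0(j, t);
    tracks.push_back(col);
    usage.push_back(usage0[t]);
  }
  std::vector<int> h1(h1v.begin(), h1v.end());
  std::vector<int> h2(h2v.begin(), h2v.end());

  std::vector<int> obs;
  std::vector<double> laa, lab, lbb, pc, den1, q1c, den2;
  obs.reserve(L);

  for (int oi = 0; oi < ord.size(); ++oi) {
    const int i = ord[oi];
    if (h1[i] >= 0) {            // release previous assignment
      usage[h1[i]]--;
      usage[h2[i]]--;
    }
    obs.clear();
    for (int j = 0; j < L; ++j)
      if (nA(j, i) + nB(j, i) > 0) obs.push_back(j);
    const int n = (int)obs.size();
    int K = (int)tracks.size();

    if (n == 0) {
      if (K == 0) {
        tracks.push_back(std::vector<double>(freqs.begin(), freqs.end()));
        usage.push_back(1);
        tracks.push_back(std::vector<double>(freqs.begin(), freqs.end()));
        usage.push_back(1);
        h1[i] = 0; h2[i] = 1;
      } else {
        int best = 0, second = -1;
        for (int t = 1; t < K; ++t)
          if (usage[t] > usage[best]) best = t;
        for (int t = 0; t < K; ++t) {
          if (t == best) continue;
          if (second < 0 || usage[t] > usage[second]) second = t;
        }
        if (second < 0) second = best;
        h1[i] = best; h2[i] = second;
        usage[best]++; usage[second]++;
      }
      continue;
    }

    laa.assign(n, 0.0); lab.assign(n, 0.0); lbb.assign(n, 0.0);
    pc.assign(n, 0.0); den1.assign(n, 0.0);
    for (int k = 0; k < n; ++k) {
      const int j = obs[k];
      const double e = arr(j, i) ? arrErr : errate;
      const double a = (double)nA(j, i), b = (double)nB(j, i);
      if (a + b > 30.0) {
        // log-space evaluation for deep piles (same form as the R path)
        const double la = a > 0.0 ? a * std::log(1.0 - e) : 0.0;
        const double lb = b > 0.0 ? b * std::log(e) : 0.0;
        const double la2 = a > 0.0 ? a * std::log(e) : 0.0;
        const double lb2 = b > 0.0 ? b * std::log(1.0 - e) : 0.0;
        laa[k] = std::exp(la + lb);
        lbb[k] = std::exp(la2 + lb2);
        lab[k] = std::exp((a + b) * std::log(0.5));
      } else {
        laa[k] = std::pow(1.0 - e, a) * std::pow(e, b);
        lbb[k] = std::pow(e, a) * std::pow(1.0 - e, b);
        lab[k] = std::pow(0.5, a + b);
      }
      pc[k] = clamp01(freqs[j], clamp);
      den1[k] = ju(pc[k], pc[k], laa[k], lab[k], lbb[k]);
    }
    const double thr1 = 1.0 / n;

    // candidate order: sire's pair, dam's pair, grandparents', then all
    std::vector<int> anc;
    const int s = sire[i], d = dam[i];
    int gps[4] = {-1, -1, -1, -1};
    if (s >= 0) { gps[0] = sire[s]; gps[1] = dam[s]; }
    if (d >= 0) { gps[2] = sire[d]; gps[3] = dam[d]; }
    int rel[6] = {s, d, gps[0], gps[1], gps[2], gps[3]};
    for (int r = 0; r < 6; ++r) {
      const int a = rel[r];
      if (a < 0) continue;
      for (int which = 0; which < 2; ++which) {
        const int t = which == 0 ? h1[a] : h2[a];
        if (t < 0 || t >= K) continue;
        bool dup = false;
        for (size_t u = 0; u < anc.size(); ++u)
          if (anc[u] == t) { dup = true; break; }
        if (!dup) anc.push_back(t);
      }
    }
    std::vector<char> isAnc(K, 0);
    for (size_t u = 0; u < anc.size(); ++u) isAnc[anc[u]] = 1;

    // ---- H1 selection ----
    int sel1 = -1;
    for (int ci = 0; ci < K + (int)anc.size() && sel1 < 0; ++ci) {
      int t;
      if (ci < (int)anc.size()) t = anc[ci];
      else { t = ci - (int)anc.size(); if (isAnc[t]) continue; }
      double prod = 1.0;
      bool disc = false;
      const std::vector<double>& tp = tracks[t];
      for (int k = 0; k < n; ++k) {
        const double q = clamp01(tp[obs[k]], clamp);
        prod *= ju(q, pc[k], laa[k], lab[k], lbb[k]) / den1[k];
        if (prod < thr1) { disc = true; break; }
      }
      if (!disc && prod > thr1) sel1 = t;
    }
    if (sel1 < 0) {
      tracks.push_back(std::vector<double>(freqs.begin(), freqs.end()));
      usage.push_back(1);
      sel1 = K;
      K++;
    } else {
      usage[sel1]++;
    }

    // ---- H2 selection (conditional on H1) ----
    q1c.assign(n, 0.0); den2.assign(n, 0.0);
    const std::vector<double>& t1 = tracks[sel1];
    for (int k = 0; k < n; ++k) {
      q1c[k] = clamp01(t1[obs[k]], clamp);
      den2[k] = ju(q1c[k], pc[k], laa[k], lab[k], lbb[k]);
    }
    const double thr2 = 1.0 / (n * (1.0 + n / 100.0));
    if ((int)isAnc.size() < K) isAnc.resize(K, 0);
    int sel2 = -1;
    for (int ci = 0; ci < K + (int)anc.size() && sel2 < 0; ++ci) {
      int t;
      if (ci < (int)anc.size()) t = anc[ci];
      else { t = ci - (int)anc.size(); if (isAnc[t]) continue; }
      if (t == sel1) continue;   // the complement is a distinct haplotype
      double prod = 1.0;
      bool disc = false;
      const std::vector<double>& tp = tracks[t];
      for (int k = 0; k < n; ++k) {
        const double q = clamp01(tp[obs[k]], clamp);
        prod *= ju(q1c[k], q, laa[k], lab[k], lbb[k]) / den2[k];
        if (prod < thr1) { disc = true; break; }
      }
      if (!disc && prod > thr2) sel2 = t;
    }
    if (sel2 < 0) {
      std::vector<double> prior(freqs.begin(), freqs.end());
      for (int k = 0; k < n; ++k) {
        const int j = obs[k];
        if (!arr(j, i)) continue;
        // complement seeding: remove H1's allele from the array genotype
        const double tot = (double)(nA(j, i) + nB(j, i));
        const double g = std::floor(2.0 * nA(j, i) / tot + 0.5);
        const double a1 = std::floor(tracks[sel1][j] + 0.5);
        double comp = g - a1;
        if (comp < 0.0) comp = 0.0;
        if (comp > 1.0) comp = 1.0;
        prior[j] = comp;
      }
      tracks.push_back(prior);
      usage.push_back(1);
      sel2 = K;
      K++;
    } else {
      usage[sel2]++;
    }

    // ---- posterior pair update at observed loci ----
    std::vector<double>& tr1 = tracks[sel1];
    std::vector<double>& tr2 = tracks[sel2];
    for (int k = 0; k < n; ++k) {
      const int j = obs[k];
      const double p1 = clamp01(tr1[j], clamp);
      const double p2 = clamp01(tr2[j], clamp);
      const double den = ju(p1, p2, laa[k], lab[k], lbb[k]);
      double post1 = (p2 * laa[k] + (1.0 - p2) * lab[k]) * p1 / den;
      double post2 = (p1 * laa[k] + (1.0 - p1) * lab[k]) * p2 / den;
      if (post1 < 0.0) post1 = 0.0; else if (post1 > 1.0) post1 = 1.0;
      if (post2 < 0.0) post2 = 0.0; else if (post2 > 1.0) post2 = 1.0;
      tr1[j] = post1;
      tr2[j] = post2;
      if (sel1 == sel2) tr1[j] = post1;
    }

    h1[i] = sel1;
    h2[i] = sel2;
  }

  const int K = (int)tracks.size();
  NumericMatrix probs(L, K);
  IntegerVector usageOut(K);
  for (int t = 0; t < K; ++t) {
    usageOut[t] = usage[t];
    for (int j = 0; j < L; ++j) probs(j, t) = tracks[t][j];
  }
  return List::create(_["probs"] = probs, _["usage"] = usageOut,
                      _["h1"] = IntegerVector(h1.begin(), h1.end()),
                      _["h2"] = IntegerVector(h2.begin(), h2.end()));
}
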