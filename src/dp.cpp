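#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Internal alphabet is DNA (U canonicalized to T upstream): A=0, C=1, G=2, T=3.
static inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1; // N and friends never pair
  }
}

// Pair class between a base x on one strand and base y on the other
// (antiparallel): 1 = Watson-Crick, 2 = G:U wobble, 0 = no pair.
static inline int pair_class(int x, int y) {
  if (x < 0 || y < 0) return 0;
  if ((x == 0 && y == 3) || (x == 3 && y == 0) ||
      (x == 1 && y == 2) || (x == 2 && y == 1)) return 1;
  if ((x == 2 && y == 3) || (x == 3 && y == 2)) return 2;
  return 0;
}

// Duplex pair-type index for the stacking table:
// 0=A:T 1=T:A 2=C:G 3=G:C 4=G:T 5=T:G (first base from strand A), -1 none.
static inline int pair_type(int x, int y) {
  if (x == 0 && y == 3) return 0;
  if (x == 3 && y == 0) return 1;
  if (x == 1 && y == 2) return 2;
  if (x == 2 && y == 1) return 3;
  if (x == 2 && y == 3) return 4;
  if (x == 3 && y == 2) return 5;
  return -1;
}

static std::vector<int> enc_seq(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc(s[i]);
  return v;
}

static const double INF = 1e18;

// ---------------------------------------------------------------------------
// miRNA target-site scoring (plant-style, zone-resolved penalties)
// ---------------------------------------------------------------------------
// Global alignment of the miRNA (5'->3') against the reversed site, so that
// miRNA position 1 faces the 3' end of the site. Penalties depend on the
// miRNA position's zone (strict = positions strict_lo..strict_hi from the
// 5' end). A gap consuming a miRNA position ("missing" target base) takes
// that position's mismatch penalty; a bulged target base takes the mismatch
// penalty of the next miRNA position (clipped to the last).

struct ScoreParams {
  double mm_strict, gu_strict, mm_non, gu_non;
  int strict_lo, strict_hi, max_gaps;
};

static inline double mm_pen(const ScoreParams& p, int mpos) {
  return (mpos >= p.strict_lo && mpos <= p.strict_hi) ? p.mm_strict : p.mm_non;
}
static inline double gu_pen(const ScoreParams& p, int mpos) {
  return (mpos >= p.strict_lo && mpos <= p.strict_hi) ? p.gu_strict : p.gu_non;
}

// core DP; if trace != NULL, fills alignment info
static double target_dp(const std::vector<int>& mir, const std::vector<int>& rs,
                        const ScoreParams& p,
                        std::string* aln, int* ngaps,
                        double* strict_sub, double* non_sub) {
  int n = (int)mir.size(), m = (int)rs.size(), G = p.max_gaps;
  // D[(g*(n+1)+i)*(m+1)+j]
  std::vector<double> D((size_t)(G + 1) * (n + 1) * (m + 1), INF);
  std::vector<signed char> bt((size_t)(G + 1) * (n + 1) * (m + 1), -1);
  auto idx = [&](int g, int i, int j) {
    return ((size_t)g * (n + 1) + i) * (m + 1) + j;
  };
  D[idx(0, 0, 0)] = 0.0;
  for (int g = 0; g <= G; ++g) {
    for (int i = 0; i <= n; ++i) {
      for (int j = 0; j <= m; ++j) {
        double best = D[idx(g, i, j)];
        signed char arg = bt[idx(g, i, j)];
        if (i > 0 && j > 0) {
          double prev = D[idx(g, i - 1, j - 1)];
          if (prev < INF / 2) {
            int pc = pair_class(mir[i - 1], rs[j - 1]);
            double pen = (pc == 1) ? 0.0 : (pc == 2 ? gu_pen(p, i) : mm_pen(p, i));
            if (prev + pen < best) { best = prev + pen; arg = 0; }
          }
        }
        if (g > 0 && i > 0) { // miRNA position unmatched: missing target base
          double prev = D[idx(g - 1, i - 1, j)];
          if (prev < INF / 2 && prev + mm_pen(p, i) < best) {
            best = prev + mm_pen(p, i); arg = 1;
          }
        }
        if (g > 0 && j > 0) { // bulged target base
          int zpos = (i < n) ? i + 1 : n;
          double prev = D[idx(g - 1, i, j - 1)];
          if (prev < INF / 2 && prev + mm_pen(p, zpos) < best) {
            best = prev + mm_pen(p, zpos); arg = 2;
          }
        }
        D[idx(g, i, j)] = best;
        bt[idx(g, i, j)] = arg;
      }
    }
  }
  double best = INF; int bestg = -1;
  for (int g = 0; g <= G; ++g)
    if (D[idx(g, n, m)] < best) { best = D[idx(g, n, m)]; bestg = g; }
  if (aln != nullptr && bestg >= 0) {
    std::string out;
    double ssub = 0, nsub = 0;
    int gg = bestg, i = n, j = m, gaps = 0;
    while (i > 0 || j > 0) {
      signed char a = bt[idx(gg, i, j)];
      if (a == 0) {
        int pc = pair_class(mir[i - 1], rs[j - 1]);
        bool strict = (i >= p.strict_lo && i <= p.strict_hi);
        double pen = (pc == 1) ? 0.0 : (pc == 2 ? gu_pen(p, i) : mm_pen(p, i));
        out.push_back(pc == 1 ? '|' : (pc == 2 ? 'o' : 'x'));
        (strict ? ssub : nsub) += pen;
        --i; --j;
      } else if (a == 1) {
        bool strict = (i >= p.strict_lo && i <= p.strict_hi);
        (strict ? ssub : nsub) += mm_pen(p, i);
        out.push_back('-');
        --i; --gg; ++gaps;
      } else if (a == 2) {
        int zpos = (i < n) ? i + 1 : n;
        bool strict = (zpos >= p.strict_lo && zpos <= p.strict_hi);
        (strict ? ssub : nsub) += mm_pen(p, zpos);
        out.push_back('^');
        --j; --gg; ++gaps;
      } else {
        stop("internal error: broken traceback in target scoring");
      }
    }
    std::reverse(out.begin(), out.end());
    *aln = out; *ngaps = gaps; *strict_sub = ssub; *non_sub = nsub;
  }
  return best;
}

// [[Rcpp::export]]
List cpp_target_score(std::string mirna, std::string site,
                      double mm_strict, double gu_strict,
                      double mm_non, double gu_non,
                      int strict_lo, int strict_hi, int max_gaps) {
  std::vector<int> mir = enc_seq(mirna);
  std::string rsite(site.rbegin(), site.rend());
  std::vector<int> rs = enc_seq(rsite);
  ScoreParams p = {mm_strict, gu_strict, mm_non, gu_non,
                   strict_lo, strict_hi, max_gaps};
  std::string aln; int ngaps = 0; double ss = 0, ns = 0;
  double sc = target_dp(mir, rs, p, &aln, &ngaps, &ss, &ns);
  if (sc > INF / 2)
    return List::create(_["score"] = R_PosInf, _["alignment"] = "",
                        _["n_gaps"] = NA_INTEGER,
                        _["strict_penalty"] = NA_REAL,
                        _["nonstrict_penalty"] = NA_REAL);
  return List::create(_["score"] = sc, _["alignment"] = aln,
                      _["n_gaps"] = ngaps,
                      _["strict_penalty"] = ss, _["nonstrict_penalty"] = ns);
}

// Scan a transcript for candidate sites: every window of width |miRNA| +/-
// max_gaps is scored; windows at or under the cutoff are returned.
// [[Rcpp::export]]
DataFrame cpp_scan_targets(std::string mirna, std::string transcript,
                           double cutoff,
                           double mm_strict, double gu_strict,
                           double mm_non, double gu_non,
                           int strict_lo, int strict_hi, int max_gaps) {
  std::vector<int> mir = enc_seq(mirna);
  int n = (int)mir.size(), L = (int)transcript.size();
  ScoreParams p = {mm_strict, gu_strict, mm_non, gu_non,
                   strict_lo, strict_hi, max_gaps};
  std::vector<int> starts, ends, gapsv;
  std::vector<double> scores, ssub, nsub;
  std::vector<std::string> alns;
  for (int w = std::max(1, n - max_gaps); w <= n + max_gaps; ++w) {
    for (int s = 0; s + w <= L; ++s) {
      std::string win = transcript.substr(s, w);
      std::string rwin(win.rbegin(), win.rend());
      std::vector<int> rs = enc_seq(rwin);
      double sc = target_dp(mir, rs, p, nullptr, nullptr, nullptr, nullptr);
      if (sc <= cutoff + 1e-9) {
        std::string aln; int ng = 0; double a = 0, b = 0;
        target_dp(mir, rs, p, &aln, &ng, &a, &b);
        starts.push_back(s + 1); ends.push_back(s + w);
        scores.push_back(sc); gapsv.push_back(ng);
        ssub.push_back(a); nsub.push_back(b); alns.push_back(aln);
      }
    }
  }
  return DataFrame::create(_["start"] = starts, _["end"] = ends,
                           _["score"] = scores, _["n_gaps"] = gapsv,
                           _["strict_penalty"] = ssub,
                           _["nonstrict_penalty"] = nsub,
                           _["alignment"] = alns,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Intermolecular duplex minimum free energy, one-loop model
// ---------------------------------------------------------------------------
// Structure = one helix, optionally interrupted by a single interior
// loop/bulge with affine cost loop_open + loop_ext * (unpaired bases),
// total unpaired per loop <= max_loop. Stacking energies from a 6x6
// nearest-neighbour table indexed by pair type of consecutive pairs.
// Antiparallel: position i in `a` (5'->3') pairs position j in `b`, with j
// decreasing as i increases; b is reversed internally.

// [[Rcpp::export]]
List cpp_duplex_energy(std::string a, std::string b, NumericMatrix stacks,
                       double loop_open, double loop_ext, int max_loop) {
  std::vector<int> A = enc_seq(a);
  std::string brev(b.rbegin(), b.rend());
  std::vector<int> B = enc_seq(brev);
  int n = (int)A.size(), m = (int)B.size();
  if (n == 0 || m == 0) stop("empty sequence in duplex computation");
  std::vector<double> H((size_t)n * m, INF), G((size_t)n * m, INF);
  // parents: pH/pG = previous cell index or -1 (helix opened here);
  // fromH: 1 = G equals H at this cell, 0 = G stack-extends G, 2 = loop from H
  std::vector<int> pG((size_t)n * m, -1), pH((size_t)n * m, -1);
  std::vector<signed char> fromH((size_t)n * m, 1);
  auto id = [&](int i, int j) { return (size_t)i * m + j; };
  std::vector<int> PT((size_t)n * m, -1);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) PT[id(i, j)] = pair_type(A[i], B[j]);
  double best = 0.0; int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      int pt = PT[id(i, j)];
      if (pt < 0) continue;
      double h = 0.0; // open a fresh helix with this single pair
      int hpar = -1;
      if (i > 0 && j > 0 && PT[id(i - 1, j - 1)] >= 0 &&
          H[id(i - 1, j - 1)] < INF / 2) {
        double v = H[id(i - 1, j - 1)] + stacks(PT[id(i - 1, j - 1)], pt);
        if (v < h) { h = v; hpar = (int)id(i - 1, j - 1); }
      }
      H[id(i, j)] = h;
      pH[id(i, j)] = hpar;
      // G: best with at most one loop
      double g = h; int par = -1; signed char fh = 1;
      if (i > 0 && j > 0 && PT[id(i - 1, j - 1)] >= 0 &&
          G[id(i - 1, j - 1)] < INF / 2) {
        double v = G[id(i - 1, j - 1)] + stacks(PT[id(i - 1, j - 1)], pt);
        if (v < g) { g = v; par = (int)id(i - 1, j - 1); fh = 0; }
      }
      for (int ga = 0; ga <= max_loop; ++ga) {
        for (int gb = (ga == 0 ? 1 : 0); ga + gb <= max_loop; ++gb) {
          int pi = i - 1 - ga, pj = j - 1 - gb;
          if (pi < 0 || pj < 0) break;
          if (H[id(pi, pj)] >= INF / 2) continue;
          double v = H[id(pi, pj)] + loop_open + loop_ext * (ga + gb);
          if (v < g) { g = v; par = (int)id(pi, pj); fh = 2; }
        }
      }
      G[id(i, j)] = g;
      pG[id(i, j)] = par;
      fromH[id(i, j)] = fh;
      if (g < best - 1e-12) { best = g; bi = i; bj = j; }
    }
  }
  if (bi < 0) { // no stabilizing duplex
    return List::create(_["energy"] = 0.0, _["n_pairs"] = 0,
                        _["a_start"] = NA_INTEGER, _["a_end"] = NA_INTEGER,
                        _["b_start"] = NA_INTEGER, _["b_end"] = NA_INTEGER,
                        _["pairs_a"] = IntegerVector(0),
                        _["pairs_b"] = IntegerVector(0));
  }
  // traceback: collect paired positions
  std::vector<int> pa, pb;
  int i = bi, j = bj;
  bool inG = true;
  while (true) {
    pa.push_back(i + 1);            // 1-based in a
    pb.push_back(m - j);            // back to original b coordinates
    int par;
    if (inG) {
      signed char fh = fromH[id(i, j)];
      if (fh == 1) { inG = false; par = pH[id(i, j)]; }
      else if (fh == 0) { par = pG[id(i, j)]; }
      else { inG = false; par = pG[id(i, j)]; } // crossed the loop into H
    } else {
      par = pH[id(i, j)];
    }
    if (par < 0) break;
    i = par / m; j = par % m;
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["energy"] = best, _["n_pairs"] = (int)pa.size(),
                      _["a_start"] = pa.front(), _["a_end"] = pa.back(),
                      _["b_start"] = pb.back(), _["b_end"] = pb.front(),
                      _["pairs_a"] = wrap(pa), _["pairs_b"] = wrap(pb));
}

// Score-only variant used for screening many pairs.
// [[Rcpp::export]]
double cpp_duplex_energy_min(std::string a, std::string b, NumericMatrix stacks,
                             double loop_open, double loop_ext, int max_loop) {
  std::vector<int> A = enc_seq(a);
  std::string brev(b.rbegin(), b.rend());
  std::vector<int> B = enc_seq(brev);
  int n = (int)A.size(), m = (int)B.size();
  if (n == 0 || m == 0) stop("empty sequence in duplex computation");
  std::vector<double> H((size_t)n * m, INF), G((size_t)n * m, INF);
  auto id = [&](int i, int j) { return (size_t)i * m + j; };
  std::vector<int> PT((size_t)n * m, -1);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) PT[id(i, j)] = pair_type(A[i], B[j]);
  double best = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      int pt = PT[id(i, j)];
      if (pt < 0) continue;
      double h = 0.0;
      if (i > 0 && j > 0 && PT[id(i - 1, j - 1)] >= 0 &&
          H[id(i - 1, j - 1)] < INF / 2)
        h = std::min(h, H[id(i - 1, j - 1)] + stacks(PT[id(i - 1, j - 1)], pt));
      H[id(i, j)] = h;
      double g = h;
      if (i > 0 && j > 0 && PT[id(i - 1, j - 1)] >= 0 &&
          G[id(i - 1, j - 1)] < INF / 2)
        g = std::min(g, G[id(i - 1, j - 1)] + stacks(PT[id(i - 1, j - 1)], pt));
      for (int ga = 0; ga <= max_loop; ++ga)
        for (int gb = (ga == 0 ? 1 : 0); ga + gb <= max_loop; ++gb) {
          int pi = i - 1 - ga, pj = j - 1 - gb;
          if (pi < 0 || pj < 0) break;
          if (H[id(pi, pj)] >= INF / 2) continue;
          g = std::min(g, H[id(pi, pj)] + loop_open + loop_ext * (ga + gb));
        }
      G[id(i, j)] = g;
      best = std::min(best, g);
    }
  }
  return best;
}

// ---------------------------------------------------------------------------
// Nussinov base-pair maximization (WC + G:U, minimum hairpin loop)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_nussinov(std::string seq, int min_loop) {
  std::vector<int> S = enc_seq(seq);
  int n = (int)S.size();
  IntegerVector partner(n, 0);
  if (n == 0) return List::create(_["n_pairs"] = 0, _["partner"] = partner);
  std::vector<int> N((size_t)n * n, 0);
  auto id = [&](int i, int j) { return (size_t)i * n + j; };
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = N[id(i + 1, j)];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (pair_class(S[i], S[k]) == 0) continue;
        int v = 1 + (k > i + 1 ? N[id(i + 1, k - 1)] : 0) +
                (k < j ? N[id(k + 1, j)] : 0);
        if (v > best) best = v;
      }
      N[id(i, j)] = best;
    }
  }
  // deterministic traceback (first k achieving the optimum)
  std::vector<std::pair<int, int>> stack;
  stack.push_back({0, n - 1});
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    if (N[id(i, j)] == N[id(i + 1, j)]) { stack.push_back({i + 1, j}); continue; }
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (pair_class(S[i], S[k]) == 0) continue;
      int v = 1 + (k > i + 1 ? N[id(i + 1, k - 1)] : 0) +
              (k < j ? N[id(k + 1, j)] : 0);
      if (v == N[id(i, j)]) {
        partner[i] = k + 1; partner[k] = i + 1;
        if (k > i + 1) stack.push_back({i + 1, k - 1});
        if (k < j) stack.push_back({k + 1, j});
        break;
      }
    }
  }
  return List::create(_["n_pairs"] = N[id(0, n - 1)], _["partner"] = partner);
}
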