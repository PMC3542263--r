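// Numerical core: PSSM window scoring, ZOOPS/OOPS EM, candidate-start
// scoring, dinucleotide-preserving shuffle, and the sequential shuffle-null
// loop behind motif E-values.  Sequences arrive as integer codes
// A=1, C=2, G=3, T=4, N=0; positions touching an N score -Inf.
// All randomness goes through R's RNG so set.seed() governs everything.

#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();
static const double LOG2E = 1.4426950408889634;

static inline double log2d(double x) { return std::log(x) * LOG2E; }

static inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// PSSM stored column-major, 4 x w: S[(b-1) + 4*j]
static inline double score_fwd(const int* s, int i, int w, const double* S) {
  double sc = 0.0;
  for (int j = 0; j < w; ++j) {
    int b = s[i + j];
    if (b == 0) return NEG_INF;
    sc += S[(b - 1) + 4 * j];
  }
  return sc;
}

// score of the reverse-complement read of the window starting at i
static inline double score_rev(const int* s, int i, int w, const double* S) {
  double sc = 0.0;
  for (int j = 0; j < w; ++j) {
    int b = s[i + w - 1 - j];
    if (b == 0) return NEG_INF;
    sc += S[(4 - b) + 4 * j];  // complement: code 5-b, zero-based 4-b
  }
  return sc;
}

// [[Rcpp::export]]
NumericMatrix cpp_score_windows(IntegerVector codes, NumericMatrix pssm,
                                bool both) {
  int w = pssm.ncol(), L = codes.size();
  int m = L - w + 1;
  if (m < 1) return NumericMatrix(0, 2);
  NumericMatrix out(m, 2);
  const double* S = REAL(pssm);
  const int* s = INTEGER(codes);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = score_fwd(s, i, w, S);
    out(i, 1) = both ? score_rev(s, i, w, S) : NEG_INF;
  }
  return out;
}

// ---------------------------------------------------------------- EM core

struct SeqView {
  const int* s;
  int L;
};

struct EMOut {
  std::vector<double> freqs;  // 4*w column-major
  double gamma;
  int iter;
  std::vector<double> obj;          // penalized objective trace (log2 units)
  std::vector<double> post;         // per-entry site-presence posterior
  std::vector<int> best_i;          // 0-based best start (-1 if none)
  std::vector<int> best_str;        // 1 fwd, 2 rev, 0 none
};

// ZOOPS mixture EM; oops=true pins gamma at 1 and removes the no-site branch.
// freqs0 must be strictly positive. Objective = observed-data log2-likelihood
// (relative to an all-background model) plus the Dirichlet smoothing penalty,
// which is non-decreasing across iterations.
static void em_core(const std::vector<SeqView>& Y, int w, const double* q,
                    std::vector<double> freqs0, double gamma, bool gamma_free,
                    double pseudo, int max_iter, double tol, bool both,
                    bool oops, EMOut& res) {
  int N = (int)Y.size();
  std::vector<double> freqs = freqs0;
  std::vector<double> S(4 * w), C(4 * w);
  std::vector<double> sc;  // scratch scores, 2*m
  res.post.assign(N, 0.0);
  res.best_i.assign(N, -1);
  res.best_str.assign(N, 0);
  res.obj.clear();
  double prevJ = NEG_INF;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    for (int j = 0; j < w; ++j)
      for (int b = 0; b < 4; ++b)
        S[b + 4 * j] = log2d(freqs[b + 4 * j] / q[b]);
    std::fill(C.begin(), C.end(), 0.0);
    double LL = 0.0, postsum = 0.0;
    int n_used = 0;
    for (int e = 0; e < N; ++e) {
      int m = Y[e].L - w + 1;
      if (m < 1) continue;  // guarded in R; defensive
      n_used++;
      int npos = both ? 2 * m : m;
      sc.resize(2 * m);
      const int* sq = Y[e].s;
      double umax;
      double u0 = oops ? NEG_INF : log2d(1.0 - gamma);
      double ubase = (oops ? 0.0 : log2d(gamma)) - log2d((double)npos);
      umax = u0;
      for (int i = 0; i < m; ++i) {
        double f = score_fwd(sq, i, w, S.data());
        double r = both ? score_rev(sq, i, w, S.data()) : NEG_INF;
        sc[2 * i] = f;
        sc[2 * i + 1] = r;
        if (f != NEG_INF && ubase + f > umax) umax = ubase + f;
        if (r != NEG_INF && ubase + r > umax) umax = ubase + r;
      }
      if (umax == NEG_INF) continue;  // all windows hit N; no contribution
      double tot = (u0 == NEG_INF) ? 0.0 : std::exp2(u0 - umax);
      double ztot_site = 0.0;
      for (int i = 0; i < 2 * m; ++i) {
        double u = sc[i];
        if (u == NEG_INF) { sc[i] = 0.0; continue; }
        double z = std::exp2(ubase + u - umax);
        sc[i] = z;
        ztot_site += z;
      }
      tot += ztot_site;
      LL += umax + log2d(tot);
      double best = -1.0;
      int bi = -1, bs = 0;
      for (int i = 0; i < m; ++i) {
        for (int str = 0; str < 2; ++str) {
          double z = sc[2 * i + str] / tot;
          if (z <= 0) continue;
          if (z > best) { best = z; bi = i; bs = str + 1; }
          // accumulate expected counts
          if (str == 0) {
            for (int j = 0; j < w; ++j) C[(sq[i + j] - 1) + 4 * j] += z;
          } else {
            for (int j = 0; j < w; ++j) C[(4 - sq[i + w - 1 - j]) + 4 * j] += z;
          }
        }
      }
      double p_site = ztot_site / tot;
      res.post[e] = p_site;
      res.best_i[e] = bi;
      res.best_str[e] = bs;
      postsum += p_site;
    }
    // penalty term at current freqs (MAP objective; keeps trace monotone)
    double pen = 0.0;
    for (int j = 0; j < w; ++j)
      for (int b = 0; b < 4; ++b)
        pen += pseudo * q[b] * log2d(freqs[b + 4 * j]);
    double J = LL + pen;
    res.obj.push_back(J);
    if (it > 0 && J - prevJ < tol) break;
    prevJ = J;
    // M-step
    double nsites = postsum;
    for (int j = 0; j < w; ++j) {
      for (int b = 0; b < 4; ++b) {
        freqs[b + 4 * j] =
            (C[b + 4 * j] + pseudo * q[b]) / (nsites + pseudo);
      }
    }
    if (gamma_free && !oops && n_used > 0) {
      gamma = postsum / n_used;
      if (gamma < 1e-6) gamma = 1e-6;
      if (gamma > 1.0 - 1e-6) gamma = 1.0 - 1e-6;
    }
  }
  res.freqs = freqs;
  res.gamma = oops ? 1.0 : gamma;
  res.iter = (int)res.obj.size();
}

static std::vector<SeqView> as_views(const List& codes) {
  int N = codes.size();
  std::vector<SeqView> Y(N);
  for (int e = 0; e < N; ++e) {
    SEXP el = codes[e];
    Y[e].s = INTEGER(el);
    Y[e].L = Rf_length(el);
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_zoops_em(List codes, NumericMatrix freqs0, NumericVector q,
                  double gamma0, bool gamma_free, double pseudo, int max_iter,
                  double tol, bool both, bool oops) {
  std::vector<SeqView> Y = as_views(codes);
  int w = freqs0.ncol();
  std::vector<double> f0(freqs0.begin(), freqs0.end());
  EMOut res;
  em_core(Y, w, REAL(q), f0, gamma0, gamma_free, pseudo, max_iter, tol, both,
          oops, res);
  NumericMatrix fr(4, w);
  std::copy(res.freqs.begin(), res.freqs.end(), fr.begin());
  return List::create(
      _["freqs"] = fr, _["gamma"] = res.gamma, _["iter"] = res.iter,
      _["obj"] = wrap(res.obj), _["post"] = wrap(res.post),
      _["best_start"] = wrap(res.best_i), _["best_strand"] = wrap(res.best_str));
}

// Cheap pre-scoring of candidate starting subsequences: each candidate word
// becomes a 0.7/0.1 PSSM and is scored as the sum over entries of the
// best-window log2 likelihood ratio (the MEME-style start heuristic).
// words: n x w matrix of codes 1..4.
// [[Rcpp::export]]
NumericVector cpp_score_candidates(List codes, IntegerMatrix words,
                                   NumericVector q, bool both) {
  std::vector<SeqView> Y = as_views(codes);
  int n = words.nrow(), w = words.ncol();
  NumericVector out(n);
  std::vector<double> S(4 * w);
  const double* qq = REAL(q);
  for (int c = 0; c < n; ++c) {
    for (int j = 0; j < w; ++j) {
      int bw = words(c, j);
      for (int b = 0; b < 4; ++b) {
        double p = (b == bw - 1) ? 0.7 : 0.1;
        S[b + 4 * j] = log2d(p / qq[b]);
      }
    }
    double tot = 0.0;
    for (size_t e = 0; e < Y.size(); ++e) {
      int m = Y[e].L - w + 1;
      if (m < 1) continue;
      double best = NEG_INF;
      for (int i = 0; i < m; ++i) {
        double f = score_fwd(Y[e].s, i, w, S.data());
        if (f > best) best = f;
        if (both) {
          double r = score_rev(Y[e].s, i, w, S.data());
          if (r > best) best = r;
        }
      }
      if (best != NEG_INF && best > 0) tot += best;
    }
    out[c] = tot;
  }
  return out;
}

// ------------------------------------------- dinucleotide shuffle (Altschul-
// Erikson): preserves exact dinucleotide counts. Codes 0..4 all treated as
// alphabet symbols, so N placement is preserved in distribution too.
static std::vector<int> dinuc_shuffle_one(const int* s, int L) {
  std::vector<int> out(s, s + L);
  if (L < 4) return out;
  std::vector<std::vector<int>> adj(5);
  for (int i = 0; i + 1 < L; ++i) adj[s[i]].push_back(s[i + 1]);
  int first = s[0], last = s[L - 1];
  std::vector<int> lastEdge(5, -1);
  bool ok = false;
  for (int guard = 0; guard < 2000 && !ok; ++guard) {
    for (int v = 0; v < 5; ++v) {
      lastEdge[v] = -1;
      if (v != last && !adj[v].empty())
        lastEdge[v] = adj[v][rand_int((int)adj[v].size())];
    }
    ok = true;
    for (int v = 0; v < 5 && ok; ++v) {
      if (v == last || adj[v].empty()) continue;
      int cur = v;
      int steps = 0;
      while (cur != last && steps++ < 6) {
        int nxt = (cur == last) ? -1 : lastEdge[cur];
        if (nxt < 0) break;
        cur = nxt;
      }
      if (cur != last) ok = false;
    }
  }
  if (!ok) return out;  // pathological; return unshuffled copy
  for (int v = 0; v < 5; ++v) {
    std::vector<int>& a = adj[v];
    int n = (int)a.size();
    if (n < 2) continue;
    for (int i = n - 1; i > 0; --i) std::swap(a[i], a[rand_int(i + 1)]);
    if (lastEdge[v] >= 0) {
      for (int i = n - 1; i >= 0; --i) {
        if (a[i] == lastEdge[v]) { std::swap(a[i], a[n - 1]); break; }
      }
    }
  }
  std::vector<int> idx(5, 0);
  out[0] = first;
  int cur = first;
  for (int k = 1; k < L; ++k) {
    int t = adj[cur][idx[cur]++];
    out[k] = t;
    cur = t;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_dinuc_shuffle(IntegerVector codes) {
  std::vector<int> out = dinuc_shuffle_one(INTEGER(codes), codes.size());
  return wrap(out);
}

// ---- site-level LLR statistic of a hard-called motif -----------------------
// Builds count matrix from called best sites, smooths, rescans the sites and
// sums their log2-odds. Mirrors the R-side definition used for observed T.
static double hard_T(const std::vector<SeqView>& Y, int w, const double* q,
                     double pseudo, const EMOut& res, bool oops) {
  int N = (int)Y.size();
  std::vector<double> C(4 * w, 0.0);
  int nsites = 0;
  for (int e = 0; e < N; ++e) {
    bool called = oops ? (res.best_i[e] >= 0) : (res.post[e] > 0.5);
    if (!called || res.best_i[e] < 0) continue;
    const int* sq = Y[e].s;
    int i = res.best_i[e];
    bool fwd = (res.best_str[e] == 1);
    bool hasN = false;
    for (int j = 0; j < w; ++j)
      if (sq[i + j] == 0) hasN = true;
    if (hasN) continue;
    for (int j = 0; j < w; ++j) {
      int b = fwd ? sq[i + j] : 5 - sq[i + w - 1 - j];
      C[(b - 1) + 4 * j] += 1.0;
    }
    nsites++;
  }
  if (nsites == 0) return 0.0;
  std::vector<double> S(4 * w);
  for (int j = 0; j < w; ++j)
    for (int b = 0; b < 4; ++b)
      S[b + 4 * j] =
          log2d(((C[b + 4 * j] + pseudo * q[b]) / (nsites + pseudo)) / q[b]);
  double T = 0.0;
  for (int e = 0; e < N; ++e) {
    bool called = oops ? (res.best_i[e] >= 0) : (res.post[e] > 0.5);
    if (!called || res.best_i[e] < 0) continue;
    const int* sq = Y[e].s;
    int i = res.best_i[e];
    double sc = (res.best_str[e] == 1) ? score_fwd(sq, i, w, S.data())
                                       : score_rev(sq, i, w, S.data());
    if (sc != NEG_INF) T += sc;
  }
  return T;
}

// best-window-sum prescore of one candidate word (0.7/0.1 PSSM), mirroring
// cpp_score_candidates for a single word over in-memory views
static double precand_score(const std::vector<SeqView>& Y, const int* word,
                            int w, const double* q, bool both) {
  std::vector<double> S(4 * w);
  for (int j = 0; j < w; ++j)
    for (int b = 0; b < 4; ++b)
      S[b + 4 * j] = log2d(((b == word[j] - 1) ? 0.7 : 0.1) / q[b]);
  double tot = 0.0;
  for (size_t e = 0; e < Y.size(); ++e) {
    int m = Y[e].L - w + 1;
    if (m < 1) continue;
    double best = NEG_INF;
    for (int i = 0; i < m; ++i) {
      double f = score_fwd(Y[e].s, i, w, S.data());
      if (f > best) best = f;
      if (both) {
        double r = score_rev(Y[e].s, i, w, S.data());
        if (r > best) best = r;
      }
    }
    if (best != NEG_INF && best > 0) tot += best;
  }
  return tot;
}

// Shuffle-null sample for the motif E-value. Per replicate: shuffle every
// entry (dinucleotide-preserving), run a single capped EM started from the
// best of `pre_cands` prescored random subsequences, hard-call sites, and
// record the site LLR statistic. Returns the vector of null statistics.
// [[Rcpp::export]]
NumericVector cpp_null_sample(List codes, int w, NumericVector q,
                              double pseudo, double gamma0, int reps,
                              int em_iters, bool both, bool oops,
                              int pre_cands) {
  std::vector<SeqView> Y0 = as_views(codes);
  int N = (int)Y0.size();
  const double* qq = REAL(q);
  NumericVector tvals(reps);
  std::vector<std::vector<int>> shuf(N);
  std::vector<SeqView> Y(N);
  // total window count for uniform start sampling
  long tot_win = 0;
  for (int e = 0; e < N; ++e) {
    int m = Y0[e].L - w + 1;
    if (m > 0) tot_win += m;
  }
  if (tot_win == 0) stop("no sequence long enough for width");
  for (int rep = 0; rep < reps; ++rep) {
    for (int e = 0; e < N; ++e) {
      shuf[e] = dinuc_shuffle_one(Y0[e].s, Y0[e].L);
      Y[e].s = shuf[e].data();
      Y[e].L = (int)shuf[e].size();
    }
    // start from the best-prescored of pre_cands random subsequences
    std::vector<double> f0(4 * w, 0.1);
    bool got = false;
    double best_pre = NEG_INF;
    int n_try = pre_cands < 1 ? 1 : pre_cands;
    for (int tries = 0; tries < n_try + 20 && !got; ++tries) {
      long k = (long)(unif_rand() * tot_win);
      if (k >= tot_win) k = tot_win - 1;
      int e = 0;
      for (; e < N; ++e) {
        int m = Y[e].L - w + 1;
        if (m <= 0) continue;
        if (k < m) break;
        k -= m;
      }
      bool hasN = false;
      for (int j = 0; j < w; ++j)
        if (Y[e].s[k + j] == 0) hasN = true;
      if (hasN) continue;
      double pre = (n_try == 1)
                       ? 0.0
                       : precand_score(Y, Y[e].s + k, w, qq, both);
      if (pre > best_pre || best_pre == NEG_INF) {
        best_pre = pre;
        std::fill(f0.begin(), f0.end(), 0.1);
        for (int j = 0; j < w; ++j) f0[(Y[e].s[k + j] - 1) + 4 * j] = 0.7;
      }
      if (tries >= n_try - 1 && best_pre != NEG_INF) got = true;
    }
    if (!got) { tvals[rep] = 0.0; continue; }
    EMOut res;
    em_core(Y, w, qq, f0, gamma0, true, pseudo, em_iters, 1e-3, both, oops,
            res);
    tvals[rep] = hard_T(Y, w, qq, pseudo, res, oops);
  }
  return tvals;
}

// Exact null distribution of integerized PSSM scores by column-wise
// convolution under order-0 marginals. S_int: 4 x w integer score matrix.
// Returns list(lo, probs) where probs[k] = Pr(S == lo + k - 1).
// [[Rcpp::export]]
List cpp_pssm_convolve(IntegerMatrix S_int, NumericVector q) {
  int w = S_int.ncol();
  long lo = 0, hi = 0;
  std::vector<double> cur(1, 1.0);
  long cur_lo = 0;
  for (int j = 0; j < w; ++j) {
    int clo = S_int(0, j), chi = S_int(0, j);
    for (int b = 1; b < 4; ++b) {
      if (S_int(b, j) < clo) clo = S_int(b, j);
      if (S_int(b, j) > chi) chi = S_int(b, j);
    }
    std::vector<double> nxt(cur.size() + (chi - clo), 0.0);
    for (int b = 0; b < 4; ++b) {
      int off = S_int(b, j) - clo;
      double qb = q[b];
      for (size_t i = 0; i < cur.size(); ++i) nxt[i + off] += cur[i] * qb;
    }
    cur.swap(nxt);
    cur_lo += clo;
  }
  lo = cur_lo;
  hi = cur_lo + (long)cur.size() - 1;
  (void)hi;
  return List::create(_["lo"] = (double)lo, _["probs"] = wrap(cur));
}
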