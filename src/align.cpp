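#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh).
// Gap cost convention: a gap of length L costs gap_open + L * gap_extend,
// i.e. the first gapped column already pays open + extend.
//
// Sequences arrive as 0-based integer codes indexing the scoring matrix S.

struct AlnStats {
  double score;
  int matches, mismatches, gap_opens, cols;
  int qs, qe, ss, se;   // 1-based inclusive, 0 when alignment empty
};

// traceback byte layout:
//   bits 0-1: H origin (0 stop, 1 diag, 2 from E, 3 from F)
//   bit  2  : E extended from E (else opened from H)
//   bit  3  : F extended from F (else opened from H)
static AlnStats gotoh_local(const int *a, const int na, const int *b, const int nb,
                            const double *S, const int nS,
                            const double open, const double ext) {
  const double NEG = -1e30;
  std::vector<double> Hprev(nb + 1, 0.0), Hcur(nb + 1, 0.0);
  std::vector<double> Eprev; // E is row-local
  std::vector<double> F(nb + 1, NEG);
  std::vector<uint8_t> tb((size_t)(na + 1) * (nb + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= na; ++i) {
    double Erow = NEG;
    Hcur[0] = 0.0;
    const int ai = a[i - 1];
    const double *Srow = S + (size_t)ai * nS;
    for (int j = 1; j <= nb; ++j) {
      uint8_t t = 0;
      // E: gap in query (consume b[j])
      double e_open = Hcur[j - 1] - open - ext;
      double e_ext  = Erow - ext;
      if (e_ext > e_open) { Erow = e_ext; t |= 4; } else { Erow = e_open; }
      // F: gap in subject (consume a[i])
      double f_open = Hprev[j] - open - ext;
      double f_ext  = F[j] - ext;
      if (f_ext > f_open) { F[j] = f_ext; t |= 8; } else { F[j] = f_open; }
      // H
      double diag = Hprev[j - 1] + Srow[b[j - 1]];
      double h = 0.0; uint8_t o = 0;
      if (diag > h) { h = diag; o = 1; }
      if (Erow > h) { h = Erow; o = 2; }
      if (F[j] > h) { h = F[j]; o = 3; }
      Hcur[j] = h;
      tb[(size_t)i * (nb + 1) + j] = t | o;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }

  AlnStats st = {best, 0, 0, 0, 0, 0, 0, 0, 0};
  if (best <= 0.0 || bi == 0) return st;

  // traceback
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  st.qe = bi; st.se = bj;
  bool in_gap_e = false, in_gap_f = false;
  while (true) {
    uint8_t t = tb[(size_t)i * (nb + 1) + j];
    if (state == 0) {
      uint8_t o = t & 3;
      if (o == 0) break;
      if (o == 1) {
        st.cols++;
        if (a[i - 1] == b[j - 1]) st.matches++; else st.mismatches++;
        --i; --j;
      } else if (o == 2) {
        state = 1; in_gap_e = true; st.gap_opens++;
      } else {
        state = 2; in_gap_f = true; st.gap_opens++;
      }
    } else if (state == 1) {          // E: consume b[j]
      st.cols++;
      bool extended = (t & 4) != 0;
      --j;
      if (!extended) { state = 0; in_gap_e = false; }
    } else {                          // F: consume a[i]
      st.cols++;
      bool extended = (t & 8) != 0;
      --i;
      if (!extended) { state = 0; in_gap_f = false; }
    }
  }
  (void)in_gap_e; (void)in_gap_f;
  st.qs = i + 1; st.ss = j + 1;
  return st;
}

static List stats_to_list(const AlnStats &st) {
  return List::create(
    _["score"] = st.score, _["matches"] = st.matches,
    _["mismatches"] = st.mismatches, _["gap_opens"] = st.gap_opens,
    _["aligned_length"] = st.cols,
    _["q_start"] = st.qs, _["q_end"] = st.qe,
    _["s_start"] = st.ss, _["s_end"] = st.se);
}

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double gap_open, double gap_extend) {
  if (S.nrow() != S.ncol()) stop("scoring matrix must be square");
  AlnStats st = gotoh_local(INTEGER(a), a.size(), INTEGER(b), b.size(),
                            REAL(S), S.nrow(), gap_open, gap_extend);
  return stats_to_list(st);
}

// Batch mode: ai/bi are 1-based indices into seqs (a list of integer vectors).
// [[Rcpp::export]]
DataFrame sw_batch_cpp(List seqs, IntegerVector ai, IntegerVector bi,
                       NumericMatrix S, double gap_open, double gap_extend) {
  const int n = ai.size();
  if (bi.size() != n) stop("index vectors differ in length");
  NumericVector score(n);
  IntegerVector matches(n), mismatches(n), gapopens(n), cols(n),
    qs(n), qe(n), ss(n), se(n);
  std::vector<IntegerVector> cache(seqs.size());
  for (int k = 0; k < seqs.size(); ++k) cache[k] = seqs[k];
  for (int k = 0; k < n; ++k) {
    const IntegerVector &a = cache[ai[k] - 1];
    const IntegerVector &b = cache[bi[k] - 1];
    AlnStats st = gotoh_local(INTEGER(a), a.size(), INTEGER(b), b.size(),
                              REAL(S), S.nrow(), gap_open, gap_extend);
    score[k] = st.score; matches[k] = st.matches; mismatches[k] = st.mismatches;
    gapopens[k] = st.gap_opens; cols[k] = st.cols;
    qs[k] = st.qs; qe[k] = st.qe; ss[k] = st.ss; se[k] = st.se;
  }
  return DataFrame::create(
    _["score"] = score, _["matches"] = matches, _["mismatches"] = mismatches,
    _["gap_opens"] = gapopens, _["aligned_length"] = cols,
    _["q_start"] = qs, _["q_end"] = qe, _["s_start"] = ss, _["s_end"] = se);
}

// Diagonals (0-based: s_pos - q_pos) of exact k-mer matches of `frag` in
// `tgt`; codes outside 0..3 (ambiguous bases) break k-mers.
// [[Rcpp::export]]
IntegerVector kmer_diagonals_cpp(IntegerVector frag, IntegerVector tgt, int k) {
  const int nf = frag.size(), nt = tgt.size();
  std::vector<int> out;
  if (k <= 0 || k > 31 || nf < k || nt < k) return IntegerVector(0);
  std::unordered_map<uint64_t, std::vector<int> > index;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t key = 0; int run = 0;
  for (int p = 0; p < nt; ++p) {
    int c = tgt[p];
    if (c < 0 || c > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) index[key].push_back(p - k + 1);
  }
  key = 0; run = 0;
  for (int p = 0; p < nf; ++p) {
    int c = frag[p];
    if (c < 0 || c > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      auto it = index.find(key);
      if (it != index.end()) {
        int q0 = p - k + 1;
        for (int s0 : it->second) out.push_back(s0 - q0);
      }
    }
  }
  return wrap(out);
}

// Shared k-mer counts between protein sequences, for hit-candidate screening.
// Returns, for every (i in set_a, j in set_b) sharing >= min_shared distinct
// k-mer types, one row (i, j). Sequences are integer-coded; any code is legal.
// [[Rcpp::export]]
IntegerMatrix kmer_pair_candidates_cpp(List seqs, IntegerVector set_a,
                                       IntegerVector set_b, int k,
                                       int min_shared, int alphabet_size) {
  std::unordered_map<uint64_t, std::vector<int> > index; // kmer -> b indices
  for (int u = 0; u < set_b.size(); ++u) {
    IntegerVector s = seqs[set_b[u] - 1];
    std::vector<bool> seen;
    std::unordered_map<uint64_t, bool> local;
    uint64_t key = 0, base = 1;
    for (int t = 0; t < k; ++t) base *= (uint64_t)alphabet_size;
    int run = 0;
    for (int p = 0; p < s.size(); ++p) {
      key = (key * (uint64_t)alphabet_size + (uint64_t)s[p]) % base;
      if (++run >= k && !local[key]) { local[key] = true; index[key].push_back(u); }
    }
    (void)seen;
  }
  std::vector<int> ra, rb;
  for (int v = 0; v < set_a.size(); ++v) {
    IntegerVector s = seqs[set_a[v] - 1];
    std::unordered_map<int, int> counts; // b index -> shared kmer types
    std::unordered_map<uint64_t, bool> local;
    uint64_t key = 0, base = 1;
    for (int t = 0; t < k; ++t) base *= (uint64_t)alphabet_size;
    int run = 0;
    for (int p = 0; p < s.size(); ++p) {
      key = (key * (uint64_t)alphabet_size + (uint64_t)s[p]) % base;
      if (++run >= k && !local[key]) {
        local[key] = true;
        auto it = index.find(key);
        if (it != index.end()) for (int u : it->second) counts[u]++;
      }
    }
    for (auto &kv : counts)
      if (kv.second >= min_shared) { ra.push_back(set_a[v]); rb.push_back(set_b[kv.first]); }
  }
  IntegerMatrix out(ra.size(), 2);
  for (size_t r = 0; r < ra.size(); ++r) { out(r, 0) = ra[r]; out(r, 1) = rb[r]; }
  return out;
}
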