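#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty, tracking the
// maximum number of identical aligned pairs ("matches") among all
// optimal-score alignments.  Identity is matches / length of the shorter
// sequence (CD-HIT convention).
//
// The (score, matches) pair is maximised lexicographically by packing it
// into one 32-bit integer: score * 2048 + matches.  Scoring constants are
// held in quarter units (SCALE = 4), so scores are exact for constants on a
// 0.25 grid; sequences must be shorter than 2048 residues.

static const int SCALE = 4;    // quarter-unit scoring grid
static const int MB = 2048;    // matches base; also the sequence-length cap

struct NwBuf {
  std::vector<int> s_prev, s_cur;
};

static inline void encode(const std::string& s, std::vector<int>& out) {
  if (s.size() >= (size_t)MB)
    stop("sequences longer than %d residues are not supported", MB - 1);
  out.resize(s.size());
  for (size_t i = 0; i < s.size(); ++i) out[i] = (unsigned char)s[i];
}

static inline int to_scaled(double x, const char* what) {
  double s = x * SCALE;
  if (std::fabs(s - std::lround(s)) > 1e-9)
    stop("%s must lie on a 0.25 grid", what);
  return (int)std::lround(s);
}

// Core DP on packed ints.  If dir != NULL it is filled with traceback
// directions (1 = diag, 2 = up/gap-in-b, 3 = left/gap-in-a), row-major on
// the (la+1) x (lb+1) grid.
static int nw_core(const std::vector<int>& a, const std::vector<int>& b,
                   int match, int mismatch, int gap,
                   NwBuf& buf, std::vector<signed char>* dir) {
  const int la = (int)a.size(), lb = (int)b.size();
  const int G = gap * MB; // a gap never adds a match
  const int DM = match * MB + 1;
  const int DX = mismatch * MB;
  std::vector<int>& prev = buf.s_prev;
  std::vector<int>& cur = buf.s_cur;
  prev.resize(lb + 1);
  cur.resize(lb + 1);
  if (dir) dir->assign((size_t)(la + 1) * (lb + 1), 0);

  prev[0] = 0;
  for (int j = 1; j <= lb; ++j) {
    prev[j] = prev[j - 1] + G;
    if (dir) (*dir)[j] = 3;
  }
  for (int i = 1; i <= la; ++i) {
    cur[0] = prev[0] + G;
    if (dir) (*dir)[(size_t)i * (lb + 1)] = 2;
    const int ai = a[i - 1];
    const int* bp = b.data();
    if (dir) {
      signed char* drow = dir->data() + (size_t)i * (lb + 1);
      for (int j = 1; j <= lb; ++j) {
        int d = prev[j - 1] + (ai == bp[j - 1] ? DM : DX);
        int u = prev[j] + G;
        int l = cur[j - 1] + G;
        int best = d;
        signed char bd = 1;
        if (u > best) { best = u; bd = 2; }
        if (l > best) { best = l; bd = 3; }
        cur[j] = best;
        drow[j] = bd;
      }
    } else {
      for (int j = 1; j <= lb; ++j) {
        int d = prev[j - 1] + (ai == bp[j - 1] ? DM : DX);
        int u = prev[j] + G;
        int l = cur[j - 1] + G;
        int best = d > u ? d : u;
        if (l > best) best = l;
        cur[j] = best;
      }
    }
    std::swap(prev, cur);
  }
  return prev[lb];
}

static inline void unpack(int packed, double& score, int& matches) {
  int m = ((packed % MB) + MB) % MB;
  matches = m;
  score = (double)((packed - m) / MB) / SCALE;
}

// [[Rcpp::export]]
List nw_identity_cpp(std::string a, std::string b,
                     double match, double mismatch, double gap) {
  if (a.empty() || b.empty())
    stop("pairwise identity requires non-empty sequences");
  std::vector<int> ia, ib;
  encode(a, ia); encode(b, ib);
  NwBuf buf;
  int packed = nw_core(ia, ib, to_scaled(match, "match"),
                       to_scaled(mismatch, "mismatch"),
                       to_scaled(gap, "gap"), buf, NULL);
  double score; int matches;
  unpack(packed, score, matches);
  int denom = (int)std::min(a.size(), b.size());
  return List::create(_["score"] = score,
                      _["n_matches"] = matches,
                      _["denominator"] = denom,
                      _["identity"] = (double)matches / denom);
}

static inline double pair_identity(const std::vector<int>& a, const std::vector<int>& b,
                                   int m, int mm, int g, NwBuf& buf) {
  double score; int matches;
  unpack(nw_core(a, b, m, mm, g, buf, NULL), score, matches);
  return (double)matches / std::min(a.size(), b.size());
}

// Equal-length ungapped matches: a cheap lower bound on alignment matches
// (the gapped optimum can only add matches), used to reject >= cutoff pairs
// without the full DP.
static inline int hamming_matches(const std::vector<int>& a, const std::vector<int>& b) {
  int n = 0;
  for (size_t i = 0; i < a.size(); ++i) n += (a[i] == b[i]);
  return n;
}

static inline bool at_least_cutoff(const std::vector<int>& a, const std::vector<int>& b,
                                   double cutoff, int m, int mm, int g, NwBuf& buf) {
  size_t den = std::min(a.size(), b.size());
  if (a.size() == b.size() &&
      hamming_matches(a, b) >= cutoff * (double)den - 1e-9)
    return true;
  return pair_identity(a, b, m, mm, g, buf) >= cutoff;
}

static void encode_all(const CharacterVector& seqs, std::vector<std::vector<int> >& out) {
  out.resize(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if (s.empty()) stop("pairwise identity requires non-empty sequences");
    encode(s, out[i]);
  }
}

// [[Rcpp::export]]
NumericMatrix identity_cross_cpp(CharacterVector a, CharacterVector b,
                                 double match, double mismatch, double gap) {
  std::vector<std::vector<int> > ea, eb;
  encode_all(a, ea); encode_all(b, eb);
  const int m = to_scaled(match, "match");
  const int mm = to_scaled(mismatch, "mismatch");
  const int g = to_scaled(gap, "gap");
  NumericMatrix out(a.size(), b.size());
  NwBuf buf;
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    for (R_xlen_t j = 0; j < b.size(); ++j)
      out(i, j) = pair_identity(ea[i], eb[j], m, mm, g, buf);
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix identity_self_cpp(CharacterVector a,
                                double match, double mismatch, double gap) {
  std::vector<std::vector<int> > ea;
  encode_all(a, ea);
  const int m = to_scaled(match, "match");
  const int mm = to_scaled(mismatch, "mismatch");
  const int g = to_scaled(gap, "gap");
  NumericMatrix out(a.size(), a.size());
  NwBuf buf;
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    out(i, i) = 1.0;
    for (R_xlen_t j = i + 1; j < a.size(); ++j) {
      double id = pair_identity(ea[i], ea[j], m, mm, g, buf);
      out(i, j) = id;
      out(j, i) = id;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Greedy incremental clustering: sequences arrive in their given (already
// sorted) order; a sequence is kept iff its identity to every kept sequence
// is < cutoff.  Returns a logical keep mask.
// [[Rcpp::export]]
LogicalVector greedy_keep_cpp(CharacterVector seqs, double cutoff,
                              double match, double mismatch, double gap) {
  std::vector<std::vector<int> > es;
  encode_all(seqs, es);
  const int m = to_scaled(match, "match");
  const int mm = to_scaled(mismatch, "mismatch");
  const int g = to_scaled(gap, "gap");
  const R_xlen_t n = seqs.size();
  LogicalVector keep(n);
  std::vector<int> kept_idx;
  NwBuf buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    bool ok = true;
    for (size_t k = 0; k < kept_idx.size(); ++k) {
      if (at_least_cutoff(es[i], es[kept_idx[k]], cutoff, m, mm, g, buf)) {
        ok = false;
        break;
      }
    }
    keep[i] = ok;
    if (ok) kept_idx.push_back((int)i);
    if ((i & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return keep;
}

// For each sequence of b: keep iff identity to every sequence of a is < cutoff.
// [[Rcpp::export]]
LogicalVector keep_between_cpp(CharacterVector b, CharacterVector a, double cutoff,
                               double match, double mismatch, double gap) {
  std::vector<std::vector<int> > ea, eb;
  encode_all(a, ea); encode_all(b, eb);
  const int m = to_scaled(match, "match");
  const int mm = to_scaled(mismatch, "mismatch");
  const int g = to_scaled(gap, "gap");
  LogicalVector keep(b.size());
  NwBuf buf;
  for (R_xlen_t i = 0; i < b.size(); ++i) {
    bool ok = true;
    for (size_t j = 0; j < ea.size(); ++j) {
      if (at_least_cutoff(eb[i], ea[j], cutoff, m, mm, g, buf)) {
        ok = false;
        break;
      }
    }
    keep[i] = ok;
    if ((i & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return keep;
}

// Accumulate aligned hit residues onto query positions.  For every hit the
// optimal (max-matches tie-broken) global alignment to the query is traced
// back; each hit residue aligned to a query position increments the count of
// that residue (rows = the alphabet, in the order given) at that position.
// Gap-aligned positions contribute nothing.
// [[Rcpp::export]]
IntegerMatrix profile_counts_cpp(std::string query, CharacterVector hits,
                                 std::string alphabet,
                                 double match, double mismatch, double gap) {
  const int la = (int)query.size();
  const int na = (int)alphabet.size();
  int code[256];
  for (int i = 0; i < 256; ++i) code[i] = -1;
  for (int i = 0; i < na; ++i) code[(unsigned char)alphabet[i]] = i;

  IntegerMatrix counts(na, la);
  std::vector<int> iq;
  encode(query, iq);
  const int m = to_scaled(match, "match");
  const int mm = to_scaled(mismatch, "mismatch");
  const int g = to_scaled(gap, "gap");
  NwBuf buf;
  std::vector<signed char> dir;
  for (R_xlen_t h = 0; h < hits.size(); ++h) {
    std::string hs = as<std::string>(hits[h]);
    std::vector<int> ih;
    encode(hs, ih);
    const int lb = (int)ih.size();
    nw_core(iq, ih, m, mm, g, buf, &dir);
    int i = la, j = lb;
    while (i > 0 || j > 0) {
      signed char d = dir[(size_t)i * (lb + 1) + j];
      if (d == 1) {
        int c = code[(unsigned char)hs[j - 1]];
        if (c >= 0) counts(c, i - 1)++;
        --i; --j;
      } else if (d == 2) {
        --i;
      } else {
        --j;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return counts;
}
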