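#include <Rcpp.h>
#include <cctype>
#include <string>
#include <vector>
using namespace Rcpp;

// Ends-free pairwise alignment with affine gap costs: all four terminal gap
// runs are unpenalised (the alignment may start and end anywhere; its
// interior is global). A gap run of length L costs gap_open + L * gap_ext.
// Identity = matches / (alignment columns of the aligned region + the
// smaller side's unaligned base count): a pure length surplus of the longer
// sequence (containment, ragged extraction) does not depress identity, but a
// short spurious overlap between dissimilar sequences does. The ends-free
// start/end is what lets a chimera's short parent segment align to its
// parent's prefix without paying for the unrelated remainder.

static const double NEG = -1e18;

enum State { ST_M = 0, ST_X = 1, ST_Y = 2, ST_START = 3 };

struct AlnOut {
  double score;
  double identity;
  int matches;
  int columns;
  std::vector<bool> match_a; // per position of a: aligned to an equal base?
  std::string a_aln;
  std::string b_aln;
};

static AlnOut nw_semiglobal(const std::string& a_in, const std::string& b_in,
                            double match, double mismatch,
                            double gap_open, double gap_ext,
                            bool want_strings) {
  std::string a(a_in), b(b_in);
  for (auto& c : a) c = std::toupper(static_cast<unsigned char>(c));
  for (auto& c : b) c = std::toupper(static_cast<unsigned char>(c));
  const int n = a.size(), m = b.size();
  AlnOut out;
  out.match_a.assign(n, false);
  if (n == 0 || m == 0) {
    out.score = 0.0; out.identity = 0.0; out.matches = 0; out.columns = 0;
    return out;
  }
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  // traceback pointers: predecessor state for each cell of each matrix
  std::vector<signed char> pM((n + 1) * W, ST_START), pX((n + 1) * W, ST_START),
      pY((n + 1) * W, ST_START);
  const double go_ge = gap_open + gap_ext;

  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int ij = i * W + j, dg = (i - 1) * W + (j - 1);
      const int up = (i - 1) * W + j, lf = i * W + (j - 1);
      // M: ai aligned to bj. Predecessor preference M > X > Y > START;
      // a free start is allowed at any cell (leading gaps in either or both
      // sequences cost nothing).
      double s = (ai == b[j - 1]) ? match : mismatch;
      double best = M[dg]; signed char ptr = ST_M;
      if (X[dg] > best) { best = X[dg]; ptr = ST_X; }
      if (Y[dg] > best) { best = Y[dg]; ptr = ST_Y; }
      if (0.0 > best) { best = 0.0; ptr = ST_START; }
      M[ij] = best + s; pM[ij] = ptr;
      // X: gap in b (consumes a[i])
      best = M[up] - go_ge; ptr = ST_M;
      if (X[up] - gap_ext > best) { best = X[up] - gap_ext; ptr = ST_X; }
      if (Y[up] - go_ge > best) { best = Y[up] - go_ge; ptr = ST_Y; }
      X[ij] = best; pX[ij] = ptr;
      // Y: gap in a (consumes b[j])
      best = M[lf] - go_ge; ptr = ST_M;
      if (X[lf] - go_ge > best) { best = X[lf] - go_ge; ptr = ST_X; }
      if (Y[lf] - gap_ext > best) { best = Y[lf] - gap_ext; ptr = ST_Y; }
      Y[ij] = best; pY[ij] = ptr;
    }
  }

  // endpoint: best cell anywhere (free trailing gaps in both sequences);
  // fixed row-major scan with strict improvement for determinism. The empty
  // alignment (score 0) is the fallback when nothing scores positive.
  double bestScore = 0.0; int bi = 0, bj = 0; signed char bstate = ST_START;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int ij = i * W + j;
      double v = M[ij]; signed char st = ST_M;
      if (X[ij] > v) { v = X[ij]; st = ST_X; }
      if (Y[ij] > v) { v = Y[ij]; st = ST_Y; }
      if (v > bestScore) { bestScore = v; bi = i; bj = j; bstate = st; }
    }
  }

  out.score = bestScore;
  // traceback
  int i = bi, j = bj; signed char st = bstate;
  int matches = 0, columns = 0;
  std::string aa, bb;
  while (st != ST_START) {
    const int ij = i * W + j;
    if (st == ST_M) {
      ++columns;
      if (a[i - 1] == b[j - 1]) { ++matches; out.match_a[i - 1] = true; }
      if (want_strings) { aa.push_back(a[i - 1]); bb.push_back(b[j - 1]); }
      st = pM[ij]; --i; --j;
    } else if (st == ST_X) {
      ++columns;
      if (want_strings) { aa.push_back(a[i - 1]); bb.push_back('-'); }
      st = pX[ij]; --i;
    } else { // ST_Y
      ++columns;
      if (want_strings) { aa.push_back('-'); bb.push_back(b[j - 1]); }
      st = pY[ij]; --j;
    }
  }
  out.matches = matches;
  out.columns = columns;
  // unaligned overhang of each sequence (i, j are at the alignment start;
  // bi, bj at its end)
  const int ua = i + (n - bi), ub = j + (m - bj);
  const int denom = columns + std::min(ua, ub);
  out.identity = denom > 0 ? static_cast<double>(matches) / denom : 0.0;
  if (want_strings) {
    out.a_aln.assign(aa.rbegin(), aa.rend());
    out.b_aln.assign(bb.rbegin(), bb.rend());
  }
  return out;
}

// [[Rcpp::export]]
List cpp_nw_align(std::string a, std::string b, double match = 1.0,
                  double mismatch = -1.0, double gap_open = 2.0,
                  double gap_ext = 1.0) {
  AlnOut r = nw_semiglobal(a, b, match, mismatch, gap_open, gap_ext, true);
  LogicalVector ma(r.match_a.size());
  for (size_t i = 0; i < r.match_a.size(); ++i) ma[i] = r.match_a[i] ? 1 : 0;
  return List::create(
      _["score"] = r.score, _["identity"] = r.identity,
      _["matches"] = r.matches, _["columns"] = r.columns,
      _["match_a"] = ma, _["a_aln"] = r.a_aln, _["b_aln"] = r.b_aln);
}

// [[Rcpp::export]]
double cpp_nw_identity(std::string a, std::string b, double match = 1.0,
                       double mismatch = -1.0, double gap_open = 2.0,
                       double gap_ext = 1.0) {
  // canonical argument order: identity is symmetric even when co-optimal
  // alignments with different match counts exist
  if (b < a) std::swap(a, b);
  return nw_semiglobal(a, b, match, mismatch, gap_open, gap_ext, false).identity;
}

// [[Rcpp::export]]
NumericVector cpp_identity_many(std::string query, CharacterVector refs,
                                double match = 1.0, double mismatch = -1.0,
                                double gap_open = 2.0, double gap_ext = 1.0) {
  const int k = refs.size();
  NumericVector out(k);
  for (int i = 0; i < k; ++i) {
    std::string a = query, b = as<std::string>(refs[i]);
    if (b < a) std::swap(a, b);
    out[i] = nw_semiglobal(a, b, match, mismatch, gap_open, gap_ext,
                           false).identity;
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_query_match(std::string query, std::string ref,
                              double match = 1.0, double mismatch = -1.0,
                              double gap_open = 2.0, double gap_ext = 1.0) {
  AlnOut r = nw_semiglobal(query, ref, match, mismatch, gap_open, gap_ext, false);
  LogicalVector ma(r.match_a.size());
  for (size_t i = 0; i < r.match_a.size(); ++i) ma[i] = r.match_a[i] ? 1 : 0;
  return ma;
}

// ---------------------------------------------------------------------------
// Paired-end overlap merging. r2 is supplied already reverse-complemented
// (s2rc) with its quality string reversed (q2r). Candidate overlap lengths L
// run from min(len1, len2) down to min_overlap; each is scored as
// matches - mismatches over the overlap; the highest score wins, ties going
// to the longest overlap. Consensus: agreement -> base with q = min(q1+q2, 41);
// disagreement -> higher-quality base with q = |q1-q2|; quality tie -> r1's
// base at q = 2.

// [[Rcpp::export]]
List cpp_merge_pair(std::string s1, std::string q1, std::string s2rc,
                    std::string q2r, int min_overlap = 5,
                    double max_mm_frac = 0.25) {
  const int l1 = s1.size(), l2 = s2rc.size();
  const int lmax = std::min(l1, l2);
  if (lmax < min_overlap) {
    return List::create(_["status"] = "no_overlap");
  }
  double best_score = NEG; int best_L = -1;
  for (int L = lmax; L >= min_overlap; --L) {
    int sc = 0;
    const int off = l1 - L;
    for (int k = 0; k < L; ++k) sc += (s1[off + k] == s2rc[k]) ? 1 : -1;
    if (static_cast<double>(sc) > best_score) { best_score = sc; best_L = L; }
  }
  const int L = best_L, off = l1 - L;
  int n_mm = 0;
  std::string cons(L, 'N'), consq(L, '!');
  for (int k = 0; k < L; ++k) {
    const char c1 = s1[off + k], c2 = s2rc[k];
    const int p1 = q1[off + k] - 33, p2 = q2r[k] - 33;
    if (c1 == c2) {
      cons[k] = c1;
      consq[k] = static_cast<char>(std::min(p1 + p2, 41) + 33);
    } else {
      ++n_mm;
      if (p1 > p2) { cons[k] = c1; consq[k] = static_cast<char>(p1 - p2 + 33); }
      else if (p2 > p1) { cons[k] = c2; consq[k] = static_cast<char>(p2 - p1 + 33); }
      else { cons[k] = c1; consq[k] = static_cast<char>(2 + 33); }
    }
  }
  const double mm_frac = static_cast<double>(n_mm) / L;
  if (mm_frac > max_mm_frac) {
    return List::create(_["status"] = "too_many_mismatches",
                        _["overlap"] = L, _["mismatch_frac"] = mm_frac);
  }
  std::string seq = s1.substr(0, off) + cons + s2rc.substr(L);
  std::string qual = q1.substr(0, off) + consq + q2r.substr(L);
  return List::create(_["status"] = "merged", _["seq"] = seq, _["qual"] = qual,
                      _["overlap"] = L, _["n_corrected"] = n_mm,
                      _["mismatch_frac"] = mm_frac);
}

// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector s1, CharacterVector q1,
                     CharacterVector s2rc, CharacterVector q2r,
                     int min_overlap = 5, double max_mm_frac = 0.25) {
  const int n = s1.size();
  CharacterVector status(n), seq(n), qual(n);
  IntegerVector overlap(n), n_corrected(n);
  NumericVector mm_frac(n);
  for (int i = 0; i < n; ++i) {
    List r = cpp_merge_pair(as<std::string>(s1[i]), as<std::string>(q1[i]),
                            as<std::string>(s2rc[i]), as<std::string>(q2r[i]),
                            min_overlap, max_mm_frac);
    std::string st = as<std::string>(r["status"]);
    status[i] = st;
    if (st == "merged") {
      seq[i] = as<std::string>(r["seq"]);
      qual[i] = as<std::string>(r["qual"]);
      overlap[i] = as<int>(r["overlap"]);
      n_corrected[i] = as<int>(r["n_corrected"]);
      mm_frac[i] = as<double>(r["mismatch_frac"]);
    } else {
      seq[i] = NA_STRING; qual[i] = NA_STRING;
      overlap[i] = (st == "no_overlap") ? NA_INTEGER : as<int>(r["overlap"]);
      n_corrected[i] = NA_INTEGER;
      mm_frac[i] = (st == "no_overlap") ? NA_REAL : as<double>(r["mismatch_frac"]);
    }
  }
  return List::create(_["status"] = status, _["seq"] = seq, _["qual"] = qual,
                      _["overlap"] = overlap, _["n_corrected"] = n_corrected,
                      _["mismatch_frac"] = mm_frac);
}
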