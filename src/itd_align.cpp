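#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Alignment scoring follows the package convention: match/mismatch scores,
// affine gaps costing gap_open + k * gap_ext for a k-base gap, and free
// soft clipping of read ends (local alignment).  All coordinates reported
// back to R are 1-based inclusive.

static const int NEG = INT_MIN / 4;

struct AlnRes {
  int score = 0;
  int ref_start = 0, ref_end = 0;   // 1-based inclusive, 0 if unaligned
  int q_start = 0, q_end = 0;
  std::string cigar = "*";
};

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default:  c = 'N'; break;
    }
  }
  return r;
}

static void rle_append(std::string& out, char op, int n) {
  if (n > 0) { out += std::to_string(n); out += op; }
}

// Smith-Waterman with affine gaps (Gotoh) and full traceback.
// E: gap in the read (consumes reference, CIGAR 'D');
// F: gap in the reference (consumes read, CIGAR 'I').
static AlnRes sw_core(const std::string& q, const std::string& r,
                      int match, int mismatch, int gap_open, int gap_ext) {
  const int m = (int)q.size(), n = (int)r.size();
  AlnRes res;
  if (m == 0 || n == 0) return res;
  std::vector<int> H((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> E((size_t)(m + 1) * (n + 1), NEG);
  std::vector<int> F((size_t)(m + 1) * (n + 1), NEG);
  const size_t W = (size_t)n + 1;
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const char qi = q[i - 1];
    for (int j = 1; j <= n; ++j) {
      const size_t c = (size_t)i * W + j, up = c - W, lf = c - 1, dg = up - 1;
      int e = std::max(E[lf] + gap_ext, H[lf] + gap_open + gap_ext);
      int f = std::max(F[up] + gap_ext, H[up] + gap_open + gap_ext);
      int s = H[dg] + (qi == r[j - 1] ? match : mismatch);
      int h = std::max(0, std::max(s, std::max(e, f)));
      E[c] = e; F[c] = f; H[c] = h;
      if (h > best) { best = h; bi = i; bj = j; }  // first max in row-major order
    }
  }
  if (best <= 0) return res;
  res.score = best;
  res.q_end = bi; res.ref_end = bj;
  std::string ops;  // reversed
  int i = bi, j = bj; char state = 'H';
  while (i > 0 && j > 0) {
    const size_t c = (size_t)i * W + j;
    if (state == 'H') {
      if (H[c] == 0) break;
      int s = H[c - W - 1] + (q[i - 1] == r[j - 1] ? match : mismatch);
      if (H[c] == s) { ops += 'M'; --i; --j; }
      else if (H[c] == E[c]) state = 'E';
      else state = 'F';
    } else if (state == 'E') {
      ops += 'D';
      if (E[c] == H[c - 1] + gap_open + gap_ext) state = 'H';
      --j;
    } else {
      ops += 'I';
      if (F[c] == H[c - W] + gap_open + gap_ext) state = 'H';
      --i;
    }
  }
  res.q_start = i + 1; res.ref_start = j + 1;
  std::string cig;
  rle_append(cig, 'S', res.q_start - 1);
  char cur = 0; int run = 0;
  for (auto it = ops.rbegin(); it != ops.rend(); ++it) {
    if (*it == cur) ++run;
    else { rle_append(cig, cur, run); cur = *it; run = 1; }
  }
  rle_append(cig, cur, run);
  rle_append(cig, 'S', m - res.q_end);
  res.cigar = cig;
  return res;
}

// ---- k-mer index over the reference (2-bit encoding) --------------------

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

static inline int base2(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2;
               case 'T': return 3; default: return -1; }
}

static bool encode_kmer(const std::string& s, int pos, int k, uint64_t& out) {
  uint64_t h = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2(s[pos + i]);
    if (b < 0) return false;
    h = (h << 2) | (uint64_t)b;
  }
  out = h;
  return true;
}

static KmerIndex build_index(const std::string& r, int k) {
  KmerIndex ix;
  for (int p = 0; p + k <= (int)r.size(); ++p) {
    uint64_t h;
    if (encode_kmer(r, p, k, h)) ix[h].push_back(p);
  }
  return ix;
}

static std::vector<int> seed_diagonals(const std::string& q, const KmerIndex& ix,
                                       int k, int step) {
  std::vector<int> d;
  for (int o = 0; o + k <= (int)q.size(); o += step) {
    uint64_t h;
    if (!encode_kmer(q, o, k, h)) continue;
    KmerIndex::const_iterator it = ix.find(h);
    if (it != ix.end())
      for (size_t t = 0; t < it->second.size(); ++t) d.push_back(it->second[t] - o);
  }
  std::sort(d.begin(), d.end());
  d.erase(std::unique(d.begin(), d.end()), d.end());
  return d;
}

// Align one oriented read: full DP on small problems, seeded windows otherwise
// (falling back to full DP when no seed hits).
static AlnRes align_one(const std::string& q, const std::string& r, const KmerIndex& ix,
                        int match, int mismatch, int gap_open, int gap_ext,
                        int k, int step, double full_max_cells) {
  const double cells = (double)(q.size() + 1) * (double)(r.size() + 1);
  if (cells <= full_max_cells)
    return sw_core(q, r, match, mismatch, gap_open, gap_ext);
  std::vector<int> diags = seed_diagonals(q, ix, k, step);
  if (diags.empty()) return AlnRes();  // no seed on a large reference: unaligned
  const int pad = 24, gap = 16;
  AlnRes best;
  size_t i = 0;
  while (i < diags.size()) {
    size_t j = i;
    while (j + 1 < diags.size() && diags[j + 1] - diags[j] <= gap) ++j;
    int ws = std::max(0, diags[i] - pad);
    int we = std::min((int)r.size(), diags[j] + (int)q.size() + pad);
    if (we > ws) {
      AlnRes a = sw_core(q, r.substr(ws, we - ws), match, mismatch, gap_open, gap_ext);
      if (a.score > best.score) {
        if (a.ref_start > 0) { a.ref_start += ws; a.ref_end += ws; }
        best = a;
      }
    }
    i = j + 1;
  }
  return best;
}

// [[Rcpp::export]]
List cpp_align_batch(CharacterVector reads, std::string ref,
                     int match, int mismatch, int gap_open, int gap_ext,
                     int k, int step, double full_max_cells, bool both_strands) {
  const int n = reads.size();
  KmerIndex ix = build_index(ref, k);
  IntegerVector score(n), ref_start(n), ref_end(n), q_start(n), q_end(n);
  CharacterVector cigar(n), strand(n), oriented(n);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(reads[i]);
    AlnRes fw = align_one(q, ref, ix, match, mismatch, gap_open, gap_ext,
                          k, step, full_max_cells);
    bool use_rc = false;
    std::string qr;
    if (both_strands) {
      qr = revcomp(q);
      AlnRes rc = align_one(qr, ref, ix, match, mismatch, gap_open, gap_ext,
                            k, step, full_max_cells);
      if (rc.score > fw.score) { fw = rc; use_rc = true; }
    }
    score[i] = fw.score; ref_start[i] = fw.ref_start; ref_end[i] = fw.ref_end;
    q_start[i] = fw.q_start; q_end[i] = fw.q_end;
    cigar[i] = fw.cigar; strand[i] = use_rc ? "-" : "+";
    oriented[i] = use_rc ? qr : q;
  }
  return List::create(_["score"] = score, _["ref_start"] = ref_start,
                      _["ref_end"] = ref_end, _["q_start"] = q_start,
                      _["q_end"] = q_end, _["cigar"] = cigar,
                      _["strand"] = strand, _["oriented_seq"] = oriented);
}

// [[Rcpp::export]]
List cpp_sw_align(std::string read, std::string ref,
                  int match, int mismatch, int gap_open, int gap_ext) {
  AlnRes a = sw_core(read, ref, match, mismatch, gap_open, gap_ext);
  return List::create(_["score"] = a.score, _["ref_start"] = a.ref_start,
                      _["ref_end"] = a.ref_end, _["q_start"] = a.q_start,
                      _["q_end"] = a.q_end, _["cigar"] = a.cigar);
}

// Best ungapped placement of a clipped subsequence inside a reference window,
// allowing a short non-templated prefix (right clips) or suffix (left clips)
// to be skipped.  Preference: highest identity, then fewest skipped bases,
// then leftmost window offset.
// [[Rcpp::export]]
List cpp_match_clip(std::string clip, std::string window, bool right_side,
                    int max_skip, int min_len, double min_identity) {
  const int m = (int)clip.size(), w = (int)window.size();
  int best_skip = -1, best_off = -1, best_mm = -1, best_len = 0;
  double best_id = -1.0;
  for (int s = 0; s <= max_skip && m - s >= min_len; ++s) {
    const int qlen = m - s;
    const char* qp = clip.data() + (right_side ? s : 0);
    for (int off = 0; off + qlen <= w; ++off) {
      int mm = 0;
      const int allowed = (int)((1.0 - min_identity) * qlen) + 1;
      const char* wp = window.data() + off;
      for (int t = 0; t < qlen; ++t) {
        if (qp[t] != wp[t] && ++mm > allowed) break;
      }
      double id = 1.0 - (double)mm / qlen;
      if (id > best_id + 1e-12) {
        best_id = id; best_skip = s; best_off = off; best_mm = mm; best_len = qlen;
      }
    }
  }
  bool found = best_id >= min_identity;
  return List::create(_["found"] = found, _["skip"] = best_skip,
                      _["offset"] = best_off + 1, _["qlen"] = best_len,
                      _["mismatches"] = best_mm, _["identity"] = best_id);
}

// Minimum-mismatch ungapped placement of each read against a reference,
// over both strands, using seeded diagonals with a brute-force fallback.
// Returns -1 when the read does not fit inside the reference.
static int ungapped_best_mm(const std::string& q, const std::string& r,
                            const KmerIndex& ix, int k, int step) {
  const int m = (int)q.size(), n = (int)r.size();
  if (m > n) return -1;
  std::vector<int> diags = seed_diagonals(q, ix, k, step);
  int best = m + 1;
  if (diags.empty()) {
    for (int d = 0; d + m <= n; ++d) {
      int mm = 0;
      for (int t = 0; t < m && mm < best; ++t) if (q[t] != r[d + t]) ++mm;
      if (mm < best) best = mm;
    }
  } else {
    for (size_t i = 0; i < diags.size(); ++i) {
      int d = std::min(std::max(diags[i], 0), n - m);
      int mm = 0;
      for (int t = 0; t < m && mm < best; ++t) if (q[t] != r[d + t]) ++mm;
      if (mm < best) best = mm;
    }
  }
  return best;
}

// [[Rcpp::export]]
IntegerVector cpp_score_reads_ungapped(CharacterVector reads, std::string ref,
                                       int k, int step) {
  const int n = reads.size();
  KmerIndex ix = build_index(ref, k);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(reads[i]);
    int fw = ungapped_best_mm(q, ref, ix, k, step);
    int rc = ungapped_best_mm(revcomp(q), ref, ix, k, step);
    int best;
    if (fw < 0) best = rc;
    else if (rc < 0) best = fw;
    else best = std::min(fw, rc);
    out[i] = best;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}
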