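// Compiled kernels: k-mer seeded gapless mapper, end-extension consensus,
// glocal (overhang-tolerant) alignment, and telomere-run scanning.
// All coordinates are 0-based half-open on the contig forward strand.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;  // N or anything else: never indexed, always a mismatch
  }
}

static inline char compbase(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'N': return 'N';
    default:  return 'N';
  }
}

static std::string revcomp1(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = compbase(c);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(seqs[i])) { out[i] = NA_STRING; continue; }
    out[i] = revcomp1(as<std::string>(seqs[i]));
  }
  return out;
}

// Hamming distance of equal-length string pairs (vectorized, recycled b).
// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string x = as<std::string>(a[i % a.size()]);
    std::string y = as<std::string>(b[i % b.size()]);
    if (x.size() != y.size()) stop("cpp_hamming: unequal lengths at element %d", (int)(i + 1));
    int d = 0;
    for (size_t j = 0; j < x.size(); ++j) if (x[j] != y[j]) ++d;
    out[i] = d;
  }
  return out;
}

// ---------------------------------------------------------------------------
// k-mer index + seeded gapless mapping
// ---------------------------------------------------------------------------

struct SeedIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> map;  // kmer -> (contig, pos)
};

static void index_contigs(const std::vector<std::string>& contigs, int k, SeedIndex& idx) {
  idx.k = k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t ci = 0; ci < contigs.size(); ++ci) {
    const std::string& s = contigs[ci];
    if ((int)s.size() < k) continue;
    uint64_t kmer = 0;
    int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
      if (++run >= k)
        idx.map[kmer].emplace_back((int32_t)ci, (int32_t)(i + 1 - k));
    }
  }
}

struct Placement {
  int32_t contig, start;   // start may be negative (overhang) for lenient mode
  bool fwd;
  int matches, mism, overlap;
};

// Evaluate a candidate placement of (oriented) read at `start` on contig `c`.
static bool eval_placement(const std::string& contig, const std::string& read,
                           int32_t start, bool require_full,
                           double min_identity, double min_frac,
                           int max_mismatch, Placement& out) {
  int L = (int)read.size(), clen = (int)contig.size();
  int from = std::max(0, (int)start);
  int to = std::min(clen, (int)start + L);
  int overlap = to - from;
  if (overlap <= 0) return false;
  if (require_full && (start < 0 || start + L > clen)) return false;
  if ((double)overlap / L < min_frac) return false;
  int mm = 0;
  for (int p = from; p < to; ++p) {
    char cb = contig[p], rb = read[p - start];
    if (cb != rb || cb == 'N' || rb == 'N') ++mm;
  }
  if (mm > max_mismatch) return false;
  if ((double)(overlap - mm) / overlap < min_identity) return false;
  out.start = start; out.matches = overlap - mm; out.mism = mm; out.overlap = overlap;
  return true;
}

static bool better(const Placement& a, const Placement& b) {
  // true if a strictly better than b: most matches, fewest mismatches,
  // lowest contig index, lowest coordinate, forward strand first
  if (a.matches != b.matches) return a.matches > b.matches;
  if (a.mism != b.mism) return a.mism < b.mism;
  if (a.contig != b.contig) return a.contig < b.contig;
  if (a.start != b.start) return a.start < b.start;
  return a.fwd && !b.fwd;
}

// Map reads against contigs. Contigs must already be ordered by id (ties in
// the best-placement rule break toward the lower index). Returns 1-based read
// and contig indices; start/end are 0-based half-open clipped to the contig.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector contigs, CharacterVector reads, int k,
                        double min_identity, double min_aligned_frac,
                        int max_mismatch, bool require_full, int seed_stride) {
  std::vector<std::string> ctg(contigs.size());
  for (R_xlen_t i = 0; i < contigs.size(); ++i) ctg[i] = as<std::string>(contigs[i]);
  SeedIndex idx;
  index_contigs(ctg, k, idx);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  std::vector<int> o_read, o_contig, o_start, o_end, o_mm, o_overlap;
  std::vector<bool> o_fwd;

  std::unordered_set<uint64_t> seen;
  for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    int L = (int)fwd.size();
    Placement best; bool have = false;
    if (L >= k) {
      std::string rev = revcomp1(fwd);
      for (int strand = 0; strand < 2; ++strand) {
        const std::string& r = strand == 0 ? fwd : rev;
        seen.clear();
        uint64_t kmer = 0; int run = 0;
        int last_taken = -1000000;
        for (int i = 0; i < L; ++i) {
          int b = base2bit(r[i]);
          if (b < 0) { run = 0; kmer = 0; continue; }
          kmer = ((kmer << 2) | (uint64_t)b) & mask;
          if (++run < k) continue;
          int off = i + 1 - k;  // k-mer start within read
          if (off - last_taken < seed_stride && off + k != L) continue;
          auto it = idx.map.find(kmer);
          if (it == idx.map.end()) continue;
          last_taken = off;
          for (auto& hit : it->second) {
            int32_t start = hit.second - off;
            uint64_t key = ((uint64_t)(uint32_t)hit.first << 33) |
                           ((uint64_t)(uint32_t)(start + 1000) << 1) | (uint64_t)strand;
            if (!seen.insert(key).second) continue;
            Placement p; p.contig = hit.first; p.fwd = (strand == 0);
            if (eval_placement(ctg[hit.first], r, start, require_full,
                               min_identity, min_aligned_frac, max_mismatch, p)) {
              if (!have || better(p, best)) { best = p; have = true; }
            }
          }
        }
      }
    }
    if (have) {
      int clen = (int)ctg[best.contig].size();
      o_read.push_back((int)ri + 1);
      o_contig.push_back(best.contig + 1);
      o_start.push_back(std::max(0, (int)best.start));
      o_end.push_back(std::min(clen, (int)best.start + L));
      o_mm.push_back(best.mism);
      o_overlap.push_back(best.overlap);
      o_fwd.push_back(best.fwd);
    }
  }

  R_xlen_t n = o_read.size();
  CharacterVector strand(n);
  for (R_xlen_t i = 0; i < n; ++i) strand[i] = o_fwd[i] ? "+" : "-";
  return DataFrame::create(
    _["read"] = wrap(o_read), _["contig"] = wrap(o_contig),
    _["start"] = wrap(o_start), _["end"] = wrap(o_end),
    _["strand"] = strand, _["n_mismatch"] = wrap(o_mm),
    _["overlap"] = wrap(o_overlap), _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// End extension by per-column majority vote
// ---------------------------------------------------------------------------

// Extend past the right edge of `end_seq` using forward-oriented candidate
// reads. A read is used at its best offset (fewest mismatches over its
// overlap with end_seq, ties to longest overlap, then leftmost) provided the
// overlap is >= min_overlap with <= max_mm mismatches. Columns beyond the end
// are appended while votes >= min_support and a strict-majority base exists.
// [[Rcpp::export]]
List cpp_extend_end(std::string end_seq, CharacterVector reads, int max_mm,
                    int min_overlap, int min_support, int max_ext) {
  int W = (int)end_seq.size();
  std::vector<std::array<int, 4>> votes(max_ext, {0, 0, 0, 0});
  int n_used = 0;
  for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
    std::string r = as<std::string>(reads[ri]);
    int L = (int)r.size();
    int best_o = -1, best_mm = max_mm + 1, best_ov = -1;
    int lo = std::max(0, W - L);          // full-overlap offset
    int hi = W - min_overlap;             // minimal-overlap offset
    for (int o = lo; o <= hi; ++o) {
      int ov = std::min(L, W - o);
      if (ov < min_overlap) continue;
      int mm = 0;
      for (int j = 0; j < ov; ++j) {
        char a = end_seq[o + j], b = r[j];
        if (a != b || a == 'N' || b == 'N') { if (++mm > max_mm) break; }
      }
      if (mm > max_mm) continue;
      if (mm < best_mm || (mm == best_mm && ov > best_ov)) {
        best_mm = mm; best_ov = ov; best_o = o;
      }
    }
    if (best_o < 0) continue;
    ++n_used;
    // overhanging bases vote: read position best_ov + c maps to extension column c
    for (int c = 0; best_ov + c < L && c < max_ext; ++c) {
      int b = base2bit(r[best_ov + c]);
      if (b >= 0) votes[c][b]++;
    }
  }
  std::string ext;
  std::vector<int> support;
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  for (int c = 0; c < max_ext; ++c) {
    int tot = votes[c][0] + votes[c][1] + votes[c][2] + votes[c][3];
    if (tot < min_support) break;
    int bi = 0;
    for (int b = 1; b < 4; ++b) if (votes[c][b] > votes[c][bi]) bi = b;
    if (2 * votes[c][bi] <= tot) break;  // strict majority required
    ext.push_back(BASES[bi]);
    support.push_back(votes[c][bi]);
  }
  return List::create(_["ext"] = ext, _["support"] = wrap(support),
                      _["n_used"] = n_used);
}

// ---------------------------------------------------------------------------
// Glocal (overhang-tolerant) gapless alignment of query against target
// ---------------------------------------------------------------------------

// Best placement of q on t (forward only; caller handles strands): scans all
// offsets with >= min_overlap columns, maximizing matching bases.
// Returns offset (q start relative to t, may be negative), overlap, matches.
// [[Rcpp::export]]
List cpp_glocal(std::string q, std::string t, int min_overlap) {
  int ql = (int)q.size(), tl = (int)t.size();
  int best_off = 0, best_ov = 0, best_m = -1;
  for (int off = -(ql - min_overlap); off <= tl - min_overlap; ++off) {
    int from = std::max(0, off), to = std::min(tl, off + ql);
    int ov = to - from;
    if (ov < min_overlap) continue;
    int m = 0;
    for (int p = from; p < to; ++p) {
      char a = t[p], b = q[p - off];
      if (a == b && a != 'N') ++m;
    }
    if (m > best_m) { best_m = m; best_ov = ov; best_off = off; }
  }
  return List::create(_["offset"] = best_off, _["overlap"] = best_ov,
                      _["matches"] = std::max(0, best_m));
}

// ---------------------------------------------------------------------------
// Telomere run scanning at contig ends
// ---------------------------------------------------------------------------

// Longest run starting at position s matching the periodic repetition of
// `unit` at phase p, allowing max_mm_per20 mismatches per complete 20 bp of
// run. A run must end on a matching base, so chance matches beyond a repeat
// boundary cannot drag the run into flanking sequence.
static int phased_run(const std::string& s, int start, const std::string& unit,
                      int phase, int max_mm_per20) {
  int u = (int)unit.size(), n = (int)s.size();
  int mm = 0, best = 0, consec = 0;
  for (int i = 0; start + i < n; ++i) {
    char expect = unit[(phase + i) % u];
    bool match = (s[start + i] == expect);
    if (match) ++consec; else { ++mm; consec = 0; }
    int L = i + 1;
    int allowed = max_mm_per20 * (L / 20);
    // a run must end in >= 4 consecutive repeat bases (one homopolymer
    // block), so chance matches in flanking sequence cannot extend it
    if (match && mm <= allowed && (consec >= 4 || consec == L)) best = L;
    if (mm > allowed + 3 * max_mm_per20) break;  // hopeless: give up
  }
  return best;
}

static int scan_left(const std::string& s, const std::string& unit,
                     int end_window, int max_mm_per20, int min_run) {
  int u = (int)unit.size();
  int best = 0;
  for (int st = 0; st <= end_window && st < (int)s.size(); ++st)
    for (int p = 0; p < u; ++p) {
      int L = phased_run(s, st, unit, p, max_mm_per20);
      if (L > best) best = L;
    }
  return best >= min_run ? best : 0;
}

// Telomere run lengths at the left and right end of seq. Each end is scanned
// for both the C-rich unit phase and its reverse complement, so contigs in
// either strand orientation classify symmetrically.
// [[Rcpp::export]]
IntegerVector cpp_telo_runs(std::string seq, std::string unit, int end_window,
                            int max_mm_per20, int min_run) {
  std::string runit = revcomp1(unit);
  std::string rseq = revcomp1(seq);
  int left = std::max(scan_left(seq, unit, end_window, max_mm_per20, min_run),
                      scan_left(seq, runit, end_window, max_mm_per20, min_run));
  int right = std::max(scan_left(rseq, unit, end_window, max_mm_per20, min_run),
                       scan_left(rseq, runit, end_window, max_mm_per20, min_run));
  return IntegerVector::create(left, right);
}

// Maximal leading run matching the periodic repetition of unit starting at
// phase 0 (exact match; whole and partial units). Vectorized over reads.
// [[Rcpp::export]]
IntegerVector cpp_telo_prefix(CharacterVector seqs, std::string unit) {
  int u = (int)unit.size();
  R_xlen_t n = seqs.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int L = 0;
    while (L < (int)s.size() && s[L] == unit[L % u]) ++L;
    out[i] = L;
  }
  return out;
}
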