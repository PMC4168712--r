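#pragma once

#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <string>
#include <vector>

// Nucleotide codes used throughout the engine.
//   0 = terminator sentinel, 1..4 = A,C,G,T, 5 = N / anything else.
// N is deliberately outside the searchable query alphabet: a query base that
// is not A/C/G/T can never extend an exact match, and reference N (code 5)
// never equals a query code, so no seed crosses an N.
static const int OCC_CHK = 64; // occurrence checkpoint stride (BWT rows)

inline int code_base(char ch) {
  switch (ch) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 3;
    case 'T': case 't': return 4;
    default: return 5;
  }
}

// query code: 1..4 searchable, -1 never matches anything
inline int qcode(char ch) {
  int c = code_base(ch);
  return c == 5 ? -1 : c;
}

inline int comp_code(int c) { return (c >= 1 && c <= 4) ? 5 - c : c; }

inline char decode_base(int c) {
  static const char tab[] = "$ACGTN";
  return (c >= 0 && c <= 5) ? tab[c] : 'N';
}

// Lightweight non-owning view over the index components stored in an R list.
struct FMView {
  const uint8_t* text;   // doubled text + terminator, codes 0..5, length n
  long long n;           // 2G + 1
  long long G;           // forward genome length
  const int* sa;         // full suffix array, length n
  const uint8_t* bwt;    // BWT of the doubled text, length n
  long long C[8];        // first-occurrence table: C[c] = #symbols < c
  const int* occ;        // checkpointed counts, (n/OCC_CHK + 1) x 6 row-major
  const int* starts;     // 0-based start of each sequence in forward text
  const int* seqlen;     // per-sequence lengths
  int nseq;
};

FMView make_view(const Rcpp::List& idx);

// count of symbol c in bwt[0, i)
inline long long fm_rank(const FMView& f, int c, long long i) {
  long long r = i / OCC_CHK;
  long long cnt = f.occ[r * 6 + c];
  for (long long j = r * OCC_CHK; j < i; ++j)
    if (f.bwt[j] == c) ++cnt;
  return cnt;
}

// one backward-search step on inclusive interval [b, e]; false if empty
inline bool fm_step(const FMView& f, int c, long long& b, long long& e) {
  long long nb = f.C[c] + fm_rank(f, c, b);
  long long ne = f.C[c] + fm_rank(f, c, e + 1) - 1;
  if (nb > ne) return false;
  b = nb; e = ne;
  return true;
}

struct MatchRL { long long b, e; int matched; };

// Suffix extension right-to-left from read position `right` (0-based),
// keeping the last non-empty interval.
inline MatchRL match_rl(const FMView& f, const std::vector<int>& q,
                        int right, long long max_len) {
  MatchRL best{0, f.n - 1, 0};
  long long b = 0, e = f.n - 1;
  int m = 0;
  for (int i = right; i >= 0 && m < max_len; --i) {
    int c = q[i];
    if (c < 1 || c > 4) break;
    long long nb = b, ne = e;
    if (!fm_step(f, c, nb, ne)) break;
    b = nb; e = ne; ++m;
    best = MatchRL{b, e, m};
  }
  return best;
}

// Leftmost-to-right extension from `start` via backward search on the
// reverse complement (the doubled text is closed under reverse complement,
// so occurrence existence is preserved). Returns length only.
inline int match_lr(const FMView& f, const std::vector<int>& q,
                    int start, long long max_len) {
  long long b = 0, e = f.n - 1;
  int m = 0;
  int qlen = (int)q.size();
  for (int i = start; i < qlen && m < max_len; ++i) {
    int c = q[i];
    if (c < 1 || c > 4) break;
    if (!fm_step(f, comp_code(c), b, e)) break;
    ++m;
  }
  return m;
}

// Resolve BWT row -> (sequence id, forward leftmost coordinate, strand).
// strand: 0 = '+', 1 = '-'. Returns false for hits spanning the
// forward/reverse junction or a boundary between concatenated sequences.
inline bool fm_locate(const FMView& f, long long row, int mlen,
                      int& seqid, long long& gpos, int& strand) {
  long long p = f.sa[row];
  long long g;
  if (p + mlen <= f.G) { strand = 0; g = p; }
  else if (p >= f.G && p + mlen <= 2 * f.G) { strand = 1; g = 2 * f.G - p - mlen; }
  else return false;
  int lo = 0, hi = f.nseq - 1, j = 0;
  while (lo <= hi) {
    int mid = (lo + hi) / 2;
    if ((long long)f.starts[mid] <= g) { j = mid; lo = mid + 1; }
    else hi = mid - 1;
  }
  if (g + mlen > (long long)f.starts[j] + (long long)f.seqlen[j]) return false;
  seqid = j; gpos = g;
  return true;
}

// One exact seed match. rpos is the 0-based offset of the seed's leftmost
// base in the read *as given* ('+' orientation); for '-'-strand hits the
// aligned-orientation offset is R - rpos - len.
struct Seed {
  int rpos;
  int len;
  long long gpos; // 0-based forward leftmost base of the match
  int strand;     // 0 '+', 1 '-'
  int seqid;
};

void seed_read(const FMView& f, const std::vector<int>& q, int k, int P,
               std::vector<Seed>& out);

inline std::vector<int> encode_query(const std::string& s) {
  std::vector<int> q(s.size());
  for (size_t i = 0; i < s.size(); ++i) q[i] = qcode(s[i]);
  return q;
}

// ---- banded gap alignment ------------------------------------------------
enum GapMode { GAP_GLOBAL = 0, GAP_FREE_REF_START = 1, GAP_FREE_REF_END = 2 };

struct GapAln {
  bool ok;
  int dist;
  int ref_consumed;     // reference bases covered by the path
  std::string ops;      // one char per op: M / I / D (left to right)
};

GapAln band_align(const uint8_t* ref, int rlen, const int* read, int mlen,
                  int d, int mode);

// ---- tag table -----------------------------------------------------------
struct SeedInfo { int len; int rpos; long long gpos; };

struct TagSlot {
  long long tag;
  int strand;
  long long serial;  // 0 = never written
  long long score;
  std::vector<SeedInfo> seeds;
};

class TagTable {
public:
  TagTable(int capacity, int t);
  void advance();
  void grant(long long tag, int strand, int len, int rpos, long long gpos);
  long long serial() const { return serial_; }
  int t() const { return t_; }
  // slots of the current top list, best first
  std::vector<const TagSlot*> top() const;
  const TagSlot* find(long long tag, int strand) const;

private:
  int cap_, t_;
  long long serial_;
  std::vector<TagSlot> slots_;
  std::vector<int> top_; // slot indices, kept in ranked order
  size_t hash_slot(long long tag, int strand) const;
  bool ranks_before(int a, int b) const;
  void update_top(int slot_idx);
};

// ---- candidate alignment -------------------------------------------------
struct CigOp { char op; int len; };

struct Candidate {
  bool ok;
  int seqid;
  long long pos;        // 0-based forward leftmost coordinate
  int strand;           // 0 '+', 1 '-'
  std::vector<CigOp> cigar;
  int edit;
  long long tag_score;
  long long tag_id;
};

// Greedy consistent anchor chain over one tag record's seeds
// (aligned-orientation read offsets). Returns indices into `seeds`,
// ordered by read position.
std::vector<int> anchor_chain(const std::vector<SeedInfo>& seeds, int d);

Candidate align_candidate(const FMView& f, const std::vector<int>& q_aligned,
                          const TagSlot& slot, int e, int d);

std::string cigar_string(const std::vector<CigOp>& cig);
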